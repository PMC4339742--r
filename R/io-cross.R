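# R/qtl "csvr" (rotated CSV) cross files: columns are individuals, rows
# are phenotypes followed by markers.  Phenotype rows leave the chr and
# position cells empty; marker rows carry chromosome, cM position and
# one genotype code per individual.  An "id" phenotype row holds the
# individual names, as read.cross() expects.

# code dialect: written A/H/B, "-" missing, D = not-BB, C = not-AA
CSVR_OUT <- c(A = "A", H = "H", B = "B", notB = "D", notA = "C")
CSVR_IN <- c(A = "A", H = "H", B = "B", D = "notB", C = "notA",
             "-" = NA, "*" = NA, "NA" = NA)

#' Write a cross to an R/qtl csvr file
#'
#' Genotypes are emitted as `A`/`H`/`B` with `-` for missing; F2
#' semi-informative calls use the dominant-marker codes `D` (not `B`)
#' and `C` (not `A`).  `notH` has no csvr representation and is written
#' as missing (a message reports the count).  cM positions are written
#' to 6 decimals.
#'
#' @param cross a [make_cross()] object.
#' @param path output file path.
#' @export
write_cross_csvr <- function(cross, path) {
  g <- cross$geno
  n_noth <- sum(g == "notH", na.rm = TRUE)
  if (n_noth > 0)
    message(n_noth, " 'notH' call(s) have no csvr code; written as missing")
  codes <- matrix(CSVR_OUT[g], nrow = nrow(g), dimnames = dimnames(g))
  codes[is.na(codes)] <- "-"
  lines <- paste(c("id", "", "", colnames(g)), collapse = ",")
  if (!is.null(cross$pheno)) {
    ph <- cross$pheno
    lines <- c(lines, vapply(seq_len(nrow(ph)), function(i) {
      paste(c(rownames(ph)[i], "", "",
              format(ph[i, ], trim = TRUE, digits = 15)), collapse = ",")
    }, ""))
  }
  map <- cross$map
  lines <- c(lines, vapply(seq_len(nrow(map)), function(i) {
    paste(c(map$marker[i], map$chr[i],
            formatC(map$pos[i], format = "f", digits = 6),
            codes[map$marker[i], ]), collapse = ",")
  }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cross from an R/qtl csvr file
#'
#' Accepts genotype codes `A`, `H`, `B`, `D` (not `B`), `C` (not `A`)
#' and the missing symbols `-`, `*`, `NA` or an empty cell.  An `id`
#' phenotype row, if present, names the individuals.
#'
#' @param path csvr file path.
#' @param cross_type cross type to stamp on the result (the csvr layout
#'   does not record it).
#' @param reorder if `TRUE`, markers out of cM order within a chromosome
#'   are sorted by position; if `FALSE` (default) they are an error.
#' @return a `cross` object.
#' @export
read_cross_csvr <- function(path, cross_type = "riself", reorder = FALSE) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop2("empty file: ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  # strsplit drops trailing empty fields; pad to the modal width
  width <- max(lengths(fields))
  fields <- lapply(fields, function(f) c(f, rep("", width - length(f))))
  n_ind <- width - 3L
  if (n_ind < 2) stop2("csvr file must have at least 2 individual columns")

  is_pheno <- vapply(fields, function(f) f[2] == "" && f[3] == "", TRUE)
  ind_ids <- paste0("ind", seq_len(n_ind))
  pheno <- NULL
  if (any(is_pheno)) {
    prows <- fields[is_pheno]
    pnames <- vapply(prows, `[[`, "", 1L)
    if (anyDuplicated(pnames))
      stop2("duplicated phenotype id(s) in csvr file")
    id_row <- which(pnames == "id")
    if (length(id_row)) {
      ind_ids <- prows[[id_row[1]]][-(1:3)]
      prows <- prows[-id_row]
      pnames <- pnames[-id_row]
    }
    if (length(prows)) {
      vals <- t(vapply(prows, function(f) {
        suppressWarnings(as.numeric(ifelse(f[-(1:3)] %in% c("", "NA", "*", "-"),
                                           NA, f[-(1:3)])))
      }, numeric(n_ind)))
      pheno <- matrix(vals, nrow = length(pnames),
                      dimnames = list(pnames, ind_ids))
    }
  }

  mrows <- fields[!is_pheno]
  if (length(mrows) == 0L) stop2("no marker rows in ", path)
  mk <- vapply(mrows, `[[`, "", 1L)
  chr <- vapply(mrows, `[[`, "", 2L)
  pos_chr <- vapply(mrows, `[[`, "", 3L)
  pos <- suppressWarnings(as.numeric(pos_chr))
  if (anyNA(pos))
    stop2("non-numeric cM position for marker(s): ",
          paste(mk[is.na(pos)], collapse = ", "))
  raw <- t(vapply(mrows, function(f) f[-(1:3)], character(n_ind)))
  known <- raw %in% names(CSVR_IN) | raw == ""
  if (!all(known))
    stop2("unknown genotype symbol(s): ",
          paste(unique(raw[!known]), collapse = ", "))
  geno <- matrix(unname(CSVR_IN[ifelse(raw == "", "-", raw)]),
                 nrow = length(mk), dimnames = list(mk, ind_ids))

  ord <- order(match(chr, unique(chr)), pos)
  if (!identical(ord, seq_along(mk))) {
    if (!reorder)
      stop2("markers out of cM order within a chromosome; ",
            "use reorder = TRUE to sort by position")
    mk <- mk[ord]; chr <- chr[ord]; pos <- pos[ord]
    geno <- geno[ord, , drop = FALSE]
  }
  make_cross(geno, genetic_map(mk, chr, pos), cross_type = cross_type,
             pheno = pheno)
}
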