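#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per marker and columns
#' `marker`, `chr`, `pos` (cM) and optionally `bp` (1-based physical
#' position).  Markers are stored in map order: grouped by chromosome
#' with non-decreasing cM positions starting at >= 0.
#'
#' @param marker character vector of globally unique marker ids.
#' @param chr chromosome name per marker.
#' @param pos cM position per marker (non-decreasing within chromosome).
#' @param bp optional physical position in bp per marker (`NA` allowed).
#' @return a `genetic_map` (data.frame subclass).
#' @export
genetic_map <- function(marker, chr, pos, bp = NULL) {
  m <- data.frame(marker = as.character(marker), chr = as.character(chr),
                  pos = as.numeric(pos), stringsAsFactors = FALSE)
  if (!is.null(bp)) m$bp <- as.numeric(bp)
  if (anyDuplicated(m$marker))
    stop2("duplicated marker id(s): ",
          paste(unique(m$marker[duplicated(m$marker)]), collapse = ", "))
  if (any(m$pos < 0)) stop2("cM positions must be >= 0")
  for (cc in unique(m$chr)) {
    p <- m$pos[m$chr == cc]
    if (is.unsorted(p)) stop2("cM positions not non-decreasing on chromosome ", cc)
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map: ", nrow(x), " markers on ",
      length(unique(x$chr)), " chromosome(s), total length ",
      round(map_length(x), 1), " cM\n", sep = "")
  invisible(x)
}

#' Total map length (sum of per-chromosome spans)
#' @param map a `genetic_map`.
#' @export
map_length <- function(map) {
  sum(tapply(map$pos, map$chr, function(p) diff(range(p))))
}

#' Construct a cross object
#'
#' Bundles a genotype matrix (markers x individuals, codes `"A"`, `"H"`,
#' `"B"`, semi-informative `"notA"`/`"notH"`/`"notB"`, `NA` = missing),
#' its genetic map, optional molecular phenotypes and optional
#' per-individual environment labels.  The marker sets of genotypes and
#' map must be identical and are stored in map order.
#'
#' @param geno character matrix of genotype calls, markers in rows.
#' @param map a [genetic_map()] covering exactly the rows of `geno`.
#' @param cross_type one of `"riself"` (RIL by selfing), `"bc"`, `"f2"`.
#' @param pheno optional numeric phenotype matrix (phenotypes x individuals).
#' @param env optional character vector of environment labels, one per
#'   individual.
#' @return an object of class `cross`.
#' @export
make_cross <- function(geno, map, cross_type = c("riself", "bc", "f2"),
                       pheno = NULL, env = NULL) {
  cross_type <- match.arg(cross_type)
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)))
  if (!setequal(rownames(geno), map$marker))
    stop2("marker sets of genotypes and map differ")
  geno <- geno[map$marker, , drop = FALSE]
  valid <- c(full_codes("f2"), SEMI_CODES)
  bad <- setdiff(unique(geno[!is.na(geno)]), valid)
  if (length(bad))
    stop2("unknown genotype code(s): ", paste(bad, collapse = ", "))
  if (!is.null(pheno)) {
    stopifnot(is.matrix(pheno))
    if (!identical(colnames(pheno), colnames(geno)))
      stop2("phenotype individuals do not match genotype individuals")
  }
  if (!is.null(env)) {
    if (length(env) != ncol(geno))
      stop2("need one environment label per individual")
    env <- as.character(env)
  }
  structure(list(geno = geno, map = map, pheno = pheno,
                 cross_type = cross_type, env = env),
            class = "cross")
}

#' @export
print.cross <- function(x, ...) {
  cat("Cross (", x$cross_type, "): ", ncol(x$geno), " individuals, ",
      nrow(x$geno), " markers on ", length(unique(x$map$chr)),
      " chromosome(s)\n", sep = "")
  if (!is.null(x$pheno))
    cat("  ", nrow(x$pheno), " phenotype(s)\n", sep = "")
  if (!is.null(x$env))
    cat("  environments: ", paste(sort(unique(x$env)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Number of individuals in a cross
#' @param cross a `cross` object.
#' @export
n_individuals <- function(cross) ncol(cross$geno)
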