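#' Export a genetic map as GFF3
#'
#' One `genetic_marker` feature line per marker that carries a physical
#' position (`bp` column); markers without one are skipped and their
#' count reported via [message()].  Coordinates are 1-based inclusive
#' point features (start = end = bp).  Attributes carry the marker id
#' (`ID`, `Name`) and its genetic position (`cM`).
#'
#' @param map a [genetic_map()] with a `bp` column.
#' @param path output file path.
#' @param source value for the GFF source column.
#' @param type feature type (default `"genetic_marker"`).
#' @return invisibly, the number of feature lines written.
#' @export
write_gff <- function(map, path, source = "phenomarker",
                      type = "genetic_marker") {
  has_bp <- if (is.null(map$bp)) rep(FALSE, nrow(map)) else !is.na(map$bp)
  n_skip <- sum(!has_bp)
  if (n_skip > 0)
    message(n_skip, " marker(s) without physical position skipped in GFF export")
  m <- map[has_bp, , drop = FALSE]
  lines <- "##gff-version 3"
  if (nrow(m)) {
    lines <- c(lines, sprintf(
      "%s\t%s\t%s\t%d\t%d\t.\t.\t.\tID=%s;Name=%s;cM=%s",
      m$chr, source, type, as.integer(m$bp), as.integer(m$bp),
      m$marker, m$marker, formatC(m$pos, format = "f", digits = 4)))
  }
  writeLines(lines, path)
  invisible(nrow(m))
}

#' Read a table of known physical positions
#'
#' Three delimited columns: phenotype id, chromosome, bp position.
#' A header line is detected (non-integer third field) and skipped.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `chr`, `bp`.
#' @export
read_physical_positions <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop2("empty file: ", path)
  sep <- sniff_sep(lines[1])
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(fields) != 3L))
    stop2("expected 3 columns at line ", which(lengths(fields) != 3L)[1])
  first_bp <- suppressWarnings(as.numeric(fields[[1]][3]))
  if (is.na(first_bp)) fields <- fields[-1L]  # header
  id <- vapply(fields, `[[`, "", 1L)
  chr <- vapply(fields, `[[`, "", 2L)
  bp_chr <- vapply(fields, `[[`, "", 3L)
  bp <- suppressWarnings(as.numeric(bp_chr))
  bad <- which(is.na(bp) | bp != round(bp))
  if (length(bad))
    stop2("non-integer bp value '", bp_chr[bad[1]], "' at row ", bad[1],
          " (id ", id[bad[1]], ")")
  if (anyDuplicated(id))
    stop2("duplicated phenotype id(s): ",
          paste(unique(id[duplicated(id)]), collapse = ", "))
  data.frame(id = id, chr = chr, bp = bp, stringsAsFactors = FALSE)
}

#' Look up the physical position of a phenotype
#'
#' @param positions table from [read_physical_positions()].
#' @param id phenotype id(s) to query.
#' @return data.frame with one row per queried id; unknown ids yield
#'   `NA` chromosome and position rather than an error.
#' @export
lookup_position <- function(positions, id) {
  i <- match(id, positions$id)
  data.frame(id = id,
             chr = ifelse(is.na(i), NA_character_, positions$chr[i]),
             bp = ifelse(is.na(i), NA_real_, positions$bp[i]),
             stringsAsFactors = FALSE)
}
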