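#' Read a phenotype matrix from delimited text, in chunks
#'
#' Reads a phenotypes-by-individuals table (first row: individual ids,
#' first column: phenotype ids) without ever holding more than
#' `chunk_rows` raw lines in memory at once.  The result is identical for
#' every chunk size; chunking only bounds peak memory.  Tab, comma and
#' semicolon separators are auto-detected from the header line.
#'
#' When `callback` is supplied it is invoked once per chunk with the
#' numeric sub-matrix for that chunk (rownames = phenotype ids, colnames
#' = individual ids) and the full matrix is *not* assembled; the list of
#' callback return values is returned invisibly instead.  This is the
#' streaming path for matrices too large to fit in memory: selection
#' steps (e.g. the parental t-test) can run per chunk and keep only the
#' survivors.
#'
#' @param path file path to a delimited text file.
#' @param chunk_rows positive integer, number of data rows per chunk.
#' @param sep field separator; `NULL` (default) auto-detects.
#' @param callback optional `function(chunk_matrix)` applied per chunk.
#' @return numeric matrix (phenotypes x individuals), or invisibly the
#'   list of callback results when `callback` is given.
#' @examples
#' tf <- tempfile()
#' write_phenotype_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("p1", "p2"), c("i1", "i2", "i3"))), tf)
#' read_phenotype_matrix(tf, chunk_rows = 1)
#' @export
read_phenotype_matrix <- function(path, chunk_rows = 1000L, sep = NULL,
                                  callback = NULL) {
  stopifnot(chunk_rows >= 1)
  con <- file(path, open = "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (length(header) == 0L) stop2("empty file: ", path)
  sep <- sep %||% sniff_sep(header)
  ind <- strsplit(header, sep, fixed = TRUE)[[1]]
  # header may or may not carry a stub cell above the id column
  n_ind_hdr <- length(ind)

  seen_ids <- character(0)
  chunks <- list()
  cb_out <- list()
  line_no <- 1L
  first <- TRUE
  n_ind <- NA_integer_

  repeat {
    lines <- readLines(con, n = chunk_rows)
    if (length(lines) == 0L) break
    fields <- strsplit(lines, sep, fixed = TRUE)
    widths <- lengths(fields)
    if (first) {
      # decide whether the header had a stub cell for the id column
      n_ind <- widths[1] - 1L
      if (n_ind_hdr == n_ind + 1L) ind <- ind[-1L]
      if (length(ind) != n_ind)
        stop2("header has ", length(ind), " individual ids but data rows have ",
              n_ind, " value columns")
      if (anyDuplicated(ind))
        stop2("duplicated individual id(s): ",
              paste(unique(ind[duplicated(ind)]), collapse = ", "))
      if (n_ind < 2) stop2("need at least 2 individuals")
      first <- FALSE
    }
    bad <- which(widths != n_ind + 1L)
    if (length(bad))
      stop2("ragged row at line ", line_no + bad[1],
            ": expected ", n_ind + 1L, " fields, found ", widths[bad[1]])
    ids <- vapply(fields, `[[`, "", 1L)
    dup <- ids[ids %in% seen_ids | duplicated(ids)]
    if (length(dup))
      stop2("duplicated phenotype id(s): ", paste(unique(dup), collapse = ", "))
    seen_ids <- c(seen_ids, ids)
    vals <- vapply(fields, function(f) {
      suppressWarnings(as.numeric(ifelse(f[-1L] %in% c("NA", "", "*"), NA, f[-1L])))
    }, numeric(n_ind))
    m <- matrix(t(vals), nrow = length(ids), ncol = n_ind,
                dimnames = list(ids, ind))
    if (is.null(callback)) chunks[[length(chunks) + 1L]] <- m
    else cb_out[[length(cb_out) + 1L]] <- callback(m)
    line_no <- line_no + length(lines)
  }
  if (first) stop2("no data rows in ", path)
  if (!is.null(callback)) return(invisible(cb_out))
  do.call(rbind, chunks)
}

#' Write a phenotype matrix as delimited text
#'
#' @param x numeric matrix with phenotype rownames and individual colnames.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_phenotype_matrix <- function(x, path, sep = "\t") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  lines <- c(
    paste(c("id", colnames(x)), collapse = sep),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], format(x[i, ], trim = TRUE, digits = 15)),
            collapse = sep)
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}
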