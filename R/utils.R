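# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop2 <- function(...) stop(..., call. = FALSE)

#' Run code under a temporary RNG seed (NULL seed = use current stream)
#' @noRd
with_seed2 <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Full-informative genotype codes per cross type; semi codes are F2-only.
full_codes <- function(cross_type) {
  switch(cross_type,
    riself = c("A", "B"),
    bc     = c("A", "H"),
    f2     = c("A", "H", "B"),
    stop2("unknown cross_type: ", cross_type)
  )
}

SEMI_CODES <- c("notA", "notH", "notB")

#' Numeric dosage coding of calls: A=0, H=1, B=2 (riself/bc collapse to 0/1).
#' Semi-informative codes map to NA here; they only carry partial information.
#' @noRd
geno_numeric <- function(calls, cross_type = "riself") {
  out <- rep(NA_real_, length(calls))
  if (cross_type == "f2") {
    out[calls == "A"] <- 0
    out[calls == "H"] <- 1
    out[calls == "B"] <- 2
  } else {
    cls <- full_codes(cross_type)
    out[calls == cls[1]] <- 0
    out[calls == cls[2]] <- 1
  }
  out
}

#' Guess the field separator of a delimited text file from its first line.
#' @noRd
sniff_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ";"
}

# log10 with 0*log(0) := 0, for LOD likelihood terms
xlog10 <- function(k, p) ifelse(k == 0, 0, k * log10(p))
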