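#' Transform phenotype values
#'
#' Elementwise transform of a numeric vector; missing values propagate.
#' Out-of-domain values are an error naming the offending method (and
#' phenotype, when `id` is given), because silently producing `NaN`
#' would corrupt downstream mixture fits.
#'
#' Domains: `log` requires values > 0; `sqrt` >= 0; `reciprocal` != 0;
#' `probit` and `logit` values strictly inside (0, 1).
#'
#' @param values numeric vector.
#' @param method one of `"log"`, `"sqrt"`, `"reciprocal"`, `"probit"`,
#'   `"logit"`.
#' @param id optional phenotype id used in error messages.
#' @export
transform_values <- function(values,
                             method = c("log", "sqrt", "reciprocal",
                                        "probit", "logit"),
                             id = NULL) {
  method <- match.arg(method)
  ok <- !is.na(values)
  v <- values[ok]
  bad <- switch(method,
    log = any(v <= 0), sqrt = any(v < 0), reciprocal = any(v == 0),
    probit = , logit = any(v <= 0 | v >= 1))
  if (bad)
    stop2("value out of domain for ", method, " transform",
          if (!is.null(id)) paste0(" of phenotype '", id, "'"))
  f <- switch(method,
    log = log, sqrt = sqrt, reciprocal = function(x) 1 / x,
    probit = stats::qnorm, logit = stats::qlogis)
  out <- values
  out[ok] <- f(v)
  out
}

#' Transform every row of a phenotype matrix
#' @param x phenotype matrix (phenotypes x individuals).
#' @inheritParams transform_values
#' @export
transform_phenotypes <- function(x, method) {
  out <- x
  for (i in seq_len(nrow(x)))
    out[i, ] <- transform_values(x[i, ], method, id = rownames(x)[i])
  out
}

#' Bundle replicated parental measurements
#'
#' @param values_A,values_B numeric matrices (phenotypes x replicates)
#'   of the two parental strains; phenotype rownames must match.
#' @param env_A,env_B optional environment label per replicate column.
#' @return object of class `parental_data`.
#' @export
parental_data <- function(values_A, values_B, env_A = NULL, env_B = NULL) {
  stopifnot(is.matrix(values_A), is.matrix(values_B))
  if (!identical(rownames(values_A), rownames(values_B)))
    stop2("parental matrices must cover the same phenotypes in the same order")
  structure(list(values_A = values_A, values_B = values_B,
                 env_A = env_A, env_B = env_B),
            class = "parental_data")
}

# Welch t-test by closed form; degenerate zero-variance-both-sides case
# defined explicitly (equal means -> p = 1; unequal -> p = 0, flagged).
welch_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) {
    return(list(p = if (mean(a) == mean(b)) 1 else 0, degenerate = TRUE))
  }
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Select phenotypes differentially expressed between the parents
#'
#' Runs a Welch (unequal-variance) two-sample t-test per phenotype
#' between the replicated parental measurements and keeps phenotypes
#' with (adjusted) p below `alpha`.  No multiple-testing correction is
#' applied by default; `"bonferroni"` and `"BH"` are available.  The
#' parental means are retained for later parental-origin labeling of
#' mixture components.
#'
#' At least 3 replicates per parent per phenotype are required; with
#' fewer, the step errors and the pipeline should be run without
#' parental data instead.
#'
#' @param parental a [parental_data()] object.
#' @param alpha significance level (default 0.01).
#' @param correction `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return data.frame with columns `id`, `mean_A`, `mean_B`, `p`,
#'   `p_adj`, `degenerate`, `selected`.
#' @export
select_parental_differential <- function(parental, alpha = 0.01,
                                         correction = c("none", "bonferroni",
                                                        "BH")) {
  correction <- match.arg(correction)
  A <- parental$values_A; B <- parental$values_B
  n_ok_A <- rowSums(!is.na(A)); n_ok_B <- rowSums(!is.na(B))
  if (any(n_ok_A < 3) || any(n_ok_B < 3))
    stop2("fewer than 3 replicates per parent for some phenotype(s); ",
          "skip the parental selection step and run without parental data")
  res <- lapply(seq_len(nrow(A)), function(i) welch_p(A[i, ], B[i, ]))
  p <- vapply(res, `[[`, 0, "p")
  p_adj <- stats::p.adjust(p, method = if (correction == "none") "none"
                           else correction)
  out <- data.frame(
    id = rownames(A),
    mean_A = rowMeans(A, na.rm = TRUE),
    mean_B = rowMeans(B, na.rm = TRUE),
    p = p, p_adj = p_adj,
    degenerate = vapply(res, `[[`, TRUE, "degenerate"),
    selected = p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  out
}
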