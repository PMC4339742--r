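# Gaussian mixture machinery used to turn multimodal molecular
# phenotypes into genetic markers.  A phenotype driven by a major QTL
# separates into one component per genotype class (2 for RIL/backcross,
# 3 for F2); posterior probabilities of component membership then give
# per-individual genotype calls.

em_once <- function(v, k, tol, max_iter, equal_variance, var_floor,
                    mu, sg2 = NULL, pr = NULL) {
  n <- length(v)
  sg2 <- sg2 %||% rep(stats::var(v), k)
  pr <- pr %||% rep(1 / k, k)
  ll_trace <- numeric(max_iter)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  dens <- post <- matrix(0, n, k)
  repeat {
    it <- it + 1L
    for (j in seq_len(k))
      dens[, j] <- pr[j] / sqrt(2 * pi * sg2[j]) *
        exp(-0.5 * (v - mu[j])^2 / sg2[j])
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < .Machine$double.xmin] <- .Machine$double.xmin
    post <- dens / rowsum_d
    ll <- sum(log(rowsum_d))
    ll_trace[it] <- ll
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
    nk <- colSums(post)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(post * v) / nk
    dev2 <- (matrix(v, n, k) - matrix(mu, n, k, byrow = TRUE))^2
    sg2 <- if (equal_variance) rep(max(sum(post * dev2) / n, var_floor), k)
           else pmax(colSums(post * dev2) / nk, var_floor)
    pr <- nk / n
  }
  list(means = mu, variances = sg2, proportions = pr, log_likelihood = ll,
       posteriors = post, converged = converged, n_iter = it,
       ll_trace = ll_trace[seq_len(it)])
}

#' Fit a Gaussian mixture to one phenotype by EM
#'
#' Runs expectation-maximization from a deterministic quantile-based
#' start (component `j` initialized at the `(j - 0.5)/k` sample
#' quantile) plus `n_starts - 1` seeded jittered restarts, and keeps the
#' fit with the best log-likelihood.  Variances are free per component
#' by default, with a floor of `1e-6` times the total variance to
#' prevent component collapse.  Components are reported in ascending
#' order of mean.
#'
#' @param values numeric vector (missing allowed; >= 10 non-missing
#'   values required).
#' @param k number of components, 2 (riself/bc) or 3 (f2).
#' @param n_starts number of EM initializations.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param seed integer seed for the random restarts (`NULL` = current
#'   RNG stream).
#' @param equal_variance constrain all components to a common variance.
#' @return object of class `mixture_fit` with elements `k`, `means`,
#'   `variances`, `proportions`, `log_likelihood`, `posteriors`
#'   (rows for all input positions; `NA` where the value was missing),
#'   `converged`, `n_iter`, `ll_trace`, `n_used`.
#' @export
fit_mixture <- function(values, k = 2, n_starts = 3, tol = 1e-8,
                        max_iter = 5000, seed = NULL,
                        equal_variance = FALSE) {
  stopifnot(k %in% c(2, 3))
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 10) stop2("need at least 10 non-missing values")
  if (max(v) == min(v)) stop2("degenerate distribution: all values identical")
  var_floor <- 1e-6 * stats::var(v)
  qs <- stats::quantile(v, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  starts <- list(qs)
  if (n_starts > 1) {
    jit <- with_seed2(seed, lapply(seq_len(n_starts - 1), function(i)
      sort(qs + stats::rnorm(k, 0, stats::sd(v) / 2))))
    starts <- c(starts, jit)
  }
  # short runs from every start, then polish only the best to
  # convergence (em-EM strategy: restarts mostly matter in the first
  # iterations, long ridge-crawling only needs doing once)
  short_iter <- min(max_iter, 200L)
  best <- NULL
  for (m0 in starts) {
    f <- em_once(v, k, tol, short_iter, equal_variance, var_floor, mu = m0)
    if (is.null(best) || f$log_likelihood > best$log_likelihood) best <- f
  }
  if (!best$converged && max_iter > short_iter) {
    f <- em_once(v, k, tol, max_iter - short_iter, equal_variance,
                 var_floor, mu = best$means, sg2 = best$variances,
                 pr = best$proportions)
    f$n_iter <- f$n_iter + best$n_iter
    f$ll_trace <- c(best$ll_trace, f$ll_trace)
    best <- f
  }
  ord <- order(best$means)
  post_full <- matrix(NA_real_, length(values), k)
  post_full[ok, ] <- best$posteriors[, ord, drop = FALSE]
  rownames(post_full) <- names(values)
  structure(list(
    k = k, means = best$means[ord], variances = best$variances[ord],
    proportions = best$proportions[ord],
    log_likelihood = best$log_likelihood, posteriors = post_full,
    converged = best$converged, n_iter = best$n_iter,
    ll_trace = best$ll_trace, n_used = length(v)), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit, k = ", x$k,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(round(data.frame(mean = x$means, sd = sqrt(x$variances),
                         proportion = x$proportions), 4))
  cat("log-likelihood:", format(x$log_likelihood), " iterations:",
      x$n_iter, "\n")
  invisible(x)
}

# single-Gaussian MLE log-likelihood (closed form)
ll_single <- function(v) {
  n <- length(v)
  s2 <- sum((v - mean(v))^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}

#' Test multimodality by parametric-bootstrap likelihood ratio
#'
#' Compares the k-component mixture against a single Gaussian with a
#' likelihood-ratio statistic whose null distribution is obtained by
#' parametric bootstrap: `n_boot` datasets are simulated from the
#' single-Gaussian MLE, the statistic is recomputed on each, and the
#' p-value is `(1 + #{LR* >= LR}) / (n_boot + 1)`.  A phenotype
#' qualifies as a candidate marker when `p < alpha`.
#'
#' For the bootstrap p-value to be exchangeable the statistic must be
#' computed by the *same* procedure on the observed and simulated data,
#' so the LR is evaluated with a fixed-effort EM (`boot_starts`
#' deterministic quantile starts, at most `boot_max_iter` iterations)
#' on both — not with the possibly better-converged `fit` (which only
#' supplies `k` and the convergence check).  On null data EM creeps
#' along a likelihood ridge for thousands of iterations; matching the
#' effort on the two sides keeps the test calibrated at finite effort.
#'
#' @param values the phenotype values the mixture was fitted to.
#' @param fit a converged [fit_mixture()] result (supplies `k`).
#' @param n_boot number of bootstrap replicates (>= 20).
#' @param seed integer seed for the bootstrap simulations.
#' @param boot_starts,boot_max_iter EM effort for the LR statistic.
#' @return the bootstrap p-value.
#' @export
test_multimodality <- function(values, fit, n_boot = 99, seed = NULL,
                               boot_starts = 1, boot_max_iter = 200) {
  if (n_boot < 20) stop2("n_boot must be at least 20")
  if (!fit$converged) stop2("mixture fit did not converge")
  v <- values[!is.na(values)]
  lr_stat <- function(x) {
    f <- try(fit_mixture(x, k = fit$k, n_starts = boot_starts,
                         max_iter = boot_max_iter), silent = TRUE)
    if (inherits(f, "try-error")) return(0)
    2 * (f$log_likelihood - ll_single(x))
  }
  lr <- lr_stat(v)
  if (lr <= 1e-9) return(1)
  n <- length(v)
  mu0 <- mean(v); sd0 <- stats::sd(v) * sqrt((n - 1) / n)
  with_seed2(seed, {
    lrb <- vapply(seq_len(n_boot), function(b)
      lr_stat(stats::rnorm(n, mu0, sd0)), 0)
    (1 + sum(lrb >= lr)) / (n_boot + 1)
  })
}

#' Check mixing proportions against the expected segregation ratio
#'
#' Expected class frequencies are 1:1 for `riself`/`bc` (two classes)
#' and 1:2:1 for `f2`.  The candidate passes when every component's
#' proportion is within `max_deviation` of its expectation.
#'
#' @param proportions length-k vector summing to 1.
#' @param cross_type `"riself"`, `"bc"` or `"f2"`.
#' @param max_deviation largest tolerated absolute deviation per
#'   component.
#' @return list with `pass`, `deviation` (per component) and `expected`.
#' @export
test_segregation <- function(proportions, cross_type, max_deviation = 0.1) {
  expected <- switch(cross_type,
    riself = c(0.5, 0.5), bc = c(0.5, 0.5), f2 = c(0.25, 0.5, 0.25),
    stop2("unknown cross_type: ", cross_type))
  if (length(proportions) != length(expected))
    stop2(length(proportions), " components inconsistent with cross type '",
          cross_type, "' (expected ", length(expected), ")")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop2("proportions must sum to 1")
  dev <- abs(proportions - expected)
  list(pass = all(dev <= max_deviation), deviation = dev, expected = expected)
}

#' Call genotypes from mixture posteriors
#'
#' The call is the component with the highest posterior, provided that
#' posterior reaches `threshold`; otherwise the call is missing.  For
#' three components (F2) a semi-informative call is emitted when exactly
#' one component can be excluded (its posterior below `1 - threshold`)
#' while the other two cannot be separated: `"notA"`, `"notH"` or
#' `"notB"`, naming the excluded class.  Ties at the maximum are always
#' missing.  Components are labeled `A`/(`H`)/`B` in ascending order of
#' mean; [label_parental_origin()] can relabel them once parental means
#' are known.
#'
#' @param fit a converged [fit_mixture()].
#' @param threshold posterior probability cutoff in `[0.5, 1]`.
#' @param cross_type used to label the two components for non-F2 crosses
#'   (`riself` classes are `A`/`B`, `bc` classes `A`/`H`).
#' @return character vector of calls, `NA` = missing.
#' @export
call_genotypes <- function(fit, threshold = 0.8, cross_type = "riself") {
  if (threshold < 0.5 || threshold > 1)
    stop2("threshold must be in [0.5, 1]")
  if (!fit$converged) stop2("mixture fit did not converge")
  labels <- if (fit$k == 2) full_codes(cross_type) else c("A", "H", "B")
  post <- fit$posteriors
  calls <- rep(NA_character_, nrow(post))
  ok <- !is.na(post[, 1])
  pm <- post[ok, , drop = FALSE]
  top <- max.col(pm, ties.method = "first")
  topp <- pm[cbind(seq_len(nrow(pm)), top)]
  tie <- abs(topp - apply(pm, 1, function(r) sort(r, decreasing = TRUE)[2])) < 1e-12
  call_ok <- topp >= threshold & !tie
  res <- rep(NA_character_, nrow(pm))
  res[call_ok] <- labels[top[call_ok]]
  if (fit$k == 3) {
    semi <- which(!call_ok)
    for (i in semi) {
      excl <- which(pm[i, ] < 1 - threshold)
      if (length(excl) == 1) res[i] <- paste0("not", labels[excl])
    }
  }
  calls[ok] <- res
  names(calls) <- rownames(post)
  calls
}

#' Relabel calls by parental origin
#'
#' Maps the lowest and highest mixture components to whichever parent's
#' mean expression is nearer, swapping `A`/`B` labels (and `notA`/`notB`)
#' when needed.  The middle F2 component stays `H`.  If a parental mean
#' is equidistant from the two extreme components the marker cannot be
#' labeled and is flagged via the `"unlabelable"` attribute.
#'
#' @param calls character calls from [call_genotypes()].
#' @param component_means ascending component means from the fit.
#' @param parental_means numeric `c(mean_A, mean_B)`.
#' @return relabeled calls (attribute `unlabelable = TRUE` when labeling
#'   failed, calls returned unchanged).
#' @export
label_parental_origin <- function(calls, component_means, parental_means) {
  stopifnot(length(parental_means) == 2)
  lo <- component_means[1]; hi <- component_means[length(component_means)]
  dA <- abs(parental_means[1] - c(lo, hi))
  dB <- abs(parental_means[2] - c(lo, hi))
  if (dA[1] == dA[2] || dB[1] == dB[2]) {
    attr(calls, "unlabelable") <- TRUE
    return(calls)
  }
  a_low <- dA[1] < dA[2]
  b_low <- dB[1] < dB[2]
  if (a_low == b_low) {
    attr(calls, "unlabelable") <- TRUE
    return(calls)
  }
  if (!a_low) {  # parent A sits at the high component: swap labels
    swap <- c(A = "B", B = "A", notA = "notB", notB = "notA")
    hit <- calls %in% names(swap)
    calls[hit] <- swap[calls[hit]]
  }
  calls
}
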