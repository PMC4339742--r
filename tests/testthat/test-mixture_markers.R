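# two-component data at a given separation (in residual sd units),
# balanced 1:1 as a segregating RIL phenotype would be
two_comp <- function(n, sep, seed, sd = 1) {
  withr::with_seed(seed, {
    g <- rbinom(n, 1, 0.5)
    list(values = sep * g + rnorm(n, 0, sd), g = g)
  })
}

test_that("EM recovers parameters of well-separated components", {
  withr::with_seed(101, {
    v <- c(rnorm(100, 0, 0.5), rnorm(100, 10, 0.5))
  })
  fit <- fit_mixture(v, k = 2, seed = 202)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$means - c(0, 10))), 0.2)
  expect_lt(max(abs(fit$proportions - 0.5)), 0.05)
  expect_equal(sum(fit$proportions), 1, tolerance = 1e-8)
  expect_true(all(fit$variances > 0))
  expect_true(!is.unsorted(fit$means))
})

test_that("log-likelihood is non-decreasing within every EM run", {
  withr::with_seed(55, {
    for (i in 1:5) {
      v <- rnorm(60, 0, 1) + sample(c(0, 3), 60, replace = TRUE)
      fit <- fit_mixture(v, k = sample(2:3, 1), seed = i)
      expect_true(all(diff(fit$ll_trace) > -1e-9))
    }
  })
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(fit_mixture(rep(1, 50), k = 2), "degenerate distribution")
  expect_error(fit_mixture(rnorm(9), k = 2), "at least 10")
  expect_error(fit_mixture(rnorm(50), k = 4), "k")
})

test_that("posterior rows sum to 1 and missing values propagate", {
  withr::with_seed(7, {
    v <- c(rnorm(50), rnorm(50, 6), NA, NA)
  })
  fit <- fit_mixture(v, k = 2, seed = 1)
  rs <- rowSums(fit$posteriors)
  expect_equal(rs[1:100], rep(1, 100), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(is.na(fit$posteriors[101:102, ])))
  expect_true(all(is.na(call_genotypes(fit, 0.8)[101:102])))
})

test_that("EM solution matches an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  d <- two_comp(200, 5, seed = 31)
  fit <- fit_mixture(d$values, k = 2, seed = 1)
  mc <- mclust::Mclust(d$values, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$means, sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 0.01)
})

test_that("bootstrap LRT separates bimodal from unimodal phenotypes", {
  d <- two_comp(148, 10, seed = 61)
  fit <- fit_mixture(d$values, k = 2, seed = 1)
  expect_lt(test_multimodality(d$values, fit, n_boot = 99, seed = 2), 0.05)

  withr::with_seed(62, v0 <- rnorm(148))
  fit0 <- fit_mixture(v0, k = 2, seed = 1)
  expect_gt(test_multimodality(v0, fit0, n_boot = 99, seed = 2), 0.05)
  expect_error(test_multimodality(v0, fit0, n_boot = 10), "at least 20")
})

test_that("bootstrap LRT is calibrated on single-Gaussian data", {
  n_rep <- 120
  hits <- 0L
  withr::with_seed(77, {
    for (i in seq_len(n_rep)) {
      v <- rnorm(120)
      fit <- try(fit_mixture(v, k = 2, n_starts = 1), silent = TRUE)
      if (inherits(fit, "try-error") || !fit$converged) next
      p <- test_multimodality(v, fit, n_boot = 49)
      if (p < 0.05) hits <- hits + 1L
    }
  })
  # two-sided binomial band for 120 draws at alpha = 0.05
  expect_lte(hits, qbinom(0.9975, n_rep, 0.05))
})

test_that("segregation check applies cross-specific expected ratios", {
  r <- test_segregation(c(0.5, 0.5), "riself", 0.05)
  expect_true(r$pass)
  expect_equal(r$deviation, c(0, 0))
  expect_false(test_segregation(c(0.7, 0.3), "riself", 0.1)$pass)
  expect_true(test_segregation(c(0.26, 0.49, 0.25), "f2", 0.05)$pass)
  expect_equal(test_segregation(c(0.3, 0.7), "riself", 1)$expected,
               c(0.5, 0.5))
  expect_error(test_segregation(c(0.5, 0.5), "f2"), "inconsistent")
  expect_error(test_segregation(c(0.6, 0.6), "riself"), "sum to 1")
})

test_that("posterior calling thresholds behave at the midpoint", {
  # symmetric fit: value at the midpoint has posteriors (0.5, 0.5)
  d <- two_comp(200, 8, seed = 41)
  v <- c(d$values, 4)  # exact midpoint of the two class means
  fit <- fit_mixture(v, k = 2, seed = 1)
  calls <- call_genotypes(fit, threshold = 0.8)
  mid_post <- fit$posteriors[201, ]
  expect_lt(max(mid_post), 0.8)
  expect_true(is.na(calls[201]))
  # threshold 0.5: everything except exact ties is called
  calls50 <- call_genotypes(fit, threshold = 0.5)
  expect_lt(mean(is.na(calls50)), 0.02)
  expect_error(call_genotypes(fit, threshold = 0.4), "0.5")
})

test_that("posterior at a component mean follows the density ratio", {
  d <- two_comp(200, 10, seed = 42)
  fit <- fit_mixture(d$values, k = 2, seed = 1)
  # value at component-1 mean: posterior from the normal density ratio
  v1 <- fit$means[1]
  dens <- fit$proportions * dnorm(v1, fit$means, sqrt(fit$variances))
  expect_gt(dens[1] / sum(dens), 0.999)
  idx <- which.min(abs(d$values - v1))
  expect_gt(fit$posteriors[idx, 1], 0.99)
})

test_that("calls are invariant under increasing affine transforms", {
  withr::with_seed(13, {
    for (i in 1:5) {
      d <- two_comp(120, 6, seed = 500 + i)
      a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
      f1 <- fit_mixture(d$values, k = 2, seed = 9)
      f2 <- fit_mixture(a * d$values + b, k = 2, seed = 9)
      expect_identical(call_genotypes(f1, 0.8), call_genotypes(f2, 0.8))
      expect_equal(f2$means, a * f1$means + b, tolerance = 1e-4)
      expect_equal(f2$posteriors, f1$posteriors, tolerance = 1e-4)
    }
  })
})

test_that("calling accuracy rises with separation, near-perfect at 8 sd", {
  acc <- vapply(c(2, 4, 8), function(sep) {
    d <- two_comp(200, sep, seed = 600 + sep)
    fit <- fit_mixture(d$values, k = 2, seed = 1)
    calls <- call_genotypes(fit, threshold = 0.8)
    mean(calls == c("A", "B")[d$g + 1], na.rm = TRUE)
  }, 0)
  expect_true(all(diff(acc) >= 0))
  expect_gte(acc[3], 0.99)
})

test_that("parental origin labeling maps components to nearer parent", {
  calls <- c("A", "B", "A", NA)
  expect_identical(label_parental_origin(calls, c(0, 10), c(0.3, 9.8)),
                   calls)
  swapped <- label_parental_origin(calls, c(0, 10), c(9.8, 0.3))
  expect_identical(swapped, c("B", "A", "B", NA))
  # relabeling the swapped calls under the swapped parents restores them
  expect_identical(label_parental_origin(swapped, c(0, 10), c(9.8, 0.3)),
                   calls)
  # f2: middle component stays H
  f2calls <- c("A", "H", "B", "notA")
  expect_identical(label_parental_origin(f2calls, c(0, 5, 10), c(10, 0)),
                   c("B", "H", "A", "notB"))
  # equidistant parents cannot label
  out <- label_parental_origin(calls, c(0, 10), c(5, 5))
  expect_true(attr(out, "unlabelable"))
})
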