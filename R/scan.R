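# Genome scans by Haley-Knott regression: phenotype regressed on
# expected genotype dosage computed from flanking markers through a
# Markov model of recombination (Haldane transitions; RIL-expanded for
# riself).  LOD = (n/2) * log10(RSS0 / RSS1).

# switch probability between two loci d cM apart, on the observed scale
switch_prob <- function(d, cross_type) {
  r <- cm_to_rf(d, "haldane")
  if (cross_type == "riself") ril_expand(r) else r
}

# F2 genotype transition matrix over d cM (states A,H,B)
f2_transition <- function(d) {
  r <- cm_to_rf(d, "haldane")
  matrix(c((1 - r)^2,      2 * r * (1 - r),     r^2,
           r * (1 - r),    (1 - r)^2 + r^2,     r * (1 - r),
           r^2,            2 * r * (1 - r),     (1 - r)^2),
         3, 3, byrow = TRUE)
}

# genotype-state transition matrix over d cM on the observed scale
state_transition <- function(d, cross_type) {
  if (cross_type == "f2") return(f2_transition(d))
  s <- switch_prob(d, cross_type)
  matrix(c(1 - s, s, s, 1 - s), 2, 2)
}

#' Genotype probabilities on a cM grid
#'
#' For every individual and every grid position (marker positions plus a
#' regular `step`-cM grid per chromosome), computes the probability of
#' each genotype class by forward-backward smoothing of a Markov chain
#' along the chromosome: Haldane transition probabilities (expanded to
#' the observed scale for `riself`), and an emission model in which an
#' observed call is wrong with probability `error_prob`.  A
#' semi-informative F2 call excludes its named class (up to the same
#' error rate); a missing call is uninformative.  With `error_prob = 0`
#' observed calls are taken as exact.
#'
#' Conditioning on *all* markers of the chromosome rather than the
#' nearest flanking pair matters once derived markers (which carry
#' occasional miscalls) enter the map: an erroneous call is then
#' out-voted by its neighbors instead of being trusted verbatim.
#'
#' @param cross a `cross`.
#' @param step grid step in cM (default 1); marker positions are always
#'   included.
#' @param error_prob per-call genotyping error probability (default
#'   `1e-4`, appropriate for curated markers; use ~`0.01` for markers
#'   derived from mixture posteriors).
#' @return list with `pos` (data.frame `chr`, `pos`, `marker` — marker
#'   id or `NA` for pseudomarkers) and `prob`, a 3-dim array
#'   (individuals x positions x genotype classes; 2 classes for
#'   riself/bc).
#' @export
calc_genoprob <- function(cross, step = 1, error_prob = 1e-4) {
  ct <- cross$cross_type
  map <- cross$map
  classes <- full_codes(ct)
  nc <- length(classes)
  n <- ncol(cross$geno)
  prior <- if (ct == "f2") c(0.25, 0.5, 0.25) else c(0.5, 0.5)
  # emission likelihood per observed symbol (rows) x true state (cols)
  semi_excludes <- c(notA = "A", notH = "H", notB = "B")
  emission_for <- function(calls) {
    E <- matrix(1, length(calls), nc)
    for (j in seq_len(nc)) {
      hit <- !is.na(calls) & calls == classes[j]
      E[hit, ] <- error_prob / max(nc - 1, 1)
      E[hit, j] <- 1 - error_prob
      if (ct == "f2") {
        ex <- !is.na(calls) & calls == names(semi_excludes)[j]
        E[ex, ] <- (1 - error_prob) / (nc - 1)
        E[ex, match(semi_excludes[j], classes)] <- error_prob
      }
    }
    E
  }
  pos_list <- list()
  prob_list <- list()
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    mpos <- map$pos[idx]
    mk <- map$marker[idx]
    grid <- sort(unique(c(mpos, seq(min(mpos), max(mpos), by = step))))
    ng <- length(grid)
    at_marker <- mk[match(grid, mpos)]
    # emission per grid position: product over markers mapped there
    E <- array(1, c(n, ng, nc))
    for (mi in seq_along(mk)) {
      gi <- match(mpos[mi], grid)
      E[, gi, ] <- E[, gi, , drop = FALSE] *
        array(emission_for(cross$geno[mk[mi], ]), c(n, 1, nc))
    }
    Tm <- lapply(diff(grid), state_transition, cross_type = ct)
    # impossible rows (contradictory calls at error_prob = 0) fall back
    # to the stationary prior
    norm_rows <- function(m) {
      rs <- rowSums(m)
      bad <- !is.finite(rs) | rs <= 0
      if (any(bad)) m[bad, ] <- matrix(prior, sum(bad), nc, byrow = TRUE)
      m / ifelse(rowSums(m) > 0, rowSums(m), 1)
    }
    Em <- function(i) matrix(E[, i, ], n, nc)
    # forward pass (row-rescaled), keeping alpha at every position
    A <- array(0, c(n, ng, nc))
    a <- norm_rows(matrix(prior, n, nc, byrow = TRUE) * Em(1))
    A[, 1, ] <- a
    if (ng > 1) for (i in 2:ng) {
      a <- norm_rows((a %*% Tm[[i - 1]]) * Em(i))
      A[, i, ] <- a
    }
    # backward pass combined into smoothed posteriors
    P <- array(0, c(n, ng, nc))
    b <- matrix(1, n, nc)
    P[, ng, ] <- A[, ng, ]
    if (ng > 1) for (i in (ng - 1):1) {
      b <- norm_rows((b * Em(i + 1)) %*% t(Tm[[i]]))
      P[, i, ] <- norm_rows(matrix(A[, i, ], n, nc) * b)
    }
    pos_list[[cc]] <- data.frame(chr = cc, pos = grid, marker = at_marker,
                                 stringsAsFactors = FALSE)
    prob_list[[cc]] <- P
  }
  pos <- do.call(rbind, pos_list)
  rownames(pos) <- NULL
  prob <- array(NA_real_, c(n, nrow(pos), nc))
  off <- 0L
  for (cc in names(prob_list)) {
    w <- dim(prob_list[[cc]])[2]
    prob[, off + seq_len(w), ] <- prob_list[[cc]]
    off <- off + w
  }
  list(pos = pos, prob = prob, classes = classes)
}

# design columns per position: additive dosage (and dominance for f2)
genoprob_design <- function(gp) {
  if (length(gp$classes) == 2) {
    list(add = gp$prob[, , 2, drop = TRUE], dom = NULL)
  } else {
    list(add = gp$prob[, , 3, drop = TRUE] - gp$prob[, , 1, drop = TRUE],
         dom = gp$prob[, , 2, drop = TRUE])
  }
}

rss_fit <- function(X, y) {
  f <- stats::.lm.fit(X, y)
  sum(f$residuals^2)
}

#' Single-QTL genome scan (Haley-Knott regression)
#'
#' At each grid position the phenotype is regressed on the expected
#' genotype (plus a dominance term for F2); `LOD = (n/2) *
#' log10(RSS0/RSS1)` against the covariate-only model.  Covariates (for
#' example the environment factor) enter both models.
#'
#' @param phenotype numeric vector, one value per individual.
#' @param cross a `cross`.
#' @param step cM grid step.
#' @param covar optional data.frame/factor/matrix of additive
#'   covariates.
#' @param genoprob optional precomputed [calc_genoprob()] (reused across
#'   phenotypes for speed).
#' @return `scan_result`: data.frame (`chr`, `pos`, `marker`, `lod`)
#'   with attributes `peak` (row index), `peak_lod`, `peak_chr`,
#'   `peak_pos`, `n`.
#' @export
scan_one <- function(phenotype, cross, step = 1, covar = NULL,
                     genoprob = NULL) {
  gp <- genoprob %||% calc_genoprob(cross, step)
  des <- genoprob_design(gp)
  ok <- !is.na(phenotype)
  if (!is.null(covar)) {
    cv <- stats::model.matrix(~., data.frame(cv = covar))[, -1, drop = FALSE]
    ok <- ok & stats::complete.cases(cv)
  }
  n <- sum(ok)
  if (n < 20) stop2("need at least 20 informative individuals")
  y <- phenotype[ok]
  X0 <- matrix(1, n, 1)
  if (!is.null(covar)) X0 <- cbind(X0, cv[ok, , drop = FALSE])
  rss0 <- rss_fit(X0, y)
  np <- nrow(gp$pos)
  lod <- numeric(np)
  for (i in seq_len(np)) {
    a <- des$add[ok, i]
    if (all(is.na(a))) { lod[i] <- NA; next }
    X1 <- cbind(X0, a)
    if (!is.null(des$dom)) X1 <- cbind(X1, des$dom[ok, i])
    lod[i] <- max(0, n / 2 * log10(rss0 / rss_fit(X1, y)))
  }
  out <- cbind(gp$pos, lod = lod)
  class(out) <- c("scan_result", "data.frame")
  peak <- which.max(lod)
  attr(out, "peak") <- peak
  attr(out, "peak_lod") <- lod[peak]
  attr(out, "peak_chr") <- gp$pos$chr[peak]
  attr(out, "peak_pos") <- gp$pos$pos[peak]
  attr(out, "n") <- n
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Genome scan over ", nrow(x), " positions; peak LOD ",
      round(attr(x, "peak_lod"), 2), " at chr ", attr(x, "peak_chr"),
      " @ ", round(attr(x, "peak_pos"), 1), " cM\n", sep = "")
  invisible(x)
}

#' Two-QTL genome scan
#'
#' For every pair of grid positions fits the additive two-QTL model
#' `y ~ g1 + g2` and the full model with interaction `y ~ g1 * g2`
#' (additive genotype coding).  Summaries: the maximum interaction LOD
#' (full minus additive, evidence of epistasis) and the second-QTL LOD
#' (best additive pair minus best single-QTL LOD, evidence of multiple
#' QTL).  Pairs across chromosomes are included.
#'
#' @inheritParams scan_one
#' @param step cM grid step (coarser than [scan_one()] by default; the
#'   pair count grows quadratically).
#' @return list of class `scan_two_summary`: `max_int_lod`,
#'   `max_add_lod`, `second_qtl_lod`, `best_single_lod`, `int_pair`,
#'   `add_pair` (chr/pos of the maximizing pairs), `n`.
#' @export
scan_two <- function(phenotype, cross, step = 5, covar = NULL,
                     genoprob = NULL) {
  gp <- genoprob %||% calc_genoprob(cross, step)
  des <- genoprob_design(gp)
  ok <- !is.na(phenotype)
  if (!is.null(covar)) {
    cv <- stats::model.matrix(~., data.frame(cv = covar))[, -1, drop = FALSE]
    ok <- ok & stats::complete.cases(cv)
  }
  n <- sum(ok)
  if (n < 20) stop2("need at least 20 informative individuals")
  y <- phenotype[ok]
  A <- des$add[ok, , drop = FALSE]
  X0 <- matrix(1, n, 1)
  if (!is.null(covar)) X0 <- cbind(X0, cv[ok, , drop = FALSE])
  rss0 <- rss_fit(X0, y)
  # best single
  np <- ncol(A)
  lod1 <- vapply(seq_len(np), function(i)
    max(0, n / 2 * log10(rss0 / rss_fit(cbind(X0, A[, i]), y))), 0)
  best_single <- max(lod1)
  max_add <- -Inf; max_int <- 0
  add_pair <- int_pair <- NULL
  for (i in seq_len(np - 1)) {
    ai <- A[, i]
    for (j in (i + 1):np) {
      aj <- A[, j]
      Xa <- cbind(X0, ai, aj)
      rss_a <- rss_fit(Xa, y)
      rss_f <- rss_fit(cbind(Xa, ai * aj), y)
      lod_a <- max(0, n / 2 * log10(rss0 / rss_a))
      lod_f <- max(0, n / 2 * log10(rss0 / rss_f))
      if (lod_a > max_add) {
        max_add <- lod_a
        add_pair <- gp$pos[c(i, j), c("chr", "pos")]
      }
      if (lod_f - lod_a > max_int) {
        max_int <- lod_f - lod_a
        int_pair <- gp$pos[c(i, j), c("chr", "pos")]
      }
    }
  }
  structure(list(max_int_lod = max_int, max_add_lod = max_add,
                 second_qtl_lod = max(0, max_add - best_single),
                 best_single_lod = best_single,
                 int_pair = int_pair, add_pair = add_pair, n = n),
            class = "scan_two_summary")
}

#' Genotype-by-environment interaction LOD at a marker
#'
#' Compares `y ~ genotype + environment` against
#' `y ~ genotype * environment`:
#' `LOD = (n/2) log10(RSS_additive / RSS_interaction)`.  With a single
#' environment the test is undefined and `NA` is returned with a
#' message (not 0 — absence of evidence is not evidence of absence).
#'
#' @param phenotype numeric vector per individual.
#' @param genotype_at_peak character or numeric genotype per individual
#'   at the candidate's peak position.
#' @param environment factor-coercible environment labels.
#' @param min_per_cell minimum individuals required per
#'   genotype-environment cell (default 5).
#' @return interaction LOD (numeric scalar, `NA` when undefined).
#' @export
test_gxe <- function(phenotype, genotype_at_peak, environment,
                     min_per_cell = 5) {
  g <- if (is.character(genotype_at_peak))
    geno_numeric(genotype_at_peak, "f2") else as.numeric(genotype_at_peak)
  env <- factor(environment)
  ok <- !is.na(phenotype) & !is.na(g) & !is.na(env)
  if (nlevels(droplevels(env[ok])) < 2) {
    message("single environment: GxE test skipped")
    return(NA_real_)
  }
  tab <- table(g[ok], droplevels(env[ok]))
  if (any(tab < min_per_cell))
    message("some genotype x environment cells have fewer than ",
            min_per_cell, " individuals; GxE LOD may be unstable")
  y <- phenotype[ok]
  d <- data.frame(g = g[ok], env = droplevels(env[ok]))
  rss_add <- sum(stats::resid(stats::lm(y ~ g + env, d))^2)
  rss_int <- sum(stats::resid(stats::lm(y ~ g * env, d))^2)
  max(0, length(y) / 2 * log10(rss_add / rss_int))
}

#' Default QC thresholds for candidate classification
#'
#' LOD cutoffs: genotype-by-environment `>= 7.5`, multiple QTL `> 15`
#' (second-QTL LOD), pairwise epistasis `>= 7.5`, and a QTL is called
#' significant when its peak LOD exceeds 5.
#'
#' @param gxe_lod,multi_lod,epi_lod,sig_lod numeric cutoffs.
#' @param action what to do with candidates failing QC: `"remove"`
#'   (default) or `"flag"`.
#' @export
qc_thresholds <- function(gxe_lod = 7.5, multi_lod = 15, epi_lod = 7.5,
                          sig_lod = 5, action = c("remove", "flag")) {
  list(gxe_lod = gxe_lod, multi_lod = multi_lod, epi_lod = epi_lod,
       sig_lod = sig_lod, action = match.arg(action))
}

#' Classify a candidate marker from its scan statistics
#'
#' Precedence: `gxe` before `multi_qtl` before `epistatic` before
#' `no_qtl`; survivors are `single_qtl` and always kept.  The action for
#' failing classes follows `thresholds$action`.
#'
#' @param peak_lod single-QTL peak LOD.
#' @param second_qtl_lod second-QTL LOD from [scan_two()].
#' @param epi_lod maximum interaction LOD from [scan_two()].
#' @param gxe_lod interaction LOD from [test_gxe()] (`NA` = untested).
#' @param thresholds a [qc_thresholds()] list.
#' @return `qc_verdict`: list with `class`, `action` and the supporting
#'   `lods`.
#' @export
classify_candidate <- function(peak_lod, second_qtl_lod, epi_lod,
                               gxe_lod = NA, thresholds = qc_thresholds()) {
  if (is.na(peak_lod) || is.na(second_qtl_lod) || is.na(epi_lod))
    stop2("missing scan input(s): ",
          paste(c("peak_lod", "second_qtl_lod", "epi_lod")[
            is.na(c(peak_lod, second_qtl_lod, epi_lod))], collapse = ", "))
  th <- thresholds
  cls <- if (!is.na(gxe_lod) && gxe_lod >= th$gxe_lod) "gxe"
    else if (second_qtl_lod > th$multi_lod) "multi_qtl"
    else if (epi_lod >= th$epi_lod) "epistatic"
    else if (!(peak_lod > th$sig_lod)) "no_qtl"
    else "single_qtl"
  action <- if (cls == "single_qtl") "keep"
            else if (th$action == "remove") "remove" else "flag"
  structure(list(class = cls, action = action,
                 lods = c(peak = peak_lod, second_qtl = second_qtl_lod,
                          epistasis = epi_lod, gxe = gxe_lod)),
            class = "qc_verdict")
}
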