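# Pipeline orchestration: candidate generation from phenotypes,
# saturation of a known map, de novo map construction, error detection
# and imputation, and resolution diagnostics.

#' Theoretical map resolution for a population size
#'
#' A map distance of 1 cM corresponds to one recombination per 100
#' individuals, so with `n` individuals one expects an informative
#' recombination every `100 / n` cM — the best marker spacing the
#' population can support.
#'
#' @param n_individuals population size (>= 1).
#' @return expected cM between informative recombinations.
#' @examples
#' theoretical_resolution(148)  # 0.68 cM
#' @export
theoretical_resolution <- function(n_individuals) {
  if (n_individuals <= 0) stop2("n_individuals must be positive")
  100 / n_individuals
}

#' Average adjacent-marker spacing of a map
#'
#' Mean over all adjacent same-chromosome marker gaps, in cM.
#'
#' @param map a [genetic_map()] with at least one adjacent pair.
#' @export
average_spacing <- function(map) {
  gaps <- unlist(lapply(split(map$pos, map$chr), function(p)
    if (length(p) > 1) diff(p) else numeric(0)))
  if (length(gaps) == 0) stop2("map has no adjacent marker pairs")
  mean(gaps)
}

#' Derive candidate markers from a phenotype matrix
#'
#' The per-phenotype front end of the pipeline: optional transform,
#' optional parental differential selection, then for each surviving
#' phenotype a Gaussian mixture fit, a multimodality test, a
#' segregation-ratio check, posterior genotype calling and (when
#' parental means are available) parental-origin labeling.
#'
#' @param pheno numeric phenotype matrix (phenotypes x individuals).
#' @param cross_type `"riself"`, `"bc"` or `"f2"`.
#' @param parental optional [parental_data()].
#' @param transform optional transform method (see [transform_values()]).
#' @param alpha_parental significance level of the parental t-test.
#' @param alpha_mix significance level of the multimodality test.
#' @param n_boot bootstrap replicates for the multimodality test.
#' @param max_deviation allowed segregation-ratio deviation.
#' @param threshold posterior calling threshold.
#' @param n_starts,max_iter EM effort.
#' @param min_informative minimum non-missing calls for a candidate.
#' @param seed integer seed.
#' @return list of class `candidate_set`: `candidates` (each with
#'   `phenotype_id`, `calls`, `values`, `mixture`, `origin_labeled`,
#'   `qc` slot filled later) and `counts` (telescoping stage counts).
#' @export
find_candidate_markers <- function(pheno, cross_type = "riself",
                                   parental = NULL, transform = NULL,
                                   alpha_parental = 0.01, alpha_mix = 0.05,
                                   n_boot = 99, max_deviation = 0.1,
                                   threshold = 0.8, n_starts = 3,
                                   max_iter = 5000,
                                   min_informative = 20, seed = NULL) {
  if (!is.null(transform)) pheno <- transform_phenotypes(pheno, transform)
  counts <- c(input = nrow(pheno))
  pmeans <- NULL
  if (!is.null(parental)) {
    if (!is.null(transform)) {
      parental$values_A <- transform_phenotypes(parental$values_A, transform)
      parental$values_B <- transform_phenotypes(parental$values_B, transform)
    }
    sel <- select_parental_differential(parental, alpha = alpha_parental)
    keep <- intersect(rownames(pheno), sel$id[sel$selected])
    pmeans <- sel[match(keep, sel$id), c("mean_A", "mean_B")]
    rownames(pmeans) <- keep
    pheno <- pheno[keep, , drop = FALSE]
  }
  counts["parental_selected"] <- nrow(pheno)
  k <- if (cross_type == "f2") 3 else 2
  candidates <- list()
  n_multi <- 0L; n_segr <- 0L; n_degen <- 0L; n_calls <- 0L
  seeds <- with_seed2(seed, sample.int(2^30, nrow(pheno) * 2))
  for (i in seq_len(nrow(pheno))) {
    id <- rownames(pheno)[i]
    v <- pheno[i, ]
    fit <- try(fit_mixture(v, k = k, n_starts = n_starts,
                           max_iter = max_iter, seed = seeds[2 * i - 1]),
               silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) { n_degen <- n_degen + 1L; next }
    p <- test_multimodality(v, fit, n_boot = n_boot, seed = seeds[2 * i])
    if (!(p < alpha_mix)) { n_multi <- n_multi + 1L; next }
    seg <- test_segregation(fit$proportions, cross_type, max_deviation)
    if (!seg$pass) { n_segr <- n_segr + 1L; next }
    calls <- call_genotypes(fit, threshold = threshold,
                            cross_type = cross_type)
    labeled <- FALSE
    if (!is.null(pmeans) && id %in% rownames(pmeans)) {
      calls2 <- label_parental_origin(calls, fit$means,
                                      unlist(pmeans[id, ]))
      if (!isTRUE(attr(calls2, "unlabelable"))) {
        calls <- calls2; labeled <- TRUE
      }
    }
    if (sum(!is.na(calls)) < min_informative) { n_calls <- n_calls + 1L; next }
    candidates[[id]] <- list(phenotype_id = id, calls = calls, values = v,
                             mixture = fit, multimodality_p = p,
                             origin_labeled = labeled, qc = NULL)
  }
  counts["degenerate_or_unconverged"] <- n_degen
  counts["rejected_unimodal"] <- n_multi
  counts["rejected_segregation"] <- n_segr
  counts["rejected_uninformative"] <- n_calls
  counts["mixture_selected"] <- length(candidates)
  structure(list(candidates = candidates, counts = counts),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate markers: ", length(x$candidates), " of ",
      x$counts["input"], " phenotypes\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Run QC genome scans over a set of candidate markers
#'
#' For each candidate: a single-QTL scan (with the cross's environment
#' as additive covariate when present), a two-QTL scan, a
#' genotype-by-environment test at the existing marker nearest the
#' single-QTL peak, and the [classify_candidate()] verdict.
#'
#' The trait that is interval-mapped is the candidate *marker* itself —
#' its genotype-call dosage — because the calls are what will enter the
#' map: a trustworthy candidate cosegregates with a single locus, while
#' calls contaminated by a second QTL, epistasis or environment show up
#' directly in these scans.  Calls are also far less noisy than the
#' underlying phenotype (individuals below the posterior threshold are
#' excluded rather than miscalled), which localizes the placement peak
#' much more sharply.  Candidates without calls (e.g. raw phenotypes
#' fed in for screening) are scanned on their values instead.
#'
#' @param candidates list of candidate records (each with `calls`
#'   and/or `values`), e.g. the `candidates` element of
#'   [find_candidate_markers()].
#' @param cross the cross whose map the scans run on.
#' @param thresholds [qc_thresholds()].
#' @param step_one,step_two scan grid steps (cM).
#' @param error_prob genotyping-error rate for the genotype
#'   probabilities (the original map's markers are assumed curated, so
#'   the default is small).
#' @param gp1,gp2 optional precomputed [calc_genoprob()] objects.
#' @return the candidates, each with `qc` (a `qc_verdict`), `peak_chr`,
#'   `peak_pos`, `peak_lod` filled in.
#' @export
scan_candidates <- function(candidates, cross, thresholds = qc_thresholds(),
                            step_one = 1, step_two = 5, error_prob = 1e-4,
                            gp1 = NULL, gp2 = NULL) {
  gp1 <- gp1 %||% calc_genoprob(cross, step_one, error_prob)
  gp2 <- gp2 %||% calc_genoprob(cross, step_two, error_prob)
  env <- cross$env
  covar <- if (!is.null(env) && length(unique(env)) > 1) factor(env) else NULL
  lapply(candidates, function(cand) {
    trait <- if (!is.null(cand$calls))
      geno_numeric(cand$calls, cross$cross_type) else cand$values
    s1 <- scan_one(trait, cross, covar = covar, genoprob = gp1)
    s2 <- scan_two(trait, cross, covar = covar, genoprob = gp2)
    gxe <- NA_real_
    if (!is.null(covar)) {
      # genotype at the nearest true marker to the single-QTL peak
      onchr <- cross$map[cross$map$chr == attr(s1, "peak_chr"), ]
      nearest <- onchr$marker[which.min(abs(onchr$pos - attr(s1, "peak_pos")))]
      gxe <- suppressMessages(
        test_gxe(trait, cross$geno[nearest, ], covar))
    }
    v <- classify_candidate(attr(s1, "peak_lod"), s2$second_qtl_lod,
                            s2$max_int_lod, gxe, thresholds)
    cand$qc <- v
    cand$peak_chr <- attr(s1, "peak_chr")
    cand$peak_pos <- attr(s1, "peak_pos")
    cand$peak_lod <- attr(s1, "peak_lod")
    cand
  })
}

#' Wrap an existing matrix of genotype calls as a candidate set
#'
#' Lets the map-building machinery ([build_denovo_map()]) run on marker
#' data that did not come from mixture modeling (e.g. previously scored
#' markers).
#'
#' @param geno character call matrix (markers x individuals).
#' @return a `candidate_set` whose candidates carry calls only.
#' @export
candidate_set_from_genotypes <- function(geno) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  cands <- lapply(rownames(geno), function(m)
    list(phenotype_id = m, calls = geno[m, ], values = NULL,
         mixture = NULL, origin_labeled = FALSE, qc = NULL))
  names(cands) <- rownames(geno)
  structure(list(candidates = cands,
                 counts = c(input = nrow(geno),
                            mixture_selected = nrow(geno))),
            class = "candidate_set")
}

#' Saturate an existing genetic map with candidate markers
#'
#' Candidates are interval-mapped on the original map; those passing QC
#' with a single significant QTL are inserted at their peak position
#' (marker id `"m_" + phenotype id`), the map is re-estimated, and
#' candidates that duplicate another marker's calls (rf = 0; the
#' duplicate with the highest peak LOD wins) or land within
#' `colocate_tol` cM of an original marker are removed.
#'
#' @param cross a `cross` with a genetic map.
#' @param candidate_set a [find_candidate_markers()] result (QC scans
#'   are run here, on the original map).
#' @param thresholds [qc_thresholds()].
#' @param map_function map function for re-estimation.
#' @param colocate_tol cM tolerance for co-localization with an
#'   original marker (default 0.5).
#' @param step_one,step_two scan grid steps in cM.
#' @return list of class `saturation_result`: `cross` (saturated),
#'   `report` (`saturation_report`), `verdicts` (per-candidate QC).
#' @export
saturate_map <- function(cross, candidate_set, thresholds = qc_thresholds(),
                         map_function = c("kosambi", "haldane"),
                         colocate_tol = 0.5, step_one = 1, step_two = 5) {
  map_function <- match.arg(map_function)
  cands <- candidate_set$candidates
  report <- as.list(candidate_set$counts)
  scanned <- scan_candidates(cands, cross, thresholds, step_one, step_two)
  classes <- vapply(scanned, function(x) x$qc$class, "")
  for (cl in c("gxe", "multi_qtl", "epistatic", "no_qtl"))
    report[[paste0("removed_", cl)]] <- sum(classes == cl)
  keep <- scanned[classes == "single_qtl" &
                    vapply(scanned, function(x) x$qc$action, "") == "keep"]
  report$placed <- length(keep)
  if (length(keep) == 0) {
    warning("no candidate markers survived QC; returning original map")
    rep_out <- finish_report(report, cross$map, cross$map)
    return(structure(list(cross = cross, report = rep_out,
                          verdicts = scanned),
                     class = "saturation_result"))
  }
  # insert survivors at their peak positions
  new_geno <- t(vapply(keep, function(x) x$calls,
                       character(ncol(cross$geno))))
  rownames(new_geno) <- paste0("m_", names(keep))
  colnames(new_geno) <- colnames(cross$geno)
  mk <- c(cross$map$marker, rownames(new_geno))
  chr <- c(cross$map$chr, vapply(keep, function(x) x$peak_chr, ""))
  pos <- c(cross$map$pos, vapply(keep, function(x) x$peak_pos, 0))
  ord <- order(match(chr, unique(cross$map$chr)), pos)
  allgeno <- rbind(cross$geno, new_geno)[mk[ord], , drop = FALSE]
  map1 <- genetic_map(mk[ord], chr[ord], pos[ord])
  cross1 <- make_cross(allgeno, map1, cross$cross_type,
                       pheno = cross$pheno, env = cross$env)
  cross1$map <- estimate_map(cross1, map_function)

  # duplicate removal: candidate whose calls match another marker exactly
  peak_lod <- vapply(keep, function(x) x$peak_lod, 0)
  names(peak_lod) <- paste0("m_", names(keep))
  rfm <- rf_matrix(cross1$geno, cross1$cross_type)
  is_new <- rownames(cross1$geno) %in% names(peak_lod)
  drop_dup <- character(0)
  dup <- which(rfm$rf == 0 & rfm$n >= 2, arr.ind = TRUE)
  dup <- dup[dup[, 1] < dup[, 2], , drop = FALSE]
  for (r in seq_len(nrow(dup))) {
    a <- rownames(rfm$rf)[dup[r, 1]]; b <- rownames(rfm$rf)[dup[r, 2]]
    if (a %in% drop_dup || b %in% drop_dup) next
    if (!is_new[dup[r, 1]] && !is_new[dup[r, 2]]) next
    if (!is_new[dup[r, 1]]) drop_dup <- c(drop_dup, b)
    else if (!is_new[dup[r, 2]]) drop_dup <- c(drop_dup, a)
    else drop_dup <- c(drop_dup,
                       if (peak_lod[a] >= peak_lod[b]) b else a)
  }
  report$removed_duplicate <- length(drop_dup)

  # co-localization with an original marker (post re-estimation)
  m2 <- cross1$map
  orig <- m2$marker %in% cross$map$marker
  drop_col <- character(0)
  for (i in which(!orig)) {
    if (m2$marker[i] %in% drop_dup) next
    same <- orig & m2$chr == m2$chr[i] &
      abs(m2$pos - m2$pos[i]) <= colocate_tol
    if (any(same)) drop_col <- c(drop_col, m2$marker[i])
  }
  report$removed_colocalized <- length(drop_col)
  drop <- c(drop_dup, drop_col)
  keep_mk <- setdiff(m2$marker, drop)
  m3 <- m2[m2$marker %in% keep_mk, , drop = FALSE]
  cross2 <- make_cross(cross1$geno[keep_mk, , drop = FALSE],
                       genetic_map(m3$marker, m3$chr, m3$pos, m3$bp),
                       cross$cross_type, pheno = cross$pheno,
                       env = cross$env)
  cross2$map <- estimate_map(cross2, map_function)
  report$final_new_markers <- sum(!cross2$map$marker %in% cross$map$marker)
  rep_out <- finish_report(report, cross$map, cross2$map)
  structure(list(cross = cross2, report = rep_out, verdicts = scanned),
            class = "saturation_result")
}

finish_report <- function(report, map_before, map_after) {
  report$spacing_before <- average_spacing(map_before)
  report$spacing_after <- tryCatch(average_spacing(map_after),
                                   error = function(e) NA_real_)
  report$length_before <- map_length(map_before)
  report$length_after <- map_length(map_after)
  structure(report, class = "saturation_report")
}

#' @export
print.saturation_report <- function(x, ...) {
  cat("Saturation report\n")
  for (nm in names(x))
    cat(sprintf("  %-28s %s\n", nm, format(round(as.numeric(x[[nm]]), 3))))
  invisible(x)
}

#' Build a genetic map de novo from candidate markers
#'
#' Forms linkage groups from pairwise recombination fractions, merges
#' mirrored (opposite-phase) groups for `riself` when parental labels
#' are absent, orders the markers of each group, estimates cM positions
#' and, when physical positions are supplied, names and orients the
#' chromosomes.  Intended for candidates obtained under strict settings
#' (high posterior threshold, tight segregation deviation), producing a
#' trustworthy skeleton map that a later saturation pass refines.
#'
#' @param candidate_set a [find_candidate_markers()] result.
#' @param n_chromosomes expected chromosome count (a warning reports the
#'   group sizes when the result differs).
#' @param cross_type cross type of the population.
#' @param physical optional [read_physical_positions()] table.
#' @param max_rf,min_lod linkage-group thresholds.
#' @param corr_threshold mirrored-merge correlation threshold.
#' @param ripple_window marker-ordering ripple window.
#' @param map_function map function for cM estimation.
#' @param min_group_size groups smaller than this are dropped as noise
#'   (default 2, i.e. singletons are discarded).
#' @return a `cross` carrying the skeleton map and the candidate calls.
#' @export
build_denovo_map <- function(candidate_set, n_chromosomes,
                             cross_type = "riself", physical = NULL,
                             max_rf = 0.35, min_lod = 6,
                             corr_threshold = 0.7, ripple_window = 6,
                             map_function = c("kosambi", "haldane"),
                             min_group_size = 2) {
  map_function <- match.arg(map_function)
  cands <- candidate_set$candidates
  if (length(cands) < 2) stop2("need at least 2 candidate markers")
  geno <- t(vapply(cands, function(x) x$calls,
                   character(length(cands[[1]]$calls))))
  rownames(geno) <- paste0("m_", names(cands))
  # group -> mirrored-merge -> regroup on the flipped calls, until the
  # phase flips stabilize: merging makes repulsion-phase fragments
  # visible to rf-based grouping, which can chain further fragments
  repeat {
    rfm <- rf_matrix(geno, cross_type)
    groups <- form_linkage_groups(rfm, max_rf = max_rf, min_lod = min_lod)
    if (cross_type != "riself") break
    merged <- merge_mirrored_groups(groups, geno,
                                    corr_threshold = corr_threshold)
    geno <- merged$geno
    if (length(merged$flipped) == 0) { groups <- merged$groups; break }
  }
  groups <- groups[lengths(groups) >= min_group_size]
  if (length(groups) != n_chromosomes)
    warning("formed ", length(groups), " linkage group(s), expected ",
            n_chromosomes, " (sizes: ",
            paste(lengths(groups), collapse = ", "), ")")
  ordered <- lapply(groups, order_markers, rfm = rfm,
                    ripple_window = ripple_window)
  mk <- unlist(ordered)
  chr <- rep(paste0("LG", seq_along(ordered)), lengths(ordered))
  map0 <- genetic_map(mk, chr, unlist(lapply(ordered, seq_along)) - 1)
  cross <- make_cross(geno[mk, , drop = FALSE], map0, cross_type)
  cross$map <- estimate_map(cross, map_function)
  if (!is.null(physical)) {
    cross$map <- name_and_orient_chromosomes(cross$map, physical)
    cross$geno <- cross$geno[cross$map$marker, , drop = FALSE]
  }
  cross
}

#' Flag probable genotyping errors (double recombinants)
#'
#' A call that differs from both its immediate flanking markers' calls,
#' with the two flanking markers less than `window_cm` apart, implies
#' two crossovers in a short interval — more often a genotyping error
#' than a real event.  Chromosomes with fewer than 3 markers are
#' skipped.
#'
#' @param cross a `cross` with an ordered map.
#' @param window_cm flanking-distance window (default 10 cM).
#' @param correct if `TRUE`, flagged calls are set to missing and the
#'   corrected cross is returned in the `cross` element.
#' @return list with `flags` (data.frame `marker`, `individual`, `chr`)
#'   and, when `correct = TRUE`, the corrected `cross`.
#' @export
detect_double_recombinants <- function(cross, window_cm = 10,
                                       correct = FALSE) {
  map <- cross$map
  flags <- list()
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    if (length(idx) < 3) next
    mk <- map$marker[idx]; pp <- map$pos[idx]
    g <- cross$geno[mk, , drop = FALSE]
    for (i in 2:(length(mk) - 1)) {
      if (pp[i + 1] - pp[i - 1] >= window_cm) next
      hit <- !is.na(g[i, ]) & !is.na(g[i - 1, ]) & !is.na(g[i + 1, ]) &
        g[i, ] != g[i - 1, ] & g[i, ] != g[i + 1, ]
      if (any(hit))
        flags[[length(flags) + 1L]] <- data.frame(
          marker = mk[i], individual = colnames(g)[hit], chr = cc,
          stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags)
    else data.frame(marker = character(0), individual = character(0),
                    chr = character(0), stringsAsFactors = FALSE)
  out <- list(flags = flags)
  if (correct) {
    g <- cross$geno
    g[cbind(flags$marker, flags$individual)] <- NA
    cross$geno <- g
    out$cross <- cross
  }
  out
}

#' Impute missing genotype calls from flanking markers
#'
#' Each missing call is replaced by the most probable genotype given the
#' nearest informative flanking markers and the map distances (Haldane
#' transitions, RIL-expanded for `riself`).  Exact ties (e.g. flanked by
#' `A` and `B` at equal distance) stay missing.  The imputed fraction is
#' reported with a message — imputed genotypes are inferences, not
#' observations, and downstream results should be read accordingly.
#'
#' @param cross a `cross` with an ordered map.
#' @return the cross with imputed calls; attribute `imputed_fraction`
#'   gives the fraction of formerly missing calls that were filled.
#' @export
fill_missing <- function(cross) {
  gp <- calc_genoprob(cross, step = max(map_length(cross$map), 1))
  # grid column of each marker (match by chr+pos: co-located markers
  # legitimately share a column)
  midx <- vapply(seq_len(nrow(cross$map)), function(i)
    which(gp$pos$chr == cross$map$chr[i] &
            gp$pos$pos == cross$map$pos[i])[1], 0L)
  n_missing <- 0L; n_imputed <- 0L
  g <- cross$geno
  empty_ind <- colSums(!is.na(g)) == 0
  if (any(empty_ind))
    warning("individual(s) with no genotype data left missing: ",
            paste(colnames(g)[empty_ind], collapse = ", "))
  for (i in seq_len(nrow(g))) {
    miss <- which(is.na(g[i, ]) & !empty_ind)
    n_missing <- n_missing + sum(is.na(g[i, ]))
    if (!length(miss)) next
    p <- gp$prob[miss, midx[i], , drop = FALSE]
    for (j in seq_along(miss)) {
      pj <- p[j, 1, ]
      top <- which(pj == max(pj))
      if (length(top) == 1 && max(pj) > 0.5) {
        g[i, miss[j]] <- gp$classes[top]
        n_imputed <- n_imputed + 1L
      }
    }
  }
  frac <- if (n_missing) n_imputed / n_missing else 0
  message("imputed ", n_imputed, " of ", n_missing, " missing calls (",
          round(100 * frac, 1), "%)")
  cross$geno <- g
  attr(cross, "imputed_fraction") <- frac
  cross
}
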