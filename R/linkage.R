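# Two-point linkage machinery: recombination-fraction estimation,
# linkage grouping, parent-free phasing via mirrored-group merging,
# marker ordering and conversion of recombination fractions to cM.

#' Map functions: recombination fraction to cM and back
#'
#' Haldane (no crossover interference): `d = -50 log(1 - 2r)`.
#' Kosambi (partial interference): `d = 25 log((1 + 2r) / (1 - 2r))`.
#' The pair are exact inverses.
#'
#' @param rf meiotic recombination fraction in `[0, 0.5)`.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @return distance in cM.
#' @export
rf_to_cm <- function(rf, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (any(rf < 0 | rf >= 0.5))
    stop2("rf must be in [0, 0.5): markers with rf >= 0.5 are unlinked")
  switch(map_function,
    haldane = -50 * log(1 - 2 * rf),
    kosambi = 25 * log((1 + 2 * rf) / (1 - 2 * rf)))
}

#' @rdname rf_to_cm
#' @param cm distance in cM (>= 0).
#' @export
cm_to_rf <- function(cm, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (any(cm < 0)) stop2("cM distances must be >= 0")
  switch(map_function,
    haldane = (1 - exp(-cm / 50)) / 2,
    kosambi = tanh(cm / 50) / 2)
}

# RIL-by-selfing map expansion: observed switch fraction R vs meiotic r.
ril_expand <- function(r) 2 * r / (1 + 2 * r)
ril_deexpand <- function(R) R / (2 * (1 - R))

# two-locus F2 joint genotype probabilities (3x3, classes A,H,B) at
# meiotic recombination fraction r: convolution of two gamete chains
f2_joint_probs <- function(r) {
  # gamete haplotype probs over (left allele, right allele)
  h <- matrix(c(1 - r, r, r, 1 - r) / 2, 2, 2)
  p <- matrix(0, 3, 3)
  for (g1a in 1:2) for (g1b in 1:2) for (g2a in 1:2) for (g2b in 1:2) {
    i <- (g1a - 1) + (g1b - 1) + 1  # dosage at left locus + 1
    j <- (g2a - 1) + (g2b - 1) + 1
    p[i, j] <- p[i, j] + h[g1a, g2a] * h[g1b, g2b]
  }
  p
}

#' Estimate the pairwise recombination fraction between two markers
#'
#' For `riself` and `bc` the estimate is the observed fraction of
#' discordant calls among jointly informative individuals, capped at
#' 0.5; the LOD is the log10 likelihood ratio against independence
#' (rf = 0.5).  Note that for `riself` this is the *observed* RIL
#' fraction `R`; it is de-expanded to the meiotic `r = R / (2(1 - R))`
#' only when converting to map distance (see [estimate_map()]).
#' For `f2` the estimate maximizes the 9-cell joint-table likelihood
#' numerically.  Semi-informative calls are treated as missing here.
#'
#' @param calls_i,calls_j character call vectors of equal length.
#' @param cross_type `"riself"`, `"bc"` or `"f2"`.
#' @return list with `rf`, `lod`, `n` (jointly informative
#'   individuals) and `phase_flipped` (`TRUE` when the observed
#'   discordance exceeded 0.5, i.e. the pair co-segregates in
#'   repulsion).  `rf` is `NA` when fewer than 2 joint observations
#'   exist (pair unlinked/undefined).
#' @export
estimate_rf <- function(calls_i, calls_j, cross_type = "riself") {
  codes <- full_codes(cross_type)
  ok <- calls_i %in% codes & calls_j %in% codes
  n <- sum(ok)
  if (n < 2)
    return(list(rf = NA_real_, lod = 0, n = n, phase_flipped = FALSE))
  if (cross_type == "f2") {
    tab <- table(factor(calls_i[ok], levels = codes),
                 factor(calls_j[ok], levels = codes))
    negll <- function(r) -sum(tab * log(f2_joint_probs(r) + 1e-300))
    opt <- stats::optimize(negll, c(1e-6, 0.5))
    rf <- opt$minimum
    lod <- (negll(0.5) - opt$objective) / log(10)
    if (negll(0.5) <= opt$objective + 1e-12) { rf <- 0.5; lod <- 0 }
    return(list(rf = rf, lod = max(lod, 0), n = n, phase_flipped = FALSE))
  }
  k <- sum(calls_i[ok] != calls_j[ok])
  R <- k / n
  flipped <- R > 0.5
  rf <- min(R, 0.5)
  lod <- n * log10(2) + xlog10(k, rf) + xlog10(n - k, 1 - rf)
  list(rf = rf, lod = max(lod, 0), n = n, phase_flipped = flipped)
}

#' Pairwise recombination fractions for all markers
#'
#' Vectorized over the 0/1 call coding for `riself`/`bc`; `f2` falls
#' back to per-pair ML.  The result is symmetric with a zero diagonal.
#'
#' @param geno character call matrix (markers x individuals).
#' @param cross_type cross type.
#' @return object of class `rf_matrix`: list of matrices `rf`, `lod`,
#'   `n` (markers x markers).
#' @export
rf_matrix <- function(geno, cross_type = "riself") {
  m <- nrow(geno)
  mk <- rownames(geno)
  if (cross_type %in% c("riself", "bc")) {
    num <- matrix(geno_numeric(geno, cross_type), m,
                  dimnames = dimnames(geno))
    I1 <- (num == 1); I1[is.na(I1)] <- FALSE
    I0 <- (num == 0); I0[is.na(I0)] <- FALSE
    storage.mode(I1) <- "numeric"; storage.mode(I0) <- "numeric"
    nj <- (I1 + I0) %*% t(I1 + I0)
    kk <- I1 %*% t(I0) + I0 %*% t(I1)
    R <- ifelse(nj > 0, kk / nj, NA_real_)
    rf <- pmin(R, 0.5)
    rf[nj < 2] <- NA_real_
    lod <- nj * log10(2) + ifelse(kk == 0, 0, kk * log10(pmax(rf, 1e-300))) +
      ifelse(nj - kk == 0, 0, (nj - kk) * log10(pmax(1 - rf, 1e-300)))
    lod[is.na(rf)] <- 0
    lod <- pmax(lod, 0)
  } else {
    rf <- matrix(NA_real_, m, m); lod <- matrix(0, m, m)
    nj <- matrix(0, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      e <- estimate_rf(geno[i, ], geno[j, ], cross_type)
      rf[i, j] <- rf[j, i] <- e$rf
      lod[i, j] <- lod[j, i] <- e$lod
      nj[i, j] <- nj[j, i] <- e$n
    }
  }
  diag(rf) <- 0; diag(lod) <- 0
  dimnames(rf) <- dimnames(lod) <- dimnames(nj) <- list(mk, mk)
  structure(list(rf = rf, lod = lod, n = nj), class = "rf_matrix")
}

#' Form linkage groups by single-linkage clustering
#'
#' Two markers are linked when `rf <= max_rf` **and** `lod >= min_lod`;
#' groups are the connected components of the resulting graph
#' (transitive closure), returned sorted by size, largest first.
#' Singletons are allowed.
#'
#' @param rfm an [rf_matrix()].
#' @param max_rf linkage threshold on the recombination fraction.
#' @param min_lod linkage threshold on the LOD.
#' @return list of character vectors of marker ids.
#' @export
form_linkage_groups <- function(rfm, max_rf = 0.35, min_lod = 6) {
  mk <- rownames(rfm$rf)
  m <- length(mk)
  adj <- !is.na(rfm$rf) & rfm$rf <= max_rf & rfm$lod >= min_lod
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, m)
  cid <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(adj[u, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  groups <- split(mk, comp)
  groups[order(-lengths(groups))]
}

#' Merge mirrored linkage groups (parent-free phasing)
#'
#' Without parental labels the mixture components of each phenotype get
#' arbitrary A/B labels, so the markers of one chromosome split into two
#' groups of opposite phase that co-segregate in repulsion (strong
#' negative correlation).  For each pair of groups whose mean pairwise
#' call correlation is at or below `-corr_threshold`, all calls of one
#' group are inverted (A and B swapped) and the groups are merged;
#' this repeats until no pair qualifies.  A group negatively correlated
#' with two distinct partners is ambiguous and raises an error naming
#' the triple.  `riself` only.
#'
#' The correlation statistic between two groups is the *minimum*
#' pairwise call correlation across the two marker sets: it detects
#' repulsion-phase contact between any parts of the two groups.  A
#' plain mean would be diluted toward zero by the many weakly
#' correlated distant marker pairs whenever groups span whole (or
#' half) chromosomes — exactly the configurations that must merge.
#' With ~150 individuals a spurious correlation of magnitude 0.7 is a
#' many-sigma event, so the minimum is safe against noise.
#'
#' @param groups list of marker-id vectors from [form_linkage_groups()].
#' @param geno character call matrix covering all grouped markers.
#' @param corr_threshold magnitude of mean negative correlation required
#'   to merge (default 0.7).
#' @return list with `groups` (merged), `geno` (calls with inverted
#'   groups flipped) and `flipped` (ids of markers whose calls were
#'   inverted).
#' @export
merge_mirrored_groups <- function(groups, geno, corr_threshold = 0.7) {
  num <- matrix(geno_numeric(geno, "riself"), nrow(geno),
                dimnames = dimnames(geno))
  flipped <- character(0)
  repeat {
    ng <- length(groups)
    if (ng < 2) break
    gcor <- matrix(NA_real_, ng, ng)
    for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
      cc <- suppressWarnings(stats::cor(t(num[groups[[i]], , drop = FALSE]),
                                        t(num[groups[[j]], , drop = FALSE]),
                                        use = "pairwise.complete.obs"))
      gcor[i, j] <- gcor[j, i] <- min(cc, na.rm = TRUE)
    }
    cand <- which(gcor <= -corr_threshold, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) == 0) break
    # a group may legitimately mirror several same-phase fragments of
    # one chromosome (merged greedily, most negative pair first); it is
    # ambiguous only when two of its partners also mirror EACH OTHER -
    # no phase assignment can then be consistent
    partners <- table(c(cand[, 1], cand[, 2]))
    for (g in as.integer(names(partners)[partners > 1])) {
      others <- unique(c(cand[cand[, 1] == g, 2], cand[cand[, 2] == g, 1]))
      op <- utils::combn(others, 2)
      bad <- which(gcor[t(op)] <= -corr_threshold)
      if (length(bad))
        stop2("ambiguous mirrored-group structure: group ", g,
              " is strongly negatively correlated with groups ",
              op[1, bad[1]], " and ", op[2, bad[1]],
              ", which also mirror each other")
    }
    best <- cand[which.min(gcor[cand]), ]
    i <- best[1]; j <- best[2]
    flip_ids <- groups[[j]]
    num[flip_ids, ] <- 1 - num[flip_ids, , drop = FALSE]
    flipped <- c(flipped, flip_ids)
    groups[[i]] <- c(groups[[i]], groups[[j]])
    groups <- groups[-j]
  }
  swap <- c(A = "B", B = "A")
  flip_geno <- geno
  hit <- flip_geno[flipped, , drop = FALSE]
  hit[] <- ifelse(is.na(hit), NA, swap[hit])
  flip_geno[flipped, ] <- hit
  names(groups) <- NULL
  list(groups = groups[order(-lengths(groups))], geno = flip_geno,
       flipped = flipped)
}

order_objective <- function(ord, rf) {
  r <- rf[cbind(ord[-length(ord)], ord[-1])]
  sum(ifelse(is.na(r), 0.5, r))
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# exhaustive minimum-rf-path ordering; test oracle for small groups
order_markers_exhaustive <- function(markers, rfm) {
  stopifnot(length(markers) <= 8)
  rf <- rfm$rf[markers, markers, drop = FALSE]
  idx <- seq_along(markers)
  best <- idx; best_obj <- order_objective(idx, rf)
  for (p in all_perms(idx)) {
    o <- order_objective(p, rf)
    if (o < best_obj - 1e-12) { best <- p; best_obj <- o }
  }
  canonical_order(markers[best])
}

canonical_order <- function(ids) {
  if (length(ids) > 1 && ids[1] > ids[length(ids)]) rev(ids) else ids
}

#' Order the markers of a linkage group
#'
#' Greedy insertion (seeded from the tightest pair, each remaining
#' marker inserted where it least increases the sum of adjacent
#' recombination fractions), refined by exhaustive ripple over sliding
#' windows of `ripple_window` markers until no improvement.  The
#' objective never increases across ripple passes.  Reversal-equivalent
#' orders are canonicalized with the lexicographically smaller endpoint
#' first.
#'
#' @param markers character vector of marker ids (the group).
#' @param rfm an [rf_matrix()] covering them.
#' @param ripple_window window size for the ripple refinement.
#' @return ordered character vector of marker ids.
#' @export
order_markers <- function(markers, rfm, ripple_window = 6) {
  m <- length(markers)
  if (m <= 2) return(canonical_order(markers))
  rf <- rfm$rf[markers, markers, drop = FALSE]
  rf[is.na(rf)] <- 0.5
  diag(rf) <- Inf
  seedpair <- which(rf == min(rf), arr.ind = TRUE)[1, ]
  ord <- as.integer(seedpair)
  rest <- setdiff(seq_len(m), ord)
  diag(rf) <- 0
  while (length(rest)) {
    # pick the unplaced marker closest to the placed set
    sub <- rf[rest, ord, drop = FALSE]
    nxt <- rest[which.min(apply(sub, 1, min))]
    slots <- seq_len(length(ord) + 1)
    objs <- vapply(slots, function(s)
      order_objective(append(ord, nxt, after = s - 1), rf), 0)
    ord <- append(ord, nxt, after = which.min(objs) - 1)
    rest <- setdiff(rest, nxt)
  }
  # ripple refinement
  w <- min(ripple_window, m)
  improved <- TRUE
  while (improved && w >= 2) {
    improved <- FALSE
    cur_obj <- order_objective(ord, rf)
    for (s in seq_len(m - w + 1)) {
      window <- ord[s:(s + w - 1)]
      for (p in all_perms(window)) {
        cand <- ord
        cand[s:(s + w - 1)] <- p
        o <- order_objective(cand, rf)
        if (o < cur_obj - 1e-12) {
          ord <- cand; cur_obj <- o; improved <- TRUE
        }
      }
    }
  }
  canonical_order(markers[ord])
}

#' Estimate cM positions along a fixed marker order
#'
#' For each chromosome, adjacent-pair recombination fractions are
#' estimated from the calls ([estimate_rf()]; for `riself` the observed
#' fraction is de-expanded to the meiotic `r = R / (2(1 - R))` first),
#' converted through the map function and cumulated into positions
#' starting at 0.  An adjacent pair without joint data, or observed at
#' rf 0.5, gets the mean of the chromosome's estimable gaps
#' (neighbor interpolation) and is flagged in the `interpolated`
#' attribute.
#'
#' @param cross a `cross` whose map fixes the marker order.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @return a new [genetic_map()] with re-estimated positions.
#' @export
estimate_map <- function(cross, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  map <- cross$map
  geno <- cross$geno
  newpos <- numeric(nrow(map))
  interp <- character(0)
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    mks <- map$marker[idx]
    if (length(mks) == 1) { newpos[idx] <- 0; next }
    d <- rep(NA_real_, length(mks) - 1)
    for (i in seq_len(length(mks) - 1)) {
      e <- estimate_rf(geno[mks[i], ], geno[mks[i + 1], ], cross$cross_type)
      R <- e$rf
      if (is.na(R) || R >= 0.5) next
      r <- if (cross$cross_type == "riself") ril_deexpand(R) else R
      if (r >= 0.5) next
      d[i] <- rf_to_cm(r, map_function)
    }
    if (anyNA(d)) {
      fill <- if (all(is.na(d))) 0 else mean(d, na.rm = TRUE)
      interp <- c(interp, mks[which(is.na(d))])
      d[is.na(d)] <- fill
    }
    newpos[idx] <- cumsum(c(0, d))
  }
  out <- genetic_map(map$marker, map$chr, newpos, map$bp)
  attr(out, "interpolated") <- interp
  out
}

#' Name and orient chromosomes from known physical positions
#'
#' Each linkage group is named by the majority physical chromosome of
#' its markers (looked up via the phenotype id, i.e. the marker id with
#' any `"m_"` prefix removed); dissenting markers are reported in the
#' `dissenters` attribute and a majority tie is an error.  A group whose
#' cM order anti-correlates with physical bp order (Spearman rho < 0)
#' is flipped.  Groups with no positioned marker keep their provisional
#' name (with a message).
#'
#' @param map a provisional [genetic_map()] (chromosome per linkage
#'   group, cM positions set).
#' @param physical table from [read_physical_positions()].
#' @return a `genetic_map` with physical chromosome names, orientation
#'   fixed and `bp` filled where known.
#' @export
name_and_orient_chromosomes <- function(map, physical) {
  pheno_id <- sub("^m_", "", map$marker)
  pos <- lookup_position(physical, pheno_id)
  out <- map
  out$bp <- pos$bp
  dissenters <- character(0)
  pieces <- list()
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    piece <- out[idx, , drop = FALSE]
    known <- !is.na(pos$chr[idx])
    if (!any(known)) {
      message("linkage group '", cc, "' has no positioned markers; ",
              "keeping provisional name")
      pieces[[length(pieces) + 1L]] <- piece
      next
    }
    votes <- table(pos$chr[idx][known])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1)
      stop2("majority vote tie for linkage group '", cc, "': candidates ",
            paste(top, collapse = ", "))
    piece$chr <- top
    dis <- map$marker[idx][known][pos$chr[idx][known] != top]
    dissenters <- c(dissenters, dis)
    on_chr <- known & pos$chr[idx] == top
    if (sum(on_chr) >= 2) {
      rho <- suppressWarnings(
        stats::cor(piece$pos[on_chr], pos$bp[idx][on_chr],
                   method = "spearman"))
      if (!is.na(rho) && rho < 0) {
        piece <- piece[rev(seq_len(nrow(piece))), , drop = FALSE]
        piece$pos <- max(piece$pos) - piece$pos
      }
    }
    pieces[[length(pieces) + 1L]] <- piece
  }
  res <- do.call(rbind, pieces)
  res <- res[order(match(res$chr, unique(res$chr))), , drop = FALSE]
  out <- genetic_map(res$marker, res$chr, res$pos, res$bp)
  attr(out, "dissenters") <- dissenters
  out
}
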