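# Synthetic crosses and molecular phenotypes with full ground truth.
# The default design mirrors a typical RIL expression-genetics study:
# 148 selfed RILs measured in 4 environments, parents replicated twice
# per environment (8 replicates each when pooled).

#' Simulate a genetic map
#'
#' Markers uniformly spaced along each chromosome (optionally jittered),
#' with physical positions on a fixed 250 kb per cM scale so that
#' physical-position-driven steps (chromosome naming, GFF export) are
#' exercisable.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers per chromosome.
#' @param length_cm chromosome length in cM.
#' @param seed integer seed.
#' @param jitter if `TRUE`, spacings are perturbed (positions stay
#'   sorted within `[0, length_cm]`).
#' @param bp_per_cm physical scale (default 250000).
#' @return a [genetic_map()] with `bp` filled.
#' @export
simulate_map <- function(n_chr = 5, markers_per_chr = 11, length_cm = 100,
                         seed = NULL, jitter = FALSE, bp_per_cm = 250000) {
  stopifnot(n_chr >= 1, markers_per_chr >= 1, length_cm >= 0)
  with_seed2(seed, {
    maps <- lapply(seq_len(n_chr), function(cc) {
      pos <- if (markers_per_chr == 1) 0
        else seq(0, length_cm, length.out = markers_per_chr)
      if (jitter && markers_per_chr > 2 && length_cm > 0) {
        mid <- pos[-c(1, markers_per_chr)]
        gap <- length_cm / (markers_per_chr - 1)
        pos[-c(1, markers_per_chr)] <-
          sort(pmin(pmax(mid + stats::runif(length(mid), -gap / 3, gap / 3),
                         0), length_cm))
      }
      data.frame(marker = sprintf("c%dm%02d", cc, seq_len(markers_per_chr)),
                 chr = as.character(cc), pos = pos,
                 bp = round(pos * bp_per_cm) + 1)
    })
    m <- do.call(rbind, maps)
    genetic_map(m$marker, m$chr, m$pos, m$bp)
  })
}

#' Simulate genotypes along a map
#'
#' Per chromosome, the first marker is drawn from the cross-type class
#' frequencies and subsequent markers follow the Markov transition
#' implied by the inter-marker recombination fraction (map-function
#' inverse; expanded to the observed scale for `riself`).  F2
#' genotypes are built from two independent gamete chains.
#'
#' @param map a [genetic_map()].
#' @param n_ind number of individuals.
#' @param cross_type `"riself"`, `"bc"` or `"f2"`.
#' @param map_function map function whose inverse turns cM gaps into
#'   recombination fractions (default `"haldane"` — simulation from an
#'   interference-free crossover process).
#' @param seed integer seed.
#' @return character genotype matrix (markers x individuals).
#' @export
simulate_genotypes <- function(map, n_ind, cross_type = "riself",
                               map_function = "haldane", seed = NULL) {
  with_seed2(seed, {
    n_gam <- if (cross_type == "f2") 2L else 1L
    geno <- matrix(NA_character_, nrow(map), n_ind,
                   dimnames = list(map$marker,
                                   sprintf("ind%03d", seq_len(n_ind))))
    for (cc in unique(map$chr)) {
      idx <- which(map$chr == cc)
      gaps <- diff(map$pos[idx])
      m <- length(idx)
      sim_chain <- function(sw) {
        g <- matrix(0L, m, n_ind)
        g[1, ] <- stats::rbinom(n_ind, 1, 0.5)
        if (m > 1) for (i in 2:m) {
          flip <- stats::rbinom(n_ind, 1, sw[i - 1])
          g[i, ] <- ifelse(flip == 1, 1L - g[i - 1, ], g[i - 1, ])
        }
        g
      }
      if (cross_type == "f2") {
        sw <- cm_to_rf(gaps, map_function)
        dosage <- sim_chain(sw) + sim_chain(sw)
        geno[idx, ] <- c("A", "H", "B")[dosage + 1]
      } else {
        r <- cm_to_rf(gaps, map_function)
        sw <- if (cross_type == "riself") ril_expand(r) else r
        cls <- full_codes(cross_type)
        geno[idx, ] <- cls[sim_chain(sw) + 1]
      }
    }
    geno
  })
}

#' Simulate molecular phenotypes with known truth
#'
#' Each phenotype belongs to one class, mirroring the kinds of
#' expression traits a cross produces:
#' * `clean_local` — single QTL of size `effect` at a marker whose
#'   physical position the phenotype carries (cis eQTL);
#' * `clean_distant` — same genetics, physical position elsewhere
#'   (trans eQTL);
#' * `gxe` — QTL effect of opposite sign (`± effect/2`) in the two
#'   halves of the environments; the marginal effect is zero, so such a
#'   trait carries no usable marker information and the QC step should
#'   discard it (as genotype-by-environment interaction when the
#'   interaction LOD is strong, otherwise as showing no QTL);
#' * `epistatic` — main effect `effect` at one locus plus an
#'   interaction of the same magnitude with an unlinked locus
#'   (`effect * 4 (g1 - 1/2)(g2 - 1/2)`): the trait is bimodal and
#'   looks like a marker, but the lump assignment follows the XOR of
#'   the two loci — a ghost marker the two-QTL scan must catch;
#' * `multi_qtl` — two additive QTL of size `effect` on different
#'   chromosomes;
#' * `no_qtl` — noise only.
#'
#' The generative model per individual is
#' `y = mu + sum(a_q * g_q * s_env) + i * 4 (g1 - 1/2)(g2 - 1/2) + e`,
#' `e ~ N(0, sigma^2)`, effects in units of `sigma`.  Parental
#' replicates are generated from the same model with all-A and all-B
#' genotypes, per environment, so parental contrasts inherit each
#' class's structure (in particular, opposite-sign `gxe` traits have
#' equal pooled parental means and are invisible to the parental
#' t-test).
#'
#' @param geno genotype matrix from [simulate_genotypes()].
#' @param map the map it was simulated on.
#' @param counts named integer vector of phenotypes per class.
#' @param effect QTL effect size in residual-sd units (default 2).
#' @param sigma residual standard deviation (default 1).
#' @param env_labels environment label per individual (default: 4
#'   environments in balanced blocks).
#' @param parental_reps parental replicates per environment per parent
#'   (default 2).
#' @param baseline grand mean `mu` (default 10, a typical log2
#'   expression level).
#' @param seed integer seed.
#' @return list with `pheno` (matrix), `parental` ([parental_data()]),
#'   `truth` (data.frame: id, class, QTL markers, effects) and
#'   `env` (labels used).
#' @export
simulate_phenotypes <- function(geno, map,
                                counts = c(clean_local = 30,
                                           clean_distant = 10, gxe = 10,
                                           epistatic = 10, multi_qtl = 10,
                                           no_qtl = 30),
                                effect = 2, sigma = 1, env_labels = NULL,
                                parental_reps = 2, baseline = 10,
                                seed = NULL) {
  n_ind <- ncol(geno)
  if (is.null(env_labels))
    env_labels <- paste0("env", rep_len(1:4, n_ind))
  n_env <- length(unique(env_labels))
  if (any(counts[c("epistatic", "multi_qtl")] > 0, na.rm = TRUE) &&
      length(unique(map$chr)) < 2)
    stop2("epistatic and multi_qtl classes need at least 2 chromosomes")
  with_seed2(seed, {
    rows <- list(); truth <- list()
    gnum <- matrix(geno_numeric(geno, "riself"), nrow(geno),
                   dimnames = dimnames(geno))
    if (anyNA(gnum))  # f2 input: dosage scaled to [0,1]
      gnum <- matrix(geno_numeric(geno, "f2") / 2, nrow(geno),
                     dimnames = dimnames(geno))
    pick2 <- function() {
      ch <- sample(unique(map$chr), 2)
      c(sample(map$marker[map$chr == ch[1]], 1),
        sample(map$marker[map$chr == ch[2]], 1))
    }
    envs <- unique(env_labels)
    half <- envs[seq_len(ceiling(n_env / 2))]
    sign_of_env <- function(e) ifelse(e %in% half, 1, -1)
    # class mean given genotypes (0/1 scale) and environment labels
    class_mean <- function(cls, g1, g2, env) {
      switch(cls,
        clean_local = ,
        clean_distant = baseline + effect * sigma * g1,
        gxe = baseline + (effect / 2) * sigma * g1 * sign_of_env(env),
        epistatic = baseline + effect * sigma * g1 +
          effect * sigma * 4 * (g1 - 0.5) * (g2 - 0.5),
        multi_qtl = baseline + effect * sigma * (g1 + g2),
        no_qtl = rep(baseline, length(g1)))
    }
    pid <- 0L
    for (cls in names(counts)) {
      for (rep_i in seq_len(counts[[cls]])) {
        pid <- pid + 1L
        id <- sprintf("ph%04d_%s", pid, cls)
        q1 <- q2 <- NA_character_; a1 <- a2 <- ii <- 0
        if (cls %in% c("clean_local", "clean_distant", "gxe")) {
          q1 <- sample(map$marker, 1)
          a1 <- if (cls == "gxe") effect / 2 else effect
        } else if (cls %in% c("epistatic", "multi_qtl")) {
          qq <- pick2(); q1 <- qq[1]; q2 <- qq[2]
          if (cls == "epistatic") { a1 <- effect; ii <- effect }
          else a1 <- a2 <- effect
        }
        g1 <- if (is.na(q1)) rep(0, n_ind) else gnum[q1, ]
        g2 <- if (is.na(q2)) rep(0, n_ind) else gnum[q2, ]
        rows[[id]] <- class_mean(cls, g1, g2, env_labels) +
          stats::rnorm(n_ind, 0, sigma)
        truth[[id]] <- data.frame(
          id = id, class = cls, qtl1 = q1, qtl2 = q2,
          effect1 = a1, effect2 = a2, interaction = ii,
          sigma = sigma, stringsAsFactors = FALSE)
      }
    }
    pheno <- do.call(rbind, rows)
    colnames(pheno) <- colnames(geno)
    # parental replicates: same model, all-A / all-B genotypes, per env
    rep_env <- rep(envs, each = parental_reps)
    n_reps <- length(rep_env)
    pa <- pb <- matrix(NA_real_, nrow(pheno), n_reps,
                       dimnames = list(rownames(pheno),
                                       paste0(rep_env, "_r",
                                              rep(seq_len(parental_reps),
                                                  n_env))))
    for (i in seq_along(truth)) {
      cls <- truth[[i]]$class
      z <- rep(0, n_reps); o <- rep(1, n_reps)
      pa[i, ] <- class_mean(cls, z, z, rep_env) +
        stats::rnorm(n_reps, 0, sigma)
      pb[i, ] <- class_mean(cls, o, o, rep_env) +
        stats::rnorm(n_reps, 0, sigma)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(pheno = pheno,
         parental = parental_data(pa, pb, env_A = rep_env, env_B = rep_env),
         truth = truth, env = env_labels)
  })
}

#' Simulate a complete study (map, genotypes, phenotypes)
#'
#' Convenience wrapper with defaults mirroring the study design the
#' package targets: a 5-chromosome, 100 cM-per-chromosome selfed-RIL
#' map, 148 individuals in 4 environments and parents replicated twice
#' per environment.
#'
#' @param n_ind individuals (default 148).
#' @param n_chr,markers_per_chr,length_cm map layout.
#' @param cross_type cross type.
#' @param counts phenotype class counts (see [simulate_phenotypes()]).
#' @param effect,sigma effect size (sd units) and residual sd.
#' @param seed integer seed.
#' @param ... passed to [simulate_phenotypes()].
#' @return list with `cross` (true genotypes + map), `pheno`,
#'   `parental`, `truth`, `env`, `physical` (positions table usable as
#'   [read_physical_positions()] output).
#' @export
simulate_study <- function(n_ind = 148, n_chr = 5, markers_per_chr = 11,
                           length_cm = 100, cross_type = "riself",
                           counts = c(clean_local = 30, clean_distant = 10,
                                      gxe = 10, epistatic = 10,
                                      multi_qtl = 10, no_qtl = 30),
                           effect = 2, sigma = 1, seed = 1, ...) {
  seeds <- with_seed2(seed, sample.int(2^30, 3))
  map <- simulate_map(n_chr, markers_per_chr, length_cm, seed = seeds[1])
  geno <- simulate_genotypes(map, n_ind, cross_type, seed = seeds[2])
  sim <- simulate_phenotypes(geno, map, counts = counts, effect = effect,
                             sigma = sigma, seed = seeds[3], ...)
  cross <- make_cross(geno, map, cross_type, env = sim$env)
  # physical positions for the phenotypes: local phenotypes sit at their
  # QTL marker, others at a random (distant) location
  phys <- with_seed2(seeds[1], {
    n <- nrow(sim$truth)
    at_qtl <- sim$truth$class == "clean_local" & !is.na(sim$truth$qtl1)
    chr <- sample(unique(map$chr), n, replace = TRUE)
    bp <- round(stats::runif(n, 0, max(map$pos) * 250000)) + 1
    i <- match(sim$truth$qtl1[at_qtl], map$marker)
    chr[at_qtl] <- map$chr[i]
    bp[at_qtl] <- map$bp[i]
    data.frame(id = sim$truth$id, chr = chr, bp = bp,
               stringsAsFactors = FALSE)
  })
  c(list(cross = cross, physical = phys), sim)
}
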