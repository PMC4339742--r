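# Small fixtures built in code, shared across test files.

# a deterministic toy riself cross: 2 chromosomes, clean genotypes
toy_cross <- function(n_ind = 6) {
  geno <- rbind(
    m1 = rep(c("A", "B"), length.out = n_ind),
    m2 = rep(c("A", "B"), length.out = n_ind),
    m3 = rep(c("B", "A"), length.out = n_ind),
    m4 = rep(c("A", "A", "B"), length.out = n_ind))
  colnames(geno) <- paste0("i", seq_len(n_ind))
  map <- genetic_map(c("m1", "m2", "m3", "m4"),
                     c("1", "1", "1", "2"), c(0, 5, 30, 0),
                     bp = c(100, 1250000, 7500000, 2000))
  make_cross(geno, map, "riself")
}

# simulated cross shared by scan/builder tests (built once per run)
sim_cross_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- simulate_map(5, 11, 100, seed = 401)
      geno <- simulate_genotypes(map, 150, "riself", seed = 402)
      cache <<- make_cross(geno, map, "riself")
    }
    cache
  }
})

genoprob_cache <- local({
  cache <- list()
  function(step) {
    key <- as.character(step)
    if (is.null(cache[[key]]))
      cache[[key]] <<- calc_genoprob(sim_cross_cache(), step = step)
    cache[[key]]
  }
})

# 0/1 dosage of a marker in the shared cross
dosage <- function(marker) {
  unname(ifelse(sim_cross_cache()$geno[marker, ] == "B", 1, 0))
}

# randomly re-phase markers (what parent-free mixture labeling does)
random_phase_flip <- function(geno, n_flip, seed) {
  withr::with_seed(seed, {
    flip <- sample(nrow(geno), n_flip)
    swap <- c(A = "B", B = "A")
    geno[flip, ] <- matrix(swap[geno[flip, ]], nrow = n_flip)
    geno
  })
}
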