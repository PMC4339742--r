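test_that("theoretical resolution is 100/n", {
  expect_equal(round(theoretical_resolution(148), 2), 0.68)
  expect_equal(theoretical_resolution(100), 1)
  expect_equal(theoretical_resolution(1), 100)
  expect_error(theoretical_resolution(0), "positive")
})

test_that("average spacing averages adjacent same-chromosome gaps", {
  m <- genetic_map(paste0("m", 1:3), rep("1", 3), c(0, 10, 20))
  expect_equal(average_spacing(m), 10)
  m2 <- genetic_map(paste0("m", 1:4), c("1", "1", "2", "2"), c(0, 5, 0, 5))
  expect_equal(average_spacing(m2), 5)
  # inserting a marker mid-gap strictly decreases the average
  m3 <- genetic_map(paste0("m", 1:4), rep("1", 4), c(0, 5, 10, 20))
  expect_lt(average_spacing(m3), average_spacing(m))
  expect_error(average_spacing(genetic_map("m1", "1", 0)), "adjacent")
})

test_that("double recombinants are flagged inside short windows only", {
  geno <- rbind(m1 = c("A", "A"), m2 = c("A", "B"), m3 = c("A", "A"))
  colnames(geno) <- c("i1", "i2")
  near <- make_cross(geno, genetic_map(rownames(geno), "1", c(0, 1, 2)),
                     "riself")
  out <- detect_double_recombinants(near, window_cm = 10)
  expect_identical(out$flags$marker, "m2")
  expect_identical(out$flags$individual, "i2")
  far <- make_cross(geno, genetic_map(rownames(geno), "1", c(0, 40, 80)),
                    "riself")
  expect_equal(nrow(detect_double_recombinants(far, 10)$flags), 0)
  # correction sets the flagged cell to missing
  corr <- detect_double_recombinants(near, 10, correct = TRUE)
  expect_true(is.na(corr$cross$geno["m2", "i2"]))
})

test_that("noise-free simulated genotypes produce no double recombinants", {
  cross <- sim_cross_cache()
  expect_equal(nrow(detect_double_recombinants(cross, 10)$flags), 0)
})

test_that("imputation fills from flanking markers, leaves ties missing", {
  geno <- rbind(m1 = c("A", "A", "A"), m2 = c(NA, NA, "B"),
                m3 = c("A", "B", "B"))
  colnames(geno) <- paste0("i", 1:3)
  cross <- make_cross(geno, genetic_map(rownames(geno), "1", c(0, 1, 2)),
                      "riself")
  filled <- suppressMessages(fill_missing(cross))
  expect_identical(filled$geno["m2", "i1"], "A")   # A...A -> A
  expect_true(is.na(filled$geno["m2", "i2"]))      # A...B tie stays missing
  expect_identical(filled$geno["m2", "i3"], "B")
})

test_that("imputation is accurate at dense marker spacing", {
  map <- simulate_map(1, 31, 30, seed = 921)  # 1 cM spacing
  geno <- simulate_genotypes(map, 100, "riself", seed = 922)
  holed <- geno
  withr::with_seed(923, {
    holes <- sample(length(geno), round(0.1 * length(geno)))
  })
  holed[holes] <- NA
  cross <- make_cross(holed, map, "riself")
  filled <- suppressMessages(fill_missing(cross))
  imputed <- holes[!is.na(filled$geno[holes])]
  expect_gt(length(imputed), 0)
  expect_gte(mean(filled$geno[imputed] == geno[imputed]), 0.95)
})

test_that("saturation places strong local eQTL near their true locus", {
  sim <- simulate_study(n_ind = 150, counts = c(clean_local = 30, no_qtl = 5),
                        effect = 4, seed = 931)
  cs <- find_candidate_markers(sim$pheno, "riself", n_boot = 49, seed = 932)
  expect_gt(length(cs$candidates), 10)
  sat <- saturate_map(sim$cross, cs, step_two = 10)
  rep <- sat$report
  # telescoping counts through the mixture stage
  expect_equal(rep$parental_selected,
               rep$degenerate_or_unconverged + rep$rejected_unimodal +
                 rep$rejected_segregation + rep$rejected_uninformative +
                 rep$mixture_selected)
  expect_equal(rep$placed - rep$removed_duplicate - rep$removed_colocalized,
               rep$final_new_markers)
  expect_lte(rep$spacing_after, rep$spacing_before)

  # placement error: scan-peak position vs the true locus, in the
  # original map's coordinates (re-estimation rescales the map later)
  newmk <- setdiff(sat$cross$map$marker, sim$cross$map$marker)
  expect_gt(length(newmk), 5)
  err <- vapply(sub("^m_", "", newmk), function(id) {
    v <- sat$verdicts[[id]]
    tq <- sim$truth$qtl1[sim$truth$id == id]
    tp <- sim$cross$map[sim$cross$map$marker == tq, ]
    if (tp$chr != v$peak_chr) Inf else abs(tp$pos - v$peak_pos)
  }, 0)
  expect_gte(mean(err <= 5), 0.8)
})

test_that("a candidate duplicating an existing marker is removed", {
  cross <- sim_cross_cache()
  dup <- cross$geno["c1m03", ]
  cs <- candidate_set_from_genotypes(
    matrix(dup, 1, dimnames = list("dupe", names(dup))))
  withr::with_seed(971,
    cs$candidates$dupe$values <- ifelse(dup == "B", 1, 0) + rnorm(150, 0, 0.1))
  sat <- saturate_map(cross, cs, step_two = 10)
  expect_equal(sat$report$removed_duplicate +
                 sat$report$removed_colocalized, 1)
  expect_equal(sat$report$final_new_markers, 0)
  expect_identical(sat$cross$map$marker, cross$map$marker)
})

test_that("de novo construction handles single-chromosome input", {
  map <- simulate_map(1, 10, 80, seed = 941)
  geno <- simulate_genotypes(map, 120, "riself", seed = 942)
  cs <- candidate_set_from_genotypes(geno)
  dn <- build_denovo_map(cs, n_chromosomes = 1)
  expect_equal(length(unique(dn$map$chr)), 1)
  expect_equal(nrow(dn$map), 10)
})

test_that("stricter selection settings yield fewer candidates", {
  sim <- simulate_study(n_ind = 120, counts = c(clean_local = 12),
                        effect = 3, seed = 951)
  lax <- find_candidate_markers(sim$pheno, "riself", n_boot = 49,
                                max_deviation = 0.15, threshold = 0.7,
                                seed = 952)
  strict <- find_candidate_markers(sim$pheno, "riself", n_boot = 49,
                                   max_deviation = 0.05, threshold = 0.95,
                                   min_informative = 100, seed = 952)
  expect_lte(length(strict$candidates), length(lax$candidates))
})

test_that("full de novo pipeline recovers chromosomes from mixtures", {
  sim <- simulate_study(n_ind = 150, n_chr = 3, markers_per_chr = 7,
                        length_cm = 60,
                        counts = c(clean_local = 40), effect = 6,
                        seed = 961)
  cs <- find_candidate_markers(sim$pheno, "riself", n_boot = 49, seed = 962)
  expect_gt(length(cs$candidates), 20)
  dn <- suppressWarnings(build_denovo_map(cs, n_chromosomes = 3,
                                          min_group_size = 3))
  # every linkage group is chromosome-pure
  truechr <- function(mk) {
    ids <- sub("^m_", "", mk)
    q <- sim$truth$qtl1[match(ids, sim$truth$id)]
    unique(sim$cross$map$chr[match(q, sim$cross$map$marker)])
  }
  purity <- vapply(split(dn$map$marker, dn$map$chr),
                   function(mk) length(truechr(mk)), 0L)
  expect_true(all(purity == 1))
})
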