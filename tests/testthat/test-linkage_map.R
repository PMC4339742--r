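test_that("map functions match closed forms and invert exactly", {
  expect_equal(rf_to_cm(0, "haldane"), 0)
  expect_equal(rf_to_cm(0, "kosambi"), 0)
  expect_equal(rf_to_cm(0.25, "kosambi"), 25 * log(3))
  expect_equal(rf_to_cm(0.25, "haldane"), -50 * log(0.5))
  r <- seq(0.01, 0.49, by = 0.01)
  for (mf in c("haldane", "kosambi")) {
    expect_equal(cm_to_rf(rf_to_cm(r, mf), mf), r, tolerance = 1e-12)
    expect_lt(max(abs(rf_to_cm(cm_to_rf(seq(1, 80), mf), mf) - seq(1, 80))),
              1e-9)
  }
  expect_error(rf_to_cm(0.5), "unlinked")
  expect_error(cm_to_rf(-1), ">= 0")
})

test_that("pairwise rf estimation has the right likelihood landmarks", {
  a <- rep(c("A", "B"), 10)
  e <- estimate_rf(a, a)
  expect_equal(e$rf, 0)
  expect_equal(e$lod, 20 * log10(2), tolerance = 1e-10)

  comp <- ifelse(a == "A", "B", "A")
  e2 <- estimate_rf(a, comp)
  expect_equal(e2$rf, 0.5)
  expect_true(e2$phase_flipped)
  expect_equal(e2$lod, 0)

  withr::with_seed(88, {
    x <- sample(c("A", "B"), 200, replace = TRUE)
    y <- sample(c("A", "B"), 200, replace = TRUE)
  })
  e3 <- estimate_rf(x, y)
  expect_lt(abs(e3$rf - 0.5), 0.07)
  expect_lt(e3$lod, 2)

  e4 <- estimate_rf(c("A", NA), c(NA, "B"))
  expect_true(is.na(e4$rf))
})

test_that("vectorized rf matrix agrees with the scalar estimator", {
  withr::with_seed(21, {
    g <- matrix(sample(c("A", "B", NA), 60, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)), 4, 15,
                dimnames = list(paste0("m", 1:4), paste0("i", 1:15)))
  })
  rfm <- rf_matrix(g, "riself")
  expect_equal(rfm$rf, t(rfm$rf))
  expect_equal(unname(diag(rfm$rf)), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4) {
    e <- estimate_rf(g[i, ], g[j, ])
    expect_equal(rfm$rf[i, j], e$rf)
    expect_equal(rfm$lod[i, j], e$lod, tolerance = 1e-10)
  }
})

test_that("f2 rf estimation recovers linkage from the joint table", {
  map <- simulate_map(1, 2, 20, seed = 1)
  g <- simulate_genotypes(map, 400, "f2", seed = 2)
  e <- estimate_rf(g[1, ], g[2, ], "f2")
  expect_lt(abs(e$rf - cm_to_rf(20, "haldane")), 0.05)
  expect_gt(e$lod, 10)
  # unlinked f2 markers
  withr::with_seed(3, {
    x <- sample(c("A", "H", "B"), 300, TRUE, prob = c(1, 2, 1) / 4)
    y <- sample(c("A", "H", "B"), 300, TRUE, prob = c(1, 2, 1) / 4)
  })
  e0 <- estimate_rf(x, y, "f2")
  expect_gt(e0$rf, 0.4)
  expect_lt(e0$lod, 2)
})

test_that("linkage grouping recovers simulated chromosomes", {
  map <- simulate_map(2, 10, 100, seed = 301)
  geno <- simulate_genotypes(map, 150, "riself", seed = 302)
  rfm <- rf_matrix(geno, "riself")
  groups <- form_linkage_groups(rfm, max_rf = 0.35, min_lod = 6)
  expect_length(groups, 2)
  chr_of <- function(g) unique(map$chr[match(g, map$marker)])
  expect_true(all(lengths(lapply(groups, chr_of)) == 1))

  # min_lod = Inf isolates every marker
  expect_length(form_linkage_groups(rfm, min_lod = Inf), nrow(geno))

  # identical markers form a single group
  same <- matrix(rep(c("A", "B"), 5), 6, 10, byrow = TRUE,
                 dimnames = list(paste0("m", 1:6), paste0("i", 1:10)))
  rfs <- rf_matrix(same, "riself")
  expect_length(form_linkage_groups(rfs, 0.35, 2), 1)
})

test_that("mirrored groups merge and unlinked groups do not", {
  map <- simulate_map(2, 10, 100, seed = 311)
  geno <- simulate_genotypes(map, 150, "riself", seed = 312)
  chr1 <- map$marker[map$chr == "1"]
  # exact complement of chromosome 1 as a second 'phase' group
  comp <- geno[chr1, ]
  comp[] <- ifelse(comp == "A", "B", "A")
  rownames(comp) <- paste0(chr1, "_m")
  g <- rbind(geno, comp)
  groups <- list(chr1, rownames(comp), map$marker[map$chr == "2"])
  merged <- merge_mirrored_groups(groups, g, corr_threshold = 0.7)
  expect_length(merged$groups, 2)
  expect_setequal(merged$groups[[1]], c(chr1, rownames(comp)))
  # flipped copies now carry identical calls
  expect_identical(merged$geno[paste0(chr1[1], "_m"), ],
                   merged$geno[chr1[1], ])
  # independent chromosomes stay apart
  expect_true(all(lengths(merged$groups) > 0))
  again <- merge_mirrored_groups(merged$groups, merged$geno, 0.7)
  expect_length(again$groups, 2)
  expect_length(again$flipped, 0)
})

test_that("contradictory mirror structure raises the ambiguity error", {
  # frustrated triangle: three balanced markers, each "B" on its own
  # third of the individuals, pairwise correlation exactly -1/2 -- no
  # phase assignment can make all three pairs coupling-consistent
  block <- function(k) {
    v <- rep("A", 30)
    v[(k - 1) * 10 + 1:10] <- "B"
    v
  }
  g <- rbind(x = block(1), y = block(2), z = block(3))
  colnames(g) <- paste0("i", 1:30)
  expect_error(merge_mirrored_groups(list("x", "y", "z"), g,
                                     corr_threshold = 0.4),
               "ambiguous")
  # a benign multi-partner case (two fragments mirroring one group)
  # resolves greedily instead of erroring
  frag <- rbind(x = block(1), y1 = ifelse(block(1) == "A", "B", "A"))
  y2 <- ifelse(block(1) == "A", "B", "A"); y2[1] <- "A"
  frag <- rbind(frag, y2 = y2)
  colnames(frag) <- paste0("i", 1:30)
  res <- merge_mirrored_groups(list("x", "y1", "y2"), frag, 0.7)
  expect_length(res$groups, 1)
})

test_that("marker ordering matches exhaustive search on small groups", {
  map <- simulate_map(1, 8, 35, seed = 321)
  geno <- simulate_genotypes(map, 200, "riself", seed = 322)
  rfm <- rf_matrix(geno, "riself")
  ord <- order_markers(map$marker, rfm)
  exact <- phenomarker:::order_markers_exhaustive(map$marker, rfm)
  expect_identical(ord, exact)
  expect_true(identical(ord, map$marker) ||
                identical(ord, rev(map$marker)))
})

test_that("ordering is canonical and objective-monotone", {
  expect_identical(order_markers(c("b", "a"),
                                 rf_matrix(matrix(c("A", "B", "A", "B"), 2, 2,
                                                  dimnames = list(c("b", "a"),
                                                                  c("i1", "i2"))),
                                           "riself")),
                   c("a", "b"))
  map <- simulate_map(1, 12, 60, seed = 331)
  geno <- simulate_genotypes(map, 120, "riself", seed = 332)
  rfm <- rf_matrix(geno, "riself")
  ord <- order_markers(map$marker, rfm, ripple_window = 4)
  obj <- function(o) sum(rfm$rf[cbind(o[-length(o)], o[-1])])
  # the refined order is no worse than the raw map order
  expect_lte(obj(ord), obj(map$marker) + 1e-12)
})

test_that("map re-estimation recovers simulated lengths", {
  map <- simulate_map(1, 11, 100, seed = 341)
  geno <- simulate_genotypes(map, 1000, "riself", seed = 342)
  cross <- make_cross(geno, map, "riself")
  est <- estimate_map(cross, "haldane")
  expect_lt(abs(map_length(est) - 100) / 100, 0.10)

  # duplicating every individual leaves distances unchanged
  g2 <- cbind(cross$geno, cross$geno)
  colnames(g2) <- paste0("i", seq_len(ncol(g2)))
  cross2 <- make_cross(g2, map, "riself")
  expect_equal(estimate_map(cross2, "haldane")$pos, est$pos,
               tolerance = 1e-12)

  single <- make_cross(geno[1, , drop = FALSE],
                       genetic_map("c1m01", "1", 0), "riself")
  expect_equal(estimate_map(single)$pos, 0)
})

test_that("chromosome naming and orientation follow physical majority", {
  map <- genetic_map(paste0("m_p", 1:4), rep("LG1", 4), c(0, 5, 10, 15))
  phys <- data.frame(id = paste0("p", 1:4), chr = c("2", "2", "2", "5"),
                     bp = c(3e6, 2e6, 1e6, 9e6))
  out <- name_and_orient_chromosomes(map, phys)
  expect_identical(unique(out$chr), "2")
  # cM order anti-correlated with bp -> orientation flipped
  expect_identical(out$marker, rev(map$marker))
  expect_equal(out$pos, c(0, 5, 10, 15))
  expect_identical(attr(out, "dissenters"), "m_p4")

  tie <- data.frame(id = paste0("p", 1:4), chr = c("1", "1", "2", "2"),
                    bp = 1:4 * 1e6)
  expect_error(name_and_orient_chromosomes(map, tie), "tie")

  nopos <- data.frame(id = "q9", chr = "3", bp = 1e6)
  expect_message(keep <- name_and_orient_chromosomes(map, nopos),
                 "provisional")
  expect_identical(unique(keep$chr), "LG1")
})
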