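# Two-point F2 estimation, grouping, ordering, Haldane distances and map
# assembly.

test_that("r is 0 with no recombinants and 0.5 under independence", {
  parental <- diag(c(24, 48, 24))   # 1:2:1 on the diagonal
  est <- estimate_r_f2(parental)
  expect_equal(est$r, 0, tolerance = 1e-6)
  expect_gt(est$lod, 10)
  margins <- c(36, 72, 36)
  indep <- outer(margins, margins) / sum(margins)   # n = 144 outer product
  est2 <- estimate_r_f2(indep)
  expect_equal(est2$r, 0.5, tolerance = 1e-3)
  expect_equal(est2$lod, 0, tolerance = 1e-6)
})

test_that("the hom-only toy table gives r = 0.2", {
  m <- matrix(0, 3, 3)
  m[1, 1] <- 8; m[1, 3] <- 2; m[3, 1] <- 2; m[3, 3] <- 8
  est <- estimate_r_f2(m)
  expect_equal(est$r, 0.2, tolerance = 1e-4)
  expect_equal(est$n_informative, 20L)
  expect_equal(est$r, brute_r_grid(m), tolerance = 1e-3)
})

test_that("the ML estimate matches a brute-force likelihood grid on random
           tables", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    r_true <- runif(1, 0.01, 0.49)
    # draw a table from the true F2 joint distribution
    probs <- vapply(1:9, function(k) {
      m <- matrix(0, 3, 3); m[k] <- 1
      exp(brute_f2_loglik(r_true, m))
    }, numeric(1))
    counts <- matrix(as.vector(rmultinom(1, n, probs)), 3, 3)
    est <- estimate_r_f2(counts)
    expect_lt(abs(est$r - brute_r_grid(counts)), 1e-3)
  }
})

test_that("an empty table yields the undefined-estimate sentinel", {
  est <- estimate_r_f2(matrix(0, 3, 3))
  expect_true(is.na(est$r))
  expect_equal(est$n_informative, 0L)
})

test_that("pairwise estimates use pairwise-complete individuals and are
           symmetric in pair order", {
  gm <- toy_cross(n_chrom = 1, n_markers = 3, n = 60, missing_rate = 0.2,
                  seed = 5)
  est <- pairwise_linkage(gm)
  expect_equal(nrow(est), 3L)
  for (k in seq_len(nrow(est))) {
    ids <- attr(est, "loci")$id
    i <- match(est$locus1[k], ids); j <- match(est$locus2[k], ids)
    counts <- brute_pair_counts(gm, i, j)
    expect_equal(est$n_informative[k], sum(counts))
    expect_equal(est$r[k], estimate_r_f2(counts)$r, tolerance = 1e-9)
    expect_equal(est$r[k], estimate_r_f2(t(counts))$r, tolerance = 1e-4)
  }
})

test_that("grouping is single linkage with a strict LOD threshold", {
  est <- tibble::tibble(
    locus1 = c("a", "b", "a"), locus2 = c("b", "c", "c"),
    r = c(0.1, 0.1, 0.2), lod = c(5, 5, 1), n_informative = 96L)
  attr(est, "loci") <- tibble::tibble(id = c("a", "b", "c"),
                                      chrom = "c1", pos = 1:3)
  g <- group_loci(est, lod_threshold = 3)
  expect_equal(length(unique(g$group)), 1L)   # transitive chain a-b-c
  est2 <- est; est2$lod <- c(2.9, 2.9, 1)
  g2 <- group_loci(est2, lod_threshold = 3)
  expect_equal(length(unique(g2$group)), 3L)  # 2.9 < 3: all singletons
  est3 <- est; est3$lod <- c(10, 1, 1); est3$r <- c(0.1, 0.1, 0.2)
  g3 <- group_loci(est3, lod_threshold = 3)
  expect_equal(length(unique(g3$group)), 2L)  # {a,b} + {c}
})

test_that("grouping respects the max_r gate", {
  est <- tibble::tibble(locus1 = "a", locus2 = "b",
                        r = 0.45, lod = 10, n_informative = 96L)
  attr(est, "loci") <- tibble::tibble(id = c("a", "b"), chrom = "c1",
                                      pos = 1:2)
  expect_equal(length(unique(group_loci(est, 3, max_r = 0.35)$group)), 2L)
  expect_equal(length(unique(group_loci(est, 3, max_r = 0.5)$group)), 1L)
})

test_that("greedy ordering recovers the chain for three loci", {
  est <- tibble::tibble(
    locus1 = c("a", "b", "a"), locus2 = c("b", "c", "c"),
    r = c(0.1, 0.1, 0.2), lod = c(20, 20, 10), n_informative = 96L)
  attr(est, "loci") <- tibble::tibble(id = c("a", "b", "c"),
                                      chrom = "c1", pos = 1:3)
  ord <- order_group(c("a", "b", "c"), est)
  expect_equal(ord, c("a", "b", "c"))   # canonical orientation by coord
  expect_equal(order_group("a", est), "a")
})

test_that("Haldane map function matches its closed form and inverts", {
  expect_equal(haldane_cm(0), 0)
  expect_equal(haldane_cm(0.2), -50 * log(0.6), tolerance = 1e-12)
  expect_equal(haldane_cm(0.2), 25.541, tolerance = 1e-3)
  expect_equal(haldane_cm(0.35), 60.199, tolerance = 1e-3)
  expect_error(haldane_cm(0.5), "0.5")
  r <- seq(0, 0.49, by = 0.005)
  expect_equal(haldane_r(haldane_cm(r)), r, tolerance = 1e-9)
})

test_that("build_map converts adjacent r to cM and drops weak loci", {
  est <- tibble::tibble(locus1 = "a", locus2 = "b",
                        r = 0.1, lod = 10, n_informative = 96L)
  attr(est, "loci") <- tibble::tibble(id = c("a", "b"), chrom = "c1",
                                      pos = 1:2)
  gmap <- build_map(group_loci(est, 3), est)
  expect_equal(attr(gmap, "total_cm"), -50 * log(0.8), tolerance = 1e-6)
  expect_equal(glance(gmap)$total_cm, 11.157, tolerance = 1e-3)

  # locus whose only link violates max_r is unmapped and counted
  est2 <- tibble::tibble(
    locus1 = c("a", "b", "a"), locus2 = c("b", "c", "c"),
    r = c(0.1, 0.4, 0.45), lod = c(10, 10, 10), n_informative = 96L)
  attr(est2, "loci") <- tibble::tibble(id = c("a", "b", "c"),
                                       chrom = "c1", pos = 1:3)
  gmap2 <- build_map(group_loci(est2, 3), est2, max_r = 0.35, min_lod = 2)
  expect_equal(attr(gmap2, "unmapped"), "c")
  expect_equal(nrow(gmap2), 2L)
  expect_equal(glance(gmap2)$mapped_fraction, 2 / 3, tolerance = 1e-9)

  # empty grouping -> empty map
  empty <- build_map(tibble::tibble(locus = character(), group = integer()),
                     est)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "total_cm"), 0)
})

test_that("map order is concordant with genome order on simulated data", {
  gm <- toy_cross(n_chrom = 2, n_markers = 8, spacing_cm = 8, n = 96,
                  seed = 20)
  est <- pairwise_linkage(gm)
  groups <- group_loci(est, 4)
  expect_equal(length(unique(groups$group)), 2L)
  gmap <- build_map(groups, est)
  conc <- map_concordance(gmap)
  expect_true(all(conc$kendall_tau > 0.95))
  # each group draws from a single chromosome
  split_chrom <- tapply(gmap$chrom, gmap$group, function(x) length(unique(x)))
  expect_true(all(split_chrom == 1L))
})
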