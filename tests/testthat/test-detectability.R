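# SNP detectability: fragment containment, read-window geometry, context
# classification, union pooling and density.

make_frags <- function(df, enzymes = c("PstI", "MspI")) {
  df$length <- df$end - df$start
  attr(df, "enzymes") <- enzymes
  df
}

test_that("a variant is detectable iff inside a selected fragment", {
  frags <- make_frags(tibble::tibble(
    chrom = "c1", start = c(7L, 100L), end = c(11L, 300L),
    left_end = "PstI", right_end = "MspI"))
  v <- tibble::tibble(chrom = "c1", pos = c(9L, 6L, 11L, 100L, 299L, 300L))
  expect_equal(detectable_snps(v, frags),
               c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("read_window restricts detection to fragment ends", {
  frags <- make_frags(tibble::tibble(
    chrom = "c1", start = 0L, end = 800L,
    left_end = "PstI", right_end = "MspI"))
  v <- tibble::tibble(chrom = "c1", pos = c(10L, 400L, 249L, 250L, 700L))
  expect_equal(detectable_snps(v, frags, read_window = 250),
               c(TRUE, FALSE, TRUE, FALSE, TRUE))
  # window 0 = whole fragment
  expect_true(all(detectable_snps(v, frags, read_window = 0)))
})

test_that("variants on sequences absent from the genome raise an error", {
  g <- Biostrings::DNAStringSet(c(c1 = "ACGT"))
  frags <- make_frags(tibble::tibble(chrom = "c1", start = 0L, end = 4L,
                                     left_end = "PstI", right_end = "MspI"))
  v <- tibble::tibble(chrom = "c9", pos = 1L)
  expect_error(detectable_snps(v, frags, genome = g), "c9")
})

test_that("genic and repeat context are independent half-open overlaps", {
  genes <- tibble::tibble(chrom = "c1", start = 10L, end = 20L,
                          category = "gene")
  reps <- tibble::tibble(chrom = "c1", start = 15L, end = 40L,
                         category = "repeat")
  v <- tibble::tibble(chrom = "c1", pos = c(16L, 5L, 10L, 20L, 39L, 40L))
  out <- classify_context(v, genes, reps)
  expect_equal(out$genic, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$`repeat`, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("report partitions detectable SNPs by context", {
  set.seed(3)
  sim <- generate_genome(c(c1 = 30000L), n_genes = 5, gene_length = 2000,
                         n_repeats = 5, repeat_length = 1500, seed = 3)
  v <- generate_variants(sim$genome, 1 / 200, seed = 4)
  fr <- digest_genome(sim$genome, "EcoRI", "MspI")
  sel <- select_fragments(fr, 100, 900, "all_internal")
  rep_ <- detectability_report(
    v, sel, sim$genome,
    gene_features = sim$features[sim$features$category == "gene", ],
    repeat_features = sim$features[sim$features$category == "repeat", ])
  tot <- rep_$summary[rep_$summary$chrom == "total", ]
  expect_lte(tot$detectable, tot$n_snps)
  expect_equal(tot$genic + tot$intergenic, tot$detectable)
  expect_equal(tot$`repeat` + tot$non_repeat, tot$detectable)
})

test_that("detectability matches a brute-force per-variant scan", {
  set.seed(9)
  for (i in 1:10) {
    g <- Biostrings::DNAStringSet(c(c1 = random_seq(4000),
                                    c2 = random_seq(3000)))
    v <- generate_variants(g, 1 / 80, seed = i)
    fr <- digest_genome(g, "EcoRI", "MspI")
    sel <- select_fragments(fr, 50, 600, "all")
    for (w in c(0, 100)) {
      expect_equal(detectable_snps(v, sel, read_window = w),
                   brute_detectable(v, sel, read_window = w))
    }
  }
})

test_that("shrinking the window or adding a read window never adds SNPs", {
  set.seed(13)
  g <- Biostrings::DNAStringSet(c(c1 = random_seq(50000)))
  v <- generate_variants(g, 1 / 100, seed = 2)
  fr <- digest_genome(g, "EcoRI", "MspI")
  wide <- detectable_snps(v, select_fragments(fr, 100, 900, "all"))
  narrow <- detectable_snps(v, select_fragments(fr, 200, 600, "all"))
  windowed <- detectable_snps(v, select_fragments(fr, 100, 900, "all"),
                              read_window = 150)
  expect_true(all(wide[narrow]))      # narrow set is a subset
  expect_true(all(wide[windowed]))
})

test_that("pooled reports take the union of detectable sets", {
  v <- tibble::tibble(chrom = "c1", pos = c(5L, 15L, 25L, 35L, 45L, 55L, 65L))
  mk_rep <- function(det) {
    pv <- v
    pv$genic <- FALSE; pv$`repeat` <- FALSE
    pv$detectable <- det
    smry <- tibble::tibble(chrom = "total", n_snps = nrow(v),
                           detectable = sum(det), genic = 0L, `repeat` = 0L,
                           fraction = mean(det), intergenic = sum(det),
                           non_repeat = sum(det))
    structure(list(combination = "x", per_variant = pv, summary = smry,
                   read_window = 0), class = "detectability_report")
  }
  r1 <- mk_rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  r2 <- mk_rep(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  u <- combine_reports(list(r1, r2))
  expect_equal(sum(u$per_variant$detectable), 7L)   # disjoint 3 + 4
  same <- combine_reports(list(r1, r1))
  expect_equal(sum(same$per_variant$detectable), 3L)
  expect_gte(u$summary$fraction[u$summary$chrom == "total"],
             max(glance(r1)$fraction, glance(r2)$fraction))
})

test_that("combine_reports rejects mismatched variant sets", {
  gm <- toy_cross(n_chrom = 1, n_markers = 3, n = 4)
  v1 <- tibble::tibble(chrom = "c1", pos = 1:3)
  r <- detectability_report(
    v1, make_frags(tibble::tibble(chrom = "c1", start = 0L, end = 10L,
                                  left_end = "PstI", right_end = "MspI")))
  v2 <- tibble::tibble(chrom = "c1", pos = 1:5)
  r2 <- detectability_report(
    v2, make_frags(tibble::tibble(chrom = "c1", start = 0L, end = 10L,
                                  left_end = "PstI", right_end = "MspI")))
  expect_error(combine_reports(list(r, r2)), "same variant set")
})

test_that("snp_density reports one SNP per d bp with sane edge cases", {
  g <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 1000), collapse = "")))
  v10 <- tibble::tibble(chrom = "c1", pos = seq(0L, 900L, 100L))
  expect_equal(snp_density(v10, g), 100L)
  v3 <- v10[1:3, ]
  expect_equal(snp_density(v3, g), 333L)
  expect_message(d0 <- snp_density(v10[0, ], g), "no SNPs")
  expect_true(is.na(d0))
})
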