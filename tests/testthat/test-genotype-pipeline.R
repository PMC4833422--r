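# The high-confidence SNP selection cascade.

toy_records <- function() {
  # 5 records: quals {5,10,11,20,30}, depths {4,4,3,4,9} in one sample
  path <- write_vcf_text(
    data.frame(chrom = "c1", pos1 = c(10L, 20L, 30L, 40L, 50L),
               ref = "A", alt = "G", qual = c(5, 10, 11, 20, 30)),
    samples = "s1",
    calls = list(c(s1 = "1/1:4"), c(s1 = "1/1:4"), c(s1 = "1/1:3"),
                 c(s1 = "1/1:4"), c(s1 = "1/1:9")))
  read_vcf(path)
}

test_that("quality is strict > and depth inclusive >=, per sample", {
  rec <- toy_records()
  kept <- filter_quality_depth(rec, 10, 4)
  expect_equal(kept$qual, c(20, 30))    # qual 10 out (strict), qual 11/dp 3 out
  tr <- filter_trace(kept)
  expect_equal(tr$n_in[tr$stage == "quality_depth"], 5L)
  expect_equal(tr$n_out[tr$stage == "quality_depth"], 2L)
  # single record spot checks
  expect_equal(nrow(filter_quality_depth(rec[rec$qual == 30, ], 10, 4)), 1L)
  expect_equal(nrow(filter_quality_depth(rec[rec$qual == 10, ], 10, 4)), 0L)
})

test_that("missing genotypes are exempt from the depth requirement", {
  path <- write_vcf_text(
    data.frame(chrom = "c1", pos1 = 1L, ref = "A", alt = "G", qual = 30),
    samples = c("s1", "s2"),
    calls = list(c(s1 = "1/1:9", s2 = "./.:0")))
  rec <- read_vcf(path)
  expect_equal(nrow(filter_quality_depth(rec, 10, 4)), 1L)
})

test_that("heterozygous parent calls remove the locus in inbreds", {
  path <- write_vcf_text(
    data.frame(chrom = "c1", pos1 = 1:3, ref = "A", alt = "G", qual = 30),
    samples = c("p1", "p2"),
    calls = list(c(p1 = "0/0:9", p2 = "1/1:9"),
                 c(p1 = "0/1:9", p2 = "1/1:9"),
                 c(p1 = "0/1:9", p2 = "0/1:9")))
  rec <- read_vcf(path)
  kept <- drop_heterozygous_inbred(rec, c("p1", "p2"))
  expect_equal(kept$pos, 0L)
  expect_equal(nrow(drop_heterozygous_inbred(rec[3, ], c("p1", "p2"))), 0L)
  expect_error(drop_heterozygous_inbred(rec, "nobody"), "unknown")
})

test_that("remove_indels drops exactly the indel records", {
  path <- write_vcf_text(
    data.frame(chrom = "c1", pos1 = 1:2, ref = c("A", "A"),
               alt = c("G", "AT"), qual = 30),
    samples = "s1", calls = list(c(s1 = "1/1:9"), c(s1 = "1/1:9")))
  rec <- read_vcf(path)
  expect_equal(remove_indels(rec)$alt, "G")
  empty <- rec[0, ]
  attr(empty, "samples") <- vcf_samples(rec)
  expect_equal(nrow(remove_indels(empty)), 0L)
})

test_that("missingness threshold is a call-rate >= rule over F2 lines", {
  gm <- toy_cross(n_chrom = 1, n_markers = 3, n = 96)
  tbl <- tibble::as_tibble(gm)
  inds <- gm_individuals(gm)
  tbl[1, inds[1:20]] <- "U"   # call rate 76/96 = 0.792 -> removed
  tbl[2, inds[1:19]] <- "U"   # call rate 77/96 = 0.802 -> kept
  gm2 <- ddradtools:::new_genotype_matrix(tbl, inds, attr(gm, "parents"))
  kept <- filter_missingness(gm2, 0.8)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$pos, tbl$pos[2:3])
})

test_that("imputation fills only agreeing flanks and flags the calls", {
  tbl <- tibble::tibble(chrom = "c1", pos = c(10L, 20L, 30L, 40L),
                        i1 = c("A", "U", "A", "B"),   # agree -> A
                        i2 = c("A", "U", "B", "B"),   # disagree -> U
                        i3 = c("U", "A", "A", "A"))   # single flank -> A
  gm <- ddradtools:::new_genotype_matrix(tbl, c("i1", "i2", "i3"), NULL)
  imp <- impute_missing(gm)
  expect_equal(imp$i1[[2]], "A")
  expect_equal(imp$i2[[2]], "U")
  expect_equal(imp$i3[[1]], "A")
  expect_equal(sum(attr(imp, "imputed")), 2L)
  strict <- impute_missing(gm, single_flank = FALSE)
  expect_equal(strict$i3[[1]], "U")
})

test_that("imputation never crosses a chromosome boundary", {
  tbl <- tibble::tibble(chrom = c("c1", "c1", "c2", "c2"),
                        pos = c(10L, 20L, 10L, 20L),
                        i1 = c("A", "A", "U", "B"))
  gm <- ddradtools:::new_genotype_matrix(tbl, "i1", NULL)
  imp <- impute_missing(gm)
  # single flank within c2 is the B at pos 20, not the A's on c1
  expect_equal(imp$i1[[3]], "B")
})

test_that("redundancy collapse merges identical segregation vectors", {
  tbl <- tibble::tibble(chrom = "c1", pos = c(1L, 2L, 3L, 4L, 5L),
                        i1 = c("A", "A", "A", "B", "B"),
                        i2 = c("H", "H", "H", "A", "A"),
                        i3 = c("B", "B", "U", "H", "H"))
  gm <- ddradtools:::new_genotype_matrix(tbl, c("i1", "i2", "i3"), NULL)
  out <- collapse_redundant(gm)   # classes {1,2,3} (U wildcard) and {4,5}
  expect_equal(out$pos, c(1L, 4L))
  rmap <- attr(out, "redundancy_map")
  expect_equal(sum(rmap$representative == "c1:2"), 3L)
  # exact-match mode keeps the U-containing locus separate
  strict <- collapse_redundant(gm, wildcard_missing = FALSE)
  expect_equal(strict$pos, c(1L, 3L, 4L))
  # vectors differing in one individual stay distinct
  tbl2 <- tbl[1:2, ]; tbl2$i1[2] <- "H"
  gm2 <- ddradtools:::new_genotype_matrix(tbl2, c("i1", "i2", "i3"), NULL)
  expect_equal(nrow(collapse_redundant(gm2)), 2L)
})

test_that("anchoring to parents codes F2 calls as A/B/H/U", {
  path <- write_vcf_text(
    data.frame(chrom = "c1", pos1 = 1:2, ref = "A", alt = "G", qual = 30),
    samples = c("p1", "p2", "f1", "f2"),
    calls = list(
      c(p1 = "0/0:9", p2 = "1/1:9", f1 = "0/0:9", f2 = "0/1:9"),
      c(p1 = "1/1:9", p2 = "0/0:9", f1 = "0/0:9", f2 = "./.:0")))
  gm <- as_genotype_matrix(read_vcf(path), c("p1", "p2"))
  expect_equal(gm$f1, c("A", "B"))   # anchored to parent alleles, not ref
  expect_equal(gm$f2, c("H", "U"))
})

test_that("the trace reconciles across a full cascade", {
  gm0 <- toy_cross(n_chrom = 2, n_markers = 10, n = 30,
                   missing_rate = 0.15, error_rate = 0.02, seed = 7)
  variants <- f2_as_variants(gm0, seed = 8)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(variants, path)
  rec <- read_vcf(path)
  out <- rec |>
    filter_quality_depth(10, 4) |>
    remove_indels() |>
    drop_heterozygous_inbred(c("parent1", "parent2")) |>
    as_genotype_matrix(c("parent1", "parent2")) |>
    filter_missingness(0.8) |>
    impute_missing() |>
    collapse_redundant()
  tr <- filter_trace(out)
  expect_equal(tr$n_in[-1], head(tr$n_out, -1))   # stages chain exactly
  expect_equal(tr$n_in[[1]], nrow(rec))
  expect_equal(tr$n_out[[nrow(tr)]], nrow(out))
  expect_true(all(tr$n_out <= tr$n_in))
})

test_that("clean synthetic F2 data lose nothing to the het filter and
           segregate ~1:2:1", {
  gm0 <- toy_cross(n_chrom = 2, n_markers = 8, n = 96, seed = 12)
  variants <- f2_as_variants(gm0, seed = 13)
  rec_like <- filter_quality_depth(variants, 10, 1)
  kept <- drop_heterozygous_inbred(rec_like, c("parent1", "parent2"))
  expect_equal(nrow(kept), nrow(variants))   # inbred parents are hom
  seg <- segregation_check(gm0)
  expect_gt(mean(seg$p_value > 0.001), 0.95)
  expect_equal(seg$n_A + seg$n_H + seg$n_B, rep(96L, nrow(seg)))
})

test_that("every cascade stage matches a brute-force reimplementation on
           random matrices", {
  set.seed(31)
  for (i in 1:25) {
    n_loci <- sample(5:20, 1)
    n_ind <- sample(3:8, 1)
    codes <- matrix(sample(c("A", "H", "B", "U"), n_loci * n_ind,
                           replace = TRUE, prob = c(.3, .3, .3, .1)),
                    nrow = n_loci)
    tbl <- tibble::tibble(chrom = "c1", pos = seq_len(n_loci) * 10L)
    inds <- paste0("i", seq_len(n_ind))
    for (j in seq_len(n_ind)) tbl[[inds[j]]] <- codes[, j]
    gm <- ddradtools:::new_genotype_matrix(tbl, inds, NULL)

    # missingness: brute per-locus loop
    rate <- 0.7
    keep <- vapply(seq_len(n_loci), function(l) {
      mean(codes[l, ] != "U") >= rate
    }, logical(1))
    expect_equal(filter_missingness(gm, rate)$pos, tbl$pos[keep])

    # imputation: brute per-cell loop
    imp <- impute_missing(gm)
    for (j in seq_len(n_ind)) {
      g <- codes[, j]
      for (l in which(g == "U")) {
        lo <- which(g[seq_len(l - 1)] != "U")
        hi <- which(g[-seq_len(l)] != "U") + l
        fl <- c(if (length(lo)) g[max(lo)], if (length(hi)) g[min(hi)])
        want <- if (length(unique(fl)) == 1) fl[1] else "U"
        expect_identical(imp[[inds[j]]][l], want)
      }
    }

    # redundancy: brute first-representative scan with wildcard match
    reps <- integer(0)
    for (l in seq_len(n_loci)) {
      hit <- FALSE
      for (r in reps) {
        both <- codes[l, ] != "U" & codes[r, ] != "U"
        if (all(codes[l, both] == codes[r, both])) { hit <- TRUE; break }
      }
      if (!hit) reps <- c(reps, l)
    }
    expect_equal(collapse_redundant(gm)$pos, tbl$pos[reps])
  }
})
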