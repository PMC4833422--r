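# Independent brute-force oracles. These re-derive results from first
# principles (per-offset scans, explicit loops, exhaustive enumeration)
# and deliberately share no code with the implementation they check.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

revcomp_chr <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# All top-strand cut coordinates of an enzyme on one sequence string,
# testing every offset against the expanded recognition set on both
# strands. Genome N never matches (no IUPAC set contains it).
brute_cuts <- function(seqchr, recognition, cut_offset) {
  chars <- strsplit(seqchr, "")[[1]]
  k <- nchar(recognition)
  L <- length(chars)
  if (L < k) return(integer(0))
  scan <- function(pattern, cut_from_left) {
    sets <- IUPAC_SETS[strsplit(pattern, "")[[1]]]
    ok <- rep(TRUE, L - k + 1L)
    for (j in seq_len(k)) {
      ok <- ok & chars[j:(L - k + j)] %in% sets[[j]]
    }
    which(ok) - 1L + cut_from_left
  }
  cuts <- scan(recognition, cut_offset)
  rc <- revcomp_chr(recognition)
  if (!identical(rc, recognition)) {
    cuts <- c(cuts, scan(rc, k - cut_offset))
  }
  sort(unique(cuts))
}

# Fragment table for a double digest of one sequence, from brute cuts.
brute_fragments <- function(seqchr, enz_a, enz_b) {
  L <- nchar(seqchr)
  ca <- brute_cuts(seqchr, enz_a$recognition, enz_a$cut_offset)
  cb <- brute_cuts(seqchr, enz_b$recognition, enz_b$cut_offset)
  cuts <- data.frame(cut = c(ca, cb),
                     enzyme = c(rep(enz_a$name, length(ca)),
                                rep(enz_b$name, length(cb))))
  cuts <- cuts[order(cuts$cut, cuts$enzyme), ]
  cuts <- cuts[!duplicated(cuts$cut), ]
  cuts <- cuts[cuts$cut > 0 & cuts$cut < L, ]
  bounds <- c(0L, cuts$cut, L)
  labels <- c("END", cuts$enzyme, "END")
  n <- length(bounds) - 1L
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L],
             left_end = labels[seq_len(n)], right_end = labels[-1L])
}

# Exhaustive per-variant detectability scan.
brute_detectable <- function(variants, fragments, read_window = 0) {
  vapply(seq_len(nrow(variants)), function(i) {
    for (j in seq_len(nrow(fragments))) {
      if (variants$chrom[i] == fragments$chrom[j] &&
          variants$pos[i] >= fragments$start[j] &&
          variants$pos[i] < fragments$end[j]) {
        if (read_window <= 0) return(TRUE)
        dl <- variants$pos[i] - fragments$start[j]
        dr <- fragments$end[j] - 1 - variants$pos[i]
        return(min(dl, dr) < read_window)
      }
    }
    FALSE
  }, logical(1))
}

# F2 two-point log-likelihood for a 3x3 table, derived independently by
# enumerating all 16 ordered gamete combinations.
brute_f2_loglik <- function(r, counts) {
  gam <- c(AB = (1 - r) / 2, ab = (1 - r) / 2, Ab = r / 2, aB = r / 2)
  a1 <- c(AB = 0L, ab = 1L, Ab = 0L, aB = 1L)  # allele at locus 1 (0=A)
  a2 <- c(AB = 0L, ab = 1L, Ab = 1L, aB = 0L)  # allele at locus 2
  p <- matrix(0, 3, 3)
  for (g1 in names(gam)) for (g2 in names(gam)) {
    geno1 <- a1[g1] + a1[g2] + 1L   # 1=AA,2=Aa,3=aa
    geno2 <- a2[g1] + a2[g2] + 1L
    p[geno1, geno2] <- p[geno1, geno2] + gam[g1] * gam[g2]
  }
  sum(counts[counts > 0] * log(p[counts > 0]))
}

brute_r_grid <- function(counts, step = 1e-4) {
  grid <- seq(step, 0.5, by = step)
  ll <- vapply(grid, brute_f2_loglik, numeric(1), counts = counts)
  grid[which.max(ll)]
}

# Joint 3x3 genotype counts for two loci of a genotype matrix (rows in
# A/H/B order), computed by explicit iteration.
brute_pair_counts <- function(gm, i, j) {
  inds <- gm_individuals(gm)
  m <- matrix(0L, 3, 3)
  code <- c(A = 1L, H = 2L, B = 3L)
  for (ind in inds) {
    g1 <- gm[[ind]][i]; g2 <- gm[[ind]][j]
    if (g1 != "U" && g2 != "U") {
      m[code[g1], code[g2]] <- m[code[g1], code[g2]] + 1L
    }
  }
  m
}

# Random nucleotide sequence.
random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Write VCF text lines directly (independent of write_vcf) and return the
# path. `rows` is a data frame with columns chrom,pos1,ref,alt,qual and
# optional per-sample "GT:DP" strings in `calls` (list of named vectors).
write_vcf_text <- function(rows, samples = character(), calls = NULL) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", if (length(samples)) c("FORMAT", samples)),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    line <- paste(rows$chrom[i], rows$pos1[i], ".", rows$ref[i], rows$alt[i],
                  rows$qual[i], ".", ".", sep = "\t")
    if (length(samples)) {
      line <- paste(c(line, "GT:DP", calls[[i]][samples]), collapse = "\t")
    }
    line
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# A small clean F2 cross used by several tests.
toy_cross <- function(n_chrom = 2, n_markers = 6, spacing_cm = 10, n = 96,
                      missing_rate = 0, error_rate = 0, seed = 42) {
  markers <- do.call(rbind, lapply(seq_len(n_chrom), function(c_) {
    data.frame(chrom = paste0("chr", c_),
               pos = seq_len(n_markers) * 1000L,
               cm = (seq_len(n_markers) - 1) * spacing_cm)
  }))
  simulate_f2(cross_spec(tibble::as_tibble(markers), n = n,
                         missing_rate = missing_rate,
                         error_rate = error_rate), seed = seed)
}
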