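# The high-confidence SNP selection cascade. Record-level stages operate
# on variant tibbles from read_vcf(); matrix-level stages operate on the
# genotype matrix. Every stage appends to the filter trace.

#' Quality and depth filter
#'
#' Keeps records whose site quality exceeds `min_qual` (strict `>` by
#' default: "quality > 10" selects 11 and up) and whose depth reaches
#' `min_depth` (inclusive `>=` by default) in every sample with a
#' non-missing genotype; samples with missing calls are exempt from the
#' depth requirement.
#'
#' @param records Variant tibble from [read_vcf()].
#' @param min_qual Site quality threshold (default 10).
#' @param min_depth Per-sample depth threshold (default 4).
#' @param qual_strict,depth_strict Use strict inequality for each
#'   threshold (defaults `TRUE` for quality, `FALSE` for depth).
#' @return Filtered variant tibble with an updated trace.
#' @export
filter_quality_depth <- function(records, min_qual = 10, min_depth = 4,
                                 qual_strict = TRUE, depth_strict = FALSE) {
  stopifnot(min_qual >= 0, min_depth >= 0)
  ok_qual <- if (qual_strict) records$qual > min_qual else records$qual >= min_qual
  ok_qual[is.na(ok_qual)] <- FALSE

  ok_depth <- rep(TRUE, nrow(records))
  for (s in vcf_samples(records)) {
    g <- records[[paste0("gt_", s)]]
    d <- records[[paste0("dp_", s)]]
    ok_s <- if (depth_strict) d > min_depth else d >= min_depth
    ok_depth <- ok_depth & (g == "missing" | ok_s)
  }
  out <- records[ok_qual & ok_depth, ]
  attr(out, "samples") <- vcf_samples(records)
  attr(out, "trace") <- filter_trace(records)
  add_trace(out, "quality_depth", nrow(records), nrow(out),
            sprintf("min_qual=%g(%s) min_depth=%g(%s)", min_qual,
                    if (qual_strict) ">" else ">=", min_depth,
                    if (depth_strict) ">" else ">="))
}

#' Exclude loci heterozygous in an inbred parent
#'
#' Inbred lines are homozygous genome-wide, so a heterozygous call in a
#' parent almost certainly reflects a sequencing or alignment artefact
#' (e.g. reads from paralogous regions); the whole locus is removed.
#'
#' @param records Variant tibble from [read_vcf()].
#' @param parent_samples Names of the inbred samples to check.
#' @return Filtered variant tibble with an updated trace.
#' @export
drop_heterozygous_inbred <- function(records, parent_samples) {
  unknown <- setdiff(parent_samples, vcf_samples(records))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown sample(s): %s", paste(unknown, collapse = ", ")))
  }
  any_het <- rep(FALSE, nrow(records))
  for (s in parent_samples) {
    any_het <- any_het | records[[paste0("gt_", s)]] == "het"
  }
  out <- records[!any_het, ]
  attr(out, "samples") <- vcf_samples(records)
  attr(out, "trace") <- filter_trace(records)
  add_trace(out, "drop_het_inbred", nrow(records), nrow(out),
            sprintf("parents=%s", paste(parent_samples, collapse = ",")))
}

#' Remove indel records
#'
#' @param records Variant tibble from [read_vcf()].
#' @return Records with `is_indel == FALSE`, trace updated.
#' @export
remove_indels <- function(records) {
  out <- records[!records$is_indel, ]
  attr(out, "samples") <- vcf_samples(records)
  attr(out, "trace") <- filter_trace(records)
  add_trace(out, "remove_indels", nrow(records), nrow(out))
}

#' Missingness filter on the F2 matrix
#'
#' Keeps loci called in at least `min_call_rate` of the F2 individuals
#' ("allowing 20% missing data" = call rate >= 0.8, the default). Note the
#' common `--max-missing 0.2` flag of vcftools means the opposite
#' (tolerating up to 80% missing); this implementation follows the
#' plain-language reading and exposes the threshold.
#'
#' @param x Genotype matrix.
#' @param min_call_rate Minimum fraction of non-missing calls per locus,
#'   in `[0, 1]` (default 0.8).
#' @return Filtered genotype matrix.
#' @export
filter_missingness <- function(x, min_call_rate = 0.8) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1)
  codes <- gm_codes(x)
  call_rate <- rowMeans(!is.na(codes))
  if (ncol(codes) == 0L) call_rate <- rep(1, nrow(x))
  out <- x[call_rate >= min_call_rate, ]
  out <- restore_gm(out, x)
  add_trace(out, "missingness", nrow(x), nrow(out),
            sprintf("min_call_rate=%g", min_call_rate))
}

# Re-attach genotype-matrix attributes after subsetting rows.
restore_gm <- function(out, template) {
  new_genotype_matrix(as_tibble(out),
                      individuals = gm_individuals(template),
                      parents = attr(template, "parents"),
                      trace = filter_trace(template),
                      imputed = attr(template, "imputed"),
                      redundancy_map = attr(template, "redundancy_map"))
}

#' Impute missing F2 calls from flanking markers
#'
#' A conservative, deterministic fill-in: a missing call is imputed only
#' when the nearest non-missing calls flanking it on the same chromosome
#' (within the same individual) agree, in which case it takes their shared
#' code. At a chromosome end, where only one flank exists, the single
#' flanking call is used when `single_flank = TRUE` (the default).
#' Imputed calls are flagged in the `imputed` attribute (a logical matrix)
#' so downstream maps can be rebuilt without them.
#'
#' @param x Genotype matrix (loci sorted by position, as constructed).
#' @param single_flank Impute from a single flank at chromosome ends.
#' @return Genotype matrix with `U` calls filled where possible.
#' @export
impute_missing <- function(x, single_flank = TRUE) {
  inds <- gm_individuals(x)
  imputed <- matrix(FALSE, nrow = nrow(x), ncol = length(inds),
                    dimnames = list(NULL, inds))
  out <- as_tibble(x)
  for (chrom in unique(out$chrom)) {
    rows <- which(out$chrom == chrom)
    for (ind in inds) {
      g <- out[[ind]][rows]
      miss <- which(g == "U")
      if (length(miss) == 0L) next
      known <- which(g != "U")
      for (i in miss) {
        lo <- known[known < i]
        hi <- known[known > i]
        left <- if (length(lo) > 0L) g[max(lo)] else NA_character_
        right <- if (length(hi) > 0L) g[min(hi)] else NA_character_
        fill <- NA_character_
        if (!is.na(left) && !is.na(right)) {
          if (left == right) fill <- left
        } else if (single_flank) {
          fill <- if (is.na(left)) right else left
        }
        if (!is.na(fill)) {
          g[i] <- fill
          imputed[rows[i], ind] <- TRUE
        }
      }
      out[[ind]][rows] <- g
    }
  }
  res <- restore_gm(out, x)
  attr(res, "imputed") <- imputed
  add_trace(res, "impute", nrow(x), nrow(x),
            sprintf("flanking-agreement single_flank=%s n_imputed=%d",
                    single_flank, sum(imputed)))
}

#' Collapse loci with identical segregation patterns
#'
#' Markers whose F2 genotype vectors are identical carry no independent
#' mapping information; each identity class is represented by its first
#' locus in genome order. Missing calls act as wildcards: two loci are
#' merged when they agree at every individual where both are called
#' (`wildcard_missing = FALSE` requires exact vector identity instead).
#'
#' @param x Genotype matrix (run [impute_missing()] first).
#' @param wildcard_missing Treat `U` as matching any code (default TRUE).
#' @return Genotype matrix of representative loci; the `redundancy_map`
#'   attribute is a tibble mapping each representative to its members.
#' @export
collapse_redundant <- function(x, wildcard_missing = TRUE) {
  codes <- gm_codes(x)
  n <- nrow(x)
  rep_of <- rep(NA_integer_, n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    matched <- NA_integer_
    for (r in reps) {
      same <- if (wildcard_missing) {
        both <- !is.na(codes[i, ]) & !is.na(codes[r, ])
        all(codes[i, both] == codes[r, both])
      } else {
        identical(codes[i, ], codes[r, ])
      }
      if (same) { matched <- r; break }
    }
    if (is.na(matched)) {
      reps <- c(reps, i)
      rep_of[i] <- i
    } else {
      rep_of[i] <- matched
    }
  }
  locus_id <- paste0(x$chrom, ":", x$pos + 1L)
  rmap <- tibble(representative = locus_id[rep_of], member = locus_id)
  out <- x[reps, ]
  out <- restore_gm(out, x)
  attr(out, "redundancy_map") <- rmap
  add_trace(out, "collapse_redundant", n, length(reps),
            sprintf("wildcard_missing=%s", wildcard_missing))
}

#' Segregation sanity check
#'
#' Chi-square goodness-of-fit of each locus's F2 calls against the
#' Mendelian 1:2:1 expectation. Reported for inspection only — no loci are
#' filtered on segregation.
#'
#' @param x Genotype matrix.
#' @return Tibble with `chrom`, `pos`, counts `n_A`, `n_H`, `n_B`,
#'   `chisq`, `p_value`.
#' @export
segregation_check <- function(x) {
  codes <- gm_codes(x)
  n_A <- rowSums(codes == 0L, na.rm = TRUE)
  n_H <- rowSums(codes == 1L, na.rm = TRUE)
  n_B <- rowSums(codes == 2L, na.rm = TRUE)
  n <- n_A + n_H + n_B
  exp_ <- cbind(n / 4, n / 2, n / 4)
  obs <- cbind(n_A, n_H, n_B)
  chisq <- rowSums((obs - exp_)^2 / exp_)
  tibble(chrom = x$chrom, pos = x$pos, n_A = n_A, n_H = n_H, n_B = n_B,
         chisq = chisq, p_value = pchisq(chisq, df = 2, lower.tail = FALSE))
}
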