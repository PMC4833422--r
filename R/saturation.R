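#' Simulate per-fragment read depth
#'
#' Allocates `n_read_pairs` paired reads over the selected fragments by a
#' multinomial draw. Each read pair sequences one fragment (inward from
#' both restriction ends), so per-fragment depth — not per-base coverage —
#' is the quantity that matters for SNP calling in ddRAD-Seq. Weights
#' default to uniform; a user-supplied vector models length or PCR bias.
#'
#' @param fragments Selected fragment tibble (or an integer count of
#'   fragments).
#' @param n_read_pairs Number of read pairs to allocate (>= 0).
#' @param weights Non-negative per-fragment sampling weights; default
#'   uniform.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of depths, one per fragment, summing to
#'   `n_read_pairs`.
#' @export
simulate_depths <- function(fragments, n_read_pairs, weights = NULL,
                            seed = NULL) {
  n_frag <- if (is.data.frame(fragments)) nrow(fragments) else as.integer(fragments)
  assert_scalar_number(n_read_pairs, "n_read_pairs", min = 0)
  weights <- weights %||% rep(1, n_frag)
  if (length(weights) != n_frag || any(weights < 0)) {
    abort("`weights` must be non-negative, one per fragment")
  }
  if (sum(weights) == 0) abort("all-zero `weights`")
  if (!is.null(seed)) set.seed(seed)
  if (n_frag == 0L) return(integer(0))
  as.integer(rmultinom(1L, size = n_read_pairs, prob = weights))
}

# Index of the selected fragment containing each variant (NA when outside
# all fragments), plus whether a read of the given length reaches it.
variant_fragment_index <- function(variants, fragments, read_length) {
  idx <- rep(NA_integer_, nrow(variants))
  if (nrow(variants) == 0L || nrow(fragments) == 0L) return(idx)
  hits <- IRanges::findOverlaps(
    GenomicRanges::GRanges(
      variants$chrom, IRanges::IRanges(variants$pos + 1L, width = 1L)),
    GenomicRanges::GRanges(
      fragments$chrom, IRanges::IRanges(fragments$start + 1L, fragments$end))
  )
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (is.finite(read_length) && read_length > 0) {
    from_left <- variants$pos[qi] - fragments$start[si]
    from_right <- fragments$end[si] - 1L - variants$pos[qi]
    ok <- pmin(from_left, from_right) < read_length
    qi <- qi[ok]; si <- si[ok]
  }
  idx[qi] <- si
  idx
}

#' SNPs detected at simulated depths
#'
#' A SNP counts as detected iff (i) a read of length `read_length` starting
#' at a fragment end reaches it, and (ii) its fragment's simulated depth is
#' at least `min_depth` in each of the required independent samples
#' (`samples_required = 2` models calling a difference between two inbred
#' lines, each of which must be covered).
#'
#' @param variants Variant tibble.
#' @param fragments Selected fragment tibble.
#' @param depths Integer vector of per-fragment depths
#'   ([simulate_depths()]), or a list of such vectors, one per sample.
#' @param min_depth Minimum depth per sample (default 4, the pipeline's
#'   depth filter).
#' @param read_length Read length in bp (default 250); `Inf` for
#'   whole-fragment reach.
#' @param samples_required 1 or 2 independent samples that must each reach
#'   `min_depth`.
#' @return Integer count of detected SNPs.
#' @export
detected_at_depth <- function(variants, fragments, depths, min_depth = 4,
                              read_length = 250, samples_required = 2) {
  stopifnot(min_depth >= 1, samples_required %in% c(1L, 2L))
  if (!is.list(depths)) depths <- list(depths)
  if (length(depths) < samples_required) {
    abort("need one depth vector per required sample")
  }
  idx <- variant_fragment_index(variants, fragments, read_length)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(0L)
  covered <- rep(TRUE, length(idx))
  for (s in seq_len(samples_required)) {
    covered <- covered & depths[[s]][idx] >= min_depth
  }
  sum(covered)
}

#' SNP-discovery saturation curve
#'
#' Monte-Carlo estimate of how many SNPs a library detects as a function
#' of the sequenced read budget. Within each replicate the budgets are
#' nested — each larger budget extends the smaller one with additional
#' multinomial draws — so every per-replicate curve is monotone
#' non-decreasing, mirroring how read subsets of a real run relate.
#'
#' @param variants Variant tibble.
#' @param fragments Selected fragment tibble.
#' @param budgets Ascending vector of read-pair budgets.
#' @param replicates Number of Monte-Carlo replicates (default 100).
#' @param min_depth,read_length,samples_required See [detected_at_depth()].
#' @param weights Optional per-fragment weights ([simulate_depths()]).
#' @param seed Master seed; replicate seeds are derived by fixed offsets.
#' @return Object of class `"saturation_curve"`: tibble with columns
#'   `n_read_pairs`, `mean_detected`, `sd_detected`, `n_replicates`, and a
#'   `params` attribute. `autoplot()` draws the curve.
#' @export
saturation_curve <- function(variants, fragments, budgets,
                             replicates = 100, min_depth = 4,
                             read_length = 250, samples_required = 2,
                             weights = NULL, seed = 1) {
  budgets <- as.integer(budgets)
  if (is.unsorted(budgets, strictly = FALSE)) {
    abort("`budgets` must be ascending")
  }
  stopifnot(replicates >= 1)
  n_frag <- nrow(fragments)
  weights <- weights %||% rep(1, max(n_frag, 1L))
  if (n_frag > 0L && sum(weights) == 0) abort("all-zero `weights`")

  idx <- variant_fragment_index(variants, fragments, read_length)
  idx <- idx[!is.na(idx)]
  increments <- diff(c(0L, budgets))

  detected <- matrix(0, nrow = replicates, ncol = length(budgets))
  set.seed(seed)
  for (rep_i in seq_len(replicates)) {
    depth <- matrix(0L, nrow = max(n_frag, 1L), ncol = samples_required)
    for (b in seq_along(budgets)) {
      if (n_frag > 0L && increments[[b]] > 0L) {
        add <- rmultinom(samples_required, size = increments[[b]],
                         prob = weights)
        depth <- depth + add
      }
      if (length(idx) > 0L) {
        cov <- rep(TRUE, length(idx))
        for (s in seq_len(samples_required)) {
          cov <- cov & depth[idx, s] >= min_depth
        }
        detected[rep_i, b] <- sum(cov)
      }
    }
  }

  out <- tibble(
    n_read_pairs = budgets,
    mean_detected = colMeans(detected),
    sd_detected = apply(detected, 2L, sd),
    n_replicates = replicates
  )
  structure(out,
            params = list(min_depth = min_depth, read_length = read_length,
                          samples_required = samples_required, seed = seed,
                          n_fragments = n_frag,
                          n_reachable_snps = length(idx)),
            class = c("saturation_curve", class(out)))
}
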