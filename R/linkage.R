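# Two-point F2 linkage analysis. Genotypes are parental-anchored codes
# from an inbred x inbred cross, so phase is known (coupling) and the
# joint distribution of a codominant marker pair depends only on the
# recombination fraction r:
#
#   gametes: parental (1-r)/2 each, recombinant r/2 each; an F2 individual
#   is the union of two independent gametes. Collapsing the 3x3 joint
#   genotype table by symmetry gives class probabilities
#     parental hom/hom   (A,A),(B,B):          ((1-r)/2)^2
#     recombinant hom/hom(A,B),(B,A):          (r/2)^2
#     hom/het            (A,H),(H,A),(H,B),(B,H): r(1-r)/2
#     het/het            (H,H):                ((1-r)^2 + r^2)/2

# Sufficient statistics of a 3x3 joint count table (rows/cols in order
# A, H, B) for the coupling-phase F2 likelihood.
f2_suffstats <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(3L, 3L)))
  list(
    n_par = counts[1, 1] + counts[3, 3],
    n_rec = counts[1, 3] + counts[3, 1],
    n_mix = counts[1, 2] + counts[2, 1] + counts[2, 3] + counts[3, 2],
    n_hh  = counts[2, 2],
    n     = sum(counts)
  )
}

# Log-likelihood of r (constants dropped; they cancel in the LOD ratio
# only if kept consistently, so we keep the full class probabilities).
f2_loglik <- function(r, ss) {
  ss$n_par * log(((1 - r) / 2)^2) +
    ss$n_rec * (if (ss$n_rec > 0) log((r / 2)^2) else 0) +
    ss$n_mix * (if (ss$n_mix > 0) log(r * (1 - r) / 2) else 0) +
    ss$n_hh * log(((1 - r)^2 + r^2) / 2)
}

#' Two-point recombination fraction for an F2 marker pair
#'
#' Maximum-likelihood estimate of the recombination fraction r from the
#' 3x3 joint genotype table of two codominant markers in an F2 population
#' (phase known, coupling). The double-heterozygote class mixes parental
#' and recombinant configurations, so the likelihood is maximized
#' numerically over `[0, 0.5]` (tolerance 1e-6). The LOD score is the
#' log10 likelihood ratio against independence (r = 0.5).
#'
#' @param counts 3x3 matrix of joint genotype counts, rows = marker 1 and
#'   columns = marker 2, both in order A, H, B.
#' @return One-row tibble with `r`, `lod`, `n_informative` (`r` and `lod`
#'   `NA` when no individual has both markers called).
#' @examples
#' m <- matrix(0, 3, 3); m[1, 1] <- 8; m[1, 3] <- 2; m[3, 1] <- 2; m[3, 3] <- 8
#' estimate_r_f2(m)  # r = 0.2
#' @export
estimate_r_f2 <- function(counts) {
  ss <- f2_suffstats(counts)
  if (ss$n == 0) {
    return(tibble(r = NA_real_, lod = NA_real_, n_informative = 0L))
  }
  opt <- optimize(f2_loglik, interval = c(0, 0.5), ss = ss,
                  maximum = TRUE, tol = 1e-6)
  # the optimum can sit on the boundary r = 0; optimize() never returns
  # the endpoints, so compare explicitly
  r_hat <- opt$maximum
  ll_hat <- opt$objective
  ll0 <- f2_loglik(1e-12, ss)  # -> r = 0 limit when n_rec = n_mix = 0
  if (ss$n_rec == 0 && ss$n_mix == 0 && ll0 >= ll_hat) {
    r_hat <- 0
    ll_hat <- ss$n_par * log(1 / 4) + ss$n_hh * log(1 / 2)
  }
  lod <- (ll_hat - f2_loglik(0.5, ss)) / log(10)
  tibble(r = min(r_hat, 0.5), lod = max(lod, 0), n_informative = as.integer(ss$n))
}

#' All pairwise two-point estimates for a genotype matrix
#'
#' Computes `r`, LOD and the informative sample size for every locus pair,
#' dropping individuals missing at either member of a pair (pairwise, not
#' listwise, deletion).
#'
#' @param x Genotype matrix.
#' @return Tibble with `locus1`, `locus2` (locus ids `"chrom:pos"`,
#'   1-based), `r`, `lod`, `n_informative`; attribute `loci` keeps the
#'   id/chrom/pos table.
#' @export
pairwise_linkage <- function(x) {
  codes <- gm_codes(x)
  n_loci <- nrow(codes)
  ids <- paste0(x$chrom, ":", x$pos + 1L)
  # joint 3x3 counts for all pairs at once via indicator cross-products
  ind <- map(0:2, function(g) {
    m <- codes == g
    m[is.na(m)] <- FALSE
    m * 1
  })
  cnt <- array(0, dim = c(n_loci, n_loci, 3L, 3L))
  for (a in 1:3) for (b in 1:3) {
    cnt[, , a, b] <- tcrossprod(ind[[a]], ind[[b]])
  }
  pairs <- which(upper.tri(matrix(0, n_loci, n_loci)), arr.ind = TRUE)
  res <- map(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    estimate_r_f2(matrix(cnt[i, j, , ], 3L, 3L))
  }) |> list_rbind()
  out <- bind_cols(
    tibble(locus1 = ids[pairs[, 1L]], locus2 = ids[pairs[, 2L]]), res)
  structure(out, loci = tibble(id = ids, chrom = x$chrom, pos = x$pos))
}

#' Group loci into linkage groups
#'
#' Single-linkage clustering: two loci join the same group when their
#' two-point LOD is at least `lod_threshold` and their recombination
#' fraction at most `max_r`; groups are the connected components of that
#' graph. Loci linked to nothing are singletons.
#'
#' @param estimates Pairwise estimate tibble from [pairwise_linkage()].
#' @param lod_threshold Grouping LOD (default 4, the midpoint of the
#'   conventional 3–6 sweep).
#' @param max_r Maximum recombination fraction for a grouping edge
#'   (default 0.5, i.e. LOD-only grouping).
#' @return Tibble `locus`, `group` (groups numbered by first locus in
#'   input order; singletons get their own group); attribute `loci`
#'   carried through.
#' @export
group_loci <- function(estimates, lod_threshold = 4, max_r = 0.5) {
  stopifnot(lod_threshold > 0, max_r > 0, max_r <= 0.5)
  loci_tbl <- attr(estimates, "loci")
  loci <- if (!is.null(loci_tbl)) loci_tbl$id else
    unique(c(estimates$locus1, estimates$locus2))
  parent <- seq_along(loci)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  edges <- estimates[!is.na(estimates$lod) &
                       estimates$lod >= lod_threshold &
                       estimates$r <= max_r, ]
  i1 <- match(edges$locus1, loci)
  i2 <- match(edges$locus2, loci)
  for (k in seq_along(i1)) {
    r1 <- find(i1[[k]]); r2 <- find(i2[[k]])
    if (r1 != r2) parent[[max(r1, r2)]] <- min(r1, r2)
  }
  roots <- vapply(seq_along(loci), find, integer(1))
  group <- match(roots, unique(roots))
  structure(tibble(locus = loci, group = group),
            loci = loci_tbl, lod_threshold = lod_threshold, max_r = max_r)
}

#' Order loci within a linkage group
#'
#' Greedy seriation: seed with the pair of highest LOD, then repeatedly
#' append the unplaced locus with the smallest recombination fraction to
#' either end of the growing order (choosing the end with the smaller r).
#' Ties break on genome coordinate, and the finished order is reported
#' with the smaller genome coordinate first, so the result is
#' deterministic.
#'
#' @param members Character vector of locus ids in the group.
#' @param estimates Pairwise estimate tibble from [pairwise_linkage()].
#' @return Character vector: the members in map order.
#' @export
order_group <- function(members, estimates) {
  if (length(members) <= 1L) return(members)
  loci_tbl <- attr(estimates, "loci")
  es <- estimates[estimates$locus1 %in% members &
                    estimates$locus2 %in% members, ]
  # symmetric lookup of r and lod
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  r_lut <- setNames(es$r, key(es$locus1, es$locus2))
  lod_lut <- setNames(es$lod, key(es$locus1, es$locus2))
  coord <- setNames(seq_along(loci_tbl$id), loci_tbl$id)

  seed <- es[order(-es$lod, key(es$locus1, es$locus2)), ][1L, ]
  ord <- c(seed$locus1, seed$locus2)
  left <- setdiff(members, ord)
  while (length(left) > 0L) {
    r_head <- r_lut[key(left, ord[[1L]])]
    r_tail <- r_lut[key(left, ord[[length(ord)]])]
    best_r <- pmin(r_head, r_tail, na.rm = TRUE)
    best_r[is.na(best_r)] <- Inf
    pick <- which(best_r == min(best_r))
    if (length(pick) > 1L) pick <- pick[order(coord[left[pick]])][[1L]]
    lx <- left[[pick]]
    rh <- r_head[[pick]]; rt <- r_tail[[pick]]
    if (is.na(rh)) rh <- Inf
    if (is.na(rt)) rt <- Inf
    ord <- if (rh <= rt) c(lx, ord) else c(ord, lx)
    left <- setdiff(left, lx)
  }
  # canonical orientation: smaller genome coordinate first
  if (!is.null(loci_tbl) &&
      coord[[ord[[1L]]]] > coord[[ord[[length(ord)]]]]) {
    ord <- rev(ord)
  }
  ord
}

#' Haldane map distance
#'
#' Converts a recombination fraction to an additive map distance under the
#' no-interference model: d = -50 ln(1 - 2r) centimorgans.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Distance(s) in cM.
#' @examples
#' haldane_cm(0.2)  # 25.541
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    abort("haldane_cm is defined for 0 <= r < 0.5 (r = 0.5 is infinite)")
  }
  -50 * log(1 - 2 * r)
}

#' Inverse Haldane map function
#'
#' @param d Map distance(s) in cM, >= 0.
#' @return Recombination fraction(s): r = (1 - exp(-d/50)) / 2.
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) abort("`d` must be >= 0")
  (1 - exp(-d / 50)) / 2
}

#' Build a genetic map from linkage groups
#'
#' Orders each group ([order_group()]), converts recombination fractions
#' between consecutive mapped loci to Haldane centimorgans, and
#' accumulates positions. A locus is dropped as unmapped when neither of
#' its adjacent links in the ordered group satisfies `r <= max_r` and
#' `lod >= min_lod`; map distances are then re-taken between consecutive
#' surviving loci. The mapped fraction is the usual genotype-quality
#' indicator: miscalled markers fail to link tightly and fall off the map.
#'
#' @param groups Grouping tibble from [group_loci()].
#' @param estimates Pairwise estimate tibble from [pairwise_linkage()].
#' @param max_r Maximum adjacent recombination fraction (default 0.35).
#' @param min_lod Minimum adjacent LOD (default 2.0).
#' @return Object of class `"genetic_map"`: tibble `group`, `locus`,
#'   `chrom`, `pos`, `cm`; attributes `unmapped` (locus ids),
#'   `mapped_fraction`, `total_cm`. `glance()` summarizes per group.
#' @export
build_map <- function(groups, estimates, max_r = 0.35, min_lod = 2.0) {
  loci_tbl <- attr(estimates, "loci")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  r_lut <- setNames(estimates$r, key(estimates$locus1, estimates$locus2))
  lod_lut <- setNames(estimates$lod, key(estimates$locus1, estimates$locus2))

  unmapped <- character(0)
  rows <- list()
  for (g in sort(unique(groups$group))) {
    members <- groups$locus[groups$group == g]
    ord <- order_group(members, estimates)
    if (length(ord) == 1L) {
      placed <- ord
    } else {
      kk <- key(ord[-length(ord)], ord[-1L])
      link_ok <- r_lut[kk] <= max_r & lod_lut[kk] >= min_lod
      link_ok[is.na(link_ok)] <- FALSE
      ok <- c(link_ok, FALSE) | c(FALSE, link_ok)  # either adjacent link
      unmapped <- c(unmapped, ord[!ok])
      placed <- ord[ok]
    }
    if (length(placed) == 0L) next
    if (length(placed) == 1L) {
      cm <- 0
    } else {
      kk <- key(placed[-length(placed)], placed[-1L])
      r_adj <- pmin(r_lut[kk], 0.4999999)
      r_adj[is.na(r_adj)] <- 0.4999999
      cm <- cumsum(c(0, haldane_cm(r_adj)))
    }
    rows[[length(rows) + 1L]] <- tibble(group = g, locus = placed, cm = cm)
  }
  out <- list_rbind(rows)
  if (nrow(out) == 0L) {
    out <- tibble(group = integer(), locus = character(), cm = numeric())
  }
  if (!is.null(loci_tbl)) {
    out <- left_join(out, rename(loci_tbl, locus = "id"), by = "locus") |>
      select("group", "locus", "chrom", "pos", "cm")
  }
  n_total <- nrow(out) + length(unmapped)
  per_group_len <- if (nrow(out) > 0L) {
    out |> group_by(.data$group) |>
      summarise(len = max(.data$cm), .groups = "drop")
  } else {
    tibble(group = integer(), len = numeric())
  }
  structure(out,
            unmapped = unmapped,
            mapped_fraction = if (n_total > 0) nrow(out) / n_total else NA_real_,
            total_cm = sum(per_group_len$len),
            max_r = max_r, min_lod = min_lod,
            class = c("genetic_map", class(tibble())))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(
    "Genetic map: %d loci in %d group(s), %.1f cM total, %.1f%% of loci mapped\n",
    nrow(x), length(unique(x$group)), attr(x, "total_cm"),
    100 * attr(x, "mapped_fraction")))
  NextMethod()
}

#' Concordance of map order with genome order
#'
#' Kendall rank correlation between cM position and genomic coordinate per
#' linkage group, the check that mapped marker order reflects physical
#' order. Reported as |tau| since a linkage group's orientation is
#' arbitrary.
#'
#' @param gmap A `"genetic_map"`.
#' @return Tibble `group`, `n_loci`, `kendall_tau`.
#' @export
map_concordance <- function(gmap) {
  gmap |>
    as_tibble() |>
    group_by(.data$group) |>
    summarise(
      n_loci = n(),
      kendall_tau = if (n() >= 2L) {
        abs(stats::cor(.data$cm, .data$pos, method = "kendall"))
      } else NA_real_,
      .groups = "drop"
    )
}
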