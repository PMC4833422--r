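#' Which variants fall inside selected fragments?
#'
#' A variant is detectable by ddRAD-Seq iff its position lies inside one of
#' the size-selected fragments. With `read_window > 0` the variant must
#' additionally lie within `read_window` bases of the nearer fragment end,
#' modelling paired-end reads that do not reach the middle of long
#' fragments (250 models 250-bp paired-end chemistry); `read_window = 0`
#' means whole-fragment detectability, the convention used for in silico
#' enzyme choice.
#'
#' @param variants Variant tibble (needs `chrom` and `pos`, 0-based).
#' @param fragments Selected fragment tibble ([select_fragments()]).
#' @param genome Optional [Biostrings::DNAStringSet]; when supplied,
#'   variants on sequences absent from it raise an error.
#' @param read_window Integer >= 0; see above.
#' @return Logical vector, one element per variant row.
#' @export
detectable_snps <- function(variants, fragments, genome = NULL,
                            read_window = 0) {
  assert_scalar_number(read_window, "read_window", min = 0)
  if (!is.null(genome)) {
    bad <- setdiff(unique(variants$chrom), names(genome))
    if (length(bad) > 0L) {
      abort(sprintf("variant sequence(s) absent from genome: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  if (nrow(variants) == 0L) return(logical(0))
  if (nrow(fragments) == 0L) return(rep(FALSE, nrow(variants)))
  q <- IRanges::IRanges(start = variants$pos + 1L, width = 1L)
  s <- IRanges::IRanges(start = fragments$start + 1L, end = fragments$end)
  hits <- IRanges::findOverlaps(
    GenomicRanges::GRanges(variants$chrom, q),
    GenomicRanges::GRanges(fragments$chrom, s)
  )
  det <- rep(FALSE, nrow(variants))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (read_window > 0) {
    from_left <- variants$pos[qi] - fragments$start[si]
    from_right <- fragments$end[si] - 1L - variants$pos[qi]
    ok <- pmin(from_left, from_right) < read_window
    qi <- qi[ok]
  }
  det[qi] <- TRUE
  det
}

#' Genic and repeat context of variants
#'
#' Classifies each variant on two independent axes: genic iff its position
#' overlaps at least one gene interval, repeat iff it overlaps at least one
#' repeat interval (half-open intervals: a point at `start` is inside, at
#' `end` outside).
#'
#' @param variants Variant tibble.
#' @param gene_features,repeat_features Feature tibbles from
#'   [read_gff3_features()] (or `NULL` to skip an axis).
#' @return `variants` with logical columns `genic` and `repeat` added
#'   (`NA` for a skipped axis).
#' @export
classify_context <- function(variants, gene_features = NULL,
                             repeat_features = NULL) {
  point_in <- function(features) {
    if (is.null(features)) return(rep(NA, nrow(variants)))
    if (nrow(features) == 0L || nrow(variants) == 0L) {
      return(rep(FALSE, nrow(variants)))
    }
    hits <- IRanges::findOverlaps(
      GenomicRanges::GRanges(
        variants$chrom, IRanges::IRanges(variants$pos + 1L, width = 1L)),
      GenomicRanges::GRanges(
        features$chrom, IRanges::IRanges(features$start + 1L, features$end))
    )
    seq_len(nrow(variants)) %in% S4Vectors::queryHits(hits)
  }
  variants$genic <- point_in(gene_features)
  variants[["repeat"]] <- point_in(repeat_features)
  variants
}

#' Detectability report for one enzyme combination
#'
#' Combines fragment containment and genomic context into the per-library
#' summary used to rank enzyme pairs: how many of the genome-wide SNPs the
#' library can see at all, and how they split into genic/intergenic and
#' repeat/non-repeat fractions, per chromosome and in total.
#'
#' @inheritParams detectable_snps
#' @param gene_features,repeat_features Optional feature tibbles.
#' @param combination Label for the enzyme pair (defaults to the
#'   `enzymes` attribute of `fragments`).
#' @return Object of class `"detectability_report"`: a list with
#'   `combination`, `per_variant` (variants + `detectable`, `genic`,
#'   `repeat`), `summary` (per-chromosome + total tibble) and the
#'   parameters used. `tidy()` returns the summary table.
#' @export
detectability_report <- function(variants, fragments, genome = NULL,
                                 gene_features = NULL, repeat_features = NULL,
                                 read_window = 0, combination = NULL) {
  combination <- combination %||%
    paste(attr(fragments, "enzymes") %||% c("?", "?"), collapse = "/")
  pv <- classify_context(variants, gene_features, repeat_features)
  pv$detectable <- detectable_snps(variants, fragments, genome, read_window)

  smry <- pv |>
    group_by(.data$chrom) |>
    summarise(
      n_snps = n(),
      genic = sum(.data$detectable & .data$genic),
      repeat_ = sum(.data$detectable & .data[["repeat"]]),
      detectable = sum(.data$detectable),
      .groups = "drop"
    )
  total <- smry |>
    summarise(across(-"chrom", sum)) |>
    mutate(chrom = "total", .before = 1L)
  smry <- bind_rows(smry, total) |>
    mutate(
      fraction = .data$detectable / .data$n_snps,
      intergenic = .data$detectable - .data$genic,
      non_repeat = .data$detectable - .data$repeat_
    ) |>
    rename(`repeat` = "repeat_")

  structure(
    list(combination = combination, per_variant = pv, summary = smry,
         read_window = read_window,
         window = attr(fragments, "window")),
    class = "detectability_report"
  )
}

#' @export
print.detectability_report <- function(x, ...) {
  tot <- x$summary[x$summary$chrom == "total", ]
  cat(sprintf(
    "ddRAD detectability report [%s]: %d/%d SNPs detectable (%.1f%%)\n",
    x$combination, tot$detectable, tot$n_snps, 100 * tot$fraction))
  invisible(x)
}

#' Pool detectability across several enzyme combinations
#'
#' Detectable SNP sets of several libraries computed against the same
#' variant set are unioned: a SNP is detectable by the pool iff at least
#' one combination detects it. Sequencing several libraries is the usual
#' way to raise the detectable fraction when single-library yields are
#' low.
#'
#' @param reports List of [detectability_report()] objects over the same
#'   variant set.
#' @return A `"detectability_report"` whose combination label joins the
#'   inputs with `"+"`.
#' @export
combine_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  sizes <- map_int(reports, function(r) nrow(r$per_variant))
  if (length(unique(sizes)) != 1L) {
    abort("all reports must be computed against the same variant set")
  }
  pv <- reports[[1L]]$per_variant
  det <- purrr::reduce(map(reports, function(r) r$per_variant$detectable), `|`)
  pv$detectable <- det

  smry <- pv |>
    group_by(.data$chrom) |>
    summarise(
      n_snps = n(),
      genic = sum(.data$detectable & .data$genic),
      repeat_ = sum(.data$detectable & .data[["repeat"]]),
      detectable = sum(.data$detectable),
      .groups = "drop"
    )
  total <- smry |> summarise(across(-"chrom", sum)) |>
    mutate(chrom = "total", .before = 1L)
  smry <- bind_rows(smry, total) |>
    mutate(fraction = .data$detectable / .data$n_snps,
           intergenic = .data$detectable - .data$genic,
           non_repeat = .data$detectable - .data$repeat_) |>
    rename(`repeat` = "repeat_")

  structure(
    list(combination = paste(map_chr(reports, "combination"),
                             collapse = "+"),
         per_variant = pv, summary = smry,
         read_window = reports[[1L]]$read_window, window = NULL),
    class = "detectability_report"
  )
}

#' Average SNP spacing
#'
#' Reports genome-wide SNP density as "one SNP per d bp", the statistic
#' used to compare lines of different divergence: d = genome length /
#' number of SNPs, rounded to the nearest integer.
#'
#' @param variants Variant tibble.
#' @param genome A [Biostrings::DNAStringSet].
#' @return Integer spacing in bp, or `NA_integer_` when there are no
#'   variants (with a message).
#' @export
snp_density <- function(variants, genome) {
  if (nrow(variants) == 0L) {
    inform("snp_density: no SNPs")
    return(NA_integer_)
  }
  as.integer(round(sum(genome_lengths(genome)) / nrow(variants)))
}
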