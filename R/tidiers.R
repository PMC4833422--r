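# broom-style tidiers for the package's result objects.

#' @describeIn detectability_report tidy(): the per-chromosome summary
#'   table with the combination label attached.
#' @param x A `detectability_report`.
#' @param ... Unused.
#' @export
tidy.detectability_report <- function(x, ...) {
  mutate(x$summary, combination = x$combination, .before = 1L)
}

#' @describeIn detectability_report glance(): one row with totals.
#' @export
glance.detectability_report <- function(x, ...) {
  tot <- x$summary[x$summary$chrom == "total", ]
  tibble(combination = x$combination, n_snps = tot$n_snps,
         detectable = tot$detectable, fraction = tot$fraction,
         genic = tot$genic, `repeat` = tot$`repeat`,
         read_window = x$read_window)
}

#' @describeIn saturation_curve tidy(): the curve as a plain tibble.
#' @param x A `saturation_curve`.
#' @param ... Unused.
#' @export
tidy.saturation_curve <- function(x, ...) as_tibble(x)

#' @describeIn saturation_curve glance(): parameters and the asymptote
#'   proxy (detected at the largest budget).
#' @export
glance.saturation_curve <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_budgets = nrow(x),
         max_budget = max(x$n_read_pairs),
         detected_at_max = x$mean_detected[[which.max(x$n_read_pairs)]],
         reachable_snps = p$n_reachable_snps,
         min_depth = p$min_depth, read_length = p$read_length,
         samples_required = p$samples_required,
         n_replicates = x$n_replicates[[1L]])
}

#' @describeIn build_map tidy(): the map as a plain tibble.
#' @param x A `genetic_map`.
#' @param ... Unused.
#' @export
tidy.genetic_map <- function(x, ...) as_tibble(x)

#' @describeIn build_map glance(): per-map totals — groups, mapped loci,
#'   unmapped count, mapped fraction, total length.
#' @export
glance.genetic_map <- function(x, ...) {
  tibble(n_groups = length(unique(x$group)),
         n_mapped = nrow(x),
         n_unmapped = length(attr(x, "unmapped")),
         mapped_fraction = attr(x, "mapped_fraction"),
         total_cm = attr(x, "total_cm"))
}

#' @describeIn summarize_digest tidy(): the summary as a plain tibble.
#' @param x A `digest_summary`.
#' @param ... Unused.
#' @export
tidy.digest_summary <- function(x, ...) as_tibble(x)

#' @describeIn summarize_digest glance(): the total row plus the pair.
#' @export
glance.digest_summary <- function(x, ...) {
  tot <- as_tibble(x)[x$chrom == "total", ]
  mutate(tot,
         combination = paste(attr(x, "enzymes"), collapse = "/"),
         .before = 1L)
}
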