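# ggplot2 visualisations of the main result types.

#' Plot a saturation curve
#'
#' Mean detected SNPs against read budget with a +/- 1 sd ribbon.
#'
#' @param object A `saturation_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturation_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_read_pairs,
                                   y = .data$mean_detected)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_detected - .data$sd_detected,
      ymax = .data$mean_detected + .data$sd_detected), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "read pairs", y = "detected SNPs",
                  title = "SNP discovery saturation") +
    ggplot2::theme_minimal()
}

#' Plot a digest summary
#'
#' Fragment counts in the size window per chromosome, split by end-class.
#'
#' @param object A `digest_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.digest_summary <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$chrom != "total") |>
    select("chrom", "win_ab", "win_aa", "win_bb", "win_with_end") |>
    tidyr::pivot_longer(-"chrom", names_to = "end_class",
                        values_to = "n", names_prefix = "win_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$n,
                                   fill = .data$end_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "fragments in window", fill = "end class",
      title = paste("Double digest:",
                    paste(attr(object, "enzymes"), collapse = "/"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a genetic map
#'
#' Classic vertical-bar map chart: one column per linkage group, ticks at
#' locus positions.
#'
#' @param object A `genetic_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genetic_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$group), y = .data$cm)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$group), linewidth = 2,
                       colour = "grey80") +
    ggplot2::geom_point(shape = 95, size = 6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "linkage group", y = "position (cM)",
                  title = "Genetic linkage map") +
    ggplot2::theme_minimal()
}
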