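#' Run the in silico design workflow
#'
#' Ties the stages together for a set of candidate enzyme pairs: digest
#' the genome with each pair, size-select, summarize, and — when a variant
#' set is supplied — compute per-pair detectability, the cross-pair
#' comparison table, and the pooled (union) detectability. Optionally a
#' saturation curve is simulated per pair.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param pairs List of length-2 character vectors of enzyme names, e.g.
#'   `list(c("SalI","PstI"), c("EcoRI","HindIII"))`.
#' @param window Inclusive fragment size window (default `c(300, 900)`).
#' @param end_mode Passed to [select_fragments()].
#' @param variants Optional variant tibble; detectability is skipped (with
#'   a message) when absent.
#' @param gene_features,repeat_features Optional feature tibbles.
#' @param read_window Passed to [detectability_report()].
#' @param saturate Simulate saturation curves per pair (needs `variants`).
#' @param budgets Read budgets for [saturation_curve()].
#' @param replicates,min_depth,read_length,samples_required Saturation
#'   parameters.
#' @param seed Seed for the saturation simulation.
#' @param out_dir If non-NULL, per-pair summary/fragments and the
#'   comparison table are written there as TSV/BED with manifest headers.
#' @param enzyme_table Enzyme lookup table.
#' @return List of class `"ddrad_workflow"` with elements `digests`
#'   (named list of [summarize_digest()] tables), `fragments` (named list
#'   of selected fragment tibbles), `reports` (named list of
#'   detectability reports or NULL), `comparison` (one row per pair),
#'   `union` (pooled report or NULL), `curves` (named list or NULL), and
#'   `params`.
#' @export
run_workflow <- function(genome, pairs, window = c(300, 900),
                         end_mode = "AB_only", variants = NULL,
                         gene_features = NULL, repeat_features = NULL,
                         read_window = 0,
                         saturate = FALSE, budgets = NULL,
                         replicates = 100, min_depth = 4,
                         read_length = 250, samples_required = 2,
                         seed = 1, out_dir = NULL,
                         enzyme_table = restriction_enzymes()) {
  stopifnot(length(pairs) >= 1L)
  labels <- map_chr(pairs, paste, collapse = "/")
  if (anyDuplicated(labels)) abort("duplicate enzyme pairs")

  fragments <- list(); digests <- list(); reports <- list(); curves <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    frags <- digest_genome(genome, p[[1L]], p[[2L]], enzyme_table)
    digests[[labels[[i]]]] <- summarize_digest(frags, window)
    sel <- select_fragments(frags, window[[1L]], window[[2L]], end_mode)
    fragments[[labels[[i]]]] <- sel
    if (!is.null(variants)) {
      reports[[labels[[i]]]] <- detectability_report(
        variants, sel, genome, gene_features, repeat_features,
        read_window = read_window, combination = labels[[i]])
      if (saturate) {
        if (is.null(budgets)) abort("`saturate = TRUE` needs `budgets`")
        curves[[labels[[i]]]] <- saturation_curve(
          variants, sel, budgets, replicates = replicates,
          min_depth = min_depth, read_length = read_length,
          samples_required = samples_required, seed = seed + i)
      }
    }
  }
  if (is.null(variants)) {
    inform("run_workflow: no variants supplied; detectability stage skipped")
  }

  comparison <- map(labels, function(lb) {
    d <- digests[[lb]]
    tot <- d[d$chrom == "total", ]
    row <- tibble(combination = lb,
                  n_fragments = tot$n_fragments,
                  ab_in_window = tot$win_ab,
                  all_in_window = tot$win_total,
                  selected = nrow(fragments[[lb]]))
    if (!is.null(variants)) {
      rt <- reports[[lb]]$summary
      rt <- rt[rt$chrom == "total", ]
      row$n_snps <- rt$n_snps
      row$detectable <- rt$detectable
      row$fraction <- rt$fraction
    }
    row
  }) |> list_rbind()

  union_report <- if (!is.null(variants) && length(reports) > 0L) {
    combine_reports(unname(reports))
  }

  out <- structure(
    list(digests = digests, fragments = fragments,
         reports = if (length(reports) > 0L) reports,
         comparison = comparison, union = union_report,
         curves = if (length(curves) > 0L) curves,
         params = list(window = window, end_mode = end_mode,
                       read_window = read_window, seed = seed)),
    class = "ddrad_workflow")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prm <- sprintf("window=%d-%d end_mode=%s seed=%d",
                   window[[1L]], window[[2L]], end_mode, seed)
    for (lb in labels) {
      safe <- gsub("/", "-", lb)
      write_tsv_with_manifest(as_tibble(digests[[lb]]),
                              file.path(out_dir, paste0("digest_", safe, ".tsv")),
                              prm)
      write_fragments_bed(fragments[[lb]],
                          file.path(out_dir, paste0("fragments_", safe, ".bed")))
      if (!is.null(variants)) {
        write_tsv_with_manifest(
          reports[[lb]]$summary,
          file.path(out_dir, paste0("detect_", safe, ".tsv")), prm)
      }
      if (length(curves) > 0L && !is.null(curves[[lb]])) {
        write_tsv_with_manifest(
          as_tibble(curves[[lb]]),
          file.path(out_dir, paste0("saturation_", safe, ".tsv")), prm)
      }
    }
    write_tsv_with_manifest(comparison,
                            file.path(out_dir, "comparison.tsv"), prm)
  }
  out
}

#' @export
print.ddrad_workflow <- function(x, ...) {
  cat("ddRAD in silico workflow\n")
  print(x$comparison)
  invisible(x)
}

#' Fragment counts under both end-mode interpretations
#'
#' For reproducing published in silico fragment counts whose end-mode
#' convention is unstated: digests a genome FASTA with the given pairs and
#' reports, per pair, the number of fragments in the size window counting
#' (a) AB fragments only and (b) all fragments. Pass the tomato SL2.50
#' FASTA with pairs SalI/PstI and EcoRI/HindIII to compare against
#' published counts.
#'
#' @param fasta_path Path to the genome FASTA.
#' @param pairs List of enzyme-name pairs; defaults to the four surveyed
#'   combinations.
#' @param window Inclusive size window (default `c(300, 900)`).
#' @return Tibble `combination`, `ab_in_window`, `all_in_window`.
#' @export
sl250_fragment_report <- function(fasta_path,
                                  pairs = list(c("SalI", "PstI"),
                                               c("PstI", "EcoRI"),
                                               c("EcoRI", "HindIII"),
                                               c("PstI", "MspI")),
                                  window = c(300, 900)) {
  genome <- read_fasta(fasta_path)
  wf <- run_workflow(genome, pairs, window = window, end_mode = "AB_only")
  select(wf$comparison, "combination", "ab_in_window", "all_in_window")
}
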