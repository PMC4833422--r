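# Shared internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Sentinel label for fragment termini at chromosome ends, which lack a
# ligatable restriction end and must be excludable downstream.
END_LABEL <- "END"

genotype_codes <- c("ref_hom", "alt_hom", "het", "missing")

#' Sequence lengths of a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Named integer vector of sequence lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  setNames(Biostrings::width(genome), names(genome))
}

# One '#' manifest line prepended to every table the package writes.
manifest_line <- function(params = character()) {
  info <- c(sprintf("ddradtools=%s", as.character(packageVersion("ddradtools"))),
            params)
  paste0("# ", paste(info, collapse = " "))
}

write_tsv_with_manifest <- function(x, path, params = character()) {
  readr::write_lines(manifest_line(params), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, min))
  }
  invisible(x)
}
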