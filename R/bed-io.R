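#' Write restriction fragments to BED6
#'
#' One line per fragment: chrom, start, end (already 0-based half-open,
#' BED's native convention), name `"<leftEnzyme>-<rightEnzyme>"` (with the
#' reserved label `END` for chromosome-end termini), score = fragment
#' length, strand ".". A single `#` header line records the tool version.
#'
#' @param fragments Fragment tibble from [digest_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  lines <- manifest_line("format=BED6 name=leftEnzyme-rightEnzyme score=length")
  if (nrow(fragments) > 0L) {
    lines <- c(lines, sprintf(
      "%s\t%d\t%d\t%s-%s\t%d\t.",
      fragments$chrom, fragments$start, fragments$end,
      fragments$left_end, fragments$right_end, fragments$length
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read restriction fragments from BED6
#'
#' Inverse of [write_fragments_bed()].
#'
#' @param path Path to a BED6 file written by [write_fragments_bed()].
#' @return Fragment tibble with columns `chrom`, `start`, `end`,
#'   `left_end`, `right_end`, `length`.
#' @export
read_fragments_bed <- function(path) {
  bed <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic"
  )
  ends <- stringr::str_split_fixed(bed$name, "-", 2L)
  tibble(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    left_end = ends[, 1L], right_end = ends[, 2L],
    length = bed$end - bed$start
  )
}
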