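#' Read genomic features from GFF3
#'
#' GFF3 stores 1-based closed intervals; internally the package uses
#' 0-based half-open coordinates everywhere, so `start` is decremented on
#' load. Gene annotations typically keep only records of type `"gene"`;
#' repeat annotations (e.g. ITAG-style repeat GFF3 files) keep every
#' record, since repeat type vocabularies vary between pipelines.
#'
#' @param path Path to a GFF3 file.
#' @param category `"gene"` or `"repeat"`; stored on each interval and used
#'   by [classify_context()].
#' @param types GFF3 `type` values to keep. Defaults to `"gene"` for
#'   `category = "gene"` and all types for `category = "repeat"`.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `category`; the `source` attribute records the path.
#' @export
read_gff3_features <- function(path, category = c("gene", "repeat"),
                               types = NULL) {
  category <- arg_match(category)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(sprintf("malformed GFF3 in %s: %s",
                                      path, conditionMessage(e)))
  )
  if (is.null(types) && category == "gene") types <- "gene"
  if (!is.null(types) && length(gr) > 0L) {
    gr <- gr[as.character(gr$type) %in% types]
  }
  out <- tibble(
    chrom    = as.character(GenomicRanges::seqnames(gr)),
    start    = GenomicRanges::start(gr) - 1L,
    end      = GenomicRanges::end(gr),
    category = category
  )
  structure(out, source = path)
}

#' Write features to GFF3
#'
#' Inverse of [read_gff3_features()]: internal 0-based half-open intervals
#' are emitted as 1-based closed GFF3 records, so a read/write round trip
#' restores the on-disk coordinates exactly.
#'
#' @param features Tibble with `chrom`, `start`, `end`, `category`.
#' @param path Output path.
#' @param type GFF3 `type` column value; defaults to the category.
#' @return `path`, invisibly.
#' @export
write_gff3_features <- function(features, path, type = NULL) {
  lines <- c("##gff-version 3", manifest_line())
  if (nrow(features) > 0L) {
    type <- type %||% features$category
    lines <- c(lines, sprintf(
      "%s\tddradtools\t%s\t%d\t%d\t.\t.\t.\tID=feat%04d",
      features$chrom, type, features$start + 1L, features$end,
      seq_len(nrow(features))
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
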