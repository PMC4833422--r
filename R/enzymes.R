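#' Built-in restriction enzyme table
#'
#' The five enzymes commonly used to survey plant genomes for ddRAD-Seq
#' library design, spanning low (SalI, PstI), middle (EcoRI, HindIII) and
#' high (MspI) cut-site frequencies. `cut_offset` is the distance in bases
#' from the first base of the recognition sequence to the top-strand
#' cleavage point, e.g. EcoRI G^AATTC has offset 1 and PstI CTGCA^G has
#' offset 5.
#'
#' @return A tibble with columns `name`, `recognition` (IUPAC string) and
#'   `cut_offset` (integer).
#' @examples
#' restriction_enzymes()
#' @export
restriction_enzymes <- function() {
  tibble(
    name        = c("EcoRI", "HindIII", "MspI", "PstI", "SalI"),
    recognition = c("GAATTC", "AAGCTT", "CCGG", "CTGCAG", "GTCGAC"),
    cut_offset  = c(1L, 1L, 1L, 5L, 1L)
  )
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence; IUPAC ambiguity codes allowed.
#' @param cut_offset Top-strand cut position measured from the first base
#'   of the recognition site, in `0..nchar(recognition)`.
#' @return One-row enzyme tibble compatible with [restriction_enzymes()].
#' @examples
#' enzyme("ApoI", "RAATTY", 1)
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!nzchar(recognition) ||
      !grepl("^[ACGTRYSWKMBDHVN]+$", recognition)) {
    abort("`recognition` must be a non-empty IUPAC nucleotide string")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition)) {
    abort("`cut_offset` must lie in 0..nchar(recognition)")
  }
  tibble(name = as.character(name), recognition = recognition,
         cut_offset = cut_offset)
}

#' Read an enzyme table extending the built-ins
#'
#' A plain TSV with columns `name`, `recognition`, `cut_offset`. Rows are
#' appended to the built-in table; a row re-using a built-in name replaces
#' it.
#'
#' @param path Path to the TSV file.
#' @return Enzyme tibble.
#' @export
read_enzyme_table <- function(path) {
  extra <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  required <- c("name", "recognition", "cut_offset")
  if (!all(required %in% names(extra))) {
    abort("enzyme table needs columns name, recognition, cut_offset")
  }
  extra <- purrr::pmap(extra[required], enzyme) |> list_rbind()
  base <- restriction_enzymes()
  bind_rows(base[!base$name %in% extra$name, ], extra)
}

# Look up one enzyme by name in a table (defaults to the built-ins).
get_enzyme <- function(name, table = restriction_enzymes()) {
  if (is.data.frame(name)) {
    stopifnot(nrow(name) == 1L)
    return(name)
  }
  hit <- table[table$name == name, ]
  if (nrow(hit) != 1L) {
    abort(sprintf("unknown enzyme '%s'; see restriction_enzymes()", name))
  }
  hit
}

# TRUE when the recognition sequence is its own reverse complement, in
# which case one top-strand scan finds every site.
is_palindromic <- function(recognition) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition)))
  identical(recognition, rc)
}
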