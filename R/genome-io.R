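#' Read a reference genome from FASTA
#'
#' Sequences are upper-cased and any IUPAC ambiguity letter other than
#' A, C, G, T or N is normalized to N: ambiguous bases cannot support a
#' confident restriction-site call, so they are treated as unknown. The
#' number of normalized bases is recorded in the `n_normalized` attribute
#' and reported via a message.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names and alphabet
#'   restricted to A,C,G,T,N.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtRGGT"), fa)
#' g <- read_fasta(fa)
#' as.character(g)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) abort(sprintf("empty FASTA file: %s", path))
  # readDNAStringSet keeps full header lines; sequence name = first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate sequence name(s) in %s: %s",
                  path, paste(dup, collapse = ", ")))
  }
  chr <- toupper(as.character(seqs))
  n_ambig <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(chr), letters = "RYSWKMBDHV"))
  if (n_ambig > 0L) {
    chr <- chartr("RYSWKMBDHV", strrep("N", 10L), chr)
    inform(sprintf("read_fasta: normalized %d ambiguous base(s) to N", n_ambig))
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(seqs)
  attr(out, "n_normalized") <- as.integer(n_ambig)
  out
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, format = "fasta")
  invisible(path)
}
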