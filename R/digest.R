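#' Find restriction cut sites on a genome
#'
#' Scans every sequence for the enzyme's recognition site and returns the
#' absolute cut coordinates (recognition start + cut offset, 0-based).
#' IUPAC ambiguity codes in the recognition sequence are expanded to their
#' base sets; N in the genome never matches, so assembly gaps produce no
#' phantom sites. Overlapping matches each yield a cut. For non-palindromic
#' recognition sequences the bottom strand is scanned as well and its cuts
#' mapped to top-strand coordinates (the five built-in enzymes are all
#' palindromic, so this path only matters for custom enzymes).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param enz Enzyme name from [restriction_enzymes()], or a one-row
#'   enzyme tibble from [enzyme()].
#' @param enzyme_table Lookup table for enzyme names.
#' @return Tibble with columns `chrom`, `cut` (0-based coordinate of the
#'   cleavage point) and `enzyme`, sorted by chromosome and coordinate.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TTGAATTCTT"))
#' find_sites(g, "EcoRI")   # one cut at coordinate 3
#' @export
find_sites <- function(genome, enz, enzyme_table = restriction_enzymes()) {
  enz <- get_enzyme(enz, enzyme_table)
  k <- nchar(enz$recognition)
  starts_fwd <- match_starts(genome, enz$recognition)
  cuts <- mutate(starts_fwd, cut = .data$start + enz$cut_offset)
  if (!is_palindromic(enz$recognition)) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(enz$recognition)))
    starts_rev <- match_starts(genome, rc)
    # the enzyme reads the bottom strand 5'->3'; its top-strand cleavage
    # point sits cut_offset bases in from the right edge of the match
    cuts_rev <- mutate(starts_rev, cut = .data$start + k - enz$cut_offset)
    cuts <- bind_rows(cuts, cuts_rev)
  }
  cuts |>
    distinct(.data$chrom, .data$cut) |>
    mutate(enzyme = enz$name) |>
    arrange(.data$chrom, .data$cut)
}

# 0-based start coordinates of all (possibly overlapping) matches of an
# IUPAC pattern on the top strand; genome-side N never matches.
match_starts <- function(genome, pattern) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  hits <- Biostrings::vmatchPattern(pattern, genome, fixed = "subject")
  res <- map2(names(genome), as.list(hits), function(nm, ir) {
    if (length(ir) == 0L) return(NULL)
    st <- IRanges::start(ir)
    # drop matches spanning an N (ambiguity in the subject never matches a
    # concrete pattern base, but pattern-side ambiguity codes are wildcards
    # under fixed = "subject", so guard explicitly)
    seqchr <- as.character(genome[[nm]])
    frag <- substring(seqchr, st, st + nchar(pattern) - 1L)
    st <- st[!grepl("N", frag, fixed = TRUE)]
    if (length(st) == 0L) return(NULL)
    tibble(chrom = nm, start = st - 1L)
  })
  out <- list_rbind(keep(res, Negate(is.null)))
  if (nrow(out) == 0L) tibble(chrom = character(), start = integer()) else out
}

#' In silico double digestion
#'
#' Cuts the genome with two restriction enzymes and returns the resulting
#' fragments. Cut coordinates of both enzymes are merged per sequence;
#' fragments are the intervals between consecutive cuts plus the two
#' chromosome-end flanks, so fragments tile each sequence exactly. Each
#' fragment end is labelled with the enzyme that produced the bounding cut,
#' or the reserved label `"END"` at chromosome ends. If both enzymes cut at
#' the same coordinate the boundary is kept once and labelled with the
#' lexicographically smaller enzyme name (with a warning).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param enzyme_a,enzyme_b Distinct enzyme names or [enzyme()] rows.
#' @param enzyme_table Lookup table for enzyme names.
#' @return Fragment tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `left_end`, `right_end`, `length`; attribute `enzymes`
#'   stores the pair.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AACTGCAGTTCCGGAA"))
#' digest_genome(g, "PstI", "MspI")
#' @export
digest_genome <- function(genome, enzyme_a, enzyme_b,
                          enzyme_table = restriction_enzymes()) {
  enzyme_a <- get_enzyme(enzyme_a, enzyme_table)
  enzyme_b <- get_enzyme(enzyme_b, enzyme_table)
  if (identical(enzyme_a$name, enzyme_b$name)) {
    abort("double digestion needs two distinct enzymes")
  }
  cuts <- bind_rows(find_sites(genome, enzyme_a),
                    find_sites(genome, enzyme_b))
  lens <- genome_lengths(genome)

  frags <- map(names(lens), function(chrom) {
    cc <- cuts[cuts$chrom == chrom, ]
    cc <- cc[order(cc$cut, cc$enzyme), ]
    shared <- unique(cc$cut[duplicated(cc$cut)])
    if (length(shared) > 0L) {
      warn(sprintf(
        "%s: %d coordinate(s) cut by both enzymes; labelled %s",
        chrom, length(shared), min(enzyme_a$name, enzyme_b$name)))
      cc <- cc[!duplicated(cc$cut), ]  # sorted by enzyme within cut
    }
    # interior cuts only: a cut at 0 or at the sequence end produces no
    # boundary between two non-empty fragments
    keep <- cc$cut > 0L & cc$cut < lens[[chrom]]
    cc <- cc[keep, ]
    bounds <- c(0L, cc$cut, lens[[chrom]])
    labels <- c(END_LABEL, cc$enzyme, END_LABEL)
    n <- length(bounds) - 1L
    tibble(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      left_end = labels[seq_len(n)],
      right_end = labels[seq_len(n) + 1L]
    )
  }) |> list_rbind()

  frags <- mutate(frags, length = .data$end - .data$start)
  structure(frags, enzymes = c(enzyme_a$name, enzyme_b$name))
}

# End-class of each fragment given the enzyme pair: "AB" (one end from
# each enzyme), "AA", "BB", or "END" (chromosome-end terminus involved).
end_class <- function(fragments, enzymes = attr(fragments, "enzymes")) {
  if (is.null(enzymes)) {
    enzymes <- setdiff(unique(c(fragments$left_end, fragments$right_end)),
                       END_LABEL)
    stopifnot(length(enzymes) <= 2L)
    enzymes <- sort(c(enzymes, rep("", 2L - length(enzymes))))
  }
  a <- enzymes[[1L]]; b <- enzymes[[2L]]
  l <- fragments$left_end; r <- fragments$right_end
  dplyr::case_when(
    l == END_LABEL | r == END_LABEL ~ "END",
    (l == a & r == b) | (l == b & r == a) ~ "AB",
    l == a & r == a ~ "AA",
    TRUE ~ "BB"
  )
}

#' Size-select fragments
#'
#' Keeps fragments whose length lies in `[min_len, max_len]` (both bounds
#' inclusive) and whose end labels are allowed by `end_mode`:
#'
#' * `"AB_only"` (default) — one end from each enzyme, the fragments that
#'   receive both ddRAD adapters and are actually sequenced;
#' * `"all_internal"` — any fragment bounded by restriction cuts on both
#'   sides (AB, AA or BB);
#' * `"all"` — every fragment, including chromosome-end flanks.
#'
#' @param fragments Fragment tibble from [digest_genome()].
#' @param min_len,max_len Inclusive size window in bp (the experimental
#'   target window is 300–900 bp).
#' @param end_mode One of `"AB_only"`, `"all_internal"`, `"all"`.
#' @return Filtered fragment tibble, input order preserved.
#' @export
select_fragments <- function(fragments, min_len = 300, max_len = 900,
                             end_mode = c("AB_only", "all_internal", "all")) {
  end_mode <- arg_match(end_mode)
  if (min_len > max_len) abort("`min_len` must be <= `max_len`")
  cls <- end_class(fragments)
  keep <- fragments$length >= min_len & fragments$length <= max_len
  keep <- keep & switch(end_mode,
    AB_only = cls == "AB",
    all_internal = cls != "END",
    all = TRUE
  )
  out <- fragments[keep, ]
  attr(out, "enzymes") <- attr(fragments, "enzymes")
  attr(out, "window") <- c(min_len, max_len)
  out
}

#' Summarize a double digestion
#'
#' Per-chromosome and total tallies of cut sites per enzyme and of
#' fragments by end-class (AB / AA / BB / END-involving), overall and
#' inside the size window.
#'
#' @param fragments Full fragment tibble from [digest_genome()] (before
#'   size selection).
#' @param window Length-2 inclusive size window, default `c(300, 900)`.
#' @return Tibble with one row per chromosome plus a `"total"` row;
#'   columns `chrom`, `sites_<enzymeA>`, `sites_<enzymeB>`, `n_fragments`,
#'   `ab`, `aa`, `bb`, `with_end`, and the same four prefixed `win_` for
#'   the window counts, plus `win_total`. Class `"digest_summary"`.
#' @export
summarize_digest <- function(fragments, window = c(300, 900)) {
  enzymes <- attr(fragments, "enzymes")
  if (is.null(enzymes)) abort("`fragments` must come from digest_genome()")
  cls <- end_class(fragments, enzymes)
  in_win <- fragments$length >= window[[1L]] & fragments$length <= window[[2L]]

  per <- tibble(chrom = fragments$chrom, cls = cls, in_win = in_win,
                left_end = fragments$left_end) |>
    group_by(.data$chrom) |>
    summarise(
      sites_a = sum(.data$left_end == enzymes[[1L]]),
      sites_b = sum(.data$left_end == enzymes[[2L]]),
      n_fragments = n(),
      ab = sum(.data$cls == "AB"),
      aa = sum(.data$cls == "AA"),
      bb = sum(.data$cls == "BB"),
      with_end = sum(.data$cls == "END"),
      win_total = sum(.data$in_win),
      win_ab = sum(.data$cls == "AB" & .data$in_win),
      win_aa = sum(.data$cls == "AA" & .data$in_win),
      win_bb = sum(.data$cls == "BB" & .data$in_win),
      win_with_end = sum(.data$cls == "END" & .data$in_win),
      .groups = "drop"
    )
  total <- per |>
    summarise(across(-"chrom", sum)) |>
    mutate(chrom = "total", .before = 1L)
  out <- bind_rows(per, total)
  names(out)[names(out) == "sites_a"] <- paste0("sites_", enzymes[[1L]])
  names(out)[names(out) == "sites_b"] <- paste0("sites_", enzymes[[2L]])
  structure(out, enzymes = enzymes, window = window,
            class = c("digest_summary", class(out)))
}
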