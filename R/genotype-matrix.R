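# Genotype matrix: one row per locus (chrom, pos), one column per F2
# individual with codes A (parent-1 hom), B (parent-2 hom), H (het),
# U (missing). Attributes: individuals, parents, trace (filter audit),
# imputed (which calls were filled in), redundancy_map.

new_genotype_matrix <- function(tbl, individuals, parents,
                                trace = empty_trace(), imputed = NULL,
                                redundancy_map = NULL) {
  structure(
    tbl,
    individuals = individuals,
    parents = parents,
    trace = trace,
    imputed = imputed,
    redundancy_map = redundancy_map,
    class = c("genotype_matrix", class(tibble()))
  )
}

empty_trace <- function() {
  tibble(stage = character(), n_in = integer(), n_out = integer(),
         params = character())
}

add_trace <- function(x, stage, n_in, n_out, params = "") {
  tr <- bind_rows(attr(x, "trace") %||% empty_trace(),
                  tibble(stage = stage, n_in = as.integer(n_in),
                         n_out = as.integer(n_out), params = params))
  attr(x, "trace") <- tr
  x
}

#' Filter audit trail
#'
#' Every stage of the genotype pipeline records how many loci went in and
#' came out; the trail reconciles exactly (each stage's input count equals
#' the previous stage's output count).
#'
#' @param x A variant tibble or genotype matrix that has passed through
#'   pipeline stages.
#' @return Tibble with columns `stage`, `n_in`, `n_out`, `params`.
#' @export
filter_trace <- function(x) attr(x, "trace") %||% empty_trace()

#' Individuals of a genotype matrix
#' @param x A genotype matrix.
#' @return Character vector of F2 individual names.
#' @export
gm_individuals <- function(x) attr(x, "individuals")

#' Build an F2 genotype matrix from variant records
#'
#' Anchors each F2 call to the parental alleles: a call equal to parent 1's
#' homozygous genotype becomes `A`, equal to parent 2's becomes `B`,
#' heterozygous becomes `H`, missing becomes `U`. Loci where either parent
#' is missing or heterozygous, or where the parents do not differ, are not
#' informative for a cross and are dropped (recorded in the trace; run
#' [drop_heterozygous_inbred()] first to see the het-specific count).
#'
#' @param records Variant tibble from [read_vcf()] with genotype columns.
#' @param parents Length-2 character vector naming the parent samples
#'   (parent 1 then parent 2).
#' @return A genotype matrix (`chrom`, `pos`, one column per F2
#'   individual) with the parents removed from the columns.
#' @export
as_genotype_matrix <- function(records, parents) {
  samples <- vcf_samples(records)
  stopifnot(length(parents) == 2L)
  missing_p <- setdiff(parents, samples)
  if (length(missing_p) > 0L) {
    abort(sprintf("unknown parent sample(s): %s",
                  paste(missing_p, collapse = ", ")))
  }
  f2 <- setdiff(samples, parents)
  p1 <- records[[paste0("gt_", parents[[1L]])]]
  p2 <- records[[paste0("gt_", parents[[2L]])]]
  informative <- p1 %in% c("ref_hom", "alt_hom") &
    p2 %in% c("ref_hom", "alt_hom") & p1 != p2

  kept <- records[informative, ]
  tbl <- tibble(chrom = kept$chrom, pos = kept$pos)
  for (ind in f2) {
    g <- kept[[paste0("gt_", ind)]]
    code <- dplyr::case_when(
      g == "het" ~ "H",
      g == "missing" ~ "U",
      g == kept[[paste0("gt_", parents[[1L]])]] ~ "A",
      TRUE ~ "B"
    )
    tbl[[ind]] <- code
  }
  tbl <- arrange(tbl, .data$chrom, .data$pos)
  out <- new_genotype_matrix(tbl, individuals = f2, parents = parents,
                             trace = filter_trace(records))
  add_trace(out, "anchor_to_parents", nrow(records), nrow(tbl),
            sprintf("parents=%s", paste(parents, collapse = ",")))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("F2 genotype matrix: %d loci x %d individuals\n",
              nrow(x), length(gm_individuals(x))))
  NextMethod()
}

#' Write a genotype matrix to TSV
#'
#' One locus per row: `chrom`, `pos` (1-based on disk), then one code
#' column (A/B/H/U) per individual.
#'
#' @param x Genotype matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(x, path) {
  out <- as_tibble(x)
  out$pos <- out$pos + 1L
  write_tsv_with_manifest(
    out, path,
    sprintf("parents=%s", paste(attr(x, "parents"), collapse = ",")))
}

#' Read a genotype matrix from TSV
#'
#' @param path Path written by [write_genotype_matrix()].
#' @param parents Optional parent names to attach.
#' @return Genotype matrix.
#' @export
read_genotype_matrix <- function(path, parents = NULL) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  tbl$pos <- as.integer(tbl$pos) - 1L
  inds <- setdiff(names(tbl), c("chrom", "pos"))
  new_genotype_matrix(as_tibble(tbl), individuals = inds, parents = parents)
}

# Integer view of the call codes: A=0, H=1, B=2, U=NA. loci x individuals.
gm_codes <- function(x) {
  inds <- gm_individuals(x)
  m <- matrix(NA_integer_, nrow = nrow(x), ncol = length(inds),
              dimnames = list(NULL, inds))
  lut <- c(A = 0L, H = 1L, B = 2L, U = NA_integer_)
  for (j in seq_along(inds)) m[, j] <- lut[x[[inds[[j]]]]]
  m
}
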