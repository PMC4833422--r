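# Synthetic data with known structure: genomes with planted restriction
# sites, variant sets with controlled density, and F2 crosses with known
# genetic maps. Everything is deterministic under a master seed, and the
# planted truth is returned alongside the data so tests can check
# recovery.

#' Generate a synthetic genome with planted restriction sites
#'
#' Background sequence is i.i.d. with the requested GC content. Recognition
#' sites are then planted by overwriting background bases at the planned
#' positions (genome length and the coordinates of other planted features
#' are preserved). Background occurrences of recognition sites are not
#' removed — the returned ledger lists only the planted positions, and
#' [find_sites()] will generally return a superset. Optional gene and
#' repeat interval plans produce a matching feature annotation.
#'
#' @param lengths Named integer vector of chromosome lengths in bp.
#' @param gc GC content of the background sequence, in `[0, 1]`.
#' @param planted_sites Tibble with columns `enzyme`, `chrom`, `pos`
#'   (0-based start of the recognition site), or `NULL`.
#' @param n_genes,gene_length Number and mean length of gene intervals to
#'   draw uniformly per genome (exponential lengths, minimum 50 bp).
#' @param n_repeats,repeat_length Same for repeat intervals.
#' @param seed Master seed.
#' @param enzyme_table Enzyme lookup for planted recognition sequences.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `features`
#'   (tibble as from [read_gff3_features()], both categories), and
#'   `planted_sites` (the ledger: `enzyme`, `chrom`, `pos`, `cut`).
#' @export
generate_genome <- function(lengths, gc = 0.35, planted_sites = NULL,
                            n_genes = 0, gene_length = 1000,
                            n_repeats = 0, repeat_length = 2000,
                            seed = 1, enzyme_table = restriction_enzymes()) {
  stopifnot(gc >= 0, gc <= 1, !is.null(names(lengths)))
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- map_chr(lengths, function(L) {
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = "")
  })

  ledger <- tibble(enzyme = character(), chrom = character(),
                   pos = integer(), cut = integer())
  if (!is.null(planted_sites) && nrow(planted_sites) > 0L) {
    for (k in seq_len(nrow(planted_sites))) {
      enz <- get_enzyme(planted_sites$enzyme[[k]], enzyme_table)
      chrom <- planted_sites$chrom[[k]]
      pos <- planted_sites$pos[[k]]
      site <- enz$recognition
      if (pos + nchar(site) > lengths[[chrom]]) {
        abort(sprintf("planted site at %s:%d extends beyond chromosome end",
                      chrom, pos))
      }
      substr(seqs[[chrom]], pos + 1L, pos + nchar(site)) <- site
      ledger <- bind_rows(ledger, tibble(
        enzyme = enz$name, chrom = chrom, pos = as.integer(pos),
        cut = as.integer(pos + enz$cut_offset)))
    }
  }

  draw_intervals <- function(n, mean_len, category) {
    if (n == 0) return(tibble(chrom = character(), start = integer(),
                              end = integer(), category = character()))
    chroms <- sample(names(lengths), n, replace = TRUE,
                     prob = lengths / sum(lengths))
    len <- pmax(50L, as.integer(round(stats::rexp(n, 1 / mean_len))))
    start <- map2_int(chroms, len, function(ch, l) {
      as.integer(floor(runif(1, 0, max(1, lengths[[ch]] - l))))
    })
    tibble(chrom = chroms, start = start,
           end = pmin(start + len, lengths[chroms]),
           category = category) |>
      arrange(.data$chrom, .data$start)
  }
  features <- bind_rows(draw_intervals(n_genes, gene_length, "gene"),
                        draw_intervals(n_repeats, repeat_length, "repeat"))

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(lengths)
  list(genome = genome, features = features, planted_sites = ledger)
}

#' Generate a synthetic variant set
#'
#' SNP positions are drawn from an inhomogeneous point process over each
#' chromosome. The intensity follows `gradient`: `"constant"` (homogeneous
#' Poisson at `density_per_bp`), `"linear"` (intensity rising linearly from
#' 0 to twice the mean along each chromosome), or `"blockwise"` (relative
#' intensity per equal-width block given in `block_weights`, emulating the
#' strongly clustered SNP distributions seen between real inbred lines).
#' The reference allele is read from the genome; the alternative allele is
#' uniform over the other three bases (positions with reference N are
#' skipped).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param density_per_bp Mean SNP density (e.g. `1/651`).
#' @param gradient `"constant"`, `"linear"` or `"blockwise"`.
#' @param block_weights Non-negative relative intensities for
#'   `"blockwise"` (recycled across chromosomes).
#' @param qual Site quality to assign (default 40).
#' @param seed Seed.
#' @return Variant tibble (`chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `is_indel`), positions sorted and unique, no sample columns.
#' @export
generate_variants <- function(genome, density_per_bp,
                              gradient = c("constant", "linear", "blockwise"),
                              block_weights = c(4, 1, 0, 1, 4),
                              qual = 40, seed = 1) {
  gradient <- arg_match(gradient)
  stopifnot(density_per_bp > 0)
  set.seed(seed)
  lens <- genome_lengths(genome)
  out <- map(names(lens), function(chrom) {
    L <- lens[[chrom]]
    n <- rpois(1L, L * density_per_bp)
    if (n == 0L) return(NULL)
    pos <- switch(gradient,
      constant = runif(n, 0, L),
      # inverse-CDF sample of intensity f(x) = 2x/L^2
      linear = L * sqrt(runif(n)),
      blockwise = {
        w <- block_weights
        blk <- sample(seq_along(w), n, replace = TRUE, prob = w / sum(w))
        (blk - 1 + runif(n)) * (L / length(w))
      })
    pos <- sort(unique(as.integer(floor(pos))))
    ref <- substring(as.character(genome[[chrom]]), pos + 1L, pos + 1L)
    keep <- ref %in% c("A", "C", "G", "T")
    pos <- pos[keep]; ref <- ref[keep]
    alt <- map_chr(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L))
    tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
           qual = qual, is_indel = FALSE)
  }) |> keep(Negate(is.null)) |> list_rbind()
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), qual = numeric(), is_indel = logical())
  }
  structure(out, samples = character())
}

#' Specify a synthetic F2 cross
#'
#' @param markers Tibble with columns `chrom`, `pos` (genomic, 0-based)
#'   and `cm` (genetic position, non-decreasing within chromosome).
#' @param n Population size (default 96).
#' @param missing_rate Per-call probability of a missing genotype.
#' @param error_rate Per-call probability of a symmetric genotyping error
#'   (the observed code is replaced by one of the other two, uniformly).
#' @return A `"cross_spec"` list.
#' @export
cross_spec <- function(markers, n = 96, missing_rate = 0, error_rate = 0) {
  stopifnot(all(c("chrom", "pos", "cm") %in% names(markers)),
            n >= 1, missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  bad <- markers |> group_by(.data$chrom) |>
    summarise(ok = !is.unsorted(.data$cm), .groups = "drop")
  if (!all(bad$ok)) abort("genetic positions must be non-decreasing")
  structure(list(markers = arrange(markers, .data$chrom, .data$cm, .data$pos),
                 n = n, missing_rate = missing_rate,
                 error_rate = error_rate),
            class = "cross_spec")
}

# One gamete for one chromosome: crossovers form a Poisson process along
# the genetic map (rate 1 per Morgan, no interference); the returned
# vector gives the transmitted parental allele (0/1) at each marker.
sim_gamete <- function(cm) {
  L <- max(cm) - min(cm)
  n_xo <- rpois(1L, L / 100)
  start <- sample(0:1, 1L)
  if (n_xo == 0L) return(rep(start, length(cm)))
  xo <- sort(runif(n_xo, min(cm), max(cm)))
  n_before <- findInterval(cm, xo)
  (start + n_before) %% 2L
}

#' Simulate an F2 population
#'
#' Each individual receives two independent gametes per chromosome, each
#' generated with crossovers as a Poisson process along the genetic map
#' (Haldane model, no interference). The genotype at a marker is the union
#' of the two gametes, coded A/H/B; missingness and symmetric genotyping
#' errors are then applied. The error-free matrix is kept in the `truth`
#' attribute for oracle tests.
#'
#' @param spec A [cross_spec()].
#' @param seed Seed.
#' @return A genotype matrix with individuals `F2_001`..., attribute
#'   `truth` (the pre-noise matrix) and attribute `markers` (the spec's
#'   marker table).
#' @export
simulate_f2 <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cross_spec"))
  set.seed(seed)
  mk <- spec$markers
  n <- spec$n
  inds <- sprintf("F2_%03d", seq_len(n))
  codes <- matrix(NA_integer_, nrow = nrow(mk), ncol = n)
  for (chrom in unique(mk$chrom)) {
    rows <- which(mk$chrom == chrom)
    cm <- mk$cm[rows]
    for (j in seq_len(n)) {
      codes[rows, j] <- sim_gamete(cm) + sim_gamete(cm)
    }
  }
  truth <- matrix(c("A", "H", "B")[codes + 1L], nrow = nrow(mk))

  observed <- truth
  if (spec$error_rate > 0) {
    err <- matrix(runif(length(observed)) < spec$error_rate,
                  nrow = nrow(observed))
    if (any(err)) {
      observed[err] <- vapply(observed[err], function(g) {
        sample(setdiff(c("A", "H", "B"), g), 1L)
      }, character(1))
    }
  }
  if (spec$missing_rate > 0) {
    miss <- matrix(runif(length(observed)) < spec$missing_rate,
                   nrow = nrow(observed))
    observed[miss] <- "U"
  }

  tbl <- tibble(chrom = mk$chrom, pos = mk$pos)
  truth_tbl <- tbl
  for (j in seq_len(n)) {
    tbl[[inds[[j]]]] <- observed[, j]
    truth_tbl[[inds[[j]]]] <- truth[, j]
  }
  out <- new_genotype_matrix(tbl, individuals = inds,
                             parents = c("parent1", "parent2"))
  attr(out, "truth") <- new_genotype_matrix(
    truth_tbl, individuals = inds, parents = c("parent1", "parent2"))
  attr(out, "markers") <- mk
  out
}

#' Export an F2 cross as a multi-sample VCF
#'
#' Turns a simulated genotype matrix into variant records (ref allele A,
#' alt allele G at every marker, parents homozygous ref/alt respectively)
#' so the full file-based pipeline can run on simulated data. Depths are
#' drawn Poisson around `mean_depth` (0 for missing calls).
#'
#' @param x Genotype matrix from [simulate_f2()].
#' @param mean_depth Mean simulated depth per call (default 20).
#' @param qual Site quality (default 40).
#' @param seed Seed for the depth draws.
#' @return Variant tibble ready for [write_vcf()], with parent columns
#'   `parent1`/`parent2` followed by the F2 individuals.
#' @export
f2_as_variants <- function(x, mean_depth = 20, qual = 40, seed = 1) {
  set.seed(seed)
  inds <- gm_individuals(x)
  out <- tibble(chrom = x$chrom, pos = x$pos, ref = "A", alt = "G",
                qual = qual, is_indel = FALSE)
  out$gt_parent1 <- "ref_hom"
  out$dp_parent1 <- rpois(nrow(out), mean_depth) + 1L
  out$gt_parent2 <- "alt_hom"
  out$dp_parent2 <- rpois(nrow(out), mean_depth) + 1L
  lut <- c(A = "ref_hom", B = "alt_hom", H = "het", U = "missing")
  for (ind in inds) {
    g <- lut[x[[ind]]]
    out[[paste0("gt_", ind)]] <- unname(g)
    d <- rpois(nrow(out), mean_depth) + 1L
    d[g == "missing"] <- 0L
    out[[paste0("dp_", ind)]] <- d
  }
  structure(out, samples = c("parent1", "parent2", inds))
}
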