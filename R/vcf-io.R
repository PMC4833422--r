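#' Read variant calls from VCF
#'
#' Loads a VCF 4.x file into a tibble of variant records, one row per
#' site. Positions are converted from VCF's 1-based convention to the
#' package-internal 0-based convention. Per-sample genotype and depth are
#' spread into wide columns `gt_<sample>` / `dp_<sample>`; genotypes are
#' coded `"ref_hom"`, `"alt_hom"`, `"het"` or `"missing"` (./.). A missing
#' DP field is treated as depth 0. A record is an indel when any REF/ALT
#' allele is longer than one base.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return Tibble with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `qual`, `is_indel`, then genotype/depth columns per sample. The
#'   sample names are stored in the `samples` attribute.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- tibble(
    chrom = fix$CHROM,
    pos   = as.integer(fix$POS) - 1L,
    ref   = fix$REF,
    alt   = fix$ALT,
    qual  = suppressWarnings(as.numeric(fix$QUAL)),
    is_indel = purrr::map2_lgl(fix$REF, fix$ALT, function(r, a) {
      alleles <- c(r, strsplit(a %||% "", ",")[[1]])
      alleles <- alleles[!is.na(alleles) & nzchar(alleles)]
      any(nchar(alleles) != 1L)
    })
  )
  samples <- character()
  if (ncol(v@gt) > 1L) {
    samples <- colnames(v@gt)[-1L]
    gt <- vcfR::extract.gt(v, element = "GT")
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
    for (s in samples) {
      out[[paste0("gt_", s)]] <- unname(decode_gt(gt[, s]))
      d <- dp[, s]
      d[is.na(d)] <- 0
      out[[paste0("dp_", s)]] <- as.integer(d)
    }
  }
  structure(out, samples = samples)
}

# Map diploid GT strings to the package's genotype codes.
decode_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  alleles <- strsplit(gt, "/", fixed = TRUE)
  map_chr(alleles, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == ".")) return("missing")
    if (length(unique(a)) > 1L) return("het")
    if (a[[1]] == "0") "ref_hom" else "alt_hom"
  })
}

#' Sample names attached to a variant or genotype table
#'
#' @param x Tibble returned by [read_vcf()] or [as_genotype_matrix()].
#' @return Character vector of sample names.
#' @export
vcf_samples <- function(x) attr(x, "samples") %||% character()

#' Write variant records to VCF
#'
#' Emits a minimal VCF 4.2 file with GT and DP FORMAT fields, converting
#' internal 0-based positions back to VCF's 1-based convention. Genotype
#' codes map back as ref_hom = 0/0, alt_hom = 1/1, het = 0/1,
#' missing = ./. — so [read_vcf()] round-trips the table exactly.
#'
#' @param variants Variant tibble as produced by [read_vcf()] or
#'   [generate_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  samples <- vcf_samples(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=ddradtools-", packageVersion("ddradtools")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples) > 0L) c("FORMAT", samples)),
          collapse = "\t")
  )
  gt_string <- c(ref_hom = "0/0", alt_hom = "1/1", het = "0/1",
                 missing = "./.")
  body <- character(nrow(variants))
  if (nrow(variants) > 0L) {
    base <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.",
                    variants$chrom, variants$pos + 1L, variants$ref,
                    variants$alt,
                    ifelse(is.na(variants$qual), ".",
                           format(variants$qual, trim = TRUE)))
    if (length(samples) > 0L) {
      cols <- map(samples, function(s) {
        paste0(gt_string[variants[[paste0("gt_", s)]]], ":",
               variants[[paste0("dp_", s)]])
      })
      body <- paste(base, "GT:DP",
                    do.call(paste, c(cols, sep = "\t")), sep = "\t")
    } else {
      body <- base
    }
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}
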