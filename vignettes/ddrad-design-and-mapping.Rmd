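---
title: "Methods: in silico ddRAD-Seq design and F2 linkage validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico ddRAD-Seq design and F2 linkage validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddradtools)
```

This vignette documents the models, parameter choices and numerical
conventions behind `ddradtools`, in the spirit of a methods section:
what is computed, under which assumptions, and where the design was
genuinely open, why it was resolved the way it was.

## Coordinates and formats

Internally every interval is 0-based half-open and every variant
position 0-based; conversions to the 1-based conventions of VCF and
GFF3 happen only in `read_vcf()`/`write_vcf()` and
`read_gff3_features()`/`write_gff3_features()`. A single convention
eliminates off-by-one drift between modules, and the reader/writer
pairs round-trip exactly (tested). Ambiguity letters other than N in a
genome are normalized to N on load and counted: an ambiguous base
cannot support a confident restriction-site call, and a conservative
caller should not cut there.

## In silico digestion

An enzyme is a recognition sequence (IUPAC allowed) plus a cut offset
`c` measured from the first base of the site on the top strand; the cut
coordinate of a match starting at `s` is `s + c`. The five built-in
enzymes (EcoRI G^AATTC, HindIII A^AGCTT, MspI C^CGG, PstI CTGCA^G,
SalI G^TCGAC) are all palindromic; for non-palindromic custom
recognition sequences the reverse strand is scanned too and the
bottom-strand cut maps to top-strand coordinate `s + k − c`. Matching
uses `Biostrings::vmatchPattern(fixed = "subject")` so IUPAC codes in
the pattern act as base sets while genome-side N never matches
(matches spanning N are dropped explicitly); N runs therefore simply
elongate fragments, as assembly gaps should.

A double digest merges the cut coordinates of both enzymes per
sequence; fragments are the intervals between consecutive cuts plus the
chromosome-end flanks, so they tile each sequence exactly — an
invariant the tests assert on random sequences, alongside equality with
a brute-force per-offset matcher. Chromosome-end termini carry the
reserved end label `END`: such fragments have no ligatable restriction
end and must be excludable downstream. If both enzymes cut at the same
coordinate the boundary is kept once and labelled with the
lexicographically smaller enzyme name — an arbitrary but deterministic
tie-break, and it is warned about because a shared cut coordinate
usually signals overlapping recognition sites worth inspecting.

Size selection keeps fragments with `min_len <= length <= max_len`.
Both bounds are **inclusive**: a published "300–900 bp" window is
normally read as containing its endpoints, and the bounds are plain
arguments for anyone who disagrees. Three end modes are exposed:

* `AB_only` (default): one end from each enzyme. ddRAD adapter
  chemistry ligates one enzyme-specific adapter per end, so only AB
  fragments acquire both adapters and get sequenced — the default
  matches what the instrument sees.
* `all_internal`: any fragment with two restriction ends (AB, AA, BB).
* `all`: everything, including END-bounded flanks.

Published in silico fragment counts do not always state which
convention they used, so `sl250_fragment_report()` reports both the
AB-only and the all-fragments count per pair for direct comparison
against printed values. Fragment length is the genomic distance between
cut coordinates; adapter bases are not added (the laboratory size
window applies after ligation, so the two windows differ by the adapter
lengths — a documented, deliberate simplification).

## SNP detectability

A variant is detectable by a library iff its position falls inside a
size-selected fragment. The default `read_window = 0` (whole-fragment
detectability) is the convention for pre-experiment enzyme choice;
`read_window = 250` models 250-bp paired-end reads that enter a
fragment from each restriction end and never reach the middle of
fragments longer than 500 bp. Genic and repeat context are two
independent overlap tests against feature sets, so `genic + intergenic`
and `repeat + non_repeat` each partition the detectable count — an
invariant the tests assert. Pooling libraries (`combine_reports()`)
unions the detectable sets; the pooled fraction can only rise, and
equals the larger set when one library's detectable set contains the
other's. Which GFF3 feature types count as "genic" is configurable and
defaults to type `gene`; repeat annotations keep all record types since
repeat GFF3 vocabularies vary between annotation pipelines.

Indel records are retained (flagged) by detectability: indel removal
belongs to the mapping-population filter, not to assay design.

## Saturation simulation

Reads are allocated to fragments, not bases: each read pair covers
`read_length` bases inward from each fragment end, which is exactly the
geometry of ddRAD paired-end sequencing. Depths are multinomial over
fragments (weights default uniform; a user weight vector is the hook
for length or PCR bias). A SNP is detected at a budget iff its fragment
reaches `min_depth` in each of `samples_required` independently
simulated samples. The default `samples_required = 2` reflects calling
differences between two lines, each of which must be covered;
`min_depth = 4` mirrors the genotype pipeline's depth filter. Base
quality is not simulated — there is no error model — so the quality
filter has no analog here; depth dominates saturation behaviour and the
simplification is intentional.

Budgets within a replicate are nested (each larger budget extends the
smaller one with fresh multinomial increments), so every per-replicate
curve is monotone, like read subsets of one real run. Because marginal
per-fragment depth is binomial, the exact expectation of the detected
count is a sum of per-SNP binomial tails; the tests hold the simulator
to that expectation (a 2-fragment, 8-read toy where
E[detected] = 2·P(Bin(8,½) ≥ 4) = 1.2734, checked over 10,000
replicates at 3 standard errors). The asymptote equals the
detectability count at the matching read window, also asserted.
Replicates default to 100; all replicate randomness derives from one
seed argument.

## The genotype filtering cascade

For an inbred × inbred cross the cascade is, in order: site quality
**strictly greater than** 10 (a "quality > 10" rule selects 11 and up;
the strictness of both inequalities is an argument), per-sample depth
≥ 4 with missing calls exempt (matching per-genotype DP semantics);
indel removal; removal of loci heterozygous in either parent (an inbred
parent is homozygous genome-wide, so a het call there is a sequencing
or alignment artefact and the locus is suspect); anchoring of F2 calls
to the parental alleles (A/B/H/U codes); a per-locus call-rate filter;
imputation; redundancy collapse. Every stage appends to a trace whose
counts reconcile exactly — each stage's input is the previous stage's
output — which is the practical audit when reproducing a published
locus accounting.

Two semantics points were genuinely open:

* **Missingness.** "Allowing 20% missing data" means keep loci with
  call rate ≥ 0.8, and that is the default
  (`filter_missingness(min_call_rate = 0.8)`). Note the widely used
  vcftools flag `--max-missing 0.2` means nearly the opposite
  (tolerate up to 80% missing) under that tool's conventions; the
  threshold is exposed so either reading can be applied.
* **Imputation.** Haplotype-phasing imputers (Beagle-class) are out of
  scope; instead a missing call is filled only when the nearest
  non-missing flanking calls of the same individual on the same
  chromosome agree (single-flank fills at chromosome ends are on by
  default and switchable). This is deterministic and conservative, but
  *not* neutral: an imputed call can never create a recombinant, so
  adjacent recombination fractions — and therefore map lengths — are
  biased downward when missingness is high (at 10% missingness the
  effect is visible; see the README example, where the imputed map is
  ~18% shorter than the truth-matrix map). Imputed calls are flagged in
  the `imputed` attribute precisely so maps can be rebuilt without
  them.

Redundancy ("loci similar to others") is interpreted as identical
segregation vectors with missing compared as a wildcard, each identity
class represented by its first locus in genome order —
JoinMap-style "identical loci"; `wildcard_missing = FALSE` gives
exact-match collapse. No segregation-distortion filter is applied;
`segregation_check()` reports per-locus 1:2:1 chi-squares for
inspection only.

## Two-point F2 linkage

Genotype codes are parental-anchored, so phase is known (coupling) and
the joint distribution of a marker pair depends only on r. Collapsing
the 3×3 genotype table by symmetry leaves four class probabilities
(parental hom/hom ((1−r)/2)²; recombinant hom/hom (r/2)²; hom/het
r(1−r)/2; het/het ((1−r)²+r²)/2 — the mixture class). The likelihood is
maximized by 1-D numerical optimization on [0, 0.5] with tolerance
1e-6; there is no closed form because of the het/het mixture. The
boundary r = 0 is compared explicitly since the optimizer never returns
interval endpoints. A pair with no jointly called individuals returns
an NA sentinel. Tests hold the estimator to a brute-force likelihood
grid (step 1e-4, agreement within 1e-3) whose likelihood is derived
independently by enumerating all sixteen gamete combinations.

Grouping is single-linkage clustering with edges requiring LOD ≥
threshold (strict ≥, so LOD 2.9 at threshold 3 does not link) and
r ≤ `max_r`. The default threshold is 4 — the midpoint of the
conventional 3–6 sweep — and sweeping the threshold is a one-line loop
for anyone validating group stability. Ordering within a group replaces
regression/multipoint mapping with greedy seriation: seed with the
highest-LOD pair, repeatedly append the unplaced locus of smallest r̂
to the better end, break ties by genome coordinate, and orient the
finished order with the smaller genome coordinate first. This is enough
for the purpose the map serves here — validating genotype quality via
the mapped fraction and the concordance of map order with physical
order (Kendall τ per group) — and is deterministic; it is *not* a
substitute for multipoint ordering when marker order itself is the
research output. Map distances between consecutive mapped loci use
Haldane's function d = −50·ln(1−2r) (no interference); a locus whose
adjacent links all violate `max_r = 0.35` or `min_lod = 2` is dropped
and counted as unmapped. Kosambi or other map functions are a trivial
extension but deliberately not defaulted, to keep distances
comparable.

## What the synthetic module emulates — and what it does not

`generate_genome()` draws i.i.d. background sequence at a requested GC
content and plants recognition sites by overwriting bases (genome
length and other planted coordinates stay fixed); the ledger of planted
sites is the test oracle, and background matches are expected
supersets. `generate_variants()` draws SNP positions from a
homogeneous, linear or blockwise-intensity point process — the
blockwise default (relative weights 4:1:0:1:4 across five equal blocks)
mimics the strongly clustered SNP distributions seen between divergent
inbred lines, including a SNP desert. `simulate_f2()` generates gametes
with crossovers as a Poisson process along the genetic map (Haldane,
no interference), adds symmetric genotyping errors and missingness,
and retains the pre-noise truth matrix.

Real data differ in ways the generator does not model: sequence
composition is not i.i.d. (isochores, methylation-driven site
depletion), fragment sampling is length- and GC-biased (only the
user-supplied weight vector covers this), there is no read-level error
model, no paralogy-driven false heterozygosity, and no segregation
distortion. Passing tests therefore demonstrate correctness of the
computations under the stated models, not calibration against any
particular sequencing platform.

## Problem sizes and numerical conventions in the test suite

The suite exercises: digestion equality with brute force on 200 random
sequences up to 5 kb; a site-count statistic on 10 Mb of uniform
sequence (expected (L−k+1)·4⁻⁶ EcoRI sites, asserted within 4 sd);
saturation exactness over 10,000 replicates; the filtering cascade
against brute-force reimplementations on 500 random toy matrices; and
linkage recovery on a simulated 12-chromosome × 20-marker, n = 96 cross
(~240 loci, ~28,700 pairwise estimates) with markers every 5 cM —
grouping must recover chromosome membership exactly, adjacent r̂ must
sit within 3 binomial standard errors of truth, total map length within
15% of the simulated 1,140 cM, and per-group Kendall τ above 0.95.
These sizes were chosen so each property is statistically sharp while
the full suite runs in minutes on a laptop.

Degenerate inputs are defined, not accidental: an empty genome digests
to nothing; a sequence without sites is one END–END fragment; zero
variants make `snp_density()` return an NA sentinel with a message
rather than dividing by zero; a read budget of zero detects nothing;
an empty grouping builds an empty 0 cM map; r ≥ 0.5 is a hard error in
`haldane_cm()` (infinite distance), and its inverse round-trips to
1e-9 over [0, 0.49].

## Known limitations

Methylation sensitivity of enzymes (a major cause of divergence between
in silico and empirical fragment yields in plants), partial digestion
and star activity are not modelled. The detectability of a SNP says
nothing about its callability from noisy reads — quality filtering is
only represented by its depth component. The greedy ordering can
misplace markers in weak-signal groups where multipoint methods would
not. `pairwise_linkage()` materializes all locus pairs and is meant for
the post-collapse marker counts typical of ddRAD maps (hundreds of
loci), not for tens of thousands.
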