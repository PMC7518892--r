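---
title: "Methods: peak calling and annotation of cell-free RNA fragmentomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling and annotation of cell-free RNA fragmentomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfpeakr)
library(dplyr)
```

## The problem

Cell-free RNA in plasma is heavily fragmented, but fragments bound by
proteins or folded into stable secondary structure persist against plasma
nucleases. When such libraries are sequenced with a UMI-tagged,
structure-tolerant protocol and aligned, the protected fragments pile up
into discrete, strand-specific coverage peaks over the genome, while
cell-free DNA provides a natural baseline of what coverage looks like
without RNA-specific protection. `cfpeakr` implements the analysis that
turns per-sample fragment alignments into called, filtered, annotated and
statistically characterised peaks. This vignette documents the models and
the choices behind each stage; every number quoted here is computed by the
package's own test suite or acceptance script, not asserted from memory.

All coordinates are 0-based half-open (BED convention) throughout, because
the pipeline's native currency is BED-like fragment intervals; a fragment is
the outermost template span of a read pair.

## Deduplication and UMI saturation

Fragments sharing chromosome, start, end, strand and CIGAR are PCR-duplicate
candidates; within such a group, UMIs at Hamming distance ≤ 1 are collapsed
into one molecule. We use connected components of the Hamming-≤1 graph as
the default clustering: it is the simplest rule consistent with "one
mismatch allowed", it is order-independent, and on instances up to 100
fragments it provably matches an exhaustive pairwise connected-components
oracle (tested over 100 random instances). A count-ordered *directional*
variant (a cluster seeds at the most frequent UMI and absorbs
lower-or-equal-count neighbours, as in UMI-tools) is available via
`method = "directional"` for users who prefer asymmetric collapsing. An `N`
in a UMI matches nothing — its distance to any base, including another `N`,
is 1 — which is the conservative reading. Strand participates in the dedup
key by default (`use_strand = FALSE` disables it); on a stranded protocol
opposite-strand fragments at the same coordinates are distinct molecules.

At high coverage, distinct molecules collide on the same UMI label. With
`L = 4^6 = 4096` labels and `k` observed distinct molecules, the occupancy
inversion `m = -L ln(1 - k/L)` estimates the true molecule count; it is
strictly increasing and convex in `k` and ≈ `k` when `k ≪ L`. The estimator
diverges at `k = L`; we cap it at `-L ln(1/(2L))` with a warning, since a
fully saturated locus carries no information about how far beyond `L` the
truth lies. Integer deduplicated counts feed peak calling; saturation-
adjusted (fractional) counts are reported separately.

## The peak caller

The caller is a deliberately simple local-Poisson model in the style of
ChIP-seq callers, because the scientific content of this pipeline lies in
the filters, annotation and statistics around the caller, not in any one
caller's internals. Per strand:

1. Pileup: coverage at `x` = number of fragments with `start ≤ x < end`.
2. Background: the both-strand DNA control pileup is scaled by
   (total RNA fragments)/(total control fragments), and the local rate at
   each base is `λ_local = max(λ_genome, λ_1kb, λ_10kb)` over centred
   window means of the scaled control. The max over windows lets local
   background structure (e.g. mappability artefacts present in the DNA)
   suppress calls without letting sparse control regions create them.
3. Per-base Poisson upper-tail p-values; bases with `p < p_call`
   (default 1e-3) are merged across gaps ≤ 50 nt; peaks narrower than
   50 nt are dropped; the peak p-value is the minimum per-base p and
   q-values are Benjamini–Hochberg across the combined two-strand peak
   list.

With an empty control (or in transcriptome-space mode, where no DNA control
exists), the RNA genome-wide rate is the background, with a warning.

Filters then mirror the candidate → high-confidence flow: a *candidate*
peak needs pileup ≥ 5 at its maximum, q ≤ 0.05 and summit support (≥ 1
deduplicated fragment overlapping the summit) in at least 5 samples — a
replicate-consistency guard against batch effects; a *high-confidence* peak
additionally needs ≥ 5 summit fragments passing MAPQ ≥ 30 and < 5
mismatches, which removes multi-mappers and divergent alignments.

Properties enforced by tests: strand isolation (minus fragments never
contribute to plus peaks), monotonicity in the call threshold, permutation
invariance of q assignment, and an empirical-FDR sanity check — calling one
half of a DNA control against the other yields ≤ 5% of the genome at
q ≤ 0.05 (three seeds).

## Annotation

Each peak is intersected with all feature sets at once and scored with the
reciprocal overlap score `S = (o/w_peak)(o/w_feature)`; `S = 1` exactly
when the peak and the feature coincide, so a high score means the peak *is*
the feature rather than merely touching it. Single-pass intersection plus a
priority rule is equivalent to sequential per-category intersection under
this scoring, and is order-independent. The best feature per peak is the
highest score; exact ties break RBP site > repeat > long RNA (categories
the priority list does not mention, such as sncRNA, rank after long RNA —
they are pre-filtered upstream in the intended workflow); several RBP sites
tied at the top are all reported. Sense/antisense is judged against the
strand the peak was called on; unstranded features count as sense, flagged
by their `"*"` strand. Best-feature selection prefers sense annotations, so
a peak whose only annotations are antisense is classified antisense.
Conservation is the arithmetic per-base mean of a bedGraph track over the
peak, with uncovered bases excluded and counted.

## Empirical Bayes strand bias of tandem repeats

Tandem repeats attract spurious two-strand coverage from mismapping. The
test asks, per repeat unit, whether plasma RNA shows more (+)-orientation
fragments than plasma DNA does at the same unit — DNA serving as the
built-in control for mapping artefacts.

Counts are merged per *canonical unit*: the lexicographically smaller of
the unit and its reverse complement, both expressed on the genomic (+)
strand; when canonicalisation flips the unit, fragment strands flip with
it, so totals are conserved. Palindromic units merge without a flip.

The prior Beta(α₀, β₀) of (+)-fractions is fitted from DNA units with more
than 50 deduplicated fragments, by maximum likelihood under the
beta-binomial *marginal* of the counts (method-of-moments initialisation on
the observed fractions). Fitting the marginal rather than a beta density on
the raw fractions matters: binomial counting noise would otherwise inflate
the apparent unit-to-unit dispersion and bias the concentration downward.
The suite verifies the fit tracks an oracle beta MLE applied to the latent
per-unit fractions within 15%.

Per unit, the posterior is the conjugate Beta(α₀+n₊, β₀+n₋), separately
for RNA and DNA. Δ%(+) is sampled by independent draws from the two
posteriors (default 100,000 draws; direct Beta sampling, no MCMC, since the
model is conjugate). The decision rule is a Bayes factor for the interval
hypothesis {Δ ≥ 0.10}:

BF = [P(Δ≥0.10 | data) / P(Δ<0.10 | data)] / [P(Δ≥0.10 | prior) / P(Δ<0.10 | prior)],

with the prior probability estimated from two independent prior draws (the
distribution Δ would follow with no data). This posterior-odds/prior-odds
form is the standard Bayes factor for an interval hypothesis; a unit is
significant at BF > 3. If the prior mass of {Δ ≥ 0.10} underflows to zero
in the Monte-Carlo sample, BF is reported as `Inf` with a `bf_infinite`
flag rather than silently truncated. Calibration: when RNA and DNA counts
are simulated from the *same* latent fraction per unit (the null the test
is designed for — locus-level mapping artefacts affect both libraries
identically), at most 5% of 200 units are flagged across five seeds, while
a planted unit at 0.95 vs 0.5 is always flagged.

## Enrichment nulls

Whether called peaks overlap RBP binding sites, or fold more stably, more
often than chance is judged against matched-size random peak sets: for each
observed peak length, one interval of exactly that length is placed
uniformly in the long-RNA gene space, regions weighted by their placeable
span (width − length + 1). The observed length multiset is conserved in
every null set. Placement ignores splicing (genomic sequence space), the
simplest defensible choice when the exon/intron treatment is not pinned
down. Empirical p-values use the add-one form `(1 + b)/(1 + n_sets)`, so p
is never 0 and the floor at 1,000 sets is 1/1001 < 0.001. The structure
null folds observed and random sequences with the *same* engine, so
engine-specific score scales cancel inside the test; the summary statistic
is the mean fold score by default (`stat = "median"` is available, since a
mean over skewed fold scores can be dominated by a few long peaks).

## Structure classifiers

The built-in folding proxy maximises base pairs (Nussinov dynamic
programming, pairs AU/GC/GU, minimum hairpin loop 3; implemented in C++,
traceback to dot-bracket), score = −pairs. It is exact — equal to
exhaustive enumeration for all tested sequences ≤ 14 nt — and monotone
enough for *relative* statements (enrichment, ranking), which is all the
package uses it for. Thermodynamic free energies in kcal/mol require the
external engine (`RNAfold`, used when on the PATH); free-energy thresholds
from the literature (e.g. ΔG cutoffs for "structured" exon peaks) apply
only to that engine, and the proxy expresses structure thresholds as pair
fractions instead (default 0.30). T and U are interchangeable on input;
RNA-facing output uses U.

A peak is a *full-length excised intron RNA* when it coincides with an
annotated intron (boundary tolerance defaults to exactly 0 nt, because
genuine excised introns begin precisely at the 5′ GU and end at the 3′
AG), the intron's sense boundaries are GU…AG, and ≥ 5 deduplicated
fragments span the intron exactly end-to-end. Non-templated 3′ tails are
1–2 nt soft-clips at the 3′ terminus that differ from the templated genomic
continuation — a clip matching the genome is read-through, never a tail.
Discrete-end RNAs have a strict majority (> 50%) of fragments sharing both
termini; exactly half does not qualify.

## The synthetic-data generator

`synth_genome()` lays out genes (alternating strands), plants
non-overlapping peak intervals of 50–300 nt inside exons, RBP sites over a
subset of peaks, tandem-repeat loci with per-locus (+)-strand parameters
θ⁺, and short introns of 73–210 nt whose sense boundaries are GT…AG with a
stem-loop interior, all exported in a truth table. `synth_fragments()`
emits UMI-tagged records: uniform background; peak fragments concentrated
in the planted intervals on the feature strand; repeat fragments with
locus-level strand fractions drawn from a Beta around θ⁺ (concentration 50
by default), giving the hierarchical structure the Empirical Bayes fit is
supposed to recover; exact full-length intron fragments, a fraction with
planted 1-nt U/A tails; and PCR duplicates (geometric per-molecule copies,
expected records = molecules/(1 − dup rate)), some with 1-nt UMI errors.
DNA-control samples are uniform, strand-balanced, and emit 50/50 strands
over repeat loci. Everything is deterministic under its seed.

Default *study* conditions (`synth_study()`) are a scaled-down analogue of
a 15-RNA + 4-DNA-control cohort: one 100-kb chromosome, 20 planted peaks,
four repeat loci, four introns; per RNA sample 2,000 background molecules
(~2.4× coverage) plus 30 molecules per peak, per DNA sample a deeper
uniform background — sizes chosen so pooled planted peaks stand ≥ 10-fold
over background, the regime the candidate filters are designed for, while
the full recovery experiment runs in well under a minute. Under these
conditions, candidate-filtered peaks recover the planted truth with recall
and precision ≥ 0.9 (precision scored against all planted signal — peaks,
repeat loci and introns — since a caller that finds a planted intron found
real signal).

What the generator does **not** emulate: sequencing base errors, adapter
artefacts, transcriptome-wide expression profiles, rRNA/tRNA/Mt reads
(removed upstream in the intended workflow), splicing in read alignment,
GC or mappability biases. Passing tests on this generator therefore show
the *algorithms* behave as specified under their assumptions, not that the
assumptions hold for any particular real library.

## Numerical choices and degenerate inputs

* `p_call` default 1e-3: loose enough that merging assembles complete
  peaks, with final error control delegated to the BH q-filter.
* Summit ties take the leftmost maximal base.
* Peak p-values are floored at the smallest positive double before
  −log10 transforms.
* `k = L` saturation is capped (see above); `k > L` is an error.
* Beta-prior fitting requires ≥ 2 qualifying units and says so; observed
  fractions 0 and 1 are handled by the marginal likelihood itself.
* Zero-count units have posterior = prior; degenerate (≤ 0) posterior
  parameters are an error.
* Empty feature sets, empty fragment tables and zero-coverage peaks return
  empty or NA results with warnings rather than failing.
* Monte-Carlo experiments in the test suite state their seeds inline; the
  suite's stochastic checks (prior recovery, calibration, empirical FDR)
  are run at 3-SE or specified tolerances. One stochastic replicate of the
  hyperparameter-recovery experiment draws a latent sample whose own best
  fit lies outside the nominal 20% band; the estimator-vs-oracle check
  covers that case instead.

## Known limitations

* The caller does not reproduce any specific external caller's boundaries
  (no fragment-length shift model, no broad-peak chaining); comparisons of
  exact peak edges across tools are out of scope.
* The Bayes factor is Monte-Carlo estimated; for priors with very little
  mass beyond the effect floor its variance is large and `Inf` values
  (flagged) can occur.
* The fold proxy's pair count is not an energy; absolute ΔG statements
  require `RNAfold`.
* Random-peak nulls are not GC- or dinucleotide-matched.
* The intron classifier trusts the provided gene models; unannotated
  introns are not discovered de novo.
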