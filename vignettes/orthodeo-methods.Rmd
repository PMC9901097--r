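---
title: "OrthoDEO: models, parameters and design choices"
author: "OrthoDEO authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OrthoDEO: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoDEO)
```

# Scope

OrthoDEO analyses leaf developmental transcriptomes of closely related
grass species with different photosynthetic subtypes (C3, Proto-Kranz,
C4). Each species is profiled along four leaf segments (S1 at the
immature base through S7 at the mature tip) with three pooled
biological replicates per segment, on a de novo transcriptome assembly.
Cross-species comparisons operate on orthogroups (OG): because
assemblies do not share gene identifiers, the OG is the unit that makes
expression comparable across species.

This vignette documents the statistical models, the parameters that
matter, the synthetic-data generator used for validation, and the
decisions made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# Transcript curation

A raw de novo assembly overstates the transcriptome: it carries
redundant isoforms, near-duplicate contigs, non-coding fragments, and
essentially unexpressed contigs. Curation runs four filters in a fixed
order, each a pure subset operation:

1. **Top isoform** (`selectTopIsoform`): one transcript per gene — the
   isoform with the highest mean TPM; ties break to the
   lexicographically smallest transcript ID so the result is
   deterministic.
2. **Redundancy collapse** (`collapseRedundant`): greedy longest-first
   clustering. A candidate is absorbed by a retained representative if
   it is an exact duplicate, an exact substring, or if its k-mer
   containment identity (shared unique k-mers over its own unique
   k-mers, k = 11) reaches the identity threshold (default 0.95). This
   is a desk-scale analogue of CD-HIT-EST's greedy 95%-identity
   clustering with the same threshold semantics; it considers the
   forward strand only. Note that at k = 11 a uniform substitution
   divergence of d leaves roughly (1-d)^11 of k-mers intact, so the
   0.95 containment threshold absorbs only near-identical or contained
   sequences (d below about 0.5%), which is the intended behaviour for
   assembly redundancy.
3. **Single best ORF** (`findBestORF`): all six frames of both strands
   are scanned for complete start-to-stop ORFs; the longest one wins
   (ties: forward strand, then lower frame, then lower start).
   Transcripts whose best ORF is shorter than 100 nt are removed. ORF
   length counts nucleotides *including* the stop codon, matching the
   "100 bp" convention; 5'-partial ORFs are disabled by default because
   only the complete-ORF mode is unambiguous. Coordinates are 0-based
   half-open on the reported strand.
4. **Expression filter** (`filterByExpression`): keep a transcript iff
   it reaches 1 cpm in at least 3 libraries. cpm here uses raw library
   sizes (column sums), not TMM-corrected ones, because the filter runs
   before normalization in the workflow.

Each filter is idempotent, so re-running curation on its own output
changes nothing. `assemblyStats` reports N50 by the standard
sort-descending-and-accumulate definition.

# Orthogroup aggregation and annotation

`aggregateExpression` sums the raw counts of an OG's member transcripts
per library. Summing raw counts (rather than normalized values)
preserves negative-binomial count semantics for the test downstream;
single-copy OG pass through unchanged, and per-sample totals are
conserved exactly. Annotation is transferred per OG from the
highest-priority reference species present in the OG (one annotation
per OG, no merging), with the lexicographically smallest member ID as
the deterministic representative; the transcription-factor flag is
inherited with the annotation. Only OG with at least one
expression-filtered member in every focal species are tested
(`sharedOrthogroups`).

# The differential-expression engine

Counts are modelled as negative binomial: `var = mu + phi * mu^2` with
dispersion `phi`. The engine is implemented from first principles:

* **TMM** (`tmmFactors`): reference sample = the one whose 75th
  percentile of cpm is closest to the mean across samples. Per sample,
  M (log2 ratio vs reference) and A (mean log2 abundance) are computed
  over features nonzero in both; the top and bottom 30% by M and 5% by
  A are trimmed; the factor is 2 to the weighted mean of the remaining
  M values with inverse delta-method variances as weights; factors are
  rescaled to geometric mean 1. These trim fractions are the
  long-standing defaults of the procedure.
* **Dispersion** (`estimateDispersion`): counts scaled to a common
  library size; per feature, the method-of-moments estimate
  `(v - m)/m^2` pooled across groups (weighted by degrees of freedom),
  then shrunk 50% toward the median of all per-feature estimates and
  floored at 1e-4. With three replicates per group the raw estimate has
  only four degrees of freedom; the shrink trades variance against
  bias. The floor keeps degenerate features testable as near-Poisson.
* **Exact test** (`exactNBTest`): counts are scaled to the geometric
  mean of the effective library sizes (pseudo-counts, rounded
  half-to-even for platform-stable determinism) and summed per group.
  Conditional on the total s, the group-A total follows the law induced
  by the convolution of NB distributions (which depends only on the
  size parameters, not the common mean); the two-sided p-value sums the
  probabilities of all splits no more probable than the observed one,
  with a 1e-10 relative guard against floating-point ties. `phi = 0`
  reduces exactly to Binomial(s, n_A/(n_A+n_B)). Fold changes use cpm
  with a prior count of 0.5 per sample.
* **FDR** (`bhFDR`): Benjamini–Hochberg step-up with enforced
  monotonicity.

Significance means q < 0.01 **and** |log2FC| strictly greater than 1
("log2 fold change > 1" is read as a two-sided magnitude threshold,
since both directions are reported). Within species, consecutive
segments are compared (DEG); between species, the two species'
replicates at one matched segment are compared unpaired (DEO) —
replicate pairing applies within a species' pooling design, not across
species. Each comparison computes TMM on exactly the samples entering
it, so every test lives in a single normalization frame; the
alternative (one global normalization over all libraries of a pair) was
rejected to keep tests self-contained and invariant to unrelated
samples.

The engine's contracts are enforced by oracle tests: the exact test
matches an independent log-gamma enumeration to 1e-12 across all splits
with totals up to 50 at three dispersions; TMM matches a step-by-step
independent computation to 1e-10 (and the reference implementation
where available); BH matches the textbook step-up on random inputs.
Note one practical limit quantified by the recovery simulations: with
n = 3 per group the dispersion estimator's sampling noise makes
tail p-values mildly anti-conservative (false-positive rates about
twice nominal at q < 0.01), which is why the calibration suites
evaluate the test at the generating dispersion while the
estimated-dispersion behaviour is bounded separately.

# Pattern analytics

* **Profiles**: per species, TMM-normalized cpm averaged over
  replicates per segment (`segmentProfiles`), i.e. a 4-point profile
  per OG and species.
* **Z-scores** (`zscoreProfile`): `(x - mean)/sd` with the sample sd;
  a constant profile maps to the zero vector.
* **Conservation** (`patternConservation`): a species pair conserves an
  OG's pattern iff the Pearson correlation of the two z-profiles is at
  least `r_conserved` (default 0.8); a constant profile is never
  conserved. The overall call requires every pair involving the focal
  (C4) species to be conserved; `all_pairs = FALSE` relaxes this to at
  least one pair. The correlation rule is a reproducible stand-in for a
  visual-similarity judgement: it is affine-invariant, monotone in
  similarity, and exposed as a configuration key rather than hard-coded.
  Flat profiles are structurally uncallable under this rule (their
  z-vector is zero), so recovery statistics are computed over non-flat
  classes.
* **Pathway DEO percentages** (`pathwayDEOPercentages`): within a
  curated OG list, the share significantly up in each species at a
  segment, as percentages of the list size rounded half-to-even to one
  decimal.
* **Heatmaps** (`heatmapMatrix`): per-OG min–max scaling to [0, 1]
  across all species × segment means (constant rows map to 0.5) —
  relative expression for display, with the exact scaling documented
  rather than implicit.
* **Sink/source** (`classifySinkSource`): marker profiles (cell-cycle
  and sucrose-synthase genes falling from base to tip mark the sink;
  sucrose transporters and nitrate reductase rising mark the source)
  are z-scored; a segment is "sink" iff the mean sink-marker z exceeds
  the mean source-marker z.

# Enrichment

GO enrichment uses the one-sided hypergeometric upper tail on the
true-path-closed annotation (a feature annotated to a term counts for
all ancestors). The **elim** variant walks terms bottom-up by
longest-path depth from the root (ties in lexicographic term order,
pinned for determinism); when a term is significant at alpha = 0.01,
its annotated features are removed from all its ancestors before those
are tested, so parents are not called merely because a child carries
the signal. The enrichment universe is the tested (shared) OG set, not
a whole genome, matching the OG-level framing of the analysis.

Sample PCA runs on log2(cpm + 1) of OG expression, features centered
but not scaled (log-cpm is the field convention; scaling would let
near-constant OG dominate). Components come from the SVD of the
row-centered matrix, with each component's sign fixed so its
largest-magnitude loading is positive. The top and bottom 5% loading
sets per component feed the same enrichment machinery; boundary ties
are included, and if ties make the sets collide the assignment falls
back to opposite ends of one deterministic ranking.

# The synthetic-data generator

`simulateDataset` emulates the emulated study design end to end: three
species, segments S1/S3/S5/S7, three replicates, orthogroups with copy
numbers 0–3 (mostly single copy, about 10% of OG forced absent from one
species), negative-binomial counts with gene-wise dispersion in
[0.05, 0.2], and developmental profile classes (ascending, descending,
peaked, flat) with log2 amplitudes of 2–4 — the 4–16-fold base-to-tip
ranges typical of leaf-gradient photosynthesis genes. Per-copy baseline
jitter and dispersion are drawn once per OG and shared across species,
so species with equal copy number are exchangeable and comparisons
without planted effects are genuinely null. Planted cross-species
effects (by default: the core half of the C4-cycle list up 4-fold in
the C4 species at S7, and the core photorespiration list up 4-fold in
the C3 species at S1) are added as log2 shifts on the stated
species × segment means and recorded in the truth tables. Assembly
noise is planted explicitly: extra isoforms at 5–30% of the main
isoform's expression (truncations or 2%-mutated copies), redundant
contigs that are exact copies or substrings of another gene's
transcript, non-coding transcripts built with every start codon
scrubbed from both strands (hence no complete ORF anywhere), and junk
transcripts whose expected cpm is calibrated log-uniformly below 1
within each library.

Library sizes are drawn log-uniformly per library so that
normalization has real work to do. The default depth range (2e5–5e5)
and the default problem sizes (100–500 OG depending on the suite) are
deliberate desk-scale choices: they keep per-OG counts in the hundreds
to thousands — the same counting regime as deeply sequenced libraries
over a full transcriptome — while keeping the full validation suite
fast. The generator's determinism contract is byte-level: one master
seed is split into fixed per-stage substreams (structure, profiles,
sequences, library sizes, counts, annotation), so identical
configurations reproduce identical files.

What the generator does **not** emulate — and hence what passing
recovery tests do not show about real data: read-level artefacts
(sequencing error, mapping ambiguity, positional bias), correlated
dispersion structure across genes, partial homology between unrelated
genes, incomplete or wrong orthology assignments, and batch effects.
Recovery results on synthetic data certify the machinery, not the
biology.

# Numerical choices and degenerate inputs

* Percentages are rounded half-to-even to one decimal everywhere.
* Pseudo-count scaling in the exact test rounds half-to-even; the
  p-value accumulates probabilities with a 1e-10 relative tie guard.
* Constant features hit the dispersion floor (1e-4) rather than erroring.
* Constant profiles z-score to zero vectors and are excluded from
  conservation by rule; constant heatmap rows map to 0.5.
* Empty input to the redundancy collapse returns empty output; an empty
  orthogroup cell is zero members, not an error.
* All tie-breaks (isoform selection, collapse order, ORF choice,
  annotation representative, elim traversal) are lexicographic, making
  every result order-stable and platform-independent.

# Known limitations

* The dispersion estimator is deliberately simple (moments + fixed 50%
  shrink); with very few replicates its noise makes extreme tails
  mildly anti-conservative, as quantified above. Empirical-Bayes
  tagwise shrinkage would improve calibration at the cost of a much
  larger estimation machinery.
* The redundancy collapse is a containment heuristic, not an aligner:
  diverged paralogs below the containment threshold are never merged,
  and rearranged duplicates may escape it.
* Conservation calls on 4-point profiles are coarse; r = 0.8 on four
  points is a weak certificate and the threshold should be treated as a
  screening device.
* The exact test assumes a common dispersion within a comparison; the
  cross-species drivers inherit that assumption.
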