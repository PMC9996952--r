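---
title: "Blocking-oligo design and depletion evaluation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocking-oligo design and depletion evaluation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoblock)
```

## The problem

A handful of RNA species can consume most of a sequencing library: a
30-33 nt YRNA (RNY4) fragment dominates plasma small-RNA libraries, and
oligo-dT primers mispriming on internal adenosine-rich stretches pull
mitochondrial rRNA or MALAT1 fragments into 3' end libraries. A
high-affinity antisense oligonucleotide — typically LNA-modified —
bound to the template immediately downstream of the priming site stops
reverse transcriptase (and later the PCR polymerase), keeping the
fragment out of the library without any extra protocol step.

`oligoblock` implements the computational side of this strategy: target
site discovery, candidate design and screening, a depletion-benefit
simulator, and the depletion/complexity metrics used to evaluate the
result. A seeded synthetic-data module generates every input class with
ground-truth manifests, so everything is testable offline.

## Priming-site detection

"Adenosine-rich" is given a precise meaning: a qualifying window is any
stretch of length at least `min_run` (default 8 nt) with an A fraction
of at least `min_a_fraction` (default 0.8). Reported sites are the
connected components of the union coverage of all qualifying windows,
trimmed to `A` at both ends. Two deliberate consequences:

* a *degenerate* run such as `AAAAGAAAAAAA` is one site, matching how
  oligo-dT actually misprimes;
* when overlapping qualifying windows bridge through a non-A patch, the
  merged component can fall below the A threshold; such a component is
  *shrunk to its longest contained qualifying window* (leftmost on
  ties) rather than dropped or reported with an out-of-contract A
  fraction — a genuine A-run flanked by semi-A-rich sequence is never
  lost.

The defaults were chosen so that documented internal priming stretches
of mitochondrial rRNA and canonical internal-priming motifs (8+ A)
qualify; both are exposed in the configuration. Terminal poly(A) tails
are excluded positionally (`tail_exclusion`, default 30 nt) rather than
via annotation, because the method must never target the genuine 3'
tail present on all mRNAs.

The test-suite oracle re-derives sites by enumerating every window of
every length — O(L^3) but unarguable — and the finder must agree
exactly.

## The design window

Reverse transcriptase travels 5' along the sense transcript from the
oligo-dT primer, so the blocker must sit *between* the primer and the
fragment body: the window is the `width` (default 50) sense-strand
bases immediately 5' of the A-run, `[max(0, start - width), start)`,
and never overlaps the run. Candidates 3' of the priming site are not
considered; reports record this restriction. For short fragments
(YRNA mode) the whole fragment is the window and the 3' end is the
anchor, because reverse transcription of a ligated small-RNA library
starts there.

## Candidate scoring and selection

Candidates are every antisense k-mer tiled across the window (a 32-nt
window yields 17 16-mers). Screening is substitution-only (Hamming)
against the sense strand of the whole transcriptome, exhaustive by
construction (a compiled full scan — no seeding heuristic that could
miss a hit), with the intended site excluded. Indels are not
considered: the mismatch convention follows the short-read alignment
tools used to define the off-target rule, and the selection retains
candidates with *zero* hits at up to 3 mismatches, falling back to the
minimal-hit set only when nothing is clean (the mitochondrial-rRNA
situation, where the transcriptome contains near-duplicates).

Melting temperature uses the two-state nearest-neighbor model: the
unified DNA/DNA parameter set (SantaLucia 1998) plus per-position LNA
perturbation increments (McTigue et al. 2004), duplex-initiation terms,
the oligo-concentration term (CT/4) and the entropic monovalent-salt
correction; divalent cations fold into an effective monovalent
concentration (von Ahsen). Default conditions — 0.25 uM oligo (the
blocker's working concentration in the RT mix), 50 mM monovalent, no
divalent — are printed in every report. Parameter tables ship as
versioned TSVs with citations under `inst/extdata/thermo/`.

Two honest limitations:

* The LNA increments describe *isolated* substitutions. Stacking
  cooperativity between consecutive LNA residues is not modeled, so
  absolute Tm values of fully substituted oligos are under-estimates
  (the package predicts 68.6 C for the fully modified 16-mer
  `ACCCACTACCATCGGA`, where vendor tools report ~90 C). Selection is
  unaffected: it depends only on the Tm *ranking* of same-length,
  same-chemistry candidates from one window, which the perturbation
  model preserves. The acceptance suite carries the absolute-value band
  check anyway and it is expected to fail; we prefer a red check over
  shipping invented "parameters" that cannot be traced to a
  publication.
* 2'-O-methyl and 2'-MOE chemistries are representable patterns (so
  reports can record chemistry comparisons) but have no shipped
  thermodynamic tables; `melting_temperature()` refuses them and
  `tm_estimate()` provides a clearly flagged heuristic (DNA-backbone Tm
  + 0.7 C per OME, + 1.0 C per MOE position).

Ties in selection break by fewer off-targets, then proximity to the
priming-site/3' anchor, then leftmost position, making the result
invariant under permutation of the candidate list.

## The depletion simulator

The simulator asks: if a transcript initially consumes a fraction
`f0` of a library and blocking removes a fraction `d` of its
molecules, how many genes are detected at a given sequencing depth?
Two conventions matter:

* **Reallocation.** Depleted target reads are *replaced* by background
  reads at fixed total depth: the target's effective share becomes
  `f0 (1-d) / (1 - f0 d)` and each background gene receives
  `(1 - eff) * fraction`. Libraries are sequenced to a chosen depth
  regardless of composition, and a gain in detected genes with
  efficiency is only possible because freed depth flows to the
  background.
* **Sampling model.** Draws are multinomial from the fraction vector
  rather than hypergeometric from one finite table, because the grid
  varies `f0` continuously (0-90%), which no single fixed table can
  realize. (Exact without-replacement subsampling of real tables is
  available separately as `subsample_counts()`.)

Defaults mirror the published simulation design: depths 0.5/1/2/4/8
million, `f0` 0 to 0.9 by 0.1, `d` 0 to 1 by 0.02, detection at
**>= 10 counts** (the Methods wording "10 counts or larger" is used
where the figure caption says "higher than 10"; the threshold is
configurable). Each (depth, f0, replicate) cell derives its own RNG
sub-stream that is shared across efficiencies: curves along `d` use
common random numbers (smoother, and at `f0 = 0` provably identical),
and replicates expose the Monte-Carlo error as a per-cell sd
(`n_reps` default 10; the original analysis reported single curves).

One subtlety of the detected-gene statistic: it includes the target, so
at high efficiency the curve can dip by about one gene when the target
itself falls below the detection threshold, even though *background*
detection is strictly non-decreasing in efficiency and depth. The
property tests therefore assert monotonicity on background detection.

## Metrics

CPM is plain counts-per-million; subsampling is exact multivariate
hypergeometric (sequential conditional `rhyper`), so full-depth
subsampling is the identity and column totals are exact. Fold reduction
is the ratio of mean control to mean treated CPM with a +0.5-count
continuity correction (flagged) when a side is zero. Detection is
>= 10 counts for genes and CPM strictly > 0.5 for miRNA-scale
features.

The DE engine is deliberately simple and pluggable: a Welch t-test on
log2 CPM with a 0.5-count offset and Benjamini-Hochberg adjustment,
behind an interface that accepts a voom-style fit. Re-implementing
voom's mean-variance weighting is out of scope; the bespoke
contribution here is the *concordance resampling procedure*: subsample
all libraries to a depth, call DE, repeat, and summarize the overlap of
significant sets. The published description ("number of overlapping DE
miRNAs between subsamples", reported as a percentage) does not pin down
a denominator, so the headline number is the mean pairwise Jaccard
percentage and the raw per-pair overlap counts are returned for any
alternative definition. Two identical sets — including two empty sets —
score 100.

Off-target flagging follows the standardized-residual rule: per matched
replicate pair, fit a least-squares line of treated on control log2
CPM, standardize residuals by their standard deviation, and flag genes
beyond the threshold (default 2) *in the same direction in every pair*.
The fit is restricted to detected features (>= 10 counts in all
libraries): undetected features carry counting noise many times the
global residual sd, which would make a global-sd threshold meaningless.
Even so, the rule's specificity is intrinsically limited under pure
counting noise, because per-gene variances span orders of magnitude
while the denominator is a single global sd — occasional low-count
false flags are expected and observed (about one gene in twenty null
data sets at the default generator settings). This is a property of the
published rule, which we implement as stated rather than silently
robustify.

## The synthetic-data module

Generators are pure functions of (parameters, seed) and each returns a
truth manifest sufficient for regeneration and round-trip testing.

* `synth_transcriptome()` plants pure-A runs and decoy near-matches
  (exact substitution counts) into uniform-random background. Two
  guarantees keep the truth unambiguous: backgrounds are *scrubbed* of
  spontaneous qualifying A-rich windows (uniform-random sequence
  contains them surprisingly often), and each planted run is isolated
  by 5-nt C spacers so that the recovered site equals the planted
  interval exactly.
* `synth_count_table()` draws a log-normal background (sigma 1.5, a
  long-tailed transcriptome abundance profile) with one gene pinned to
  a stated fraction of reads (default 0.2, the order of the published
  whole-blood hemoglobin case).
* `synth_depletion_pair()` emulates matched standard/blocking library
  pairs. Defaults are the plasma small-RNA world in which the
  standardized-residual rule was applied: 13 million reads, 600
  miRNA-scale features, the blocked fragment at 29.74% of reads
  (platelet-free plasma), 4 matched pairs (2 samples x 2 technical
  replicates). Replicates are multinomial (technical counting noise
  only); real library preparations are over-dispersed, so a green
  round-trip here establishes correctness of the computation, not
  realism of plasma noise.
* `synth_two_group_counts()` plants symmetric log2 fold changes with a
  greedy mass-balancing direction assignment. Without balancing, the
  renormalization of the perturbed group shifts every null gene by a
  common compositional factor — with multinomial precision at millions
  of reads that turns exact nulls into real differences and destroys
  FDR calibration. Balancing keeps non-DE genes exact nulls, which is
  what a calibration test must assume.

## What a green test establishes (and what not)

The synthetic world is multinomial: no over-dispersion, no ligation or
capture bias, no mapping ambiguity, no batch structure. Green tests
therefore establish algorithmic correctness (oracle equivalence,
conservation laws, closed-form calibration, planted-truth recovery) and
the stated statistical properties under counting noise. They do not
establish that real plasma or 3' end libraries meet the same numbers;
the published fold reductions and concordance percentages are tied to
controlled-access data and are deliberately not asserted.

## Numerical and degenerate-input choices

0-based half-open coordinates everywhere, with 1-based twins in
human-facing reports. `N` is allowed in transcriptomes and counts as a
mismatch against every base (off-targets are never under-counted);
candidates may not contain `N`. Zero-variance genes in the t-test get
p = 1 (no evidence) unless the means differ exactly (p = 0, only
possible with zero noise). Identical libraries produce a zero residual
sd in the flagging fit; the standardized residuals are then defined as
0 (no outliers). Sub-seeds derived from the master seed stay below
2^31. The CLI accepts JSON configuration files merged under explicit
flags (flags win); YAML is not supported in this build.
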