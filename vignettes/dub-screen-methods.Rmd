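---
title: "Models and methods behind dubscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dubscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dubscreen implements the computational core of a pooled in vivo shRNA
dropout/enrichment screen in hematopoietic stem and progenitor cells
(HSPCs), together with an AP-MS interactome filtering scheme. This
vignette is the package's own account of the models it implements, the
parameters that matter, and the choices made where the design was open.

## The screen and its generative model

A pooled screen transduces lineage-negative bone-marrow cells with a
lentiviral shRNA library at low multiplicity of infection (each cell
carries one hairpin), transplants them into irradiated recipient mice, and
sequences the hairpin census before injection (the T0 input) and in
tissues harvested after an in vivo growth window. A hairpin that drops out
relative to T0 implicates its target gene in supporting cell fitness; an
enriched hairpin implicates a restrictive gene.

`simulate_screen()` emulates this design as a chain of explicit sampling
steps, each with its own knob:

1. **Plasmid pool** - per-hairpin proportions are lognormal in log2 with
   sd `plasmid_abundance_sd` (default 0.5 log2 units), reflecting uneven
   pooling of individually picked clones.
2. **Transduction (T0)** - a multinomial draw of `n_cells_transduced`
   cells (default 1e6) from the plasmid proportions.
3. **Engraftment bottleneck** - per mouse, a multinomial draw of
   `n_cells_transduced * engraftment_fraction` cells (default 0.1, i.e.
   1e5 cells, roughly 200 cells per hairpin for a 508-hairpin pool) from
   the T0 cell proportions. This is the step that produces per-mouse
   stochastic drift; `engraftment_fraction = 1` is the exact
   no-bottleneck limit (the whole T0 population engrafts).
4. **Selection** - each hairpin's proportion is multiplied by
   `2^(fitness x efficacy x weeks)` and renormalized. Fitness is a
   per-gene log2 change per week (negative = dropout); efficacy in [0, 1]
   scales the gene effect per hairpin, modeling heterogeneous knockdown
   potency. The default window is 4 weeks.
5. **Sequencing** - `reads_per_sample` reads (default 2e6) are drawn
   multinomially from the proportions perturbed by per-hairpin lognormal
   PCR amplification factors with sigma `pcr_overdispersion` (default
   0.25, the standard natural-log lognormal parameterization).

The two-level stochasticity (cell-level bottleneck plus read-level
multinomial with a lognormal PCR factor) was chosen over a single
negative-binomial draw because it separates the biological drift knob
(engraftment) from the technical one (PCR), and reproduces the
characteristic per-mouse gain/loss of hairpins after in vivo growth.
Spleen samples, when enabled, are an independent second bottleneck from
the same T0, supporting bone-marrow-vs-spleen concordance QC.

All randomness flows from one integer seed through named substreams
(`substream_seed()`), so any sample can be regenerated independently and
whole runs are byte-reproducible.

What the generator does **not** model: sequencing error beyond an optional
uniform substitution rate in `write_fastq()`, PCR chimeras, index
hopping, cell-cycle or niche effects, and clonal interference. Passing
tests on synthetic data therefore demonstrate the correctness of the
pipeline's accounting and statistics under a plausible noise model, not
the biological fidelity of any particular screen.

## Deconvolution

Reads are assigned by exact substring matching of each hairpin's 21-nt
target key (and its reverse complement) against the read; a read counts
for a hairpin iff exactly one hairpin's key occurs. Ambiguous and
unmatched reads are kept in an explicit `unassigned` tally so that
assigned + unassigned always equals the reads processed. Exact matching
is the conservative, auditable default for short fixed keys; reads
shorter than the key are counted as unassigned rather than dropped
silently. Collisions (two hairpins sharing a key on either strand) are
rejected when the index is built.

## Differential abundance

Counts are normalized to log2 counts-per-million with a fixed pseudocount
of 0.5: `log2((count + 0.5) / (library + 1) * 1e6)`. The fixed
pseudocount keeps the transform zero-tolerant; its cost is that scaling a
sample's counts changes values by at most ~`0.5/(count * ln 2)`, which is
negligible at sequencing depth but not exactly zero.

Replicate outliers are screened in principal-component space: samples are
projected onto the first two PCs of the centered matrix and flagged when
their distance from the group's componentwise median exceeds 3 MADs above
the median distance (a robust z-score on distances). The rule is
deterministic and invariant to sample order; with fewer than three test
samples no outlier screening is attempted.

The test statistic is an empirical-Bayes moderated t: per hairpin, the
two-group residual variance (d_g degrees of freedom) is shrunk toward a
prior (d0, s0^2) estimated by closed-form moment matching of log sample
variances to the scaled-F model via digamma/trigamma inversion, and the
fold change is referred to a t distribution with d0 + d_g df. The moment
method (rather than iterative ML) is deterministic and matches the
standard behavior of the published moderated-t framework; the suite
verifies agreement with an independent implementation to 1e-8. BH
adjustment is applied within each screen x tissue comparison.

One property of the screen's layout deserves note: the design has a
single T0 reference sample, which carries sequencing and PCR noise but no
engraftment drift, while every bone-marrow sample carries both. The
pooled equal-variance model therefore charges slightly too much variance
for the reference, and neutral-screen t statistics are mildly deflated
(standard deviation around 0.96 rather than 1). Per comparison this is
within Kolmogorov-Smirnov tolerance of uniformity; it is a feature of
one-reference designs, not of the moderation, and disappears if the
reference is replicated.

## Gene-level hit calling

Hits are called in two tiers, both thresholds exposed in
`hit_rule_config()`:

- **Per hairpin** (statistical gate): |log2 FC| >= 1, BH-adjusted
  p <= 0.02, and average log2-CPM abundance > 2.5.
- **Per gene and screen** (magnitude gate): at least 2 hairpins that pass
  the statistical gate and individually show a >= 10-fold median change
  across replicate mice, in the same direction. The two gates are applied
  conjunctively per hairpin - the only reading that uses both criteria.
- **Across screens**: a consolidated hit requires the same per-screen
  verdict in >= 2 independent screens. A gene with qualifying hairpins in
  both directions in any screen is excluded outright; exclusion requires
  both directions to pass the full bar, so noise-level discordance does
  not disqualify a gene.

Per-mouse fold changes are pseudocounted CPM ratios against T0, and the
median is taken across mice (not a fold change of medians): with few
animals the median over replicates is the more robust reading, and both
alternatives remain selectable through the per-hairpin fold-change matrix.

A power boundary worth knowing: because the T0 reference is a single
sample, its per-hairpin measurement error shifts all mice jointly and
does not average out across replicates. At the default PCR overdispersion
this noise has sd ~0.36 log2, so a gene whose true depletion is exactly
16-fold sits only ~1.9 sd from the 10-fold-median gate and will
frequently miss it in one of two screens. Recovery studies in the test
suite therefore plant dropout magnitudes spanning 20-60-fold - the regime
of the strong, reproducible dropouts this design is built to find -
and the 16-fold edge should be treated as near the design's detection
floor rather than comfortably inside it.

## AP-MS interactome filtering

The proteomics module consumes a log2 LFQ intensity matrix (missing
values explicit) with bait-IP and IgG-control samples per condition and
applies, per condition:

1. **Abundance filters** - at least 2 peptides per protein and at least 3
   valid (non-missing) values among the bait replicates.
2. **Gaussian-downshift imputation** - missing values are drawn column
   wise from `Normal(mu - 1.8 sd, (0.2 sd)^2)` of the column's observed
   values. This models missing-not-at-random dropout of low-abundance
   proteins: an unquantified protein is treated as sitting below the
   detection limit. Imputation is applied to all columns of the condition
   after filtering (the column-wise reading); restricting it to bait
   columns is available by imputing a subsetted matrix.
3. **Moderated enrichment vs IgG** - the same moderated t and BH
   machinery as the screen, with two explicit significance tiers: 10% FDR
   for "significantly enriched" per condition, and a stricter
   per-condition adj. p < 0.05 used for the cross-condition consensus.
4. **Consensus and novelty** - consensus interactors pass the 0.05 bar in
   every required condition (cell line x treatment); a user-supplied
   known-interactor list flags novel candidates. No live database queries
   are made.

The synthetic AP-MS generator plants true interactors whose unbound (IgG)
abundance sits just below the probit detection limit and whose bait
abundance is 3 log2 above it - the textbook MNAR-in-IgG situation the
downshift imputation is designed for. Background proteins bind both IPs
equally. Planted proteins near or above the detection limit on the bait
side are exactly the cases the filter-and-impute scheme cannot rescue,
and the generator's defaults deliberately keep the planted truth out of
that gray zone so that recall measures the pipeline, not the gray zone.

## Numerical choices and degenerate inputs

- Variances of exactly zero are floored at `1e-5 x median(s^2)` before
  log-moment estimation, and a prior df estimate of infinity falls back
  to the pooled mean variance.
- `prior_df = 0` disables moderation and reproduces the ordinary pooled
  two-sample t exactly; `prior_df = Inf` fixes the posterior variance at
  the pooled mean.
- The trigamma inversion is Newton iteration with the standard
  asymptotic endpoints (1/y above 1e7, 1/sqrt(y) below 1e-6).
- Empty libraries, duplicate hairpin ids or target sequences, all-zero
  samples, unknown sample ids, fewer than 3 samples for PCA, fewer than
  2 observed values per imputation column, and missing required
  conditions all fail fast with named errors.

## Problem sizes used by the test suite

Property tests run the full 508-hairpin library at the design scale
(1e6 cells, 2e6 reads, 5 mice) where the property concerns the screen's
stated operating point (representation, calibration, recovery), and a
10-hairpin toy library at reduced depth where the property is structural
(conservation, determinism, monotonicity). Calibration and recovery
checks use 25 seeded replicate runs; the imputation moment check uses
10,000 imputed values.
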