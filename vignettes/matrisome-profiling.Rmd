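---
title: "Quantitative matrisome profiling from isobaric-label proteomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative matrisome profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriquant)
```

## The problem

The extracellular matrix (ECM) of a tissue — its *matrisome* — remodels
extensively during tumor progression, and in particular around the
angiogenic switch, the point at which a lesion acquires a vascular supply.
`matriquant` implements a complete analysis pipeline for quantifying that
remodeling with iTRAQ 4-plex isobaric labeling: ECM-enriched samples from a
normal reference tissue and three staged tumor time points (T6, T9, T12 —
hyperplastic, angiogenic, and frank tumor in a staged insulinoma model) are
labeled with the 117, 116, 115 and 114 reporter tags respectively, mixed,
and analyzed together by LC-MS/MS. Each peptide-spectrum match (PSM) then
carries four reporter-ion intensities whose ratios quantify the relative
abundance of the parent protein across the four samples. The experiment is
performed in two biological replicates (A and B).

The pipeline covers everything downstream of the database search: PSM
quality filtering, protein-level ratio rollup, channel normalization,
differential testing across time points, matrisome annotation, definition of
the normal-tissue matrisome, and relative-abundance ranking. A synthetic PSM
generator with planted ground truth stands in for raw mass-spectrometry
data, so every stage is testable end to end.

## PSM filtering and protein rollup

Three exclusion rules remove PSMs that cannot support quantitation:

* **no iTRAQ label** — unlabeled peptides carry no reporter signal;
* **negative delta forward–reverse score** — the identification scores
  better against the reversed decoy database than the forward one, i.e. it
  is an estimated false positive;
* **precursor-isolation purity < 50%** — more than half the isolation-window
  intensity comes from co-eluting peptides, so the reporter ions are
  dominated by co-isolated background.

Boundary values (purity exactly 50%, delta exactly 0) are kept; only strict
violations are excluded. `filter_psms()` attaches an attrition table so the
per-rule losses are auditable.

For each protein and replicate, each surviving PSM contributes per-channel
ratios `reporter / reference` (reference channel 117), and the protein-level
ratio per time point is the **median** of its PSM ratios, reported as log2.
The median is robust to the long-tailed interference artifacts typical of
reporter-ion data. For an even number of PSMs the midpoint of the two
central ratios is taken *on the natural scale* and then logged; this matches
the usual midpoint-median convention, at the cost that the identity
`log2(median(r)) = median(log2(r))` is exact only for odd counts (for even
counts it is bracketed by the two central log-ratios).

PSMs with zero reference-channel intensity have undefined ratios; they are
dropped with a warning rather than imputed, and a protein whose every PSM is
undefined is absent from the quant table.

## Matrisome-median normalization

The four co-labeled samples differ both in total protein amount and in the
degree of ECM enrichment achieved by decellularization. Normalizing each
channel by the median log2 ratio of the *matrisome proteins only* removes
both effects under the assumption that the bulk of the matrisome is not
changing. Concretely, for each replicate and each time-point channel the
offset is the median log2 ratio over proteins annotated core-matrisome or
matrisome-associated, and that offset is subtracted from every protein in
the channel, matrisome or not. After normalization the matrisome median is
zero (to floating-point rounding) in every channel by construction —
non-matrisome contaminants may sit far from zero, which is informative
rather than an error.

## The moderated F-test

Statistical testing asks, per protein, whether the normalized log2 ratio is
non-zero in *any* time-point group; an F-shaped alternative deliberately
captures non-monotone trends (up at the angiogenic switch, down in tumors,
etc.). With two replicates per group, protein-wise variance estimates have
only `d = 3` residual degrees of freedom, so the test moderates them with an
empirical-Bayes prior estimated from all proteins.

Let `y_gjr` be the normalized log2 ratio of protein `g` in group
`j ∈ {T6, T9, T12}` and replicate `r`. With group means `m_gj` and residual
variance `s²_g = Σ_jr (y_gjr − m_gj)² / d`:

* the prior is a scaled inverse-chi-squared with parameters `(d0, s0²)`,
  estimated by moment-matching the log-variances: with
  `e_g = log s²_g − digamma(d/2) + log(d/2)`, solve
  `trigamma(d0/2) = var(e) − mean(trigamma(d/2))` for `d0` by monotone
  root-finding and set `s0² = exp(mean(e) + digamma(d0/2) − log(d0/2))`.
  When the empirical spread of log-variances does not exceed its sampling
  expectation the equation has no positive solution; the prior then
  degenerates to `d0 = ∞` with `s0² = exp(mean(e))` and every protein is
  shrunk completely to the common variance;
* the posterior variance is the convex blend
  `s̃²_g = (d0·s0² + d·s²_g) / (d0 + d)`, which always lies between `s²_g`
  and `s0²`;
* the statistic `F_g = (Σ_j n_j m_gj² / k) / s̃²_g` (with `k = 3` groups,
  `n_j = 2`) tests H0: all three group means are zero, referred to an
  `F(k, d0 + d)` distribution — `χ²_k / k` in the `d0 = ∞` limit, and the
  classical single-protein F-test in the `d0 = 0` limit.

The null hypothesis is on the three tumor/reference ratios only: the
reference/reference ratio is identically zero and carries no replicate
information, so the reference group contributes no degrees of freedom.

Nominal `p < 0.05` is the primary decision threshold — appropriate when the
tested family is on the order of a hundred proteins — with Benjamini–
Hochberg adjusted values reported alongside (`bh_fdr()`, the classic
step-up rule). Significant proteins are called `higher` or `lower` by the
sign of the average of the three group means; the measure-zero case of an
exactly zero average is flagged `ambiguous` rather than silently assigned.

**Calibration.** Treating the estimated `(d0, s0²)` as known makes the test
slightly conservative when only ~120 proteins (3 df each) inform the prior:
in the package's own global-null simulations (2,000 datasets of 120
proteins, Gaussian noise, the configuration run by `scripts/acceptance.R`)
the empirical type-I rate at nominal 0.05 is ≈ 0.044. The same behavior, to
a similar degree, is observed with the reference implementation of
moderated statistics used as a cross-check in the test suite; it fades as
the number of proteins grows. Power on planted effects is unaffected in
practice (see the recovery results below).

## Heatmap column clustering

For presentation, the per-time-point mean normalized log2 ratios of the
significant proteins are clustered **by column** with complete linkage on
Minkowski distance, exponent 2. Leaf order is made deterministic by placing,
at every merge, the subtree containing the smaller column index on the left.
Row clustering is intentionally out of scope.

## Normal-tissue matrisome and abundance ranking

A protein belongs to the normal-tissue matrisome when it is detected in both
replicates (no peptide threshold: agreement between independent biological
replicates is the evidence), or in a single replicate with at least two
unique peptides (multiple independent sequence identifications substitute
for cross-replicate agreement).

Relative abundance in the normal tissue is the **precursor-ion-weighted
average normalized 117-reporter intensity**: within each replicate, every
PSM's 117 intensity is divided by the median 117 intensity over all PSMs of
that replicate, then averaged per protein with precursor intensities as
weights — intense precursors give better reporter statistics and also track
protein amount. Where a "normalized" reporter intensity admits several
readings, we chose division by the replicate-wide median: it is the minimal
location normalization that makes replicates comparable, and the resulting
ranks are invariant to the scale constant, which is the property the ranking
actually needs. Replicate values are averaged with equal weight, and exact
ties are broken lexicographically by gene symbol so output is deterministic.
A protein whose PSMs all have zero precursor intensity falls back to the
unweighted mean, with a warning.

## Matrisome annotation

The bundled reference maps canonical mouse gene symbols to a division
(core matrisome / matrisome-associated) and category (ECM glycoproteins,
collagens, proteoglycans for the core; ECM-affiliated, ECM regulators,
secreted factors for the associated division). Matching is case-insensitive
with whitespace stripped; no alias or ortholog resolution is attempted,
since inputs are mouse symbols from a single search pipeline. Distinct
protein entries (isoforms) sharing a gene symbol are counted separately in
composition summaries, keyed by protein identifier. Symbols absent from the
reference are annotated non-matrisome, so contaminants never silently enter
matrisome-median normalization or the tested set. The package also ships a
120-entry fixture of ECM protein entries quantified in both replicates of
the insulinoma-progression experiment this pipeline models, used by the
composition acceptance checks.

## The synthetic-data generator

`simulate_experiment()` emulates the statistical structure of the modeled
study, not its spectra. Per protein: a log10 abundance drawn from
N(6, 0.5); a PSM count of `1 + Poisson(psm_rate × relative abundance)`
(default rate 5, so abundant proteins are sampled more often, as in data-
dependent acquisition); and per PSM an observed reporter vector

```
observed = depth × [ (1 − α) × truth × noise  +  α × background ]
```

where `truth` is the baseline abundance scaled by `2^effect` in the tumor
channels, `noise` is mean-one log-normal per channel (CV 0.2 by default),
`background` is flat across channels at the baseline level (co-isolated
peptides drawn from the unchanged bulk), and the mixing fraction α is
uniform on [0.2, 0.3]. This convex-mixing model produces the 20–30% ratio
compression characteristic of co-isolation interference — a planted 2-fold
change at α = 0.25 is observed at `(0.75·2 + 0.25)/(0.75·1 + 0.25) = 1.75`
— and ties isolation purity causally to accuracy via
`purity = 100(1 − α)`, so the purity filter does real work when the α range
is widened. Small fractions of PSMs are unlabeled (2%, near-zero reporters)
or carry a negative delta score (1%, structureless reporters), exercising
the exclusion rules.

Default effect profiles follow the modeled design: 35 of 120 matrisome
proteins carry planted effects, 9 increasing (0, +1, +1.5 log2 across
T6/T9/T12) and 26 decreasing (0, −1, −1.5); 30 contaminant proteins carry a
monotonically decreasing trend (−0.5, −1, −1.5), emulating exocrine
carry-over that falls as tumors become easier to dissect cleanly. Planted
magnitudes of ≥ 1 log2 unit in at least one group against reporter-level
noise of CV 0.2 (protein-level ratio noise ≈ 0.25 sd) represent the clearly
remodeled proteins such a study is designed to detect. Everything is
reproducible from a single integer seed, and the generator restores the
caller's RNG state.

`simulate_ratio_matrix()` bypasses the PSM layer and draws protein-level
normalized ratios directly (effect + Gaussian noise, default sd 0.25); it is
the right tool for statistical calibration and recovery studies, where PSM
detail is irrelevant.

What the generator does **not** emulate: spectrum-level detail (m/z peaks,
fragmentation, retention time), in-silico digestion of real sequences,
shared/razor peptide ambiguity, isotope-impurity cross-talk between adjacent
reporter channels, and biological between-replicate variation beyond
measurement noise (both replicates share the same true effects). Passing
tests on synthetic data therefore validate the pipeline's statistical
machinery and bookkeeping, not the upstream identification chain.

## Problem sizes and numerical choices

The test suite and acceptance script use: 2,000 Monte-Carlo datasets of 120
proteins for null calibration; 20 seeded experiments for planted-effect
recovery (observed: 100% sensitivity, empirical FDR ≈ 0.10 at nominal
p < 0.05); 10,000 proteins for prior parameter recovery (d0 recovered
within 2%, s0² within 2% at truth d0 = 4, s0² = 0.05). The trigamma
inversion brackets its root in [1e−8, 1e8] and solves on the log scale to
tolerance 1e−12. Degenerate inputs are errors, not guesses: all-zero
variances, a replicate with no matrisome proteins, p-values outside (0, 1].

## Limitations

* Protein inference is assumed resolved upstream; proteins are keyed by the
  search engine's protein identifier.
* The matrisome reference bundled here covers the gene symbols needed for
  the shipped fixtures and simulations; for new tissues, supply a fuller
  reference CSV via `matrisome_reference(path)`.
* The moderated F-test assumes homoscedastic Gaussian noise on log2 ratios
  within each protein; gross violations (e.g. one outlier replicate) are
  not down-weighted.
* With two replicates there is no protection against a single aberrant
  replicate driving a call; the complete-case gate is strict by design.
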