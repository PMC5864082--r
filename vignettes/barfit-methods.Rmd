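---
title: "Models and methods behind barfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barfit)
```

This vignette explains the statistical models, the simulator, the numerical
choices and the limitations of the package, in the spirit of how count-model
packages document their internals. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The experiment being modelled

A pooled collection of heterozygous deletion strains, each carrying two
unique molecular barcodes (UPTAG and DOWNTAG) at the deletion locus, is
grown competitively: an initial pool (P) goes through ~24 h of batch growth
(B), is switched to continuous (chemostat) culture, and is sampled at early,
mid and late steady state (ESS, MSS, LSS — 0, 20 and 30 steady-state
generations). Barcodes are PCR-amplified and sequenced; the count of a
strain's barcodes in a sample estimates its relative abundance. A strain
whose deletion halves the dose of an important ncRNA falls behind
(haplo-insufficient, HI); one that benefits from reduced dosage pulls ahead
(haplo-proficient, HP). Two biological repeats per condition and two TAGs
per strain give four independent barcode measurements per strain.

## The simulator

The generator is first-class, tested code, because every downstream claim
is validated against its ground truth.

**Pool dynamics.** Per generation, abundances update by replicator
dynamics: `f_i <- f_i 2^(1+s_i) / sum_j f_j 2^(1+s_j)`, where `s_i` is the
per-generation log2 growth-rate offset (0 for null strains, ±`effect_size`
otherwise). The shared factor 2 cancels, so over `g` generations the log2
abundance ratio of two strains moves by exactly `g (s_1 - s_2)` — the
analytic anchor used by the recovery tests (`g·s = 6 × 0.2 = 1.2` for the
standard pool→batch setting).

**Stage layout.** `g_batch = 6` generations pool→batch (24 h of batch
growth at roughly four-hour doublings), `g_settle = 7` generations
batch→ESS (the ~42–48 h the culture takes to settle into steady state at
chemostat dilution rates, i.e. ~7 h doublings), then MSS at 20 and LSS at
`g_ss = 30` steady-state generations after ESS. Only the batch count is
printed as hours in the underlying protocol; the generation equivalents
are package defaults, configurable in `sim_config()`.

**Biological repeats.** Each repeat applies jitter `s' = s + N(0, 0.02)`
per strain, so repeats are genuinely non-identical and the dispersion
estimator has something to estimate. The magnitude is a package default
chosen to represent mild between-culture variation; it is the dominant
source of overdispersion at the simulated depths.

**Reads.** Each sample draws `depth` reads per TAG run multinomially over
abundances. A read is `flank5 + TAG + flank3`, the flanks being the 3'
ends of the amplification primers (the 3' flank reverse-complemented), with
independent per-base substitution errors (no indels — the matcher is
Hamming-based) and constant `I` qualities. The 6-mer sample index travels
in the FASTQ header (`index=XXXXXX`), mimicking demultiplex-ready data, and
read ids encode the true strain. `simulate_counts()` is the error-free
shortcut that draws the same per-sample multinomials without materialising
FASTQ; the equality of counted reads and the recorded draw at
`error_rate = 0` is itself a test.

**What the simulator does not emulate.** PCR amplification bias, GC
effects, index hopping, indels, quality degradation along the read,
chemostat wall growth and take-over events, and frequency-dependent
selection. Passing tests therefore demonstrate correctness of the
algorithms under a clean generative model, not robustness to every
real-data artefact.

## Barcode identification

A read yields a TAG if the 5' flank occurs exactly once and enough bases
follow; the TAG is identified if it matches the full length of a catalog
TAG with at most one mismatch. Distance-0 matches are unique by
construction (the catalog enforces global TAG uniqueness); a single
distance-1 match is a hit with one mismatch; two or more candidates at the
minimum distance ≤ 1 are ambiguous and discarded (tallied, not counted) —
the underlying aligner-based procedure does not specify tie handling, and
discarding is the conservative choice. Index matching is exact-only: a
1-mismatch index rescue would risk cross-sample bleed for no measurable
gain at 6-mer distances. Quality scores are ignored; the identification
rule does not use them.

The matcher hashes exact hits and resolves the remainder by Hamming
distance computed as one-hot inner products over unique observed tags,
chunked to bound memory. Its contract is exact agreement with an
exhaustive scan; the test suite and the acceptance script verify this
against an independent oracle built on `Biostrings::vcountPattern`.

## The fitness test

The count model is the standard negative binomial with variance
`μ + α μ²`, normalised by median-of-ratios size factors (the arithmetic
median of per-strain ratios; with an odd strain count this equals the
log-median convention of the reference implementation exactly).

Dispersion is estimated per strain by method of moments on normalised
counts, pooling within-group variances across the two contrasted groups,
with a least-squares trend `α_tr(μ) = a0 + a1/μ` fit over strains with
positive raw estimates; the final `α_i = max(α̂_i, α_tr(μ_i))`. The max
rule guards against variance underestimation at two replicates per group,
at a price: because the raw estimate carries roughly χ²-distributed noise
at these degrees of freedom, taking the maximum biases the final
dispersion upward, and the Wald test below is therefore mildly
conservative (the test suite's null-calibration check measures a p < 0.05
fraction of ~0.02–0.04 rather than the nominal 0.05; feeding the true
dispersion into the same statistic restores ~0.05). This behaviour is
shared with the classic count-model tools that use a "maximum" sharing
mode, and is accepted here as the documented cost of never underestimating
variance.

The statistic is a Wald test on
`log2FC = log2((mean_B + c)/(mean_A + c))`, pseudocount `c = 0.5`
(stabilising fold changes at zero counts; strains with all-zero counts in
both groups report `log2FC = 0, p = 1`). The delta-method variance of each
group mean is `(1/n²) Σ_j (μ/sf_j + α μ²)`. Calls require `p < 0.05` and
`|log2FC| ≥ log2(1.5)`; the raw p is used for calling (as in the source
analysis) with BH-adjusted values always reported alongside. The stricter
`|log2FC| ≥ 1.5` variant used in intersection (UpSet-style) tabulations is
exposed as `theta = 1.5` in `classify_calls()`. Both thresholds are
configurable.

Replication enters at the biological-repeat level only: the two TAGs of a
strain are summed into one count per sample (matching the stated counting
rule), so each group has two replicate libraries. Repeats are pooled as
group replicates rather than paired; the source analysis does not state a
pairing, and with two repeats a paired test would leave no residual
degrees of freedom.

## Co-fitness analysis

Profiles are the strain × 8 matrix of log2 fold changes over
{B>P, L>E} × {C-lim, N-lim} × {30 °C, 36 °C}, in fixed canonical column
order; the LiCl conditions are excluded by default (they probe RNA
stability rather than the phase/nutrient/temperature design) but can be
included, making 12 columns.

Selection fits, per strain, a gaussian linear model of the eight values on
binary-coded phase, nutrient and temperature. Coefficient p-values use the
t distribution on the residual degrees of freedom (4), as a gaussian GLM
reports them; with a pure normal approximation at 4 df the intended
per-strain type-I rate of `1 − 0.95³ ≈ 0.14` for noise strains would
roughly double. A strain is retained if any non-intercept coefficient has
`p ≤ 0.05`.

Clustering is partitioning around medoids on Euclidean distances:
greedy BUILD initialisation, then exhaustive best-improvement SWAP until no
medoid/non-medoid exchange lowers the total cost, ties broken by lowest
index, making the procedure fully deterministic. The swap local search is
not guaranteed globally optimal for k ≥ 3 on unstructured inputs — in
every such case we have examined, the reference implementation
(`cluster::pam`) stops at the identical cost, and the test suite asserts
both that agreement and brute-force optimality at k = 2 on small point
sets. The cluster count is chosen by maximum mean silhouette over
k = 2..10 (ties to the smaller k), replacing an unexplained fixed choice
of four clusters in the source analysis; k can be pinned. Sub-clusters
split strains by the sign of their mean profile value, the "direction of
fitness change".

Enrichment of the SUT and CUT classes in each cluster uses the exact
binomial tail-doubling test against the class's background proportion
among all clustered strains, `p = min(1, 2 min(P(X≤x), P(X≥x)))` — when
the observed proportion equals the background exactly, both tails cover
the median and p = 1 — with BH adjustment across all cluster × class rows.
The BH step-up is implemented directly
(`q_(i) = min_{j≥i} min(1, p_(j) m/j)`) and cross-checked against
`p.adjust` in the tests.

## Colony screen

Plate normalisation divides each plate by its median colony size, then
applies one round of multiplicative row- and column-median polish. One
round removes a multiplicatively separable positional effect exactly
(a planted 1.5× row effect cancels to numerical precision, a tested
property); iterating further would also start absorbing genuine biology on
plates with correlated strain placement. Missing colonies propagate as
missing; replicate positions are averaged per strain before model fitting.

The two-component normal mixture is fit by standard EM, initialised by
splitting at the 10th percentile (the lower tail seeds the putative
reduced-fitness component). Convergence is declared when the
log-likelihood gain drops below `1e-8`; standard deviations are clamped at
`σ_floor = 1e-3` so degenerate inputs (for example, all values identical)
return a well-defined fit rather than a singularity; non-convergence at
`max_iter` is flagged, not thrown. The log-likelihood is non-decreasing
across iterations, asserted on every fixture.

Scoring uses the component whose mean is nearer the wild-type reference —
the mean of designated control positions when the plate layout has them,
else the global median of strain values. P-values are two-sided,
`2(1 − Φ(|v − μ_wt|/σ_wt))`, because both unusually large and unusually
small colonies are biologically meaningful; a one-sided option exists.
Significance is strict `p < 0.05`.

Monoculture growth curves are summarised by the trapezoidal area under the
OD–time curve. The original spline-based fitting is deliberately replaced
by this simpler, assumption-free rule; at the 5-minute sampling intervals
of plate readers the quadrature error is far below biological variation
(a tested 0.5% bound against fine-grid integration on logistic curves).

## Pipeline and reproducibility

`run_pipeline()` executes catalog/sheet generation, read simulation,
counting, contrasts and the colony screen from one config. All randomness
flows from a single master seed through named substreams (one per
stage/sample), so stages are individually reproducible and a rerun is
byte-identical — artifact files are written with fixed `\n` endings and a
header naming the config hash. Read accounting
(`reads = hits + ambiguous + unmatched + no_tag` per sample) is audited
from the written artifacts, not in-memory state.

Default problem sizes in the tests and the acceptance script — 1000
strains at 10⁶–2×10⁶ reads per sample for the statistical calibration and
recovery checks, 100–200 strains at 5×10³–5×10⁴ reads for end-to-end runs,
1500 colonies for the screen — are chosen so each property is measured
with comfortable statistical resolution while the whole suite stays quick
on a laptop.

## Known limitations

- Fold-change "scale invariance" under per-sample count scaling is exact
  for the statistic only up to the pseudocount and the re-estimated
  moments; the tests bound the discrepancy rather than asserting identity.
- The conservative dispersion max rule (above) lowers null rejection below
  nominal at two replicates; with more replicates the effect shrinks.
- No shrinkage of fold changes, outlier refitting or independent
  filtering: none are part of the analysis being reproduced.
- The catalog enforces global TAG uniqueness, so a read can never match
  both an UPTAG and a DOWNTAG exactly; foreign catalogs violating this
  must be de-duplicated first.
- No genome-coordinate annotation, GO analysis or website export; the
  scope ends at the statistical calls and cluster/enrichment tables.
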