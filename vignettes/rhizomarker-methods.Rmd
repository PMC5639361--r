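---
title: "Methods: from aligned ion features to annotated rhizosphere markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from aligned ion features to annotated rhizosphere markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizomarker)
```

`rhizomarker` turns aligned untargeted LC-MS feature tables from a
plant-vs-control soil design into an annotated, class-level profile of
rhizosphere-enriched chemistry, and provides the companion microbiome
and root-damage statistics such an experiment needs. This vignette
explains the statistical model behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the numerical decisions taken where the design was genuinely open.

## The data model

The central object is the `feature_table`: ions (features) described by
`feature_id`, `mz` (Da), `rt` (seconds) and ionization `mode`, with one
intensity column per sample and a sample design (`soil_type` in
{control, plant}, extraction `solution` in {0, 50, 95} % MeOH,
`replicate`). Intensities are arbitrary non-negative units as produced
by peak integration; missing cells mean "not detected or not
integrated" and are stored as missing, never as zero, because the
presence/absence accounting (`presence_overlap()`) and the imputation
rule treat the two differently. Each (solution × mode) dataset is a
separate alignment namespace: feature ids do not correspond across
datasets, which drives how pooling and the ANOVA refinement are
defined below.

## Preprocessing

The chain is impute → median-normalize → cube-root → Pareto, applied
exactly once (each stage records itself on the table and refuses to
run twice; re-scaling an already scaled matrix is a classic silent
error).

* **Half-minimum imputation.** Each missing cell becomes half the
  minimum observed positive intensity of its feature — the common
  metabolomics default when no censoring model is available. The
  package deliberately makes no intensity-dependent missingness
  assumption (see the generator section). Features missing everywhere
  are dropped with a warning.
* **Median normalization.** Every sample is scaled by
  reference/median(sample), the reference being the median of all
  sample medians, so all sample medians coincide afterwards. Medians
  are computed over all features including imputed cells, for
  determinism. A zero-median sample is an error naming the sample.
* **Cube root and Pareto.** The multivariate branch additionally
  applies x → x^(1/3) and per-feature (x − mean)/sqrt(sd) with the
  n−1 standard deviation. Pareto scaling leaves each feature with
  variance equal to its original standard deviation — a compromise
  between unit-variance scaling (which over-weights noise features)
  and no scaling (which lets the most intense ions dominate).
  Constant features map to zero rows.

The volcano statistics intentionally run on the **imputed,
median-normalized but untransformed** intensities: a fold change is an
intensity-ratio quantity, and after cube-root/Pareto it has no
physical meaning. The multivariate models consume the fully processed
matrix.

## Multivariate overview

PCA is the SVD of the column-centered samples × features matrix
(`stats::prcomp`), with a fixed sign convention (the largest-magnitude
loading of each component is positive) so scores are comparable across
runs. Explained percentages are taken over total variance, so the full
component set sums to 100; with n samples ≤ p features only n − 1
components exist.

PLS-DA is NIPALS PLS1 against a centered 0/1 class indicator, two
components by default — with 8 samples per dataset a larger latent
space invites overfitting. R² = 1 − RSS/TSS measures fit;
Q² = 1 − PRESS/TSS measures predictability, with PRESS from
cross-validation in which **every fold refits from scratch, including
centering** (leave-one-out by default, suiting n = 8; a seeded k-fold
option exists). Q² ≤ R² on any fixture, Q² can be negative, and on
permuted labels its mean should not exceed zero — the package's tests
assert both tails (a separable fixture reaches Q² ≥ 0.9; permuted
nulls average below zero). Clustering uses d = 1 − Pearson r between
sample profiles with average linkage; zero-variance samples have no
defined correlation and are rejected by name.

## The marker funnel

Per ion, a two-sided Welch unequal-variance t-test compares plant and
control intensities; log₂FC uses arithmetic group means. Degenerate
ions (zero variance and equal means in both groups) get t = 0, p = 1
rather than NaN. Selection applies strict inequalities — *P* < 0.01
and fold change > 2 exactly as printed thresholds are usually meant.

Within each volcano plot, qualifying ions are ranked by ascending P,
ties broken by descending |log₂FC| then feature id; a fold-change-first
ranking (`rank_by = "fc"`) is provided because "ranked by fold change
and statistical significance" admits both readings. The top 20 per
plot (50 in the single-solution crop design) are pooled per direction;
six plots × 20 = 120 candidates, two plots × 50 = 100. If a plot has
fewer qualifying ions than k, all are taken with a warning — the pool
count is then data-dependent, which the report shows honestly.

Candidates are refined by a classical equal-variance one-way F-test
(a heteroscedastic Welch ANOVA is available behind `welch = TRUE`)
across the soil × solution groups **available in the candidate's own
dataset**. Because each (solution × mode) dataset is its own alignment
namespace, a candidate from a single-solution alignment is tested
across its two soil groups; if the caller supplies a shared-alignment
table spanning several solutions, the same function tests across all
six soil × solution groups. Benjamini–Hochberg correction is applied
within each direction's candidate pool (two pools of 120, matching how
two per-direction marker counts arise from two pools), with pool-wide
joint correction available; `kept` means q < 0.01.

One caveat the simulations make visible: with 5 plant vs 3 control
replicates, an ion enriched in the *control* direction concentrates
its variance in the n = 3 group, so the Welch degrees of freedom drop
toward 2 and the t needed for P < 0.01 (~9.9) exceeds the statistic's
plateau (~√3/CV). Detection power for control-enriched ions is
therefore structurally lower than for plant-enriched ions at the same
fold change — a property of the design, not of the implementation.
The package's power check targets the plant (rhizosphere) direction,
the method's primary use case. Half-minimum imputation under missing
data adds a second, smaller power cost: a missing cell in the
high-intensity group imputes to a low value and inflates that group's
variance.

## Deconvolution and annotation

Marker ions are grouped into compound families at the published
tolerances: m/z 0.1 Da, RT 10 s. Ions are first RT-binned by single
linkage; within a bin, every ion pair is linked if some ordered pair
of adduct rules gives implied neutral masses agreeing within the m/z
tolerance, or if the pair is separated by a multiple of the ¹³C
spacing (1.00336 Da). The default rules suit acidified (formic-acid)
electrospray: [M+H]⁺, [M+Na]⁺, [M+K]⁺, [M+NH₄]⁺ positive; [M−H]⁻,
[M+HCOO]⁻, [M+Cl]⁻ negative; singly charged only, as appropriate for
small soil metabolites. All rules are configurable.

Within a connected component, every (ion, rule) pair proposes a
neutral mass; the hypothesis with the greatest **coverage**
(adduct-explained ions plus their attachable isotopologues) wins, ties
broken by smaller mean |error| and then larger direct adduct support.
Its ions form a group, and any remaining component members are
re-resolved into further groups ("peeling"). Peeling matters because
at a 0.1 Da tolerance, coincidental rule-delta matches (e.g. the
NH₄–Na shift difference of 4.955 Da versus an unrelated 5.02 Da ion
spacing) occasionally chain two genuine compound families into one
component; resolving one hypothesis per component would then assign
one family the other's mass.

Two numerical choices deserve emphasis:

* **Isotope spacing tolerance.** Isotope links use their own tolerance
  (`iso_tol`, default `mz_tol/5` = 0.02 Da) rather than the full
  grouping tolerance. The spacing compares two *measured* masses, whose
  difference is far more precise than the absolute alignment
  tolerance; at ±0.1 Da, background ions sitting 1.0 ± 0.1 Da from a
  true adduct regularly pose as isotopologues and can flip the winning
  hypothesis.
* **Neutral mass as a median.** The inferred neutral mass is the
  median of the supporting implied masses. For a clean two-adduct
  family this equals the mean; when a background ion falls legitimately
  inside the 0.1 Da window and joins a group, the median keeps the
  compound's mass while a mean would drift by up to tol/members.

Annotation lists every library compound within the match tolerance
(default equal to `mz_tol`), sorted by |mass error|. Compounds flagged
implausible in soil — synthetic drugs, mammalian hormones — are
reported but marked excluded; a group whose matches are all
implausible is excluded entirely, and an unmatched group is class
"unknown". The class composition counts every member ion of a
non-excluded group toward the group's best plausible class (multiple
ions annotating to one metabolite count additively), with percentages
over counted ions. The bundled library computes its masses from
elemental formulas at load time (IUPAC monoisotopic masses, electron
mass included in adduct arithmetic), so no stored mass can silently
disagree with its formula.

## Microbial diversity

The OTU filter keeps taxa with counts strictly above 5 in at least
30 % of samples *and* a total strictly above 20 ("more than" read as
strict; an inclusive variant exists for sensitivity checks). Shannon
diversity uses natural log by default (log2 optional) via vegan;
rarefaction subsamples reads without replacement with seeded
replicates. Distances default to Bray–Curtis — a deliberate stand-in
for phylogenetic (UniFrac) distances, which need a tree; `permanova()`
accepts any externally computed distance matrix so UniFrac results can
be plugged in. The PERMANOVA is Anderson's one-way distance-based
pseudo-F with P = (1 + #{F\* ≥ F}) / (1 + n_perm) under seeded label
permutations; the implementation is cross-checked against
`vegan::adonis2` in the tests. One calibration subtlety: with 4
samples per group a two-group design has only 35 distinct label
splits, so the attainable type-I error at α = 0.05 is ~0.029 for
purely combinatorial reasons; the package's calibration check
therefore uses 6 per group, where the permutation null is effectively
continuous.

## Damage statistics

Electrolyte leakage is expressed relative to the conductivity of fully
lysed tissue (100 %). The omnibus test is Welch's heteroscedastic
ANOVA on jointly mid-ranked data — robust to both non-normality and
unequal variances, and invariant to monotone transforms. Groups with
zero rank variance get a 1e-12 variance floor (with a warning) so the
Welch weights stay finite. At n = 4 per group the rank-Welch
combination is noticeably liberal under strong heteroscedasticity
(the joint rank transform couples the groups and the Welch df
approximation degrades); calibration within [0.03, 0.07] holds from
about 6–8 replicates per group, which is where the package's
calibration test operates. Games–Howell post-hoc comparisons use
q = |Δmean|/√((s²ᵢ/nᵢ + s²ⱼ/nⱼ)/2) with Welch–Satterthwaite df against
the studentized-range distribution; tail probabilities are computed by
nested numerical integration (~1e-8 accuracy — the base-R
approximation is only ~1e-5 in places, which matters when validating
against an independent quadrature oracle at 1e-6). The compact letter
display uses the standard insert–absorb algorithm with alphabetical
letters in group-input order; a dedicated property test asserts that
letters reproduce the pairwise significance pattern exactly. CFU
comparisons are pooled-variance Student t-tests, on raw counts by
default with an optional log10 transform (zero counts are rejected
with a pseudo-count suggestion rather than silently dropped).

## The synthetic-data generator

Everything downstream is validated against generated data with known
ground truth, so the generator's assumptions bound what the tests can
show:

* Baseline feature mean intensities are log-normal (log10-mean 4,
  log10-sd 0.8), a typical untargeted dynamic range; replicate noise
  is multiplicative log-normal with CV 0.2 by default, inflated 1.5×
  at 95 % MeOH, which showed the largest replicate variability.
* Enriched ions (5 % per direction by default) multiply the mean of
  one soil type by 2^f, f uniform in [1.5, 4]; the lower bound exceeds
  1 so spiked ions can pass the >2-fold cut. The table scale defaults
  to 4,000 features per mode — a desk-scale stand-in for the tens of
  thousands in a real run, keeping the full test suite in minutes.
* Missingness is MCAR only. Real LC-MS missingness is largely
  intensity-dependent (left-censoring); the package takes no position
  on a censoring model, so passing tests say nothing about imputation
  behavior under censoring.
* Spiked compound families place one ion per adduct plus a ¹³C
  isotopologue at 10 % of the parent's intensity (plausible for
  ~10-carbon metabolites), share RT within ±2 s, and correlate
  intensities through a common sample factor. Families are placed at
  ≥40 s RT spacing and compound picks are filtered to be mutually
  collision-free under the deconvolution tolerances — homologous
  series (C16/C18 fatty acids, exactly 24.000 Da apart) are inherently
  ambiguous at 0.1 Da and would conflate any mass-only deconvolution.
  The generator also reports the residual spike/background collision
  rate.
* OTU tables are multinomial draws over Dirichlet-perturbed base
  proportions with a fold-change effect on a chosen OTU subset;
  leakage assays are gamma replicates with specified means and CV.

All generators are pure functions of (parameters, seed); a single
pipeline seed fans out deterministically per (solution, mode) so any
stage can be re-run in isolation.

## Problem sizes and runtime

The shipped tests and the acceptance script use: 10,000-ion null
tables over 20 seeds for volcano type-I error; 2,000-ion tables over
20 seeds for enrichment recovery; 600-ion tables with 4 spiked
compounds over 20 seeds for deconvolution; 500 null OTU tables with
999 permutations each for PERMANOVA calibration; 1,000 random fixtures
for the Welch/ANOVA/BH/rank-Welch oracle comparisons and 40 for the
studentized-range quadrature (each quadrature costs ~0.5 s). These
sizes were chosen so the whole suite runs in a few minutes on one core
while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* Identification is putative: mass-only matching at 0.1 Da cannot
  distinguish isomers (DIBOA vs. an isobaric phenolic, for instance);
  MS/MS evidence is out of scope.
* The deconvolution handles singly charged ions only, and its
  grouping is a greedy hypothesis resolution — pathological ion sets
  with several equally supported masses are resolved by mean error and
  logged, not enumerated.
* Fold-change estimates use arithmetic means on the intensity scale;
  with n = 3 in one group they are noisy, and control-direction power
  is structurally limited (see the funnel section).
* The PERMANOVA is one-way; stratified or multi-factor designs need a
  different tool (e.g. `vegan::adonis2` directly).
* Rank-Welch omnibus results at n = 4 per group should be read with
  the liberality caveat above in mind.
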