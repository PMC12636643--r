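---
title: "Methods: prognostic modeling of AD from CSF proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic modeling of AD from CSF proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`csfprog` implements an end-to-end prognostics workflow for tandem-mass-tag
(TMT) cerebrospinal-fluid proteomics in Alzheimer's disease: batch
harmonization of multi-plex intensity matrices, per-subject longitudinal
phenotyping, differential abundance and brain-module enrichment, predictive
protein-panel selection and evaluation, and event-based staging of
pre-symptomatic biomarker changes. Because the clinical source data
(ADNI-class cohorts) are access-restricted, the package ships a synthetic
cohort generator with complete ground truth; every statistical guarantee the
package claims is demonstrated on those synthetic cohorts, and the tests state
exactly what was simulated.

# The synthetic cohort generator

`sim_config()` fixes the study conditions; `simulate_study()` draws, from one
seed, (i) baseline metadata with round-robin TMT batch assignment and
converter/stable labels, (ii) a raw intensity matrix, (iii) longitudinal
outcome series, and (iv) staged biomarker data.

The intensity model on the log2 scale is

```
log2 A_ij = baseline_i + batch_{b(j)} + loading_j
          + lambda * f_{m(i), j} + effect_i * group_j + noise_ij
```

with per-batch offsets `batch ~ N(0, batch_log2_sd^2)`, per-sample loading
factors, a shared module-level latent factor `f` with loading `lambda = 0.5`
inducing within-module co-expression, planted signed group effects on a
`frac_differential` subset of proteins, and i.i.d. residual noise. The matrix
is exponentiated to raw intensities; cells below the
`missing_mnar_quantile` intensity quantile and a further `missing_mcar`
fraction of random cells are set to **zero**, matching the convention of raw
TMT exports in which zero encodes "not quantified".

Defaults (200 proteins x 300 subjects x 10 batches, batch sd 1.0 log2 units,
residual sd 0.5, 10% differential proteins at 1 log2 unit, visits at 0/12/25
months, slope sd 0.1 units/month, outcome noise sd 1, 30% converters,
post-event biomarker mean 2 z with sd 0.5) are the conditions under which the
acceptance-style tests are run. Conversion times are uniform on
[6, max follow-up] months: published cohorts report mean times to conversion
but not their distribution, so a flat distribution over follow-up is the
neutral choice. The per-subject baseline spread (`intercept_sd = 1`) is
deliberately moderate; note that a *smaller* intercept spread makes subject
slopes easier to recover (the random-intercept prior sharpens the slope
posterior), so this knob matters when comparing recovery numbers.

What the generator does **not** emulate: peptide-level structure,
reporter-ion interference, non-linear trajectories, informative dropout of
visits, and correlation between conversion status and missingness. Passing
tests on these cohorts therefore demonstrate correctness of the algorithms
under their stated models, not robustness to every pathology of real CSF data.

# Batch harmonization (median polish of ratios)

`tampor()` removes inter-batch technical variance in two stages. First, every
protein's intensities within a batch are divided by the median over that
batch's denominator samples (all batch samples by default; a designated
reference set — e.g. common pooled channels — in `designated_samples` mode).
Any per-batch multiplicative factor cancels *exactly* in this ratio, which is
the core guarantee: harmonization is invariant to batch-level scaling.
Second, the log2 ratio matrix is polished by alternately subtracting row
(protein) and column (sample) medians until the largest absolute median falls
below `tol = 1e-8` or `max_iter = 250` sweeps (values chosen well below any
biologically meaningful scale; the polish typically converges in well under
100 sweeps). Degenerate denominators (missing or zero medians) invalidate the
affected protein/batch block, which is set missing with a warning rather than
silently propagated.

Residual between-batch variance after harmonization reflects only the
finite-sample gap between batch means and batch medians; on the default
synthetic cohort the median per-protein between-batch variance fraction drops
from ~0.6 to ~0.02.

After harmonization, `bootstrap_regress_covariates()` removes residual
covariate structure: per protein, OLS coefficients are estimated on 100
bootstrap resamples of samples and the covariate contribution (median
coefficient across bootstraps; the intercept, i.e. the protein's own level,
is retained) is subtracted. The bootstrap count is a stability choice, not a
significance device.

# Longitudinal phenotyping

`select_longitudinal()` applies the inclusion rules: 3 visits spanning at
least 24 months for clinical scales and hippocampal volume, 2 visits spanning
12 months for tau and FDG PET. `fit_subject_slopes()` fits
`value ~ months + (1 + months | subject)` by REML (lme4) and extracts each
subject's slope as fixed effect + BLUP. Singular fits — which are the rule on
noiseless toy data — fall back to per-subject OLS slopes, flagged in the
`method` column so downstream code can distinguish them. Slopes beyond 4 sd
of the cohort mean are removed in a single pass (mean and sd are not
recomputed after removal; with a 4 sd band the difference is immaterial and a
single pass is reproducible). `median_split()` dichotomizes at the median of
the worsening-oriented slope with a strict-greater rule, so exact-median
subjects are "slow" and an all-tied cohort degenerates to all-slow with a
warning.

Recovery of true slopes is information-limited: with 3 visits at 0/12/25
months, slope sd 0.1 and outcome noise 1, the expected Pearson correlation
between estimated and true slopes is about 0.90 (the random-intercept prior
contributes real information beyond the per-subject OLS slope), so observed
values fluctuate in roughly 0.88–0.92 across cohorts of 300.

# Differential abundance and enrichment

`dap_linear()` fits per-protein OLS of log2 abundance on a binary or
continuous trait over observed cells only (exact closed form; for a binary
trait this is the pooled two-sample t test), with BH adjustment across tested
proteins. No covariates are adjusted by default; an explicit design can be
regressed out beforehand. Proteins observed in fewer than 4 samples are
skipped and reported.

`module_enrichment_z()` scores a protein set (brain co-expression module)
against the background of tested proteins: observed statistic = mean member
p-value; null = mean p-values of `B = 10000` same-sized draws without
replacement; `z = (perm_mean - observed) / perm_sd`, oriented so enrichment
for small p is positive (the published phrase "difference between observed
and permuted means" does not fix a sign; the positive-enrichment orientation
matches how significant modules are plotted above a threshold);
`p = (count(perm <= observed) + 1) / (B + 1)`, the exact-permutation
convention that bounds p away from zero. When `choose(background, module)`
is at most 10,000, all subsets are enumerated and the p-value is exact. The
member statistic is the raw mean p, the literal reading of the source method;
the statistic function is internal and could be swapped without changing the
permutation machinery.

# Predictive panels

`stability_select()` runs L1-penalized logistic regression on 100
class-stratified bootstrap resamples, each with its penalty chosen by
internal 5-fold cross-validation at the `lambda.1se` rule (the published
method states LASSO and the bootstrap count but not the penalty path;
`lambda.1se` is the conservative conventional choice), and retains features
selected in at least 90% of bootstraps.

`evaluate_panel()` measures a panel over `n_runs = 100` stratified train/test
splits (80/20 by default; 70/30 is provided for small cohorts). Random-forest
hyperparameters (trees in {100, 300, 500}, depth in {3, 5, unlimited}) are
tuned by grid search with 5-fold CV inside the training split only. The
summary is the median test AUC with a 2.5–97.5 percentile interval across
runs — an interval over resampling runs, not a parametric CI. AUC is the
Mann–Whitney statistic with ties counted one half; the Youden threshold
maximizes TPR − FPR with ties broken toward sensitivity. Both fixed-panel
(select once on all data, the published primary analysis) and nested
(re-select inside every training split via `select_fun`) modes are available;
the test suite checks that nested evaluation does not trail the fixed panel
by more than the resampling noise, which quantifies the optimism of fixed
selection.

`attribute_features()` produces Shapley-value attributions by averaging
marginal contributions over feature orderings with a marginal-expectation
value function over a background sample. Each ordering telescopes from the
base value to the sample's score, so local accuracy
(`base + sum(attributions) = score`) holds exactly for any number of sampled
orderings; sampling only affects the variance of the per-feature split
(orderings are enumerated exhaustively up to 5 features).

`compare_predictor_sets()` compares two feature blocks with a synchronized
permutation test: both blocks are evaluated over identical splits, the
observed statistic is the difference in median AUC, and the null is built by
`B = 100` joint row permutations of both blocks against fixed labels,
re-evaluated over the same splits, with the exact-permutation two-sided
p-value. The published description ("shuffled the assignment of CSF peptides
and biomarkers for each participant") is ambiguous; the joint row permutation
is this package's documented choice and no equivalence to other readings is
claimed. One practical note: the statistic is a difference of test AUCs, so
with very small test sets its support is coarse and ties make the p-value
conservative; calibration checks should use test sets of a few dozen samples
(e.g. a 70/30 split of n = 100).

# Event-based staging

The single-subtype staging model treats disease progression as an ordered
sequence of biomarker "events". Given z-scored biomarkers (standardized
against the stable group and oriented so events are increases), a subject at
stage `k` has the first `k` biomarkers in the sequence at mean `z_event = 2`
(a conventional abnormality threshold) and the rest at mean 0, with sd
`sigma`; subjects are uniform mixtures over stages `0..N`. This step-function
z-score model is the single-subtype, one-threshold case of subtype-and-stage
inference, which suffices for staging one converter group over a top-10
protein panel; multi-threshold piecewise-linear events are an extension
point, not implemented. Log densities are floored at `exp(-700)` so
near-noiseless data remain comparable across orders.

`fit_event_sequence()` maximizes the order likelihood by greedy
single-element relocation from 25 random restarts, then runs 10,000
Metropolis iterations with pairwise-swap proposals to quantify positional
uncertainty; the MAP order, biomarker-by-position probabilities, stage
posteriors and the MCMC acceptance rate are returned. For 3 biomarkers the
MAP provably matches exhaustive enumeration (tested); stage MAP ties break
toward the lower stage.

# Pipeline and reproducibility

`run_pipeline()` chains the stages, exchanging data only through declared
TSV/JSON files in the output directory, and writes a manifest with the
package version, per-stage seeds derived deterministically from one global
seed, and MD5 digests of every artifact. The manifest contains no timestamps,
so a rerun with the same config is bit-identical — this is asserted in the
test suite. Default pipeline sizes (90–300 subjects, 100–200 proteins,
reduced permutation/bootstrap counts) are chosen so a full run completes in
about ten seconds while exercising every stage; method-level defaults
(B = 10,000 permutations, 100 bootstraps, 100 runs) remain the published
operating points.

# Known limitations

* The AT classification follows the published rule literally (ratio above
  the Aβ42/pTau181 cutoff of 39.20 is AT+), which is the reverse of the usual
  biochemical direction for this ratio; `positive_above = FALSE` restores the
  conventional direction. The package does not silently "fix" this.
* Enrichment treats module membership as given; building co-expression
  modules is out of scope.
* The event model assumes a single subtype and one z threshold per
  biomarker.
* KNN imputation (`k = 5`, sample-wise distances over mutually observed
  proteins) and the covariate-regression bootstrap count are conventional
  choices where the source method is silent; both are parameters.
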