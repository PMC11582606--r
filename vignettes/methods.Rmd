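---
title: "Methods: priming analytics, relaxed elastic-net modelling and GAVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: priming analytics, relaxed elastic-net modelling and GAVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

primava models whether a glioblastoma sample will die by intrinsic apoptosis
when an anti-apoptotic block (BCL-xL) is inhibited alongside a DNA-damaging
backbone (irradiation or temozolomide). The working hypothesis it encodes is an
interaction: cell death requires **both** a functional readiness to undergo
apoptosis (high mitochondrial priming, measured by BH3 profiling) **and** an
intact p53 signalling axis (TP53 wild-type, MDM2 not amplified; for the
temozolomide arm additionally a repair-deficient "MGMT negative" state). This
vignette records the models, the tunable parameters, and the design choices
made where the methodology was genuinely open.

## Priming analytics

BH3 profiling exposes permeabilized cells to pro-apoptotic BH3 peptides and
reads % cytochrome c release by flow cytometry. Raw measurements are
normalized by subtracting the DMSO negative control and clipping to
[0, 100] (`normalize_to_vehicle()`); subtraction keeps the normalized values
on the same percentage-point scale as the treated-minus-vehicle deltas used in
dynamic profiling (`dynamic_delta()`), so all derived quantities are
differences of release percentages.

Mitochondrial priming is summarized as the **BIM AUC**: the BIM peptide is
titrated over the grid 0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10 µM and release is
integrated over the *dynamic range* 0.03–3 µM (the closed interval; these
concentrations show the greatest spread of responses across samples).
`compute_bim_auc()` integrates with the trapezoid rule over
log10(concentration) — the grid is log-spaced, so a linear axis would let the
top decade dominate — and divides by the spanned log-width. The score
therefore reads as a mean % release over the dynamic range, lies in [0, 100],
is exactly invariant to titration points outside the range, and is monotone in
pointwise release. Replicates are averaged per concentration before
integration (mean-first); computing one AUC per replicate and averaging
afterwards gives the same value for balanced designs but degrades less
gracefully with missing points, and the assay here is balanced by design.

Dependency calls from dynamic profiling compare the HRK (BCL-xL) and MS1
(MCL-1) deltas to a threshold, default 10 percentage points
(`call_dependency()`); the threshold is configurable because published
heatmaps support the labelling semantics but not a specific numeric cutoff.

## Feature construction

`mgmt_status()` encodes the composite MGMT rule: a tumour is MGMT *negative*
(repair-deficient, TMZ-sensitive) when its promoter is methylated **or** its
MGMT RNA expression is below the cohort median; only unmethylated,
high-expressing tumours are MGMT positive. The median is a cohort-level
statistic: for verification cohorts it must be frozen from training, which is
why `cohort_features()` computes it once per cohort and
`fit_full_and_predict()` documents the freeze.

The **IMF** (Integrated Molecular and Functional) feature set is every product
over non-empty subsets of four base variables — the BIM AUC and
favorable-status indicators TP53 (wild-type = 1), MDM2 (not amplified = 1),
MGMT (negative = 1) — giving 2^4 − 1 = 15 features. This enumeration is
adopted because it is the unique reading that produces 15 features from 4 base
variables under product-only ("without individual main effects") notation, and
the favorable-indicator coding makes each product read as an
"all conditions met" score; the top-ranked features are then literally the
biomarker products used by GAVA. The **GM** (Global Molecular) set is the
genome-wide blocks (expression, copy number, mutations), each reduced by
`merge_identical_features()` (columns with bitwise-identical values collapse,
names concatenated with `|`) and stripped of zero-variance columns. Products
of GM features with the molecular indicators are available behind an explicit
argument (`interact_with`) and default off: the published table enumerating
which combinations entered which model is not machine-readable, so the default
is the conservative main-effects reading.

Treatment response (% cell death, normalized to the DNA-damaging agent alone)
is binarized at the arm mean with a strict inequality ("above the mean"), so a
degenerate all-equal arm has no sensitive samples.

## The relaxed elastic net under nested cross-validation

The penalized fit minimizes

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
  \lambda\left(\alpha\lVert\beta\rVert_1 +
  \frac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

by cyclic coordinate descent (compiled; convergence when the largest
coefficient change in a full sweep falls below 1e-7, at most 1e5 sweeps,
active-set iteration with full KKT sweeps). Predictors are standardized
internally to zero mean and unit population variance — binary indicators are
standardized identically, a uniform treatment that keeps the penalty
comparable across feature types — and coefficients are reported on the
original scale. At $\lambda = 0$ on a full-rank design the solver short-cuts
to exact least squares. Because the elastic net biases retained coefficients
toward zero, `relax_fit()` refits unpenalized least squares on the selected
support and blends with the penalized coefficients by the debiasing factor
$\gamma$ ($\gamma = 1$ pure penalized, $\gamma = 0$ pure refit); a singular
refit falls back to the penalized coefficients with a warning.

The model-comparison protocol is a Pearson filter (keep features with
$|r| \ge$ cutoff against the response; zero-variance features excluded)
followed by the relaxed elastic net, with **all four** hyperparameters —
Pearson cutoff, $\alpha$, $\lambda$, $\gamma$ — tuned by repeated k-fold CV in
the inner loop of a nested scheme whose outer loop is leave-one-out. The
filter is re-run inside every inner fold (the strict no-leakage reading);
consequently a held-out sample influences nothing about its own fold's
training, which the test suite asserts by hashing fold artifacts under
sentinel perturbations. Fold assignments and all derived seeds are keyed by
sample id rather than position, and rows/columns are canonicalized by name
internally, so results are invariant to sample and feature order.

Accuracy is reported as RMSE over held-out predictions and $r^2$ defined as
the **squared Pearson correlation** between predicted and observed. The
squared-correlation definition is primary because a near-useless model then
scores close to 0 rather than negative (the coefficient-of-determination form
$1 - SS_{res}/SS_{tot}$, which can go negative out of sample, is also reported
as `r2_cod`). Constant predictions leave the correlation undefined; it is
reported as 0 with `r2_defined = FALSE` rather than silently.

Tuning defaults mirror common practice where the protocol leaves them open:
cutoff ∈ {0, 0.2, 0.4, 0.6}, $\alpha$ ∈ {0, 0.25, 0.5, 0.75, 1}, $\lambda$ on
a 50-point log grid from $\lambda_{max}$ of the tuning data (floor 1e-4
· $\lambda_{max}$ when n > p, 1e-2 otherwise — tiny penalties in
high dimension are slow and never win validation), $\gamma$ ∈ {0, 0.25, 0.5,
0.75, 1}, inner 5-fold CV with 20 repeats. Ties in inner RMSE break toward
larger $\lambda$, then larger $\gamma$, then larger cutoff and $\alpha$
(parsimony first).

## LASSO-path feature ranking and the permutation null

To compare the integrated features against the genome-wide pool, IMF and GM
features are pooled and ranked by how late the lasso ($\alpha = 1$) shrinks
each coefficient to zero along a 200-point log-spaced penalty grid
(`lasso_path_order()`); rank 1 exits last. A lasso solution can hold at most
about n active features, so in high dimensions most features never activate
and would tie at exit 0. Tied features are therefore ordered by their
*marginal entry penalty* $|x_j^\top y_c|/n$ — the penalty at which the feature
would enter an otherwise empty model, i.e. the natural continuation of
"how late does it survive" to features the multivariate path never admits —
with feature name as the final key for exact duplicates (which should have
been merged upstream; residual ties are flagged). A name-based tie rule alone
would silently bias top-k composition toward alphabetically early provenance
prefixes and destroy the enrichment test below.

Enrichment of IMF features among the top k (default 100) is assessed by
permuting the response (features untouched, preserving their correlation
structure — the conservative choice) and recounting, by default 1000 times.
The primary p-value uses the add-one rule $p = (1 + \#\{null \ge obs\})/(1 +
B)$, which can never be zero and is always valid, but the count statistic is
integer-valued and heavily tied, so the add-one p-value is *conservative* —
its null distribution is superuniform, not uniform, and a uniformity test on
it would reject by construction. `permutation_pvalue()` therefore also
reports `p_value_randomized`, the observed statistic's uniformly tie-broken
rank among the null draws, which is exactly uniform under exchangeability;
that is the quantity the calibration tests examine, while inference should
quote the conservative add-one value.

## GAVA

The GBM Apoptotic Vulnerability Assessment applies the top-ranked IMF products
as binary variables: a sample is GAVA **positive** when it is highly primed
AND TP53 wild-type AND MDM2 wild-type (the `BIMAUC*TP53*MDM2` product), with
MGMT-negative status additionally required on the TMZ arm
(`BIMAUC*TP53*MDM2*MGMT`); lacking any component makes it negative, so a
TMZ-positive call always implies an IR-positive call. Two priming cutoffs are
provided and recorded in output metadata rather than silently chosen: an ROC
threshold maximizing Youden's J over midpoints between sorted unique scores
(used for cell-line cohorts; inclusive `>=` at the threshold, ties resolved
toward the more inclusive cutoff) and the cohort median (used for ex vivo and
patient material; strictly-above). When both arms are scored on one cohort, a
single priming cutoff should be shared across arms — priming is a property of
the sample, not of the treatment — and only then is the superset implication
between the arms' calls guaranteed sample by sample. Youden's J is the default
operating point because it weighs sensitivity and specificity equally — the
natural choice when no clinical cost asymmetry has been established — and the
criterion is an explicit function argument. Evaluation reports sensitivity/specificity of the
binary call, Fisher's exact two-sided p on the 2×2 call-by-response table, and
an AUROC computed by the rank statistic on the continuous pre-threshold score
— the BIM AUC masked by the molecular indicators, which is exactly the
top-ranked IMF product itself.

## The synthetic-cohort generator

`simulate_cohort()` generates the statistical structure the analysis assumes:
Bernoulli genotypes (defaults: TP53 mutant 35%, MDM2 amplified 15%, MGMT
methylated 50%, matching the rough prevalences in published glioma cohorts);
MGMT expression log-normal with a lower location for methylated samples
(meanlog log 2 vs log 20, sdlog 0.5) so methylation and low expression
co-occur but imperfectly; per-sample BIM titrations that are Hill curves —
the published release curves are sigmoid in log-concentration and a Hill form
with configurable EC50 and slope is the minimal standard parameterization —
with EC50 drawn log-uniformly over 0.01–10 µM (the titration's span; the
biological distribution of priming across gliomas is not established, so it is
config, not assertion) and Gaussian measurement noise (sd 3 points, 2
replicates); and responses

```
death = baseline + beta * primed * TP53_WT * MDM2_WT (* MGMT_neg for TMZ) + N(0, sd)
```

clipped to [0, 100] (Annexin V/PI percentages cannot leave that range), with
baseline 10, effect beta 30 and noise sd 5 points. "Primed" truth is the
noise-free BIM AUC exceeding a generative cutoff (default 50, the midpoint of
the score's range), mirroring the binary stratification the analysis applies.
The omics matrix is i.i.d. log-normal with a configurable number of exactly
duplicated genes (default 2000 genes, 50 duplicates) — deliberately
uninformative, so recovery tests ask whether the pipeline *prefers* the
integrated features when the generative truth is the interaction. Four
purpose-specific RNG streams (genotype, titration, omics, response) derive
from the config seed, so enlarging one block never perturbs another; a fixed
seed reproduces the cohort bit-identically.

What the generator does **not** emulate: correlated co-expression structure,
batch effects, omics features genuinely associated with response, censored or
longitudinal endpoints, and measurement artefacts beyond additive Gaussian
noise. Passing recovery tests therefore demonstrate correctness of the
machinery and its preference for the generative signal, not clinical
performance on real tumours.

## Problem sizes and numerical choices

Full-scale defaults are kept on every function (inner 5-fold × 20 repeats,
50-point λ grids, 1000 shuffles, top-100 counts). The test-suite and
acceptance-script runs use desk-scale settings chosen once for a single-CPU
workflow: 20 replicate cohorts of n = 40 with 2000 genes; inner 5-fold × 1
repeat over cutoff {0.3, 0.5} × α {0.5, 1} × 8 λ values × γ {0, 1};
ranking on a 100-point grid (floor 0.01); permutation tests with 200 shuffles
on a 50-point grid (floor 0.05); and 500 replicates × 99 shuffles for the
null-calibration study. Degenerate inputs are handled explicitly rather than
silently: constant responses, empty Pearson selections (fall back to the
intercept-only model), singular relaxation refits (fall back to penalized
coefficients with a warning), one-class ROC inputs and empty contingency
groups (flagged partial results).

## Known limitations

The fitter is a dense cyclic coordinate descent without covariance updates or
strong-rule screening; it is comfortable at thousands of features but not at
the hundreds of thousands. The permutation test re-runs the full path per
shuffle (no shortcut surrogate), which is the faithful but slower choice. The
exit-order ranking resolves ties through the marginal entry statistic; when
two features are exactly collinear the order between them is nominal and the
result is flagged. GAVA's two priming-cutoff rules can disagree near the
median; the choice of rule is an explicit argument and is recorded in the
pipeline manifest, because fixing a prospective clinical cutoff is beyond what
the data here can decide.
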