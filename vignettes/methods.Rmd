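---
title: "Methods: NMR metabolic fingerprinting with OPLS-DA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR metabolic fingerprinting with OPLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabofinger)
```

## The problem

Insulin deficiency in pediatric type 1 diabetes perturbs carbohydrate,
lipid and amino-acid metabolism simultaneously. A 1D ¹H-NMR spectrum of
fasting plasma captures dozens of metabolites in one measurement; the
question is whether the joint pattern of relative concentrations — the
*metabolic fingerprint* — separates patients from matched controls, and
which spectral regions drive the separation. `metabofinger` implements
that analysis as a reusable, fully tested pipeline, and ships a synthetic
cohort generator so the entire chain can be exercised and calibrated
without access to clinical spectra.

## From spectrum to variables

A spectrum is a pair of vectors (chemical shift in ppm, intensity). A
*region table* partitions the informative part of the shift axis into
closed intervals `[ppm_lo, ppm_hi]`; the variable for a region is the
trapezoidal integral of intensity over that interval, with both endpoints
included by linear interpolation at the exact bounds. Trapezoidal
integration on the stored grid is bit-reproducible, linear in the signal,
invariant to the storage direction of the ppm axis, and converges at
second order under grid refinement, all of which the test suite asserts.

The packaged default scheme has 110 regions spanning 0.80–8.60 ppm,
omitting the 4.50–5.00 ppm water band, with 15 regions flagged as
glucose-related. Seventeen regions carry literature-anchored boundaries
and metabolite assignments (glucose multiplets, triglyceride/phospholipid
resonances, serine, tryptophan, cysteine); the remaining 93 are contiguous
synthetic fillers labelled as such in the `assignment` column, present so
that the 110-variable/95-variable bookkeeping of the analysis is
executable. Seven of the fillers inside the glucose spectral envelope
(3.20–3.40, 3.96–4.00, 5.22–5.28 ppm) carry the glucose flag so the
excluded set has the realistic size of 15. Users with a measured scheme
load it with `load_region_table()`; validation rejects overlapping
regions, duplicate ids and inverted bounds, naming the offending rows.
Shared boundaries between adjacent regions are legal (closed intervals;
the boundary point contributes to both). No implicit normalisation or
masking is applied to spectra: the region scheme is the sole arbiter of
what is integrated.

## Preprocessing

Variables are mean-centered and Pareto-scaled:
`x' = (x - mu_j) / sqrt(s_j)`, with `s_j` the sample SD (n − 1
denominator, matching the univariate *t*-test convention). Pareto scaling
damps — without flattening — the dominance of intense signals such as
glucose, which pure unit-variance scaling would equalise and raw data
would let dominate. Scaling parameters are a first-class object
(`scaling_params`) so the transform fitted on training samples can be
applied unchanged to held-out samples. Within cross-validation the
parameters are refitted on each training fold by default
(`rescale_per_fold = TRUE`); this is the conservative, leakage-free choice
— commercial implementations are not explicit about it, so it is exposed
as a switch. Constant columns are rejected (degenerate under Pareto), and
a fitted transform inverts exactly (`invert_scaling()`).

## PCA quality control

Unsupervised PCA (NIPALS with deflation) provides the cluster view,
confounder staining (`plot(pca, meta = ...)`), and two outlier
diagnostics:

* **Hotelling's T²** over the A model components,
  `t2_i = sum_a t_ia^2 / var(t_a)`, with the F-based control limit
  `A (N^2 - 1) / (N (N - A)) * F(1 - alpha; A, N - A)`. This is the
  classical limit for a new observation; for in-model samples it is
  slightly conservative at small N, which the calibration tests account
  for by checking the flag rate at N = 200, where the distinction is
  negligible.
* **DModX**, the normalised residual distance
  `(s_i / s0) * sqrt(N / (N - A - 1))` with
  `s_i^2 = sum_j e_ij^2 / (K - A)` and
  `s0^2 = SSE / ((N - A - 1)(K - A))`, against the limit
  `sqrt(F(1 - alpha; K - A, (N - A - 1)(K - A)))`. The
  `N / (N - A - 1)` factor undoes the shrinkage of in-model residuals, so
  under homogeneous Gaussian residuals the flag rate sits at the nominal
  alpha (the suite verifies 0.05 ± 0.01 by simulation).

Defaults: A = 2 components for QC (the conventional two-component score
plot) and alpha = 0.05 for both limits.

Numerical choices: NIPALS iterates to a relative score-change tolerance of
1e-12 with a 500-iteration cap per component; on near-degenerate
eigengaps (e.g. pure-noise matrices, where adjacent eigenvalues differ by
a few percent) convergence to that tolerance can genuinely require more
iterations, so `max_iter` is exposed and the simulation tests raise it.
Each loading vector's largest-magnitude element is made positive, fixing
the sign indeterminacy so runs are reproducible across platforms. A
numerically exact fit (A equal to the matrix rank) leaves only
floating-point dust in the residual matrix; DModX treats a residual sum
of squares below 1e-16 of the total as exactly zero rather than forming a
0/0 ratio.

## OPLS-DA

The response is the centered class vector (control = +1, case = −1). The
single-response OPLS sequence is:

1. predictive weight `w = X'y / ||X'y||`;
2. for each of `a_ortho` orthogonal components: current loading
   `p = X't/(t't)` with `t = Xw`; orthogonal weight
   `w_o = p - (w'p) w`, normalised; `t_o = X w_o`,
   `p_o = X't_o/(t_o't_o)`; deflate `X <- X - t_o p_o'`;
3. predictive component on the deflated matrix: `t = Xw`,
   `p = X't/(t't)`, `q = y't/(t't)`.

R²Y(cum) is `1 - ||y - t q||^2 / ||y||^2` on the centered response;
R²X(cum) accumulates `||t p'||_F^2 / ||X||_F^2` over the predictive and
orthogonal components. `a_ortho` defaults to 1 — the canonical score plot
is t[1]P against t[1]O — and is configurable. A useful identity the tests
pin down: flipping the sign of y negates `w`, `t_pred`, the fitted
responses and the S-line statistics, but leaves `q`, R²Y, Q² and VIP
unchanged (`q = y't/(t't)` is even in the simultaneous sign flip).

Prediction for new samples applies the stored scaling, strips orthogonal
variation with the training `w_o, p_o` pairs, projects on `w`, and labels
by the sign of `t q`. With `a_ortho = 0` the model coincides with
one-component PLS1, which the suite verifies against an independent
eigen-decomposition oracle at 1e-10.

### Cross-validation

Sevenfold by default, the convention for this design (each fold of a
7 vs 7 cohort holds out one case and one control). Fold assignment is a
deterministic stratified round-robin: within each class the sample order
is shuffled under the seed, then samples are dealt cyclically to folds
with a counter that continues across classes — so `n_folds = N` is exact
leave-one-out (asserted against an explicit loop). Per fold, scaling and
model are refitted on the training rows and the held-out responses are
predicted as above; `Q2(cum) = 1 - PRESS / SS` with SS the total sum of
squares of the full centered response, computed once. Training folds
lacking a class are refused with a suggestion to use fewer folds.

### S-line and VIP

`p_ctr_j` is the covariance (n − 1) between the predictive score and the
scaled variable — large for intense signals, scale-dependent — and
`p_corr_j` the corresponding correlation, the scale-free reliability
measure plotted on the S-line and thresholded at 0.6 for selection. Both
are computed against the Pareto-scaled working space of the model.

VIP defaults to the predictive-component definition
`VIP_j = sqrt(K) |w_j|`, whose mean square over variables is exactly 1;
an optional `"total"` mode weighs the orthogonal weight vectors by their
share of modelled X-variation. The exact formula used by commercial OPLS
software is version-dependent, so the mode is recorded in every output.
VIP uncertainty is the jack-knife standard error over the G = 7
cross-validation submodels,
`cvse_j = sqrt(((G - 1)/G) * sum_g (VIP_jg - mean_g VIP_jg)^2)`.

## Univariate testing and selection

Per variable: Student's pooled-variance two-sample *t*-test (the
conventional reading of an "independent samples t test" with equal group
sizes; Welch is available behind a flag), Benjamini–Hochberg adjustment
across the variables of the active model (110 or 95), percent change
`100 (mean_case - mean_control) / mean_control`, and the direction arrow
from the sign of the mean difference. `ttest_summary()` computes the
identical statistic from group moments, making published summary tables
verifiable without raw data. A region is a declared discriminator only
when adjusted *p* < 0.05 **and** |p(corr)| > 0.6 **and** VIP > 0.5; the
significance level for criterion 1 is a documented default, and selection
is monotone in all three thresholds.

## The synthetic cohort generator

`default_template()` carries, for each of the 110 regions, target
arithmetic group means and SDs: the 17 anchored regions use published
case/control summaries (glucose up 23–68 %, lipids down 17–36 %,
serine/tryptophan/cysteine down 25–64 %); the 93 fillers are null
(case = control), with means drawn once from a log-uniform 0.5–50 range
and SD fixed at 15 % of the mean — a typical coefficient of variation for
binned plasma NMR variables. `generate_profiles()` draws correlated
log-normal vectors: on the log scale, a block-structured correlation
matrix (glucose block rho = 0.8, lipid block rho = 0.6 — plausible values
for multiple bins of one metabolite, not literature estimates) is combined
with per-variable sigmas chosen by moment matching
(`sigma^2 = log(1 + (s/m)^2)`, `mu = log m - sigma^2/2`), Cholesky
factorised, exponentiated. Log-normal marginals keep integrals positive
and right-skewed, as real plasma data are, while the template means and
SDs stay interpretable in arithmetic units. One pseudo-random stream per
dataset is split deterministically by purpose (draws, shuffle, spectral
noise), so adding noise never perturbs group assignment, and a seed
regenerates the dataset bit-identically.

`generate_spectra()` renders each profile as a spectrum: one Lorentzian
per region, centred mid-region, half-width 20 % of the region width.
Because Lorentzian tails leak across boundaries, peak amplitudes are
obtained by solving the K × K linear system that makes every region's
within-region integral equal its target, so the noise-free round trip
through `integrate_spectrum()` is exact to solver precision; white noise
is added at a configurable signal-to-noise ratio.

What the generator does **not** emulate: chemical-shift drift, peak
overlap between metabolites, baseline and phasing artifacts, or any
upstream acquisition variability. Passing tests therefore demonstrate the
statistical machinery — scaling, projection, cross-validation, selection —
under the assumed effect structure, not robustness to spectroscopy
physics, which is upstream of this package's scope.

## Calibration findings and limitations

The suite runs the full pipeline over 100 seeded synthetic cohorts per
condition (7 vs 7, 110 variables — the study design; larger sizes only
where an asymptotic claim needs them):

* With real effects, Q²(cum) > 0 and the correct p(corr) signs (glucose
  negative, lipids positive under the control = +1 coding) in ≥ 95 % of
  seeds, and held-out balanced accuracy above 0.8.
* Under the all-null template the three-criterion selection averages
  fewer than one false discriminator per 110 variables, and raw *t*-test
  p-values are uniform.
* Null Q²(cum), however, is positive in roughly a fifth of seeds
  (measured ≈ 0.17 here, and comparable when the same protocol is driven
  through an independent PLS implementation). Sevenfold CV at N = 14
  simply has that much variance: a positive Q² of modest size on a
  14-sample cohort is weak evidence on its own and should be read
  together with the selection table. This is a property of the design
  size, not of the implementation.

Other limitations: the 93 filler regions and the 7 unpublished
glucose-flagged fillers are stand-ins — analyses of real spectra must
supply the measured region scheme; two classes only (no multi-class
extension, no O2PLS); no permutation test of the model (validation is by
CV only); missing values are rejected rather than imputed, since
imputation would silently change every downstream statistic.
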