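---
title: "Methods: tri-exponential IVIM, ASL CBF, and multimodal fusion"
author: "ivimfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tri-exponential IVIM, ASL CBF, and multimodal fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimfuse)
```

# Overview

`ivimfuse` implements a complete multimodal quantitative-MRI analysis chain
for two-group (healthy control vs. mild traumatic brain injury) studies:

1. voxelwise **tri-exponential IVIM** fitting of multi-b-value diffusion MRI;
2. **CBF quantification** from pseudo-continuous arterial spin labeling
   (pCASL) via the single-compartment kinetic model;
3. **ROI feature extraction** over a 90-region parcellation, z-scored per
   region across subjects;
4. **two-stage multimodal fusion**: multi-block regularized generalized
   canonical correlation analysis (RGCCA, $\tau = 1$) followed by joint
   independent component analysis (jICA);
5. **inference**: per-component two-sample tests, component-region Spearman
   maps, outcome (GOS-E) correlations, all with Benjamini–Hochberg FDR
   control; and
6. **test–retest reliability** via two-way intraclass correlation maps.

Because clinical imaging data of this kind cannot be redistributed, the
package ships a synthetic cohort generator that emulates every input the
pipeline needs. The generator is first-class, tested code: its defaults are
the study conditions under which all recovery and error-rate properties are
verified.

# The tri-exponential IVIM model

The diffusion-weighted signal at b-value $b$ is modeled as

$$\frac{S_b}{S_0} = F_p e^{-b D_p} + F_f e^{-b D_f} + F_s e^{-b D_s},$$

with signal fractions $F_p + F_f + F_s = 1$: a fast, perfusion-related
pseudo-diffusion compartment ($D_p$, capillary blood motion), an
intermediate free-water-like compartment ($D_f$), and a slow compartment
($D_s$) reflecting restricted tissue diffusion.

## Two-step constrained fitting

Fitting all six parameters at once is ill-conditioned, so the estimator is
segmented:

* **Step 1.** Because the fast and intermediate compartments have decayed by
  a factor $\le e^{-3}$ at $b \ge 1000$ s/mm², $D_s$ is first estimated by
  log-linear least squares of $\ln S$ on $b$ restricted to the high-b shells
  ($S = S_0 e^{-bD_s}$). This closed form is exact on clean mono-exponential
  data and fast; estimates are clipped into the $D_s$ bounds with a
  diagnostic flag.
* **Step 2.** The full model is refit over all shells by bounded
  Levenberg–Marquardt least squares with $D_f$ **fixed at
  $3\times10^{-3}$ mm²/s** (free-water diffusivity at body temperature),
  $D_s$ free but initialized at the step-1 estimate (holding it fixed is
  selectable via `triexp_config(ds_fixed_step2 = TRUE)`), $D_p$ bounded in
  $[3\times10^{-3}, 0.2]$ mm²/s (initial $10^{-2}$), $D_s$ bounded in
  $[10^{-5}, 3\times10^{-3}]$ mm²/s, and the simplex constraint enforced
  exactly by the reparameterization $F_s = 1 - F_p - F_f$. If the optimum
  implies $F_s < 0$ the voxel is re-solved on the simplex boundary
  ($F_s = 0$). The signal is normalized by the b0 shell mean; $S_0$ is fixed
  to that mean by default (`refit_s0 = TRUE` frees it).

Numerical choices worth knowing:

* **Shells are direction-averaged before fitting.** IVIM treats the decay as
  isotropic, so the 81 directions collapse to 14 shell means plus b0. The
  acquisition has unequal shell sizes (3–20 directions), so the shell means
  are heteroscedastic; step 2 therefore uses weighted least squares with
  per-shell weight $\sqrt{n_\text{dir}}$.
* Voxels with non-positive high-b signal, or with b0 mean below a
  configurable dropout threshold (`dropout_sigma_mult` times a supplied
  noise-floor estimate; disabled by default since phantoms have no air
  background), are excluded and flagged — degenerate voxels never return
  silent NaNs.
* Optimizer controls: at most 200 LM iterations, `ftol = 1e-10`; analytic
  Jacobians are supplied for speed and stability.

# CBF quantification from pCASL

Control and label volumes are split by the label-order flag, averaged
(grand means; pairwise means are equivalent in expectation), and subtracted
to give $\Delta M$. CBF in mL/100 g/min follows the single-compartment
kinetic model

$$\mathrm{CBF} = \frac{6000\,\lambda\,\Delta M\,e^{\mathrm{PLD}/T_{1b}}}
{2\,\alpha\,T_{1b}\,M_0\,\bigl(1 - e^{-\tau/T_{1b}}\bigr)},$$

with labeling duration $\tau = 1.8$ s and post-labeling delay
$\mathrm{PLD} = 2.0$ s from the acquisition protocol, and consensus-model
defaults $\lambda = 0.9$ mL/g, $\alpha = 0.85$, $T_{1b} = 1.650$ s — all
overridable via `asl_constants()` and recorded in the output. A dedicated
M0 volume is used when available; voxels with $M_0 \le 0$ are masked and
counted. The quantification is linear in $\Delta M$ and exactly inverts the
generator's forward model (round-trip error below $10^{-10}$ relative).

# ROI features

`extract_roi_means()` averages in-region, in-mask, finite voxels per atlas
label in ascending label order; regions with no valid voxel yield a missing
value plus a warning rather than silently shrinking the 90-column contract.
Blocks are z-scored per column with the sample SD ($n-1$); zero-variance
columns become zeros with a flag. GOS-E enters the outcome fusion as a
one-column block z-scored the same way.

# Two-stage fusion

## RGCCA with full shrinkage

Block weight vectors $w_b$ maximize
$\sum_{b \ne c} c_{bc}\, g\bigl(\mathrm{cov}(X_b w_b, X_c w_c)\bigr)$
with full inter-block connectivity ($c_{bc} = 1$), $\tau = 1$ shrinkage
(weights constrained to unit Euclidean norm: a covariance, PLS-like
criterion), and the **factorial** scheme $g(x) = x^2$ by default (horst and
centroid selectable). Factorial was chosen because the two-block case then
has a closed-form oracle — the weights equal the leading singular vectors of
$X_1^\top X_2$ — used to validate the implementation to machine precision.
The inner loop is the classical block-ascent update (the criterion is
non-decreasing; verified property-style on random instances), initialized
deterministically at each block's leading right singular vector, and stops
when the relative criterion increment falls below `tol` (default $10^{-8}$).
Successive components are obtained by deflating each block against its own
variate; within-block variates are mutually orthogonal. A block with fewer
columns than $k$ contributes only as many components as it has columns, so a
one-column GOS-E block adds a single variate.

Per component and block the **outer AVE** (average variance explained) is
the mean squared correlation between the block's features and the block
variate, in percent. The default component count is fixed at $k = 3$ per
block — the parsimony point for this pipeline — with an automatic
diminishing-returns rule (`select_n_components(rule = "marginal")`: smallest
$k$ before the cross-block mean AVE gain drops under 5 percentage points)
available.

## Joint ICA

The canonical variates are standardized to unit variance and concatenated in
block order (five 3-component imaging blocks give a subjects × 15 matrix).
`fit_jica()` runs symmetric fixed-point ICA with the logcosh contrast,
treating **subjects as the sample dimension**: columns are centered, the
matrix whitened through its SVD, and an orthogonal unmixing matrix estimated
from a seeded random orthogonal start. The decomposition is
`joint = loading %*% source`: subject loadings are the independent
components (the per-subject IC scores used in all downstream statistics) and
each source row is the component's pattern over the concatenated variates.
This orientation matches what a fast fixed-point ICA routine does when
handed a subjects × variates matrix, reproduces the 15-IC count for five
3-component blocks, and — because the generator plants subject-mode sources
— is the statistically efficient direction (hundreds of subjects rather than
15 variates feed the contrast statistics).

Conventions required by ICA's order/sign ambiguity: components are ordered
by decreasing explained variance and signed so each source row's
largest-magnitude element is positive. The component count defaults to the
number of concatenated variates and is reduced to the matrix's effective
rank with a warning — this is why adding a redundant one-column GOS-E block
to five imaging blocks yields 16 components rather than 18.

# Statistics

* **Group comparisons**: two-sample t-tests per IC (pooled-variance default
  — the conventional reading of "two-sample t-test" — Welch selectable),
  with group means, the 95% CI of the mean difference, and BH-FDR across
  components.
* **Component–region maps**: tie-corrected Spearman correlations between IC
  scores and z-scored ROI values, p-values from the t-approximation, FDR
  applied **within each IC × modality family** (90 tests); the top five
  regions per family are ranked by $|\rho|$ with ties broken by ascending
  label. The FDR family choices are conventions (recorded in output), since
  families can be defined more or less conservatively.
* **Voxelwise tests** within a chosen ROI use the same pooled t-statistic,
  vectorized, with FDR across the ROI's voxels.
* **Outcome correlations**: Spearman between IC scores (or ROI features) and
  GOS-E within the patient group, FDR across components (or within each
  modality's 90 regions).
* **Demographics**: Pearson chi-squared on the 2×2 sex × group table
  *without* continuity correction (the variant whose statistic on the
  reference cohort counts is 0.029), Shapiro–Wilk normality per group, and
  Wilcoxon rank-sum (normal approximation with continuity and tie
  correction) for continuous variables.

# Test–retest reliability

`icc_two_way()` computes, from the two-way ANOVA mean squares with
$k$ visits,

* consistency ICC(3,1): $(\mathrm{MS}_R - \mathrm{MS}_E) /
  (\mathrm{MS}_R + (k-1)\mathrm{MS}_E)$, and
* absolute-agreement ICC(2,1): the same numerator over
  $\mathrm{MS}_R + (k-1)\mathrm{MS}_E + \tfrac{k}{n}(\mathrm{MS}_C -
  \mathrm{MS}_E)$.

The literature's labeling of these forms is often inconsistent ("absolute
agreement" attached to the (3,1) label); both variants are implemented, the
default is the consistency form, and the variant used is recorded in the
output. `icc_map()` vectorizes the estimator over masked voxels and reports
the in-mask mean ± SD, excluding degenerate (zero-variance) voxels with a
count. A planted systematic visit offset lowers the agreement form but not
the consistency form, which the tests exercise.

# The synthetic cohort generator

`phantom_spec()` + `generate_phantom()` produce region-wise constant ground
truth on a desk-scale grid (default 24 × 24 × 12 voxels, 90 contiguous
parcels standing in for an anatomical 90-region atlas):

* fractions $F_p \approx$ 0.05–0.12, $F_f \approx$ 0.10–0.25,
  $F_s = 1 - F_p - F_f$;
* $D_s \approx$ 0.5–0.9 × 10⁻³ mm²/s and $D_p \approx$ 0.03–0.1 mm²/s. The
  $D_p$ range follows tri-exponential brain IVIM reports for the capillary
  pseudo-diffusion compartment; it matters that the fast compartment is well
  separated from the fixed $D_f = 3\times10^{-3}$ mm²/s, as near-collinear
  compartments make $F_p$ and $F_f$ jointly unidentifiable regardless of the
  optimizer;
* CBF ≈ 40–70 mL/100 g/min;
* the mTBI group effect defaults to −15% CBF and −20% $F_p$ with a small
  $F_s$ increase in four designated subcortical-like regions (reduced
  perfusion with increased tissue fraction being the expected injury
  direction); fractions are re-normalized to the simplex after any shift so
  the forward model stays valid, and shifts that would push a diffusivity
  outside the fit bounds are rejected with a message;
* between-subject variability is seeded multiplicative region-level jitter
  (default 5% relative SD). The within-group biological variance of these
  metrics is not established quantitatively in the literature; 5% is a
  plausible desk-scale choice, set once.

`simulate_dwi()` evaluates the forward model and adds **Rician** noise by
default (magnitude-MRI physics: the magnitude of a complex Gaussian
perturbation with $\sigma = S_0/\mathrm{snr}$), with Gaussian and noiseless
modes for linear-theory tests. Direction vectors are placed by a
deterministic spherical-Fibonacci construction per shell — fitting is
shell-averaged, so only reproducibility and rough uniformity matter.
`simulate_asl()` inverts the quantification formula at the ground-truth CBF
so the noiseless round trip is an algebraic identity.
`simulate_block_matrices()` bypasses imaging entirely for fusion tests:
$X_b = A S_b + E_b$ with shared unit-variance Laplace subject sources,
sparse block patterns, Gaussian noise (default SD 0.2, i.e. per-feature SNR
5), and the first source mean-shifted between groups by the chosen effect
size. GOS-E is synthesized by a monotone quantile map from a latent source
onto integers 3–8 with bin probabilities giving the clinically typical
mean ≈ 6.4, SD ≈ 1.1–1.3.

What the generator does **not** emulate: head motion, EPI distortion,
partial-volume mixing, spatially correlated noise, registration error, and
multi-site effects. Passing recovery tests on these phantoms therefore
demonstrates correctness of the estimators and the fusion chain under the
stated noise models — not robustness to real-world acquisition artifacts,
which the out-of-scope preprocessing tools are responsible for removing.

# Problem sizes and runtime choices

The shipped tests and the acceptance script use: a 24 × 24 × 12 phantom
(6 912 voxels) for IVIM recovery; 100 seeded replicates at 200 subjects for
fusion recovery; ~134 null datasets (≥ 2 000 ICs) for the type-I error
check; 500 subjects for the ICC ratio recovery; and an 8 × 8 × 4 grid with a
21-subject cohort for the end-to-end smoke test. These sizes give stable
Monte-Carlo estimates at interactive runtimes on a single core.

# Known limitations

* Only $\tau = 1$ (covariance criterion) RGCCA is implemented; intermediate
  shrinkage would require per-block covariance inversion that nothing in
  this pipeline exercises.
* ICA separation quality of weakly non-Gaussian (Laplace) sources embedded
  in a higher-dimensional whitened space is intrinsically limited at these
  sample sizes; when the number of extracted components greatly exceeds the
  number of latent sources, several components can share a source and
  per-source correlations below 0.9 occur in a minority of replicates (the
  same behavior is observed with reference fixed-point ICA
  implementations).
* The voxel grid uses contiguous equal-size parcels, not anatomical
  geometry; region adjacency effects (partial voluming across boundaries)
  are absent.
* Fits are per-voxel and independent; no spatial regularization.
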