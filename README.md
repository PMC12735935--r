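# ivimfuse

Multimodal quantitative-MRI fusion for two-group brain studies: voxelwise
**tri-exponential intravoxel incoherent motion (IVIM)** fitting,
**pCASL cerebral blood flow (CBF)** quantification, atlas-based ROI feature
extraction, **mCCA+jICA fusion** (multi-block regularized generalized
canonical correlation analysis followed by joint independent component
analysis), group/outcome statistics with FDR control, and test–retest
**ICC** mapping — plus a synthetic cohort generator so the whole chain is
testable without patient data.

## Who it is for

Neuroimaging researchers combining perfusion and diffusion MRI in small
clinical cohorts (e.g. mild traumatic brain injury vs. healthy controls)
who need a reproducible, tested implementation of the full analysis chain
rather than a collection of one-off scripts.

## The models at the core

**Tri-exponential IVIM.** The diffusion signal decay over b-values is

S_b / S_0 = F_p·exp(−b·D_p) + F_f·exp(−b·D_f) + F_s·exp(−b·D_s),

with fractions on the unit simplex: a fast perfusion compartment
(F_p, D_p), an intermediate free-water compartment (F_f, D_f fixed at
3×10⁻³ mm²/s), and a slow tissue compartment (F_s, D_s). Fitting is
segmented: D_s from a log-linear fit of the b ≥ 1000 s/mm² shells, then a
bounded Levenberg–Marquardt fit of the full model with the simplex enforced
by reparameterization (F_s = 1 − F_p − F_f).

**pCASL CBF.** The single-compartment kinetic model,

CBF = 6000·λ·ΔM·e^(PLD/T1b) / (2·α·T1b·M0·(1 − e^(−τ/T1b))),

with τ = 1.8 s, PLD = 2.0 s and consensus defaults λ = 0.9 mL/g, α = 0.85,
T1b = 1.650 s.

**mCCA+jICA.** Per-modality subject × ROI matrices (CBF, F_p, F_f, F_s,
D_s, optionally a GOS-E outcome column) are z-scored, entered into RGCCA
with full inter-block connectivity and τ = 1 (covariance criterion,
unit-norm weights), three canonical components per block retained by outer
average-variance-explained (AVE) inspection; the concatenated variates are
decomposed by symmetric fixed-point logcosh ICA into independent components
with per-subject loadings — five 3-component blocks give 15 ICs, and a
rank-limited extra GOS-E block gives 16.

## Worked example

Simulate a 43-subject cohort's block matrices with three planted latent
sources (one carrying a 1-SD group effect), fuse them, and test the IC
scores between groups:

```r
library(ivimfuse)

sim    <- simulate_block_matrices(n_subjects = 43, n_sources = 3,
                                  effect_size = 1, seed = 42)
fusion <- fuse(sim$blocks, k = 3, seed = 1)
fusion
#> fusion_result: 5 blocks -> 15 variates -> 15 ICs over 43 subjects

stats <- compare_groups(as.matrix(fusion$scores[, -1]), sim$truth$group)
head(stats[order(stats$p), c("component", "t", "p", "p_fdr")], 3)
#>    component     t      p p_fdr
#> 8        IC8  2.36 0.0232 0.172
#> 6        IC6 -2.29 0.0273 0.172
#> 12      IC12  2.19 0.0344 0.172
```

IC8 separates the groups at uncorrected p = 0.023 (it carries the planted
group source; at n = 43 the effect does not survive FDR across 15
components — exactly the regime such pilot cohorts live in). The AVE table
shows how much of each modality block the canonical components explain
(percent):

```r
round(compute_ave(fusion$rgcca, sim$blocks)[, 1:5], 1)
#>        CBF  F_p  F_f  F_s  D_s
#> comp1 24.2 22.2 24.5 22.3 22.4
#> comp2 18.6 21.8 21.4 22.6 20.6
#> comp3 16.3 14.8 15.6 14.2 15.7
```

The imaging-level pipeline (phantom → DWI/ASL simulation → IVIM + CBF fits
→ ROI blocks → fusion → statistics → ICC) runs end-to-end from one
configuration:

```r
res <- run_end_to_end(default_run_config(grid_shape = c(16, 16, 8)),
                      out_dir = "demo_run")
```

which writes subject tables, IC scores, AVE and group-comparison CSVs, and
JSON run metadata; identical config + seed reproduces identical files.

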