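---
title: "Fractional motion modelling of diffusion MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional motion modelling of diffusion MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmdiff)
```

## The model

Conventional diffusion MRI summarises signal decay with the mono-exponential
model $S = S_0 e^{-b\,\mathrm{ADC}}$. Measured decay curves in brain tissue
deviate from this form, and the fractional motion (FM) framework models the
underlying water displacement as an $H$-self-similar process with
$\alpha$-stable, stationary increments. Its diffusion-weighted signal over a
pulsed-gradient spin-echo acquisition is

$$\frac{S}{S_0} = \exp\!\left(-\eta\, D_{\alpha,H}\,
\gamma^\alpha G_0^\alpha\, \Delta^{\alpha + \alpha H}\right),$$

with $\gamma$ the gyromagnetic ratio, $G_0$ the diffusion gradient
amplitude, $\Delta$ the gradient separation time, and $\eta$ a dimensionless
factor determined by $\alpha$, $H$, the pulse duration $\delta$ and
$\Delta$. The three model parameters are:

* $\alpha$ — the Noah exponent, the stability index of the increment
  distribution. $\alpha = 2$ gives Gaussian increments; $0 < \alpha < 2$
  gives heavy-tailed (Lévy) increments.
* $H$ — the Hurst exponent, the self-similarity index of the trajectory.
* $D_{\alpha,H}$ — the anomalous diffusion coefficient, in
  $\mathrm{mm}^\alpha\,\mathrm{s}^{-\alpha H}$.

The memory parameter $\mu = H - 1/\alpha$ is always derived, never
estimated independently: $\mu < 0$ indicates anti-persistent increments,
$\mu > 0$ persistent ones, and Brownian motion ($\alpha = 2$, $H = 1/2$)
gives $\mu = 0$.

### The $\eta$ factor

The FM literature defines $\eta$ through the underlying stochastic theory
without a single canonical closed form, so `fmdiff` treats it as a pluggable
strategy (`eta_model`). The default, `"narrow_pulse"`, uses the
factorisation $\eta = (\delta/\Delta)^\alpha$, under which the exponent
reduces to $D\,\gamma^\alpha G_0^\alpha \delta^\alpha \Delta^{\alpha H}$.
This choice is dimensionally consistent, and it makes the Gaussian case
exact: at $\alpha = 2$, $H = 1/2$ the FM signal coincides with the
mono-exponential model at the narrow-pulse b-value
$b = \gamma^2 G_0^2 \delta^2 \Delta$ to machine precision (a tested
invariant). Two consequences matter in practice:

1. Simulation and fitting must use the same $\eta$ strategy.
2. Absolute $D$ values are convention-dependent and comparable only within
   one $\eta$ family. $\alpha$, $H$ and $\mu$ are not affected: within
   this family $\alpha$ and $H$ enter only through the $G_0$ and $\Delta$
   exponents, which the $\eta$ choice does not alter.

At this protocol's $\delta/\Delta \approx 0.40$–$0.77$ a finite-pulse
correction could change fitted $D$; users comparing $D$ across software
should confirm the convention on both sides.

## The acquisition scheme

The default protocol (`default_scheme()`) uses three gradient separation
times (27.060, 39.560, 52.060 ms), six gradient amplitudes geometrically
spaced from 15.67 to 49.00 mT/m (`make_gradient_amplitudes()`), a fixed
pulse duration of 20.676 ms, three orthogonal gradient directions and 12
$b=0$ volumes — 66 volumes and 18 distinct non-zero b-values from about
151 to 3317 s/mm². b-values follow the Stejskal–Tanner relation
$b = \gamma^2 G_0^2 \delta^2 (\Delta - \delta/3)$ with the proton
$\gamma = 2.6752218744 \times 10^8\,\mathrm{rad\,s^{-1}\,T^{-1}}$;
recomputing the published 18-entry table reproduces every entry within
1 s/mm² after integer rounding (most exactly; a few printed entries sit on
the opposite side of a rounding boundary). Scheme files (JSON/CSV) carry
ms and mT/m, as consoles report them; all computation is in SI units, and
fitting always uses $(\Delta, G_0, \delta)$ directly rather than rounded
b-values. Volume order is fixed: $b=0$ volumes first, then weighted volumes
grouped by $\Delta$, $G_0$ ascending, direction x, y, z.

## Fitting

`fit_fm_volume()` estimates $(D, \alpha, H)$ per voxel from
direction-averaged normalised attenuations:

* $S_0$ is fixed as the arithmetic mean of the 12 $b=0$ volumes rather
  than fitted. Twelve averages give a stable estimate and leave only three
  free parameters for 18 observations.
* Directions are combined by the geometric mean of $S/S_0$ — the
  arithmetic mean of log-attenuations — which cancels multiplicative
  anisotropy between directions exactly (an arithmetic option exists via
  `fm_fit_config(direction_average = "arithmetic")`). Attenuations are
  clipped to $[10^{-6}, 1]$ before logs.
* The least-squares problem is solved in the attenuation domain by bounded
  Levenberg–Marquardt (`minpack.lm::nls.lm`) with an analytic Jacobian,
  cost tolerance $10^{-10}$ and at most 1000 iterations per start. Bounds
  are $D \in [10^{-8}, 10]$ (model units), $\alpha \in [0.5, 2]$,
  $H \in [0.05, 0.95]$ — deliberately wider than any hippocampal value
  reported in health or disease, while keeping all exponents finite.
* Multi-start: $\alpha_0 \in \{1.0, 1.5, 2.0\} \times H_0 \in
  \{0.3, 0.5, 0.7\}$, with $D_0$ per start from a Gaussian-limit
  log-linear regression. The lowest-SSE start wins; ties resolve to the
  first start in grid order, making maps bit-reproducible.

The two-point ADC uses the direction-averaged attenuation at one weighted
cell: the configuration key `adc_b_target` (default 954 s/mm²) selects the
cell whose b-value is nearest the target — ties towards the lower b — and
the cell's actual b enters $\mathrm{ADC} = \ln(S_{b0}/S_b)/b$. The default
grid contains no cell at exactly 954 s/mm² (the nearest are 939 and 964,
and 964 is selected); anchoring on a target rather than a hard-coded index
keeps the definition meaningful for any scheme. Voxels with non-positive
$S_0$ or fewer than three usable cells are flagged unfittable and recorded
as NaN, which survives NIfTI round-trips.

## The synthetic cohort generator

`generate_cohort()` builds the desk-scale stand-in for a clinical cohort;
its defaults *are* the study conditions everywhere in the test-suite:

* Three groups — 11 healthy controls, 12 mild AD, 12 moderate AD — with
  per-hemisphere $\alpha$, $H$ and ADC means/SDs, ages, and MMSE/MoCA
  distributions taken from the published group summary table
  (`reference_cohort_spec()`). Parameters are drawn from truncated normal
  distributions (summaries report mean ± SD only, and normality is the
  parsimonious completion); truncation keeps draws inside the legal
  parameter ranges. Between-parameter correlation is zero except the
  score–$\alpha$ coupling below. $\mu$ is computed, never sampled.
* Cognitive scores are linear in the subject's standardised bilateral mean
  $\alpha$ plus Gaussian noise, calibrated so the population correlation
  equals the target (default $r = 0.45$ — the source study reports a
  significant positive $\alpha$–score correlation without printing its
  magnitude, so this is a modelling choice, not a published value). Scores
  are truncated to the 0–30 scale range. The printed mild-AD MMSE SD
  (11.27) is used as printed even though it is plausibly a misprint of
  1.27; truncation keeps the resulting scores on-scale. MoCA was not
  collected for controls and is generated as `NA` there; correlation
  analyses run within patients only, so this never propagates.
* Each subject's $D$ is calibrated so the FM attenuation at the scheme's
  median-b cell equals $e^{-b\,\mathrm{ADC}}$ with the subject's ADC
  (`calibrate_D_from_adc()`), keeping phantom signal levels realistic.
* Phantoms are abstract blocks, not anatomy: a 16×16×4 volume with two
  disjoint 3×3×2 ROIs at S0 = 1000, background at 10% of S0, and Rician
  noise $|S + n_1 + i n_2|$ with $\sigma = S_0/\mathrm{SNR}$
  per channel. SNR defaults to 50, a typical 3 T echo-planar regime.
  The nominal voxel spacing written to NIfTI is 1.875×1.875×5 mm; it plays
  no computational role.
* Reproducibility: one master seed drives covariate sampling; each
  subject's phantom uses a stream derived deterministically from
  (seed, subject index), so per-subject volumes do not depend on how many
  subjects precede them being rendered.

What the phantoms deliberately omit: partial-volume mixtures, anatomical
geometry, EPI distortion/ghosting, motion, and between-parameter
correlations beyond the score coupling. Passing recovery tests therefore
demonstrates estimator correctness under the stated noise model, not
robustness to acquisition artefacts in real data.

## Statistics

`run_group_analysis()` reproduces the group-study battery on a subject
table:

* **t-tests** — pooled-variance Student's test by default (the published
  analysis says only "two-sample t-test", and its printed left-$\alpha$
  p-value is closest to the pooled form recomputed from the group
  summaries); Welch via `ttest_variant = "welch"`. Patients vs controls
  and moderate vs mild, per parameter and hemisphere (16 tests).
  `ttest_from_summary()` runs the same formulas from sufficient statistics,
  and `pool_summaries()` merges two subgroups' (mean, SD, n) exactly so a
  combined patient group can be tested from printed rows alone.
* **ROC** — empirical curve with ties treated as one threshold step, AUC
  equal to the Mann–Whitney concordance (0.5 per tie), orientation chosen
  so AUC ≥ 0.5 and reported. The Youden threshold maximises
  $J = \mathrm{sens} + \mathrm{spec} - 1$ over midpoints between adjacent
  distinct scores plus $\pm\infty$, calling disease when the oriented
  score is ≥ the cut; ties resolve to the smallest threshold.
* **Marker combination** — the linear predictor of an unregularised
  maximum-likelihood logistic regression (intercept, 100 iterations,
  tolerance $10^{-8}$); the published study combines markers without
  naming a rule, and the logistic score is the standard choice for
  continuous diagnostic markers. Under perfect separation, where the ML
  optimum diverges, the score falls back to a ridge-stabilised direction
  (penalty $10^{-6}$) with a warning. Combinations reported:
  $\alpha+\mathrm{ADC}$ and $\alpha+\mathrm{ADC}+H+\mu$.
* **Partial correlation** — Pearson correlation of the residuals after
  regressing each variable on the covariates (age by default, the
  published adjustment), $p$ from
  $t = r\sqrt{(n-2-k)/(1-r^2)}$.
* **FDR** — Benjamini–Hochberg over the family of 16 correlation tests
  (4 parameters × 2 hemispheres × 2 scales), computed within patients;
  group comparisons are reported with raw p, mirroring the published
  analysis. Implemented via `stats::p.adjust`.

Reports are deterministic and invariant to subject order (the table is
sorted by subject id internally).

## Numerical choices and degenerate inputs

The forward-model exponent is evaluated in log space,
$E = D\,e^{\alpha a + \alpha H b}$ with per-cell constants
$a = \log(\gamma_{\mathrm{mm}} G_0 \delta)$, $b = \log\Delta$, so extreme
$(\alpha, H)$ never overflow; $\gamma_{\mathrm{mm}} = \gamma \times 10^{-3}$
puts $D$ in millimetre units, where the Gaussian-limit $D$ is an ADC in
mm²/s. Constant signals fit to $D$ at its lower bound with zero SSE.
Zero-variance t-tests return $p = 1$ when means agree. Empty masks produce
maps defined nowhere and a zero fitted-voxel count. Scheme files are
validated on read, including consistency of stored b-values with the
stored timing.

## Problem sizes in the test-suite

The packaged checks run at desk scale, chosen to exercise every code path
with comfortable statistical margins: noiseless round-trips to 0.1%,
a 500-voxel Rician recovery study at SNR 50 (observed median absolute
errors ≈ 0.02 for both $\alpha$ and $H$, against a 0.05 acceptance bound),
a 20-seed cohort study of fitted group ordering restricted to the left ROI
(18 voxels per subject), and 200 null cohorts for type-I calibration of
the t-test battery. Larger sizes change none of the conclusions, only the
precision of the stochastic checks.

## Known limitations

* The $\eta$ convention caveat above: fitted $D$ is not comparable across
  conventions.
* The FM fit assumes isotropy after direction averaging; tensor-level
  anisotropy is out of scope.
* ADC from two points inherits the FM/mono-exponential model mismatch
  when the underlying decay is not mono-exponential; on FM phantoms the
  fitted ADC therefore deviates slightly from the generating ADC (the
  calibration cell and the ADC cell differ).
* The generator emulates group summaries, not subject-level data; printed
  patient-level AUCs and thresholds from any particular clinical sample
  are not recoverable from summaries and are not targets of the
  test-suite.
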