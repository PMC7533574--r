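# fmdiff

Fractional-motion (FM) modelling of diffusion-weighted MRI, with the full
group-discrimination workflow used in clinical anomalous-diffusion studies
of the hippocampus.

Conventional diffusion MRI summarises signal decay with the
mono-exponential model `S = S0·exp(−b·ADC)`, but measured decay in brain
tissue deviates from that form. The FM framework instead models water
displacement as an *H*-self-similar process with α-stable, stationary
increments, giving the signal

```
S/S0 = exp( −η · D_{α,H} · γ^α · G0^α · Δ^(α + αH) )
```

over a pulsed-gradient spin-echo acquisition with gradient amplitude `G0`,
separation `Δ`, pulse duration `δ` and gyromagnetic ratio `γ`; `η` is a
dimensionless timing factor. The Noah exponent α (α = 2: Gaussian
increments; α < 2: heavy-tailed), the Hurst exponent *H*, and the derived
memory parameter `μ = H − 1/α` characterise the tissue's anomalous
diffusion; α in particular falls with the loss of microstructural
complexity in neurodegeneration, which makes it a candidate imaging marker
for identifying and grading Alzheimer's disease.

`fmdiff` provides, for researchers evaluating anomalous-diffusion markers:

- **Acquisition schemes** — multi-(Δ, G0) Stejskal–Tanner protocols with
  derived b-values (`build_scheme()`, `default_scheme()`,
  `make_gradient_amplitudes()`), JSON/CSV scheme files and FSL-style
  bval/bvec export.
- **The FM forward model** and the mono-exponential comparison model
  (`fm_signal()`, `mono_exp_signal()`, `memory_parameter()`).
- **Voxelwise fitting** — bounded multi-start nonlinear least squares for
  (D, α, H) maps plus the two-point ADC (`fit_fm_volume()`), on NIfTI
  volumes or in-memory arrays.
- **Synthetic cohorts** — digital phantoms with Rician noise emulating a
  published three-group hippocampal study (11 controls, 12 mild AD,
  12 moderate AD), for end-to-end testing without any data download
  (`generate_cohort()`).
- **Statistics** — two-sample t-tests (raw or from printed summaries),
  ROC/AUC with Youden thresholds, logistic marker combination, Pearson
  partial correlation adjusting for age, and Benjamini–Hochberg FDR
  (`run_group_analysis()`).

## Worked example

Simulate the reference cohort, fit every subject's hippocampal ROIs, and
run the group analysis:

```r
library(fmdiff)

sch <- default_scheme()
sch
#> <fm_scheme> 54 weighted volumes (18 distinct b), 12 b0 volumes
#>   gamma = 2.67522e+08 rad/s/T, delta = 20.68 ms
#>   b range: 152 - 3318 s/mm^2

round(memory_parameter(1.588, 0.464), 3)   # healthy-control left-hippocampus mu
#> [1] -0.166

cohort <- generate_cohort(snr = 50, seed = 42)
cohort
#> <fm_cohort> 35 subjects (controls: 11, mild_AD: 12, moderate_AD: 12), seed 42, with phantoms

tab <- fit_cohort(cohort)             # voxelwise FM + ADC fits, ROI means
rep <- run_group_analysis(tab)

subset(rep$ttests, measure %in% c("alpha_left", "adc_left"))
#>            contrast    measure statistic df        p
#> 1     AD_vs_control alpha_left     -5.78 33 1.86e-06
#> 4     AD_vs_control   adc_left      2.07 33 4.62e-02
#> 9  moderate_vs_mild alpha_left     -3.27 22 3.47e-03
#> 12 moderate_vs_mild   adc_left      3.37 22 2.74e-03
```

Fitted hippocampal α is lower in patients than controls (negative t) and
lower again in moderate than mild disease, while ADC rises — the expected
direction for progressive loss of tissue complexity. ROC analysis on the
same table shows α discriminating patients from controls and the logistic
α + ADC combination doing at least as well as either marker alone:

```r
subset(rep$roc, contrast == "AD_vs_control" & roi == "left")[,
       c("markers", "auc", "threshold", "sensitivity", "specificity")]
#>              markers   auc threshold sensitivity specificity
#> 1              alpha 0.947   1.56806       0.875       0.909
#> 2                adc 0.712   0.00106       0.667       0.818
#> 3          alpha+adc 0.955        NA       0.917       0.909
#> 4 alpha+adc+hurst+mu 0.958        NA       0.917       0.909
```

The single-marker `threshold` is the Youden-optimal cut in marker units
(here: call disease when α ≤ 1.568). Partial correlations (age-adjusted,
within patients) recover the simulated positive α–cognition coupling, with
BH-adjusted q-values over the 16-test correlation family:

```r
head(rep$correlations[rep$correlations$measure %in%
                      c("alpha_left", "alpha_right"), ], 4)
#>    scale     measure     r       p df  n      q
#> 1   mmse  alpha_left 0.240 0.27008 21 24 0.4321
#> 5   mmse alpha_right 0.615 0.00177 21 24 0.0284
#> 9   moca  alpha_left 0.582 0.00357 21 24 0.0286
#> 13  moca alpha_right 0.540 0.00780 21 24 0.0416
```

The same pipeline is scriptable from a shell via the thin CLI in
`inst/scripts/fmdiff` (`simulate`, `fit`, `roistats`, `stats`), each stage
writing a manifest with its configuration, seed and input checksums.

See the vignette (`vignettes/fractional-motion-dmri.Rmd`) for the model's
assumptions, the η convention, fitting and generator design choices, and
known limitations.

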