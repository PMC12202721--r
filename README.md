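# cmsgr — renal corticomedullary sodium gradient from ²³Na MRI

Sodium (²³Na) MRI can measure how tissue sodium concentration rises from
the renal cortex toward the medulla. The slope of that rise — the
**corticomedullary sodium gradient (CMSG)**, in mM/mm — reflects the
kidney's concentrating work and is a candidate functional biomarker for
kidney disease. `cmsgr` implements the full quantification chain for
radiologists' and physicists' workflows:

1. **aTSC mapping.** The sodium signal volume is corrected by the surface
   coil's normalized sensitivity profile, voxels under 10% of the maximum
   intensity are excluded, the mean signal of agarose reference tubes
   (50/75/100/125 mM) is regressed on concentration, and the apparent
   tissue sodium concentration map is computed as

   aTSC(x) = c · S(x) / m,

   where `m` is the calibration slope (signal/mM) and
   c = c(agarose)/c(kidney) compensates relaxation differences, with

   c(a/k) = (1 − e^(−TR/T₁)) · [ f·e^(−TE/T₂ₛ\*) + (1−f)·e^(−TE/T₂ₗ\*) ]

   under mono-exponential T₁ recovery and bi-exponential T₂\* decay
   (defaults: f = 0.6; kidney T₁ = 34.0 ms, T₂ₛ\*/T₂ₗ\* = 2.2/20.4 ms;
   agarose T₁ = 38.5 ms, T₂ₛ\*/T₂ₗ\* = 6.0/13.0 ms; TR = 60 ms,
   TE = 0.3 ms).

2. **Segmentation** of the renal parenchyma on one coronal slice, two ways:
   **TLCO** (twelve-layer concentric objects) — an exact Euclidean distance
   transform splits the parenchyma mask into 12 concentric depth layers —
   and the **Line method** — a drawn corticomedullary line sampled as a
   3 × 3-sample band spanning 9 mm transversally, one in-plane pixel per
   step.

3. **Gradient regression.** Either path yields a depth profile (mean aTSC
   vs. distance from the cortex). `cmsg()` truncates it at its aTSC maximum
   and fits ordinary least squares; the slope is the CMSG.

4. **Reader agreement.** `agreement_report()` computes Lin's CCC, ICC(3,1)
   and Pearson's r with Fisher-z 95% CIs and qualitative bands, plus
   Bland–Altman bias/limits of agreement, CV, paired t and one-way ANOVA.

Because no public dataset accompanies this methodology, `make_phantom()`
generates complete synthetic studies — kidney slab with a known linear
gradient (defaults: 137.2 mM cortex → 202.3 mM medullary peak, 7.0 mM/mm),
reference tubes, decaying coil sensitivity, Rician noise calibrated to
medullary SNR ≈ 12 — so the whole pipeline is testable against ground
truth.

## Worked example

```r
library(cmsgr)

study <- make_phantom(phantom_spec(), seed = 7)   # noisy synthetic study
res   <- run_quantify(run_config(study = study))
res
#> CMSG quantification run
#>   calibration: m = 2.025 signal/mM (r^2 = 0.9998), c = 0.9983
#>   medullary SNR: 11.93
#>   TLCO: CMSG 6.39 mM/mm over 9.7 mm (r^2 = 0.998)
#>   Line: CMSG 6.47 mM/mm over 10.0 mm (r^2 = 0.929)
#>   ground truth: 7.00 mM/mm

summary(res$tlco)
#> Corticomedullary sodium gradient (TLCO method)
#>   CMSG:      6.385 mM/mm
#>   intercept: 132.8 mM
#>   r^2:       0.9979
#>   evaluated distance: 9.714 mm over 9 points
#>   slope std. error: 0.1103 mM/mm
```

The calibration recovered the true slope (2.0 signal/mM) from the four
tubes; the relaxation correction is ≈1 because agarose and kidney nearly
cancel at this TR/TE; both segmentation methods estimate the 7.0 mM/mm
ground-truth gradient to within ~9% at SNR 12, with the expected
truncation at the ~9.3 mm concentration peak. `plot(res$tlco)` draws the
depth profile with the fitted line and truncation point.

A thin CLI wraps the same functions
(`inst/cli/cmsg.R simulate | all | agreement`), writing NIfTI
intermediates, per-layer/profile CSV tables and a results + provenance
JSON.

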