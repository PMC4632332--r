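# liverfcm

R2\* relaxometry of the liver with fuzzy c-means vessel segmentation, for
MRI-based liver iron concentration (LIC) assessment in iron-overloaded
(e.g. thalassemia major) patients.

## What it does, and for whom

Multi-echo gradient-echo liver MRI measures the effective transverse
relaxation rate R2\* = 1/T2\*, which biopsy calibration maps linearly to
LIC (mg per g dry weight). The ROI of a mid-hepatic slice inevitably
contains blood vessels: slow-decaying, low-LIC outliers that inflate the
spread of the pixel-wise LIC distribution — worst at severe overload,
exactly where precise chelation monitoring matters most. This package is
for image-analysis researchers and MR physicists who need:

* **Pixel-wise C-EXP fitting** — `S(TE) = S0·exp(−TE·R2*/1000) + C`,
  bounded Levenberg–Marquardt, no echo truncation (the offset `C` absorbs
  the noise floor), plus linear R2\*→LIC calibration and clinical band
  classification (normal/mild/moderate/severe at 3/7/15 mg/g dw).
* **FCM vessel/parenchyma segmentation** — standard fuzzy c-means
  (`C = 2`, `m = 2`) minimising
  `J_m = Σ_i Σ_j u_ij^m ‖x_j − v_i‖²` subject to `Σ_i u_ij = 1`, on either
  the acquired intensity of one echo (1D-FCM) or intensity + LIC
  (2D-FCM), with membership-threshold defuzzification.
* **Parameter-selection schemes** — OP (exhaustive 20 echoes × 50
  thresholds per mode, scored against a manual reference), SA
  (echo fixed automatically at the maximum signal-range-to-noise ratio,
  threshold picked by the user from an exported gallery), and MIX (the
  better of 1D and 2D).
* **Evaluation metrics** — per-class dice accuracy
  `TSA(%) = 2·N_cs·100/(N_ts + N_tr)`, the combined error
  `D_TSA(%) = √((100−TSA_par)² + (100−TSA_ves)²)`, robust LIC summaries
  (median, quartiles, `nIQR(%) = (Q3−Q1)·100/median`), and agreement CV.
* **A seedable synthetic phantom** — elliptical liver, circular plus
  branching vessels, coil bias field, partial volume, severity-coupled
  vessel blooming, noise — so the whole pipeline is testable without
  patient data.

See `vignettes/liverfcm-methods.Rmd` for the model details and design
rationale.

## Worked example

```r
library(liverfcm)

ph  <- generate_phantom(phantom_config(shape = c(64, 64),
                                       lic_level = "severe", seed = 42))
r2  <- fit_r2star_map(ph$stack, ph$roi)
lic <- r2star_to_lic(r2)                      # default biopsy calibration
op  <- op_search(ph$stack, lic, ph$roi, ph$truth)
op
lic_summary(lic, op$mix$mask, "parenchyma")
lic_summary(lic, klass = "roi-all")
```

prints

```
OP scheme search:
1D-FCM [OP]: TE 2 (1.87 ms), u0 0.46, D_TSA 6.92%
2D-FCM [OP]: TE 3 (2.67 ms), u0 0.58, D_TSA 3.81%
MIX-FCM [OP]: TE 3 (2.67 ms), u0 0.58, D_TSA 3.81%
LIC summary (1257 px): median 27.76 [Q1 24.52, Q3 31.94] mg/g dw, nIQR 26.7%, severe
LIC summary (1456 px): median 26.74 [Q1 22.32, Q3 31.02] mg/g dw, nIQR 32.5%, severe
```

Reading this: on a severe-overload phantom the best exhaustive 1D
(intensity-only) segmentation leaves a 6.9 % combined error while adding
the LIC feature halves it — the severe-band regime where the bias-immune
LIC feature pays off; MIX keeps the better result. Excluding the
segmented vessels leaves the LIC median nearly unchanged (26.7 → 27.8,
the median is robust) but cuts nIQR from 32.5 % to 26.7 % — the precision
gain vessel segmentation exists for. `sa_run()` runs the semi-automatic
scheme the same way; with `selection = "reference-auto"` it emulates the
user's threshold pick so it can be compared against OP.

## Command line

A thin CLI wraps the same functions:

```sh
liverfcm phantom --out study/ --level severe --seed 7
liverfcm fit     --stack study/stack.nii.gz --tes study/tes.yaml --roi study/roi.nii.gz --out fit/
liverfcm op      --stack ... --tes ... --roi ... --ref manual.nii.gz --out op/
liverfcm sa      --stack ... --tes ... --roi ... --out sa/ --choose 2D:31
liverfcm metrics --pred op/mask_mix.nii.gz --ref manual.nii.gz
```

Outputs are NIfTI label maps (0 outside, 1 parenchyma, 2 vessel), a JSON
report with the configuration echo, a per-candidate CSV, and (for SA) a
100-panel PNG threshold gallery. Exit codes: 0 success, 2 input error,
3 degenerate computation.

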