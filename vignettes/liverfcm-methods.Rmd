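---
title: "Methods: R2* liver iron mapping and fuzzy c-means vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: R2* liver iron mapping and fuzzy c-means vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverfcm)
```

## The measurement problem

Transfusion-dependent anemias such as thalassemia major cause progressive
iron loading of the liver. The clinical quantity of interest is the liver
iron concentration (LIC, mg per g dry weight), which at 1.5 T can be read
out non-invasively from the effective transverse relaxation rate R2\* =
1/T2\* of liver tissue: iron shortens T2\*, and biopsy calibration studies
established an approximately linear R2\*–LIC relationship. The acquisition
is a breath-hold multi-echo gradient-recalled-echo sequence of a mid-hepatic
slice; this package assumes the common 20-echo protocol with echo times
1.07 ms to 16.27 ms in 0.8 ms steps (`default_te_grid()`).

A practical nuisance is that the liver cross-section contains blood
vessels. Blood decays far more slowly than iron-loaded parenchyma, so
vessel pixels are strong low-LIC outliers inside the region of interest
(ROI). The pixel-wise LIC *median* is robust to them, but the spread
statistics that quantify measurement precision are not: the interquartile
range is inflated, most severely at high iron burden where the
vessel–parenchyma contrast is largest. The package therefore implements a
posteriori vessel/parenchyma segmentation by fuzzy c-means (FCM)
clustering, together with the parameter-selection schemes and evaluation
metrics needed to use and assess it.

## Pixel-wise relaxometry

Each pixel's echo train is fitted with the constant-offset
mono-exponential (C-EXP) model

$$S(TE) = S_0\, e^{-TE \cdot R_2^*/1000} + C,$$

with TE in milliseconds and R2\* in s^-1 (hence the factor 1000). The
offset $C$ absorbs the magnitude-image noise floor, so no echoes are
truncated from the fit. Fitting is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) with $R_2^* \ge 0$, at most 500 iterations and
convergence tolerances of 1e-8. Initialisation is deterministic:
$S_0 = \max S - \min S$, $C = \min S$, and R2\* from a log-linear fit of
the offset-corrected first half of the train. A constant signal carries no
decay information and is flagged invalid; invalid pixels are excluded from
all downstream statistics (the choice to exclude rather than impute is
deliberate and documented here).

R2\* maps are converted to LIC maps with a linear biopsy calibration,
`lic_calibration(slope = 0.0254, intercept = 0.202)` by default. The
coefficients are site-configurable — they are a calibration convention,
not a property of this method — and every report echoes the values used.
Overload severity bands are left-closed: LIC < 3 normal, [3, 7) mild,
[7, 15) moderate, ≥ 15 severe (mg/g dw). The bands are quoted clinically
with strict inequalities, which leaves the boundary points unassigned;
closing them on the left makes classification total without changing any
interior value.

## Fuzzy c-means segmentation

FCM partitions the $n$ ROI pixels into $C$ clusters by minimising

$$J_m(u, v) = \sum_{i=1}^{C}\sum_{j=1}^{n} u_{ij}^m\,
  \lVert x_j - v_i\rVert^2, \qquad \sum_i u_{ij} = 1,\; u_{ij}\in[0,1],$$

with the standard alternating updates (memberships from inverse squared
distances with exponent $1/(m-1)$, centroids as $u^m$-weighted means). The
segmentation task uses $C = 2$ (parenchyma, vessel) and the customary
fuzzifier $m = 2$.

Two feature spaces are supported:

* **1D-FCM** — the acquired intensity (AI) of one echo image;
* **2D-FCM** — that intensity plus the pixel's LIC value.

Each feature is min–max normalised to [0, 1] over the ROI so both enter
the Euclidean distance on a common, scale-free footing. The rationale for
the 2D mode is that a smooth multiplicative coil bias field corrupts
intensities but cancels in the exponential decay *rate*: the LIC map is
bias-immune, so it can rescue clustering exactly where the intensity
feature fails.

Numerical choices, all deterministic:

* **Seeding.** Centroids are seeded by the maximin rule: the data point
  farthest from the feature-space mean, then the point farthest from the
  seeds chosen so far. Quantile-based "diagonal" seeding (both centroids
  on the low/high corner of every feature) was rejected because the 2D
  intensity/LIC cloud is anti-correlated — bright pixels are low-LIC — and
  a diagonal start is exactly symmetric to it, collapsing both centroids
  onto the grand mean.
* **Zero distances.** A point coinciding with a centroid gets membership
  1 there (split evenly if on several), the standard FCM convention.
* **Convergence.** Maximum centroid displacement below 1e-6, cap of 300
  iterations. The objective trace is recorded and asserted non-increasing
  to 1e-9 in the tests.
* **Degeneracy.** A constant feature (min = max) or coincident final
  centroids raise a distinct degenerate-computation condition, which the
  command-line interface maps to exit code 3 (input errors give 2).

Hard masks come from *defuzzification*: with vessel-cluster membership
$u_v$ and threshold $u_0$, a pixel is vessel iff $u_v \ge u_0$ (ties go to
vessel), every other ROI pixel parenchyma — so the two classes always
partition the ROI, and raising $u_0$ can only shrink the vessel mask. The
vessel cluster itself is identified structurally: lower LIC centroid in 2D
mode, higher intensity centroid in 1D mode.

## Parameter-selection schemes

An FCM segmentation depends on two inputs: which echo supplies the
intensity feature, and the threshold $u_0$. Three schemes are implemented.

* **OP (optimal)** — exhaustive: all 20 echoes × 50 thresholds
  ($u_0 \in \{0, 0.02, \dots, 0.98\}$) = 1,000 candidates per FCM mode,
  each scored against a manual reference segmentation; the minimum-error
  candidate wins. Ties break towards the lower echo index, then the lower
  threshold. OP is defined only relative to a reference mask and serves
  as the best-achievable benchmark; calling it without a reference is an
  error by design.
* **SA (semi-automatic)** — the echo is chosen automatically as the
  argmax of the per-echo signal-range-to-noise ratio RNR = (max − min of
  ROI signal)/noise SD; the user then picks one of the 50 thresholds per
  mode from an exported gallery. Noise SD is estimated per echo from the
  pooled SD of four 8×8 corner patches (assumed signal-free background);
  a user-supplied noise mask can replace this. For testing, a
  `reference-auto` mode emulates the user by picking the minimum-error
  candidate, which makes SA directly comparable to OP: since SA searches
  a subset of OP's grid, SA error is bounded below by OP error study-wise.
* **MIX** — keeps whichever of the 1D and 2D outcomes has the lower
  error; with an exact tie the 1D result (simpler input) is kept.

## Evaluation metrics

Segmentation accuracy per class is the dice coefficient in percent,

$$TSA(\%) = \frac{2 N_{cs} \cdot 100}{N_{ts} + N_{tr}},$$

defined as 100 when both masks are empty (agreement on absence — a
convention, logged here). Both classes combine into the distance from the
perfect corner,

$$D_{TSA}(\%) = \sqrt{(100 - TSA_{parenchyma})^2 + (100 - TSA_{vessels})^2},$$

which is 0 exactly for a perfect segmentation and decreases monotonically
in either TSA.

LIC variability is summarised by the normalised interquartile range

$$nIQR(\%) = \frac{(Q_3 - Q_1)\cdot 100}{\mathrm{median}},$$

computed with linearly interpolated quartiles (R's default type 7; the
convention matters only in the third decimal at realistic pixel counts).
nIQR is scale-invariant and undefined for a zero median (an error, not a
silent NaN). Agreement between two paired series is reported as
$1.96\,\mathrm{SD}(a-b)/\overline{(a,b)} \times 100$ with the bias
$\overline{a-b}$ alongside, using the sample (n−1) SD — reporting both
makes either reading of the conventional "mean ± 1.96 SD over the mean"
phrasing recoverable.

## The synthetic phantom

Patient studies cannot ship with a package, so all pipeline-level claims
are exercised on a seedable synthetic phantom (`generate_phantom()`,
`generate_cohort()`). One study is an elliptical liver cross-section on a
128×128 grid (tests and the acceptance script use 64×64 and 48×48 to keep
runtimes in seconds) containing circular vessels plus one branching
polyline-dilated structure (to exercise non-convex masks), imaged through
the forward model

$$S_e = b \cdot S_0 \cdot e^{-TE_e\, R_2^{*,\mathrm{app}}/1000}
  \;(\ast\, G_\sigma) \;+\; \text{noise},$$

where $b$ is a smooth multiplicative bias field (two random-phase cosine
modes), $G_\sigma$ a Gaussian point-spread blur modelling finite
resolution, and the noise either folded Gaussian or two-channel Rician
magnitude noise. Parenchyma R2\* is set so the true median LIC falls
inside the requested overload band, with 15 % smooth spatial
heterogeneity.

Three ingredients beyond plain geometry turned out to be essential for
the phantom to show the failure modes the method exists to fix — a
piecewise-constant phantom is exactly thresholdable at some echo, which
would make intensity-only clustering spuriously perfect at every severity:

* **Per-vessel amplitude jitter** (default ±20 %): inflow and flow-state
  differences make vessel brightness vary between structures, so no
  single intensity threshold cuts all vessels at their true boundary.
* **Partial volume** (blur σ = 0.6 px): vessel-edge pixels are mixtures;
  their C-EXP fit is dominated by the slow component, which biases edge
  R2\* towards the vessel value and gives the 2D mode a realistic,
  band-independent handicap at vessel rims.
* **Susceptibility blooming**: each vessel's apparent R2\* is
  $30 + \kappa \max(0, R_2^{*,par} - 250)$ s^-1, $\kappa \in [0.25,
  0.55]$ per structure. Field gradients from heavily iron-loaded tissue
  extend into adjacent lumen, so vessel conspicuity falls as overload
  rises, while at mild overload vessels remain pure slow-decaying blood.
  This single mechanism reproduces both documented regimes: at severe
  overload the intensity feature degrades (vessels themselves decay,
  brightness spreads) while the LIC feature keeps a large margin, so
  2D-FCM beats 1D-FCM; at mild overload the intensity contrast is clean
  but the vessel–parenchyma LIC contrast is small relative to fit noise
  and partial-volume bias, and the ordering reverses. The MIX scheme
  dominates both by construction.

The default acquisition profile (bias amplitude ±45 %, noise SD 30 at
$S_0 = 1000$, i.e. first-echo SNR ≈ 33) represents an unnormalised
surface-coil acquisition; with it, a 30-study design pilot gave mild-band
mean OP errors of ~0.5 % (1D) vs ~5.4 % (2D) and severe-band ~5.0 % (1D)
vs ~3.3 % (2D), magnitudes in line with clinical experience at mild
overload. The defaults were frozen at that point.

Because D_TSA is heavy-tailed (most studies near zero, occasional large
failures), the band-wise *mean* over a 10-study draw is itself noisy:
the severe-band 2D-over-1D advantage held in 10 of 10 independent
10-study severe cohorts during design verification, but an individual
small cohort can reverse it by sampling luck. The cohort regression test
therefore fixes its seed, as any simulation-based regression test must.

What the phantom does **not** emulate: respiratory/motion ghosting,
anatomically realistic vessel trees and liver shape, diffuse or focal
liver disease, fat–water chemical shift, and the full severity of
in-vivo intensity-clustering failures (clinical severe-band 1D errors are
reported several times larger than the phantom's). Passing the cohort
tests therefore demonstrates that the implementation responds to bias,
noise, partial volume and severity-dependent contrast exactly as the
method predicts — not that the numeric error levels transfer to patients.

A note on fit bias: with magnitude noise, severe-band R2\* fits read
~10 % high (the noise floor curls the decay tail upward and the offset
cannot absorb it completely at SNR 33). The phantom guarantees the *true*
median LIC sits in the configured band; the fitted median can overshoot
at the top band, which is physics, not a generator defect.

## Problem sizes and runtime

The test-suite and acceptance-script sizes are chosen so the whole
pipeline stays in the tens of seconds on one CPU: unit fixtures are 32–48
px phantoms, the full OP-grid demonstration runs one 128×128 study
(~5,900 ROI pixels, 2,000 scored candidates), and the cohort regression
uses 30 studies at 64×64 (10 per band). Larger grids change nothing
structurally; the per-study cost is dominated by the pixel-wise C-EXP
fits and scales linearly in ROI pixels.

## Worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_config(shape = c(64, 64),
                                      lic_level = "severe", seed = 42))
r2 <- fit_r2star_map(ph$stack, ph$roi)
lic <- r2star_to_lic(r2)
op <- op_search(ph$stack, lic, ph$roi, ph$truth)
op$mix
lic_summary(lic, op$mix$mask, "parenchyma")
lic_summary(lic, klass = "roi-all")
```
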