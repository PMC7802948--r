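---
title: "Quantitative diaphragm ultrasound and muscle physiology: methods"
author: "diaphragmUS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative diaphragm ultrasound and muscle physiology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaphragmUS)
```

# Scope

`diaphragmUS` implements the quantitative readouts used to follow
respiratory-muscle involvement in dystrophic (*mdx*) mouse studies:

1. **Echodensity** — mean grayscale pixel intensity of an outlined
   diaphragm region on B-mode stills, with per-animal averaging over
   repeated frames and group percent differences.
2. **Abdominal-wall (AW) attenuation** — a per-column edge analysis of the
   superficial hyperechoic band that tests whether a thicker abdominal wall
   shades the tissue beneath it, which would confound echodensity.
3. **M-mode amplitude** — per-inspiration baseline-to-peak diaphragm
   excursion from a digitised position-versus-time trace.
4. **Ex vivo physiology** — specific twitch/tetanic force of isolated
   diaphragm strips, eccentric-contraction force decay, recovery and
   stiffness, and longitudinal percent changes.
5. **Statistics** — one-way ANOVA with Bonferroni post hoc comparisons,
   classical unpaired t, a variance-ratio + t operator-agreement check, and
   Pearson correlations with OLS fits.

Because raw study images and recordings are rarely shared, the package
ships first-class synthetic generators with known ground truth so that
every estimator has a recovery test.

# Image model and preprocessing

Frames are numeric matrices wrapped in `UltrasoundFrame`: row 1 is the
shallowest depth, and coordinates are 1-based with inclusive bounds (the R
matrix convention). `loadFrame()` collapses RGB(A) exports to one channel
with BT.709 luminance weights (0.2126, 0.7152, 0.0722), rounding half-up to
the 8-bit scale. For gray-on-gray ultrasound exports any constant weight
set gives identical results; the weights are a package constant rather than
a user knob.

`normalizeFrame()` divides by the *frame's own maximum*, so the brightest
pixel becomes exactly 1. Dividing by the theoretical maximum 255 instead
would make the attenuation analysis sensitive to per-frame gain; per-frame
normalization is the interpretation adopted here, and the choice only
rescales intensities inside one frame, leaving the below/AW intensity
*ratio* unchanged either way (the ratio is invariant to global rescaling,
a property the test suite checks).

Echodensity is deliberately computed on the raw 0-255 scale — the scale on
which group means such as 88 versus 113 are conventionally reported — while
the attenuation analysis runs on normalized frames. Outlined regions are
supplied as masks or polygons (even-odd fill); automatic diaphragm
segmentation is out of scope. ROIs are drawn at near-constant size (4514
pixels by default); the pipeline warns, rather than fails, when a mask
deviates by more than 2%, because hand-drawn regions legitimately vary by a
few pixels. The per-animal value is the unweighted mean of per-frame means
(4 frames of one acquisition by convention): frames are the experimental
replicates, so a pixel-weighted pooled mean would silently favour larger
outlines.

# The abdominal-wall attenuation analysis

Per image: normalize, Gaussian blur (`blurSigma`, default 1 px), Canny edge
detection, then scan each pixel column top-down. The first (shallowest)
pair of consecutive edge rows separated by strictly more than 5 and
strictly fewer than 50 pixels is taken as the AW band — the most
superficial bright layer — and deeper pairs are ignored. For an accepted
column with edges `(top, bottom)`:

* `aw_thickness = bottom - top` pixels,
* `aw_mean_pi` = mean normalized intensity over the half-open row range
  `[top, bottom)`,
* `below_aw_pi` = mean over the 50 pixels `[bottom, bottom + 50)`,
* `ratio = below_aw_pi / aw_mean_pi`.

Columns with no qualifying pair, or with fewer than 50 pixels left under
the band, are excluded and counted in the per-image report. All accepted
columns are pooled into one data frame; the Pearson correlation *r* between
thickness and ratio and the determination coefficient of the OLS fit of
ratio on thickness summarise whether a thicker wall attenuates the signal
below (for the simple linear fit R² = r², enforced to 1e-12).

Metrics are always read from the *normalized, un-blurred* pixels: blurring
is part of edge detection only, so the intensity summaries are not
contaminated by smoothing.

## Canny details and numerical choices

No installed R package provides Canny edge detection, and the per-column
analysis is the core algorithm here, so the detector is implemented in the
package: separable Gaussian smoothing (symmetric/reflect boundaries, kernel
radius 3 sigma), Sobel gradients scaled so a unit step has magnitude about
1, non-maximum suppression over four quantised gradient directions, and
double-threshold hysteresis with 8-connected linking. Three choices matter
in practice:

* **Thresholds are fractions of the maximum gradient magnitude** (defaults
  low 0.1, high 0.2). Absolute thresholds on a derivative-of-Gaussian
  magnitude scale as 1/sigma and would silently break when the smoothing
  scale changes; relative thresholds keep the defaults meaningful across
  sigma and across frames of different contrast. A constant frame has zero
  maximum magnitude and yields no edges.
* **Gradients use reflect boundaries.** Zero padding would manufacture
  strong spurious edges along the frame border, which the per-column scan
  would happily pair with a true band edge.
* **Sub-pixel non-maximum suppression.** A blurred intensity step peaks
  midway *between* two pixel rows, so the two adjacent gradient samples are
  exactly tied and any noise flips the discrete argmax — a coin-flip that
  biases thin-band intensity means (one misplaced edge row dilutes an 8-px
  band's mean by far more than a 30-px band's) and thereby induces a
  spurious negative thickness-ratio correlation even when no attenuation
  exists. The suppression step therefore fits a parabola through the three
  magnitudes along the gradient direction and marks the first pixel at or
  after the interpolated peak. Ties are resolved structurally (the edge row
  is the first row of the new region), and jitter now requires the
  interpolated peak to move by half a pixel rather than by one noise
  quantum. The brute-force equivalence and null-recovery tests pin this
  behaviour down.

A 10-sample moving average of a column profile can be plotted
(`columnProfilePlot()`) as a visual aid; it plays no role in the metrics.

# M-mode amplitude

`detectInspirations()` finds inspiratory peaks on a lightly smoothed trace
(Savitzky-Golay, order 3, default window 11 samples; 0 disables) as local
maxima with topographic prominence of at least `minProminence` (default
0.2 mm — well below a mouse diaphragm excursion of roughly 0.4-1 mm and
well above trace noise) separated by at least `minSeparation` (default
0.2 s, matching anesthetised breathing of about 2-4 Hz). Peak and baseline
values are read from the same smoothed signal: taking a raw maximum over
noisy samples would add a positive bias to every amplitude.

The onset (baseline) of each breath is the last local minimum before the
peak that lies at least `minProminence` below it; small noise dimples on
the inspiratory upslope therefore cannot masquerade as baselines. A
per-breath baseline is the default because it is robust to slow drift; a
global-median baseline is available (`baseline = "global_median"`) and
agrees on drift-free traces. Amplitudes average up to 5 breaths; when more
are detected, breaths 2-6 are used — a deterministic choice that also skips
a possibly clipped first cycle — and fewer than 3 triggers a warning.

# Ex vivo force

The cross-sectional area of a strip is estimated from wet mass, optimal
length and density, CSA = mass / (L0 · (Lf/L0) · D) with D = 1.06 g/cm³
and Lf/L0 = 1 for diaphragm. Specific force is sP = P / CSA, expressed in
kN/m² (1 N/cm² = 10 kN/m²); the normalisation is sometimes printed as
`P/(Mass/Lf*D)`, which is operator-ambiguous — the reading adopted here,
P·Lf·D/Mass, is the only one whose denominator is an area with correct
units (the standard wet-mass CSA normalisation). Twitch tension averages 5
twitches. Eccentric decay is the percent force reduction at the 5th and
10th pulse of a 10-pulse series relative to the 1st; recovery is the
percent of the pre-protocol tetanus reached 4 and 30 minutes after the
series. Stiffness is the before/after-stretch force difference per
reference volume (mN/mm³); the reference volume is caller-supplied because
no published convention pins it down, with muscle volume mass/density as
the documented default.

Longitudinal percent changes can be computed from group means (default) or
as the mean of per-animal changes; the two differ whenever baselines vary
across animals, and published tables do not always say which was used, so
both are exposed (`groupPercentChange(mode = )`).

# Statistics

All tests delegate to the standard `stats` implementations behind a small
uniform interface, and the test suite cross-checks them against explicit
formulas. ANOVA is the classical between/within F with (k-1, N-k) degrees
of freedom; on two groups it equals the squared pooled t (checked to
1e-10). Degenerate inputs (all observations identical) report F = 0, p = 1
rather than NaN. Pairwise post hoc tests use the pooled within-group SD
from the full design (classical Bonferroni-protected comparisons, adjusted
p = min(1, p·m)); a per-pair variance variant is available via
`pooled = FALSE`. Tests are two-sided throughout, and the Welch correction
is off by default (classical pooled tests), available by flag. Operator
agreement is a two-sided variance-ratio F (larger over smaller variance)
followed by an unpaired t; agreement requires both p-values above alpha.

# Synthetic data: what it emulates and what it does not

* `simulateBMode()` builds a bright AW band (default intensity 0.9 of full
  scale) over a dimmer background (0.35) with a linear attenuation law —
  the expected below-band intensity is
  `base + slope · thickness · bandIntensity`, clamped to [0, 1] — and
  multiplicative Gaussian speckle `1 + cv·z` (default cv 0.05), also
  clamped. The defaults mimic the geometry of a murine abdominal-wall
  scan: band thickness 8-40 px within the accepted 5-50 px window, 50+
  rows of tissue below. Multiplicative Gaussian speckle is a deliberate
  simplification: real speckle is Rayleigh-like and spatially correlated
  by the point-spread function, and no anatomy is rendered, so passing
  recovery tests demonstrate estimator correctness on the stated model,
  not performance on clinical images.
* `simulateMMode()` produces baseline + half-sine inspiratory deflections
  (the waveform is not specified by convention; the estimator must be
  shape-agnostic) at 150 breaths/min with inspiration occupying 40% of the
  cycle, plus additive Gaussian noise (default SD 0.05 mm against a 0.9 mm
  amplitude).
* `simulateCohort()` draws per-animal readouts from a multivariate
  Gaussian with group means/SDs and an exchangeable readout correlation —
  enough to exercise the statistics end to end, with no claim to match
  real animal-level distributions.

All generators are bit-reproducible under their seed, and zero-noise
settings reproduce ground truth exactly.

# Validation problem sizes

The shipped tests and the acceptance script exercise: 20-replicate phantom
sets of 18 frames (120 x 32 px, thicknesses 8-40 px, about 570 accepted
columns per replicate) for the null and negative-slope attenuation
recovery; brute-force oracle equivalence on 30 x 30 fixtures (with a
shortened 10-px below-window so the geometry fits); 20-seed amplitude
recovery at 0.9 mm amplitude and 0.05 mm noise sampled at 200 Hz; and 1000
null simulations (4 groups of 8) for the empirical size of ANOVA and t at
alpha 0.05. These sizes give stable Monte-Carlo estimates while keeping a
full run in well under a minute per module.

# Known limitations

* The attenuation headline of any particular study (e.g. a weak r of
  about -0.2 on 36 real images) is not reproducible without the source
  images; the package instead validates the algorithm by parameter
  recovery on phantoms with known slope.
* Edge detection assumes one dominant superficial bright layer; multiple
  stacked hyperechoic layers are resolved by the "shallowest qualifying
  pair" rule, which may pick a sub-layer if the true wall is thinner than
  5 px or thicker than 50 px.
* M-mode strips are accepted as digitised traces (CSV); tracking the
  membrane line in a strip image is out of scope.
* Repeated-measures designs are analysed as independent groups, matching
  common practice in these studies; mixed models are out of scope.
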