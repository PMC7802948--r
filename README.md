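# diaphragmUS

Quantitative analysis of diaphragm ultrasonography and ex vivo muscle
physiology for preclinical studies of muscular dystrophy in the *mdx*
mouse.

In dystrophin-deficient mice the diaphragm degenerates early and
progressively, so noninvasive respiratory readouts matter for translational
work. Two ultrasound readouts carry that load: **diaphragm movement
amplitude** (the baseline-to-peak excursion, in mm, of each inspiration on
an M-mode trace) and **diaphragm echodensity** (the mean grayscale pixel
intensity, P.I., of an outlined diaphragm region on a B-mode still —
higher values indicate more fibrotic/fatty tissue). A fair echodensity
comparison must rule out a confounder: a thicker hyperechoic abdominal
wall (AW) above the diaphragm could attenuate the signal from deeper
tissue. The package implements the per-column edge analysis that tests
this, plus the ex vivo force metrics and statistics such studies report.

## What it computes

| Module | Core quantity |
|---|---|
| `echodensity` | ROI grayscale histogram, mean P.I. per frame, per-animal mean over 4 frames, group percent difference |
| `aw_attenuation` | per-column AW thickness (Canny edges, strict 5-50 px window), AW mean P.I., mean P.I. of the 50 px below, and the Pearson r / R² of ratio vs thickness |
| `mmode` | per-inspiration baseline-to-peak amplitude, mean over 3-5 breaths, body-weight normalisation |
| `physiology` | CSA = Mass/(L0·(Lf/L0)·D) with D = 1.06 g/cm³; specific force sP = P/CSA in kN/m²; eccentric decay at the 5th/10th pulse vs the 1st; recovery at 4/30 min; stiffness in mN/mm³; longitudinal % changes |
| `stats` | one-way ANOVA + Bonferroni pairwise, unpaired t, variance-ratio operator agreement, Pearson fits |
| `synthetic_data` | speckled B-mode phantoms, half-sine breathing traces, correlated cohorts — all with known ground truth |

Central objects are S4 classes (`UltrasoundFrame`, `ROI`, `MModeTrace`,
`EchodensityResult`, `AmplitudeResult`, `AttenuationDataset`,
`MusclePrep`) with validity checks and accessors; `runStudy()` drives a
YAML-configured end-to-end run with seeded, byte-reproducible outputs.

## Worked example

```r
library(diaphragmUS)

## 18 synthetic B-mode frames, wall thickness 8-40 px, a true attenuation
## slope of -0.01 per px of wall, 5% multiplicative speckle
frames <- simulateBModeSet(
  thicknesses = rep(seq(8, 40, by = 4), 2), height = 120, width = 32,
  seed = 1, attenuationSlope = -0.01, speckleCV = 0.05
)
runAttenuationAnalysis(frames)
#> AttenuationDataset: 576 columns, 42624 pixels analyzed
#>   ratio ~ thickness: r = -0.9992, R^2 = 0.99835 (slope -0.0098, intercept 0.385)
#>   images: 18
```

The fitted slope of the below-wall/wall intensity ratio against wall
thickness (-0.0098 per pixel) recovers the simulated attenuation law
(-0.01), and every one of the 576 accepted columns satisfied the strict
5-50 px thickness criterion. On a noisy breathing trace:

```r
tr <- simulateMMode(
  mmodeTruth(amplitudeMm = 0.9, noiseSdMm = 0.05, seed = 1),
  sampleRate = 200
)
breathAmplitudes(tr)
#> AmplitudeResult: mean amplitude 0.938 mm over 5 breaths (0.949, 0.973, 0.901, 0.947, 0.919)

groupPercentDifference(88.40, 112.82) # echodensity delta between group means
#> [1] 27.62443
specificForce(0.5, crossSectionalArea(musclePrep(mass = 0.0106, l0 = 1)))
#> [1] 500  # kN/m^2
```

The estimator recovers the simulated 0.9 mm amplitude to within a few
hundredths of a millimetre; an echodensity rise from a mean P.I. of 88.40
to 112.82 is a +27.6% difference; and a 0.5 N tetanus over a 0.01 cm²
strip is a specific force of 500 kN/m².

## Documentation

The methods vignette
(`vignettes/quantitative-diaphragm-ultrasound.Rmd`) describes the image
model, the Canny/per-column algorithm and its numerical choices, the
amplitude estimator, the force normalisations, what the synthetic
generators do and do not emulate, and known limitations.
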