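---
title: "Quantifying scleral crosslinking from SHG micrographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scleral crosslinking from SHG micrographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scleraSHG)
```

## The scientific problem

Therapeutic tissue crosslinking (TXL) of the sclera — here by sub-Tenon's
injection of sodium hydroxymethylglycinate (SMG) — stiffens the collagenous
wall of the eye and is a candidate treatment for pathological myopia.
Second-harmonic-generation (SHG) microscopy images fibrillar collagen
directly, and two quantitative readouts of crosslinking can be taken from
such micrographs of treated versus paired control eyes:

1. **Brightness.** The mean of the image's intensity histogram ("mean pixel
   density") rises with crosslinking.
2. **Fiber straightening.** Collagen fiber bundles are wavy; under fixation
   while mechanically loaded by intraocular pressure, crosslinked bundles
   straighten. Waviness of a traced bundle is the arc-to-chord ratio
   $W = L_\text{curve} / L_\text{linear} \ge 1$, and the headline statistic
   compares the treated condition to its control:
   $$\text{Waviness-\%} = 100\,\frac{W_\text{treated} - 1}
                                     {W_\text{control} - 1}.$$
   Values below 100% mean the treated fibers are straighter.

A third readout localizes the effect anatomically: the globe is cut into 16
sectors (sector 2 = the injection site), and the shift in collagen thermal
denaturation temperature, $\Delta T_m$ (treated minus paired control,
measured by DSC), is tested per sector with paired t-tests, giving a "zone
of effect" map.

The original tissue images are not deposited, so this package couples the
full analysis pipeline to a synthetic-data generator with known ground
truth. Every stage — histogram statistics, seeded fiber tracing, the
hierarchical waviness protocol, the mixed model, the sector map — is
exercised end-to-end against values planted by construction.

## The analysis pipeline

### Brightness

`image_histogram()` bins at every integer intensity level over the nominal
bit range (one bin per level, no normalization), so its mean is *identical*
to the direct pixel mean — an exact invariant the tests assert rather than
approximate. `paired_intensity_analysis()` forms per-animal
treated-minus-control differences of image means and reports their mean,
sample SD, and a two-sided paired t-test. Across doses,
`fit_random_intercept()` fits

$$y_{ij} = \mu + \beta_{\text{condition}(j)} + b_i + \varepsilon_{ij},
  \qquad b_i \sim N(0, \sigma_b^2),$$

a linear mixed model with a random intercept per animal, by maximum
likelihood (a `method = "REML"` switch is exposed). Inference on condition
contrasts is Wald with a normal reference; no small-sample df correction is
applied. In the balanced two-condition case the ML contrast equals the
simple mean of within-animal differences — the tests check agreement to
1e-8, which pins the estimator rather than trusting it. Estimation is
delegated to `lme4`; the closed form serves as the independent oracle.

### Waviness

The published protocol traced fibers by hand. `trace_fiber()` replaces the
human with a deterministic seeded ridge follower: from a seed point, the
initial direction is the principal axis of the local intensity second-moment
matrix; each step advances 2 px and re-centers on the intensity-weighted
centroid along the local normal (bilinear interpolation, weights floored at
the stop threshold); tracing runs both ways from the seed and halts at the
image border, when ridge intensity falls below half the seed intensity, at a
direction change beyond 30 degrees (the straightest-continuation rule a
human applies at bundle crossings), or at the step cap.

Two numerical choices matter and are worth stating plainly:

* **Direction baselines.** The rasterized tube center oscillates around the
  continuous centerline by a few tenths of a pixel, so single-step
  directions carry ~10 degrees of jitter. Marching and turn-gating use a
  direction estimated over a 3-step baseline, and the gate engages only
  once that baseline has filled (the seed direction is an orientation
  estimate, not a tangent).
* **Jitter smoothing.** A polygonal arc length of a jittery trace is biased
  upward. Traces are resampled at 1 px and smoothed with a 5-vertex moving
  average — far below the ~150 px undulation wavelength of interest, so the
  waviness signal is untouched while the bias drops an order of magnitude.

On noise-free renders the tracer stays within 0.5 px RMS of the true
centerline (measured over points whose nearest true vertex is interior —
the trace deliberately runs onto the rounded tube end caps, and that
overhang is a different property than centering accuracy) and recovers
waviness within 1% across $W \in [1.0, 1.4]$.

Averaging follows the published hierarchy exactly: ten fibers are averaged
within an image field, ten field means are averaged within a condition, and
the condition means enter the Waviness-% formula; image fields, not fibers,
are the replication unit for the t-test. The formula as written uses
condition means; averaging per-image ratios instead is possible via the
exposed per-image means but is not the default, since the defining equation
is stated on condition-level waviness. Pairing by animal is the default
test (the synthetic design is paired); a Welch option covers unpaired use
and the 40-vs-400 mM comparison.

### Sector map

`sector_delta()` and `sector_tests()` compute per-sector
$\Delta T_m$ mean ± sample SD and two-sided paired t-tests at
$\alpha = 0.05$. No multiple-testing correction is applied by default —
matching how per-sector tests are conventionally reported for this design —
but `p_adjust` accepts any `stats::p.adjust` method. Zero-variance sectors
(exactly reproducible tables, noise-free simulations) are flagged
`degenerate` and given the limiting p-value (0 for a nonzero shift, 1
otherwise) instead of crashing. `zone_of_effect()` returns the sorted
significant sectors and renders a 16-cell text map of the anatomical layout
(sector 2 at 12 o'clock flanked by 1 and 3; 4–6 superonasal; 7–9
superotemporal; 10–11 medial; 12–13 lateral; 14–16 inferior).

## The synthetic-data generator

### What it emulates

`generate_condition_set()` produces, per animal, one treated and one
control 12-bit image (16-bit container) of bright wavy fiber bundles on a
dark background:

* **Paired-eye structure.** A per-animal brightness intercept (SD 10
  counts) is shared by both eyes, so it cancels in paired differences but
  gives the mixed model a real variance component to estimate.
* **Condition-dependent brightness.** `fiber_intensity_offset_{control,treated}`
  are defined as each arm's fiber contribution *to the image mean*. After a
  layout is rasterized, the common peak intensity is calibrated as
  `peak = offset * n_pixels / sum(weights)`, so the clean image mean equals
  background + intercept + offset exactly, independent of placement
  randomness, and the expected treated-minus-control difference equals its
  configured ground truth by construction.
* **Between-animal treatment variability.** A zero-mean per-animal effect
  (`difference_sd`, default 28 counts) perturbs the treated offset. Without
  it, paired differences would be constant to within read noise averaged
  over a megapixel (~0.05 counts) — a spread no real paired-eye experiment
  exhibits; the published differences scatter with SDs near 28 counts.
* **Condition-dependent waviness.** Centerlines are single-frequency
  sinusoids with three full periods along the chord (so the arc/chord ratio
  is phase-independent), amplitude solved by bisection against a Simpson
  quadrature of the continuous arc length to hit the target ratio within
  1e-4. Per-fiber jitter (SD 0.02 on the ratio) makes the hierarchical
  averaging non-trivial without biasing the arm mean.
* **Noise.** Zero-mean models: none, additive Gaussian read noise
  (default sigma 20 counts), or Poisson shot noise plus read noise. Values
  are rounded and clipped to 0–4095 last.

### Fiber placement

Fibers are laid as a locally aligned bundle: all fibers of one field share
a random orientation and occupy parallel lanes whose pitch exceeds the
sinusoid band plus a configured separation, with slots along each lane
spaced by the chord plus cap diameter plus a gap. Non-overlap therefore
holds *by construction*. Isotropic random placement with rejection cannot
deliver this: segments of total length $T$ thrown into area $A$ cross about
$T^2/(\pi A)$ times (roughly a hundred times at the coverage these images
need), so a rejection sampler never terminates. Locally parallel lamellae
are also how scleral collagen is actually organized. The lane pitch for
traced presets (separation 25 px) keeps neighboring tubes outside the
tracer's centering window.

Tubes have a flat-top cross profile with a one-pixel linear edge rolloff
approximating pixel-area coverage (a Gaussian profile is not provided; the
flat top keeps image-mean arithmetic exactly checkable). The rolloff also
preserves the tube's sub-pixel position, which hard-edged rasterization
would quantize to ~0.3–0.5 px — at the tracer's accuracy floor.

### Presets and calibration

The named presets plant ground truth such that a perfect analysis would
reproduce the published summary numbers:

| preset | ground truth |
|---|---|
| `cfg-int-40` | mean difference 66.3 counts |
| `cfg-int-400` | mean difference 361.4 counts |
| `cfg-null` | mean difference 0 |
| `cfg-wav-40` | $W$ 1.300 control / 1.189 treated → 63% |
| `cfg-wav-400` | $W$ 1.300 control / 1.165 treated → 55% |
| `cfg-tm-40-insitu`, `cfg-tm-400-insitu` | sector-2 shift 4 / 13 °C |
| `cfg-tm-40-map` | sectors 1–3 shifted 3.4 °C |
| `cfg-tm-400-map` | sectors 1–9 shifted 19 °C; 10 and 14 by 2 °C |

The control waviness 1.300 is a documented convention: only the ratio
statistic is published, never absolute waviness. Absolute intensity scales,
fiber widths (10 px) and lengths (450 px for traced presets; 200 px for
brightness presets, which are never traced and use many short fibers to
reach ~19% coverage so the calibrated peaks stay inside 12 bits) are
likewise conventions, not published facts.

## Reproduction study and problem sizes

`run_intensity_roundtrip()`, `run_waviness_roundtrip()` and
`run_tm_roundtrip()` regenerate data and run the full pipeline over
replicate seeds; `run_study()` assembles the comparison table. The shipped
configuration uses 10 pairs × 20 seeds for brightness, 10 images × 10
fibers per arm × 20 seeds for waviness (1024-px fields), and n = 3 animals
× 20 seeds at noise SD 0.5 °C for the sector tables. The brightness round
trips run on 512-px fields with proportionally scaled fiber geometry: the
recovered difference is calibrated into the image mean and is therefore
scale-free, and the quarter-size field keeps a full run to a couple of
minutes. The acceptance script (`scripts/acceptance.R`) uses exactly these
sizes.

All randomness descends from one base seed through deterministic
sub-streams (a polynomial hash of the seed with animal, arm and stage
indices, kept below $2^{31}$), so identical configurations are
bit-reproducible and different stages never share a stream.

## What passing tests do and do not show

The generator emulates the *statistical structure* of the study — paired
eyes, between-animal variability, condition effects on brightness and
waviness, localized $T_m$ shifts with measurement noise — not the optics of
SHG. There is no point-spread function beyond the 1-px edge rolloff, no
polarization dependence, no depth sectioning, no vasculature or cellular
texture, and fibers within a field are parallel rather than interwoven at
crossing angles. Consequently, round-trip recovery demonstrates that the
pipeline is faithful (unbiased statistics, sub-pixel tracing, correct
hierarchical averaging and tests), but says nothing about tracing
performance on real interwoven collagen networks, where seed selection and
the crossing rule would carry real weight. The tracer's straightest-path
continuation and the 10-seed selection protocol are parameterized for that
reason.

Known limitations, stated once: Waviness-% is undefined when the control
arm is numerically straight (condition mean ≤ 1 + 1e-6) and errors rather
than returning a value; zero-variance paired tests are reported as
degenerate rather than invented; the Wald inference in the mixed model is
mildly liberal at small animal counts (the type-I-error test budgets for
it); and the per-sector analysis deliberately reports uncorrected p-values
by default.
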