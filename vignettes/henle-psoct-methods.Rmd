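---
title: "Quantifying Henle's fiber layer with PS-OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Henle's fiber layer with PS-OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Henle's fiber layer (HFL) — the obliquely running photoreceptor axons that
fan out radially from the fovea — backscatters too little light to be seen
reliably in standard OCT. Being fibrous, however, it is form-birefringent:
polarization-sensitive OCT (PS-OCT) can detect it through the phase
retardation it introduces and, more sensitively, through the orientation of
its optic axis, which tracks the fiber direction. Around the fovea the fibers
point radially, so the measured slow-axis orientation increases linearly with
the azimuth angle along any circle centred on the fovea. `HenlePS` implements
a pipeline that turns this regularity into a quantitative statistic: how far
from the fovea is the radial axis pattern still distinguishable from noise?

Because no clinical data accompany this package, a synthetic PS-OCT generator
(`makeTruth()`, `renderEnface()`, `renderVolume()`, `simulateCohort()`)
produces ground-truthed scenes with exactly the structure the analysis
assumes, which makes every stage testable end to end.

## Stokes frame and the retarder model

All polarimetric data are Stokes vectors $(I, Q, U, V)$ on en-face grids.
The instrument illuminates the eye with a single circular polarization
state; we work in the measurement frame in which that input state lies along
$+Q$. A linear retarder with single-pass retardance $\delta$ (degrees) and
axis orientation $\theta \in [-90^\circ, 90^\circ)$ acts on the polarized
part $(Q, U, V)$ as the Poincaré-sphere rotation about
$(0, \cos 2\theta, \sin 2\theta)$ by $2\delta$ — the factor two folds the
double pass of the sample arm into one application, so every retardation the
package reports is single-pass-equivalent (9° at 860 nm corresponds to
21.5 nm via $\delta/360 \cdot \lambda$, `retardationDegToNm()`). Under this
convention the read-outs are literal:

$$\delta = \tfrac{1}{2}\cos^{-1}\!\big(\langle Q/I\rangle_N\big), \qquad
  \theta = \tfrac{1}{2}\,\mathrm{atan2}\!\big(\langle U/I\rangle_N,\,
  -\langle V/I\rangle_N\big),$$

with $(\cdot)_N$ the components of the normalized mean Stokes vector.
Averaging is always performed on Stokes components *before* conversion
(`averageStokes()`, `smoothStokes()`): retardation values are non-negative,
so averaging them directly inflates noisy estimates by a positive bias,
whereas componentwise Stokes means do not (this is covered by a Monte-Carlo
test).

Anterior structures (cornea, retinal nerve fiber layer) retard the beam
before it reaches HFL. `compensateAnterior()` estimates the anterior retarder
per A-line from the Stokes state at a reference surface between the RNFL-GCL
and INL-OPL interfaces — identifiable from a single measurement because the
input state is known — and applies its inverse rotation to the target map.

## The mean-deviation (MD) statistic

Axis orientations are *axial* data: $\theta$ and $\theta + 180^\circ$ are the
same axis. Before any averaging the axis is therefore mapped onto the full
unit circle by doubling,

$$Z = e^{\,i\,2\theta},$$

the standard device of circular statistics for axial quantities
(`axisToComplex()`). Each of the 14 one-degree-wide annuli around the fovea
(inner radii 0–13°) is divided into 360 azimuthal segments of 1°; $Z$ is
averaged per segment, and the MD of an annulus is the mean, over non-empty
segments, of

$$d_s = \big|\mathrm{Re}\,\bar Z_s - \mathrm{Re}\,Z_{\mathrm{ideal}}(\phi_s)\big|
      + \big|\mathrm{Im}\,\bar Z_s - \mathrm{Im}\,Z_{\mathrm{ideal}}(\phi_s)\big|,$$

where the ideal radial pattern is $Z_{\mathrm{ideal}}(\phi) =
e^{\,i\,2\theta_{\mathrm{ideal}}(\phi)}$ with $\theta_{\mathrm{ideal}}(\phi)
= (\phi \bmod 180^\circ) - 90^\circ$ (axis $-90^\circ$ at azimuth zero, two
full oscillations of $\mathrm{Re}\,Z$ and $\mathrm{Im}\,Z$ per turn).

Two limits calibrate the scale.

* **Perfect pattern.** $\bar Z_s = Z_{\mathrm{ideal}}(\phi_s)$, so MD $= 0$.
* **No pattern.** For uniformly random axes the doubled angles are uniform on
  the full circle, so segment means vanish and
  $\mathrm{E}[d_s] \to \mathrm{E}|\cos| + \mathrm{E}|\sin| = 4/\pi \approx
  1.27$, the noise floor (finite segments push it slightly higher; the full
  procedure on a 1024×250 random map measures ≈ 1.29, which
  `scripts/acceptance.R` recomputes).

The doubling matters: without it the mean of $e^{i\theta}$ over axes uniform
on $[-90^\circ, 90^\circ)$ is $2/\pi$, not zero, and the floor would come out
near $0.92$ — inconsistent with the ≈1.3 floor that anchors the cut-off. The
$L_1$ component distance is used rather than the complex modulus because it
reproduces that floor. The boundary between "pattern present" and "no
pattern" is the cut-off $0.65$, roughly half the noise floor; it is a
configurable default (`makeRunConfig()`).

`computeMD()` evaluates one annulus; segment membership is computed in
*degree* space because pixels are anisotropic (1024 px across 28° in x,
250 px across 21° in y — a circle in visual angle is an ellipse in pixels).
Segments without valid pixels are excluded; an annulus with more than half
its segments empty is undefined (NA).

## The correction pipeline

Four effects would otherwise corrupt the statistic; `fullCorrection()`
removes them in order:

1. **Global axis rotation** (`rotationCorrection()`): the instrument reports
   axis orientation only up to an unknown additive constant. The constant is
   chosen so the measured pattern aligns with the ideal anchor in the 1–2°
   annulus — implemented as an exhaustive 1° sweep over the 180 candidate
   rotations minimizing the MD, followed by a continuous circular-mean phase
   refinement that is kept only if it lowers the MD. Equivalently, this
   locates the $+90^\circ/-90^\circ$ wrap of the measured axis; the sweep
   form is robust to an inaccurate initial centre because the azimuth
   distortion caused by a displaced centre is zero-mean around the annulus.
2. **Fovea centre** (`refineCenter()`): every pixel of a 31 × 31 window
   around the current centre is tried as a new centre, keeping the one with
   minimal MD in the 1–2° annulus, iterated to a fixed point (ties go to the
   smallest displacement, a reproducibility rule).
3. **Compensation offsets** (`offsetSearch()`): the reference measurement is
   noisy, and deviations of only a few degrees visibly distort the "donut".
   The maps are recompensated for every offset pair
   $(\Delta\delta, \Delta\theta) \in \{-5,\dots,5\}^2$ degrees and the pair
   with minimal MD in the 1–2° annulus wins (ties: smallest
   $|\Delta\delta| + |\Delta\theta|$, then lexicographic). Because an axis
   offset on the reference shifts the extracted axis map in a way partially
   degenerate with the global rotation, the rotation is re-aligned
   analytically per candidate; otherwise the argmin lands next to the true
   offsets whenever the first-pass rotation absorbed part of the
   compensation error.
4. **Centre again.** A residual compensation error biases the centre
   estimate and vice versa, so steps 3–4 are repeated until offsets and
   centre stop changing (at most four rounds; the first round is the
   canonical four-step sequence, and on data with small reference errors the
   loop terminates after verifying the fixed point).

`hflExtension()` then scans the 14-annulus MD profile outward from its
minimum and linearly interpolates, between annulus mid-radii, where it
crosses the cut-off — the estimate of the lateral extension of
the fiber layer. Profiles that never cross are flagged (`"ceiling"` at the
14° field limit, `"no_pattern"` at 0°). `selectBestRepeat()` picks, among
repeated acquisitions, the one with minimal mean MD over the 1–8° annuli.

## The retardation profile

For the "donut" quantification the compensated Stokes map is smoothed with a
9 × 9 componentwise window (`smoothStokes()`) and the *retardation* is then
averaged circumferentially per eccentricity bin
(`circumferentialAverage()`, 0.25° bins; bin centres at multiples of the
width so that the 1° and 8° endpoints fall on the grid). Stokes vectors are
deliberately *not* averaged around a ring: the fiber axis rotates with
azimuth, so their transverse components would cancel and the converted
retardation would collapse toward zero. Scalar summaries
(`profileMetrics()`) are the peak retardation and its eccentricity, the
area under the curve between 1° and 8° (trapezoid rule with endpoints
interpolated exactly onto 1 and 8), and the mean retardation in the exact
1°-wide rings 1–2° … 7–8°.

## The synthetic generator

`makeTruth()` samples a `HenleGroundTruth`; `renderEnface()` renders it.
The forward model is: ground-truth axis = azimuth about the fovea mapped to
$[-90^\circ, 90^\circ)$ plus a global rotation offset; ground-truth
retardation = a raised-cosine bump in eccentricity, zero at the centre,
peaking at `peakEccentricity`, returning to zero at `hflExtension` (smooth
and compactly supported; the real radial profile shape is unknown, so this
is a surrogate); both the IS/OS map and the reference map are corrupted by
one anterior retarder; independent Gaussian noise is added to every Stokes
component.

Defaults are the study conditions the analysis targets:

| parameter | default (healthy) | why |
|---|---|---|
| `hflExtension` | U(5, 12)° | the observed range of lateral extensions |
| `peakRetardation` | U(9, 11)° | donut peak near 9–11.5° single-pass |
| `peakEccentricity` | U(1.8, 2.2)° | peak close to 2° eccentricity |
| `asymmetryRatio` | U(1, 1.3) | slight nasal–temporal widening |
| `anteriorRetardation` | U(10, 35)° | cornea + RNFL surrogate |
| `snrDb` | U(12, 25) dB (age-coupled in cohorts) | realistic image quality |
| `rotationOffset` | U(−90, 90)° | arbitrary instrument axis offset |

Glaucoma cohorts use slightly narrower extension (U(4.5, 11.5)°) and lower
peak retardation (U(8, 10.5)°), so group comparisons have a small true
effect of the kind the method is meant to detect.

The SNR convention is the intensity reading of the threshold-ratio
definition: `snrDb` $= 10\log_{10}(I/\text{threshold})$ with threshold
$= 7\sigma$ of the component noise. The noise is additive, Gaussian and
independent per Stokes component — it reproduces the qualitative
SNR-dependence of the axis statistics (axis noise grows as the local
retardation falls, so low SNR erodes the measurable pattern from the rim
inward, shortening the measured extension), which is the property the
analysis needs; it does **not** model speckle statistics, the axial PSF,
eye-motion artifacts, vessel shadows, or spatially varying anterior
birefringence. Passing tests therefore demonstrate the correctness and
self-consistency of the algorithms under the stated model, not performance
on clinical data.

`renderVolume()` adds a minimal depth dimension for the preprocessing
operators: a dim polarization-preserving inner band, a brighter reference
plane, a peaked bright IS/OS band carrying the pattern, a depolarizing RPE
band of random polarization states, and a background noise floor decaying
linearly with depth — sized so the bright structures stay within the
brightest ~20% of pixels, matching the darkest-80% assumption of the
threshold estimator (`thresholdProfile()`: mean + 7 sd of the darkest 80%,
decaying by 0.08% of the sd per pixel row). `simulateCohort()` additionally
injects the observation-side unknowns the pipeline must undo: an initial
fovea-centre estimate off by up to ±15 px per coordinate and an integer
perturbation of the reference within ±3°.

## Numerical choices

* `acos` arguments are clamped to $[-1, 1]$; violations beyond $10^{-9}$
  warn before clamping.
* Box filters (DOPU kernel, Stokes smoothing) use summed-area tables with
  border windows cropped, never padded; masked pixels are excluded from the
  mean, windows without valid pixels yield invalid output.
* Even kernels (the 10 × 10 DOPU kernel) extend one pixel further
  down/right of the centre pixel.
* Brightest-pixel selections (IS/OS refinement, reference measurement) break
  ties toward the shallower pixel; grid searches break ties by smallest
  displacement / offset magnitude, then lexicographically — all choices are
  fixed for bit-reproducibility.
* The axis is undefined (invalid pixel) where the transverse Stokes
  components vanish: beyond the fiber layer on noiseless data, and at exact
  half-wave retardance.
* DOPU cut 0.75 and search half-width 8 px for the IS/OS refinement are
  configurable defaults chosen in the middle of the plausible range.
* All randomness flows through explicit integer seeds; generators use a
  private RNG stream and restore the caller's RNG state.

## Problem sizes used by the tests

The bundled suite runs the pipeline at the native 1024 × 250 grid where the
geometry matters (parameter recovery over 50 subjects at 25 dB, the noise
floor, SNR sweeps) and at a half-resolution 512 × 125 grid or on small
synthetic volumes (96 × 96 × 24) where it does not; these sizes are the
package's choice of smallest faithful experiment for each property. The
t-test type-I error check uses $10^4$ null replicates.

## Known limitations

* The raised-cosine truth profile and the layered mini-volume are
  surrogates; absolute biases against real HFL morphology cannot be assessed
  from synthetic data.
* The anterior retarder is spatially uniform per eye; real corneal and RNFL
  birefringence varies across the field, which the per-A-line compensation
  handles in principle but the generator does not exercise.
* The MD cut-off 0.65 is an empirical constant; extensions measured at low
  SNR are systematically conservative (the SNR–extension regression in
  `cohort_stats` exists precisely to make that visible).
* Fovea-centre recovery is quantized to the pixel grid (anisotropic:
  ~0.03° in x, ~0.08° in y).
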