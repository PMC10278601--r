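# HenlePS

Quantitative analysis of Henle's fiber layer (HFL) from polarization-sensitive
OCT (PS-OCT) en-face Stokes data, for researchers in retinal polarimetry.

HFL — the radially oriented photoreceptor axons fanning out from the fovea —
is nearly invisible in standard OCT but is form-birefringent. PS-OCT sees it
through the retardation δ it introduces and through its optic-axis
orientation θ, which tracks the fiber direction: along any circle centred on
the fovea, θ increases linearly with the azimuth angle φ. `HenlePS` turns
this regularity into a statistic. Axis orientations (half-turn periodic,
θ ∈ [−90°, 90°)) are mapped onto the unit circle as Z = e^{i·2θ}; each
1°-wide annulus around the fovea (inner radii 0–13°) is cut into 360
azimuthal segments, Z is averaged per segment, and the **mean deviation**

MD = mean over segments of |Re Z̄ − Re Z_ideal(φ)| + |Im Z̄ − Im Z_ideal(φ)|,
  with Z_ideal(φ) = e^{i·2·((φ mod 180°) − 90°)},

is ≈ 0 for a perfect radial pattern and ≈ 4/π ≈ 1.27 (the "1.3" noise floor)
for patternless data. The eccentricity at which the MD profile crosses the
cut-off 0.65 is the lateral extension of HFL. Supporting stages implement
bias-free Stokes averaging (δ = ½·acos⟨Q/I⟩_N), DOPU maps, Poincaré-sphere
compensation of cornea/RNFL birefringence with a ±5° offset grid search, a
four-step correction pipeline (global axis rotation, fovea-centre refinement,
compensation offsets, re-centering), circumferential "donut" retardation
profiles, and cohort statistics (Student's t, box-plot rule, SNR–extension
regression, repeatability). A ground-truthed synthetic PS-OCT generator
drives everything, so the pipeline runs and is tested without clinical data.

## Worked example

One synthetic subject with everything the pipeline must undo: a donut of
peak retardation 10° at 2° eccentricity extending to 10°, an anterior
retarder of 20° at 35°, an unknown +25° axis rotation, a reference
measurement perturbed by (+3°, −2°), an initial fovea estimate off by
(12, −14) px, at 25 dB SNR.

```r
library(HenlePS)

geom  <- sceneGeometry()        # 28 x 21 deg on 1024 x 250 px, 860 nm
truth <- makeTruth(config = list(hflExtension = 10, peakRetardation = 10,
                                 peakEccentricity = 2, asymmetryRatio = 1.2,
                                 anteriorRetardation = 20, anteriorAxis = 35,
                                 rotationOffset = 25, snrDb = 25,
                                 foveaCenterX = 512, foveaCenterY = 125),
                   seed = 3)
scene <- renderEnface(truth, geom, perturbReference = c(3, -2))

fc  <- fullCorrection(list(scene = scene,
                           initialCenter = truth@foveaCenter + c(12, -14)))
fc$profile
ext <- hflExtension(fc$profile)
cat(sprintf("HFL extension: %.2f deg (%s)\n", ext, attr(ext, "flag")))

profile <- circumferentialAverage(smoothStokes(fc$stokes), fc$center)
m <- profileMetrics(profile)
cat(sprintf("donut peak %.1f deg at %.2f deg; AUC(1-8 deg) %.1f; peak = %.1f nm\n",
            m$peak, m$peakEcc, m$auc, retardationDegToNm(m$peak)))
```

```
HenleMDProfile (annuli 0-1 .. 13-14 deg):
  0.01 0.00 0.00 0.00 0.00 0.00 0.00 0.00 0.00 0.05 0.58 1.01 1.26 1.26
  center (512.0, 125.0) px, rotation -25.0 deg, offsets (-3, 2) deg
HFL extension: 10.66 deg (ok)
donut peak 9.9 deg at 2.50 deg; AUC(1-8 deg) 49.9; peak = 23.6 nm
```

Every unknown is recovered: the rotation (−25°), the injected reference
perturbation (offsets (−3, 2)), the fovea centre (512, 125). The MD profile
sits near zero inside the fiber layer, climbs through the 0.65 cut-off just
past 10°, and saturates at the ≈1.27 noise floor beyond — the measured
extension of 10.66° brackets the true 10° (the subject's 1.2 nasal–temporal
asymmetry widens the pattern horizontally). The donut peaks at 9.9°
retardation (23.6 nm at 860 nm) near 2° eccentricity.

Cohort-level runs — simulate healthy and glaucoma groups, process every
subject, compare extensions and per-annulus retardations — go through
`runPipeline(makeRunConfig(...))`, or the command-line wrapper
`inst/scripts/henleps.R` (`simulate`, `process`, `cohort`) with TIFF/JSON/CSV
artifacts and YAML configuration.

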