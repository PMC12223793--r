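---
title: "Airway compliance elastography with aoctel: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Airway compliance elastography with aoctel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoctel)
```

## The measurement

Anatomical OCT (aOCT) images the airway lumen from a rotating fiber-optic
catheter: each rotation yields one polar frame (depth × angle), and a
co-located intraluminal pressure probe records the ventilation pressure at
high rate. As the ventilator cycles pressure, the lumen cross-sectional area
(CSA) breathes with it. The mechanical summary of a scan is

- cross-sectional compliance, `CC = dCSA / dp` (mm²/cmH₂O), and
- normalized cross-sectional compliance,
  `nCsC = 100 · (dCSA / CSĀ) / dp` (%/cmH₂O),

where `dCSA` and `dp` are the differences between the averaged per-cycle
maxima and minima of CSA and pressure, and `CSĀ` is the mean of all those
extrema. Normalizing by `CSĀ` makes nCsC dimensionless in size: for a
thick-walled elastic tube it depends only on the wall material and the
radius *ratio*, not on absolute caliber, so airways of different size can be
compared. A stiffened (injured) wall lowers nCsC.

`aoctel` implements the full chain — synthetic data generation, lumen
segmentation with fold-over correction and sheath calibration, pressure
synchronization and cycle analysis, compliance computation, and study-level
statistics — and validates every stage against analytic ground truth.

## Mechanical model and its analytic oracle

The wall is modeled as a homogeneous, isotropic, linearly elastic
thick-walled cylinder (inner radius `a`, outer radius `b`, Young's modulus
`E`, Poisson ratio `ν`) in plane strain. The Lamé solution gives the inner
wall displacement under a small internal pressure increment, hence

```
nCsC = 100 · 2 (1 + ν) ((1 − 2ν) a² + b²) / (E (b² − a²))   [%/cmH₂O]
```

(`analytic_ncsc()`). The test suite checks this closed form against an
independent finite-difference solution of the axisymmetric displacement ODE
`u'' + u'/r − u/r² = 0` with traction boundary conditions; the two agree to
numerical precision. The closed form is scale-invariant (`(ka, kb)` gives
the same value), inversely proportional to `E`, and increases as the wall
thins — all asserted as properties.

The simulator (`simulate_boundary()`) drives the tube quasi-statically:
`CSA(p) = π a² (1 + (nCsC/100)(p − p₀))`, i.e. CSA is *exactly linear* in
the frame-averaged pressure, and the radius is the square root of that
factor. An earlier draft used the first-order radius expansion
`r = a(1 + ½ s (p − p₀))`; we rejected it because at an 13 cmH₂O pressure
swing its quadratic term distorts the realized area response by several
percent, so the generator would not embody the linear CSA–pressure model the
compliance estimator assumes. Linear-in-CSA is the model; the generator
states it exactly.

Note one estimator-level subtlety: nCsC normalizes by the mid-range `CSĀ`
rather than the rest-state area, so for a compliant tube the extrema-based
estimate equals `s / (1 + s·dp/2)` with `s = nCsC/100` — about 1–6% below
the rest-state derivative for the compliance range simulated here. This is
inherent to the finite-cycle definition, affects real and synthetic data
identically, and is inside the recovery tolerances.

## The rendered world

`render_frames()` produces log-compressed (dB) polar intensity frames
containing, per column:

- a bright sheath ring at the catheter sheath outer radius (0.85 mm OD),
  rendered with partial-volume coverage at its edges so that its radius is
  defined to sub-pixel precision — it is the calibration target;
- the tissue wall starting at the boundary radius, with round-trip
  attenuation of 20 dB/mm (an effectively 1–2 mm visible wall). We render an
  attenuated semi-infinite band rather than a uniform slab of fixed
  thickness: a slab's sharp back edge would create a second strong edge that
  makes the folded region ambiguous in a way real OCT tissue is not;
- the system sensitivity roll-off, log-linear in dB between the stated
  endpoints 105 dB at 1 mm and 55 dB at 8.5 mm, extrapolated beyond;
- fully developed speckle (exponential intensity statistics) on reflectors
  and an additive exponential noise floor at −110 dB (optional, `speckle =
  FALSE` gives the deterministic mean image);
- fold-over aliasing: any reflector beyond the 12.5 mm range appears
  mirrored at `2·range − r`, so a folded wall is upside down, its surface
  being the *deepest and brightest* edge of the mirrored haze.

A reference-arm length mismatch is emulated by `apparent_scale`, which
scales all apparent radii including the sheath.

What the renderer does *not* emulate: multi-layer wall structure
(epithelium/cartilage), catheter shadowing, motion within a rotation,
non-circular lumen shapes, mucus, and physical interferogram formation. A
green round-trip test therefore establishes that the segmentation recovers
the geometry it was shown — under realistic speckle, roll-off, attenuation,
fold-over and calibration error — not that it would survive every in vivo
artifact; unusable-scan conditions (wall contact, majority-missing columns)
are modeled only as rejection paths.

The ventilator waveform is a smoothed trapezoid (cosine rise over the first
30% of inspiration, plateau, cosine fall over 30% of expiration, PEEP
baseline) with period `60/breaths_per_min`. Defaults: 20 breaths/min, MIP
18 cmH₂O, sensor noise 1.32 cmH₂O at 5 kHz. The acquisition protocol this
emulates does not fix PEEP or the inspiratory fraction; we set PEEP =
5 cmH₂O (a typical setting for a ventilated pig) and inspiratory fraction
1/3, chosen once.
`attenuation` scales the modulation amplitude to emulate the weaker pressure
modulation observed toward the larynx; it is a free knob, not a fitted law.
Optional cardiac coupling adds a sinusoidal CSA modulation (default 1.5 Hz)
without touching the pressure channel.

## Segmentation

Per column of the dB frame, the detector finds sustained rises of the
depth-smoothed intensity above an adaptive threshold (background median +
15 dB, 3-px run). Columns then split into three regimes:

- **ordinary**: the surface is the first rise; its position is refined by a
  half-intensity crossing against the local band maximum and then snapped to
  the largest neighbouring-pixel intensity ratio, which removes the
  smoothing/attenuation bias (sub-pixel exact on clean frames);
- **fold-over**: if the deep edge of the band is brighter than its shallow
  edge (intensity increasing with depth — the signature of a mirrored band),
  the column is flagged aliased and the *deeper* edge is the surface (the
  "lower surface preferred" rule);
- **bottom contact**: where brightness reaches the bottom rows, the direct
  wall and its mirrored tail may have merged; if the column is bright to the
  very bottom row the surface is the deepest significant intensity step,
  otherwise the bright region stops just short of the bottom and marks a
  fold surface there. A fading direct band is told apart from a fold by its
  orientation (dimming vs. brightening toward the deep edge).

Fold flags are majority-smoothed circularly; the surface is median-filtered
(window 25 columns) and lightly mean-smoothed *in the corrected (unfolded)
domain*, where the boundary has no kink at the fold junction. Mirrors
(`correct_aliasing()`, `r → 2·depth − r`) apply only inside flagged runs,
which must be bounded by bottom-touching columns; the mapping is an
involution. `seed_depths` emulates the manual input of a semi-automatic
workflow by vetoing candidate surfaces away from per-column seeds; the
automatic detector is a documented stand-in for the unpublished
semi-automatic method the original workflow used.

Scale calibration divides the known sheath radius by the detected one
(`calibrate_scale()`), exactly as a rigid-phantom reference standard is used
to normalize sheath size across scans. Detection is sub-pixel: the ring
profile is roll-off-compensated and the edge interpolated from the
partial-volume intensity of the edge pixel. On clean frames the calibrated
CSA is accurate to <0.5%, and scans rendered with up to ±10% reference-arm
scale error agree after calibration to well within 2%.

CSA is the polygon area of the star-shaped boundary,
`A = ½ Σ r_j r_{j+1} sin Δθ`; invalid columns are filled by circular linear
interpolation first, and a scan with more than half its columns unusable is
rejected, as are frames whose wall touches the sheath over most columns.

**Known limitation.** Under speckle, columns whose wall crosses the range
within ~0.2 mm of 12.5 mm have no resolvable per-column edge (the direct
band and its mirrored tail coincide); they fall back to a fold-at-depth
estimate and are repaired by the corrected-domain median. Clean frames are
exact there; median-based accuracy criteria are unaffected, but per-column
worst-case error at the fold junction under speckle is a few pixels.

## Cycle analysis and compliance

Pressure is synchronized to frames by averaging the 5 kHz samples within
each half-open frame window `[t_f, t_f + 1/frame_rate)` — 125 samples per
40 Hz frame. Cycles are detected on the frame-mean pressure (the cleaner
periodic driver; CSA is a usable fallback): boundaries at the centres of
below-midlevel runs, merged below half a nominal period, and only intervals
containing an above-midlevel excursion count. A 12.5 s scan at 20
breaths/min yields 4 complete cycles; fewer than 2 is a rejection.

Extrema of CSA and pressure are taken per cycle *independently*, which makes
the estimator insensitive to lag between the channels (hardware
asynchronization or viscoelastic delay): imposing up to ±¼ cycle of lag
moves nCsC by under 3%. `compliance()` then applies the defining arithmetic
and the uncertainty rule: per cycle, the CSA standard deviation over the
five frames before and after the max (resp. min) CSA frame; per-cycle values
pooled by averaging (the pooling rule is not specified upstream; averaging
is the natural choice and is exposed in the result fields), and
`sd(CSĀ) = sqrt(sd_max² + sd_min²)`. "Root sum" is read as
root-sum-of-squares — the standard propagation for a mean of two uncertain
quantities — with the literal sum available as `sd_rule = "sum_of_roots"`.

## Statistics

Covariates use the study's numeric coding (intensity low/medium/high →
1/2/3; time before → −1, after → 0, 30 min → 0.5, then hour marks; position
0 at the carina to 1 at the larynx) and are treated as continuous
regressors, matching that coding. `anova_ncsc()` fits the linear model with
any requested interaction products and reports per-term F tests; the
sum-of-squares type is not derivable from the upstream description, so Type
II (each term against the model of all terms not containing it — the
sensible default for unbalanced data) is the default with Type I available.
`regress()` reports OLS coefficients, standard errors and p-values; the
ordinal injury grade is modeled by OLS on its 1–3 code, as a linear model of
grading implies (an ordinal logit would be the natural alternative and can
be layered on the same table). No multiple-testing correction is applied,
matching the reporting style it mirrors. Calibration is tested: under a
Gaussian null the time-term p-values are uniform (KS test across 1000
replicates), and an injected 3-σ time effect is detected at p < 0.01 in
≥95% of replicates. One pig received one intensity in the study design this
mirrors, so intensity is confounded with animal; no mixed-effects structure
is attempted, deliberately.

## Numerical and design choices

- All randomness (pressure noise, speckle) sits behind integer seeds;
  `run_scan()` writes a manifest (package version, seed, config MD5) and is
  byte-identical under a fixed config + seed.
- Frame timestamps are rotation starts; pressure windows are half-open.
- Tolerances: segmentation round trip ≤1 px clean / ≤3 px median under
  speckle; calibrated CSA ≤0.5% clean, ≤2% median under speckle; end-to-end
  nCsC median relative error ≤5% clean and ≤15% with speckle + 1.32 cmH₂O
  pressure noise over a 3×3 grid of tube radii (5, 8, 11 mm) and moduli
  (1000–4000 cmH₂O, nCsC ≈ 0.2–0.9 %/cmH₂O).
- Tests and the acceptance script run at reduced geometry (288×208 px
  frames, 280-frame scans; 768×624 for the fold-over criterion) to stay
  inside time budgets; the 12.5 mm range, 40 Hz frame clock, sheath OD and
  ventilator settings are the real acquisition values throughout.
- Frame stacks travel as uncompressed 16-bit multi-page TIFF with a JSON
  sidecar (geometry, timestamps, dB quantization); the minimal TIFF codec is
  implemented in-package because no TIFF reader exists in the target R
  environment, and was validated against an independent Python reader.

## Worked example

```{r example, eval = FALSE}
geom <- scan_geometry(n_frames = 280, depth_px = 288, n_angles = 208)
tube <- tube_model(8, 10, 2000, 0.45)      # nCsC ~ 0.43 %/cmH2O
pressure <- make_pressure(ventilator_params(), geom, seed = 1)
gt <- simulate_boundary(tube, pressure, geom,
                        catheter_offset_mm = c(0.5, 0.2))
stack <- render_frames(gt, geom, speckle = TRUE, seed = 2)
series <- segment_stack(stack, geom)
scan_compliance(series, pressure, frame_rate = geom$frame_rate)
analytic_ncsc(tube)                        # ground truth to compare
```

Or from the command line, end to end with files on disk:

```sh
aoctel synth --config cfg.yaml --seed 1 --out scan/
aoctel run   --config run.yaml
```
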