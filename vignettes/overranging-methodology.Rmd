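---
title: "Measuring helical-CT over-ranging from dosimeter timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring helical-CT over-ranging from dosimeter timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctoverrange)
```

## The measurement problem

A helical CT scan must collect projection data beyond the operator-selected
volume of interest (VOI) — at least half a gantry rotation before the first
reconstructed section and after the last — so every acquisition irradiates an
*over-ranging* length that the console's dose summary may not fully reflect.
Over-ranging matters clinically because dose-length product (DLP) is
proportional to irradiated length: on a routine abdominal protocol the extra
length is around 5 cm, roughly 10% extra dose, and it falls on tissue the
radiologist never asked to image.

This package implements a direct, timing-based measurement of that length.
Three point dosimeters with 10 ms temporal resolution are (conceptually)
deployed:

* a **bore dosimeter**, stationary inside the fan for the whole scan, whose
  above-threshold interval gives the beam-on duration $T$;
* two **table dosimeters** a known distance $s$ apart, carried through the
  beam by the table, whose peak timing gives the table speed
  $v = s / \Delta t_\text{lead}$.

The total scanned length is then $vT$ (the table translation), or
$vT + W$ with $W$ the total beam collimation if one counts everything the
beam actually exposes — film shows the exposure extends half a collimation
beyond each end of the translation. Over-ranging is simply

$$L_\text{over} = \text{total length} - L_\text{VOI}.$$

Both length conventions are first-class in the package (`convention =
"exposure"` vs `"translation"` in `direct_overrange()`); they differ by
exactly $W$, and keeping them explicit is what reconciles the
console-reading literature (which adds a full collimation) with film (which
shows only half a collimation of extra exposure relative to the console's
displayed length). The rival estimators — dose-slope extrapolation of DLP
versus number of rotations, and console readings adjusted down by $W/2$ —
are implemented in the comparators so all three can be run on the same
simulated scan.

## What the simulator emulates

No scanner is attached to a unit test, so `simulate_scan()` stands in for
the hardware. It embeds a configurable ground-truth over-ranging model and
returns it in a `truth` record that estimators never see, which turns every
accuracy question into a parameter-recovery experiment.

The emulation covers what the timing methodology is actually sensitive to:

* **Kinematics.** Table speed is the helical relation
  $v = p \, W / t_\text{rot}$. The beam plane is fixed; in table
  coordinates its center translates $D = L_\text{VOI} + L_\text{over} - W$
  mm during the beam-on time, so the exposed band ($D + W$) equals the VOI
  plus the over-ranging, centred on the VOI (half the extra length at each
  end).
* **Trace shapes.** The bore sees a plateau for the full beam-on time; each
  table dosimeter sees the beam's longitudinal profile swept past at $v$ —
  a trapezoid with a linear penumbra (default 10% of $W$; the real profile
  is not published, and a trapezoid preserves well-defined 10% crossings).
  The finite 0.5 mm scintillator is a boxcar blur of that profile
  (toggleable; its effect is far below the timing resolution).
* **Nuisances.** Multiplicative Gaussian noise per sample (default 1%; no
  noise model is published for the instrument, and 1% is a conservative
  figure for a scintillator/PMT chain well above its noise floor),
  gantry-rotation ripple up to the 5% free-in-air anisotropy bound, and
  optional table acceleration/deceleration ramps. Ramps default to zero:
  on the real scanner the dosimeters are placed mid-scan precisely so the
  acceleration regions are negligible, and a nonzero ramp biases the
  method by $v \cdot t_\text{ramp}$, which is exactly the robustness
  question the option exists to explore.

Two conventions are worth stating because the source measurements do not
pin them down:

* **Tube turn-on/turn-off** is a linear ramp (default 50 ms) anchored so
  that the continuous 10%-of-plateau crossing falls exactly at the nominal
  beam-on boundary. The threshold convention thereby *defines* beam-on
  time, which keeps the simulator's truth record and the edge detector
  consistent without privileging either.
* **Joint parameter dependence.** The pitch law (linear) and the
  reconstruction-slice-thickness law (constant, then an abrupt jump of
  77–88%, then linear — the thin-slice cone-beam-corrected regime versus
  thick-slice z-filtering) were each measured separately. The package
  combines them multiplicatively around the reference configuration
  (pitch 1.0, thin-slice plateau). That joint behaviour is a simulator
  convention, not a measured fact; estimates of either marginal law are
  unaffected.

What the simulator does **not** emulate: scatter (the real dosimeters hang
free-in-air to suppress it), energy spectra and bowtie filtration, tube
current modulation (the reference protocol runs with AEC off), detector
dead time, and dynamically collimated scanners — on those the method is
explicitly inapplicable, because the beam width at the scan ends is no
longer $W$. Passing tests therefore demonstrate that the *arithmetic and
signal processing* recover known truth under realistic trace shapes and
noise; they cannot certify any particular scanner's over-ranging values.

## Default model parameters

The ground-truth defaults (`siemens_overrange_model()`) are fitted to
published bench measurements of a 16-slice scanner: at 24 mm collimation,
over-ranging rises linearly from 43.8 mm at pitch 0.5 to 63.9 mm at pitch
1.5 (slope 20.1 mm per unit pitch, intercept 33.75 mm); the slice-thickness
plateau is 25.5 mm over 2–4 mm with a 77% jump to the linear regime ending
at 52.5 mm for 10 mm slices. At 12 mm collimation the plateau is 11.1 mm
over 0.75–2 mm with an 88% jump and a linear rise to 29.7 mm. The published
record contains one internal inconsistency here: the abstract quotes
6.72 cm at pitch 1.5 where the results section and comparison table give
6.39 cm / 67.3 mm; the tabulated values are treated as canonical and the
abstract figure is ignored. Likewise a "typical pitch-1 speed of 30 mm/s"
appears alongside measured 48.4 mm/s — different collimations produce both,
and the package simply exposes collimation as an input rather than
reconciling the quote.

Protocol validation is strict by default — pitch 0.50–1.50 in steps of
0.05, rotation times {0.5, 0.75, 1, 1.5} s, collimations {12, 24} mm,
slice widths 0.75–10 mm with a collimation-dependent minimum (0.75 mm at
12 mm, 2 mm at 24 mm) — mirroring the scanner menus the defaults were
fitted on; `strict = FALSE` accepts any positive values for other
geometries.

## Numerical choices

**Edge detection.** Crossings are taken at a fraction (default 10%) of the
trace's own peak, which makes them invariant to gain; the crossing time is
refined by linear interpolation between the two straddling samples. On the
linear ramps the simulator produces, interpolation is near-exact — the
residual error arises only when a straddling sample falls off the ramp and
is bounded well below one sample period — so the quantization bound
$v \cdot 10\,\text{ms}$ quoted for the method is conservative for the
interpolated estimator. A sample-aligned mode (`interpolate = FALSE`)
reproduces plain 10 ms-resolution readings, since the source measurements
do not say which was used. Ties (consecutive samples exactly at threshold)
resolve to the earliest sample on the rise and the latest on the fall.
Multiple disjoint above-threshold runs raise an `ambiguous_peak` error that
lists the runs; an optional 3-sample median pre-filter (off by default —
the methodology uses raw traces) handles isolated spikes.

**Speed from edges.** Leading-edge-only is the default; the
`lead_and_trail` mode divides the separation by the mean of the leading-
and trailing-edge time differences. On simulated traces the two agree to
well within the ±2.4% reported for the physical system.

**Dose-slope fit.** Unweighted ordinary least squares of DLP on rotation
count (no weighting scheme is published), intercept converted to length by
dividing by CTDIvol. Treating CTDIvol as uniform across the over-ranged
region is the method's inherent first-approximation bias; CTDI is known to
be inaccurate at scan edges, and the package documents rather than corrects
this. Fewer than three distinct rotation counts is an error; a negative
intercept is flagged, not raised.

**Uncertainty budget.** Quadrature of the separation-measurement precision
(0.5 mm) and the timing term $v \times 10\,\text{ms}$ — 0.7 mm at high
table speeds. The worst-case 0.5 mm finite-scintillator term is excluded by
default (it assumes uniform response across the full diameter, which the
cylindrical geometry makes unlikely) but can be switched on. In
one-dosimeter mode the separation term is replaced by the 2 mm
console-co-dependence allowance (the quality-control upper bound), giving
≈1.1% of a 19.1 cm scan. One quoted figure does not survive arithmetic:
"30 mm/s yields 0.28 mm" where the formula gives 0.30 mm; the formulaic
value is used.

**Film analysis.** The strip's body rows are integrated across the width
into a column profile and the band extent is taken between the 10%
crossings with the same sub-pixel interpolation as the traces — the
simplest reproducible choice, since the original pixel-measurement
procedure is not described. Marker centroids are intensity-weighted over
symmetric footprints, so calibration recovers the pixel pitch to sub-pixel
accuracy; multi-image averaging reports the mean and pixel standard
deviation. Note the published calibration factor "0.04 mm/pixel" is
arithmetically inconsistent with 695 px ≡ 27.8 cm, which requires
0.4 mm/px; the package works with 0.4 and treats the printed figure as a
likely typographical slip rather than silently correcting the record.

**Degenerate results.** Zero or negative over-ranging produces a flagged
`overrange_result` instead of an exception, so parameter sweeps never
abort mid-grid; geometry that cannot produce a scan at all (a dosimeter
that never meets the beam, a bore plateau shorter than the table transit)
raises a structured error.

## A worked example

```{r}
p <- scan_protocol(pitch = 1, rotation_time = 0.5, collimation = 24,
                   slice_thickness = 3, voi_length = 251)
spec <- simulation_spec(p, noise_sd = 0.01, seed = 42)
sim <- simulate_scan(spec)
est <- direct_overrange(sim$bore, sim$table_1, sim$table_2, spec$layout,
                        voi_length = p$voi_length, collimation = p$collimation)
est
c(truth = sim$truth$overrange_length, estimate = est$length)
dose_report(p$ctdi_vol, p$voi_length, est$length)
```

```{r}
ds <- dose_slope_overrange(simulate_rotation_series(p, 2:6, seed = 7))
adj <- adjusted_console_overrange(63.0, 24)  # published console value, pitch 1
method_comparison(list(ds), est)
adj
```

## Problem sizes and reproducibility

Every stochastic test and script draws all randomness from an explicit
seed, and identical configurations produce byte-identical CSV output. The
validation suite uses 100 random noise-free scans and 50 noisy replicates
for recovery properties, 50 random geometries for the film round-trip, and
21-point pitch sweeps for the regression properties — sizes at which the
quantization and noise statistics are already stable while a full run
completes in seconds on a laptop.

## Known limitations

* The over-ranging law's joint pitch × slice-thickness behaviour is a
  modelling convention (see above); only the marginal laws are anchored to
  published measurements.
* The exposure convention assumes the beam width at the scan ends equals
  the nominal collimation: dynamically collimated scanners violate this
  and are out of scope.
* DLP-based length conversion inherits the edge-region CTDI approximation.
* The simulator's noise is white and multiplicative; correlated
  disturbances (table vibration, mains ripple aliasing) are not modelled.
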