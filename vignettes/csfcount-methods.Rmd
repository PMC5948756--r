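---
title: "Counting CSF blood cells from chamber micrographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting CSF blood cells from chamber micrographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(csfcount)
```

`csfcount` turns paired bright-field/fluorescence micrographs of a tall
counting chamber into WBC and RBC concentrations, and plans the physical
protocol around that measurement (sedimentation wait, staining
condition). This vignette documents the models, every calibrated
constant, and the choices made where the design was genuinely open.

## The measurement

A CSF sample fills a hemocytometer-style chamber 532 µm deep whose
floor carries a dried, cell-permeant nucleic-acid stain. After loading,
two things happen in parallel: cells settle onto the floor (the focal
plane of the fixed-focus miniature microscope) and WBCs take up the
stain. Four areas of the floor are then imaged in both channels. Total
cells are counted in bright-field, WBCs in fluorescence (RBCs have no
nucleus and stay dark), RBCs by subtraction, and counts become
concentrations over the calibrated 588 nL analysis volume.

### The analysis volume: 588 nL, not 597 nL

The field of view (0.61 × 0.46 mm) times the chamber height
(0.532 mm) times four areas gives ≈ 597 nL, while the instrument's
calibrated analysis volume is 588 nL. The package treats 588 nL as an
independent constant — `chamber_spec(analysis_volume = 588)` — rather
than recomputing it from the geometry, so that the counting arithmetic
matches the instrument's. When a configuration file states both the
volume and a conflicting geometry, `load_config()` warns and keeps the
stated volume. (A plausible origin of the difference is an effective
imaged area slightly smaller than the nominal FOV, but the package does
not guess.)

## Circle-Hough detection

Cells are detected by radial symmetry and size, not intensity
thresholds. The pipeline is `edge_map()` → `hough_accumulate()` → peak
extraction, all assembled in `find_circles()`.

**Edge map.** The image is smoothed with a 3 × 3 binomial kernel and
differentiated by central differences. Pixels whose gradient magnitude
exceeds the `edge_percentile` (default 0.95) of nonzero magnitudes form
the edge mask. A constant image yields an empty mask and, downstream,
an all-zero accumulator — not an error. The outermost pixel ring, where
central differences are undefined, never votes.

**Voting.** Each edge pixel votes at the two candidate centres
displaced +r and −r along its gradient direction, for every candidate
radius r in the diameter band (4.3–7.1 µm in steps of `radius_step` =
0.5 µm). Voting both polarities makes dark rings on bright background
(bright-field) and bright disks on dark background (fluorescence) share
one code path. Votes are weighted by `magnitude / gradient_ref` (see
below) and pooled over a 3 × 3 neighbourhood, which absorbs the
rounding of sub-pixel centre positions.

**Normalization.** Each radius slice is divided by the ideal
concentrated vote mass of a complete circle, `κ · 2πr_px` with
κ = 1.4. The factor κ reflects two opposing effects measured on the
package's own renderer: the smoothed central-difference response of an
edge is about two pixels thick (each circumference unit contributes
roughly twice the peak-gradient weight), but only the radially coherent
part of that band lands inside the 3 × 3 pooling window, and
ring-profiled objects present two offset edges of which only one
concentrates per candidate radius. The resulting score is ≈ 1 for a
clean, in-focus, fully visible circle and is clamped to [0, 1] on
output.

**Border correction.** Near the image border part of a circle lies
outside the field, so the maximum attainable vote is smaller. The
normalization therefore scales the border bands by the visible arc
fraction (row and column factors combined multiplicatively, each
floored at 0.5). Without this, every cell centred within about one
radius of the field edge is lost and counts at all concentrations are
biased low by ~4%.

**Sensitivity semantics.** `sensitivity_threshold` (default 0.9) is
the *minimum* normalized score: raising it accepts fewer, more
perfectly circular objects. Blur, partial occlusion, irregular outline,
and low contrast all reduce the score, which is what rejects debris and
clumps ("low degree of radial symmetry") and out-of-focus cells.
Detection count is non-increasing in the threshold by construction
(greedy NMS processes peaks in descending score order).

**Peaks and suppression.** Peaks are accumulator cells at or above the
threshold that are maxima of their 3 × 3 × 3 (y, x, radius)
neighbourhood. Greedy non-maximum suppression in descending score order
(ties broken row-major, so output is deterministic) removes peaks
within `min_center_distance` (default `d_min` = 8.6 µm) of an accepted
peak: two true cells closer than one small-cell diameter are optically
merged anyway.

**The gradient reference.** Vote weights need a scale: what gradient
counts as "a real edge at full strength"? The instrument has fixed
illumination and camera gain, so the package uses calibrated
per-channel constants, `gradient_ref_bf = 3200` and
`gradient_ref_fl = 235` intensity units per pixel — just under the
measured peak gradient of a nominal in-focus cell edge rendered by the
simulator (≈ 3510 bright-field, ≈ 259 fluorescence at the optimal
staining condition). Estimating the reference from each frame instead
(available by setting these to `NULL`) is attractive for uncalibrated
images but unstable at the extremes this pipeline must handle: in a
nearly empty frame the estimate collapses to the noise floor and
inflates every score, while in a crowded frame the steepest gradients
come from overlapping cells and deflate every score. Both failure modes
were observed on simulated dilution endpoints (5.2 and 1040 cells/µL).

**Known biases.** The reported radius can sit one `radius_step` below
the apparent radius for ring-profiled objects (the inner edge
concentrates at the smaller candidate); radius is used only for gating
and region definitions, so this is cosmetic. Cells within ~1 px of each
other's suppression radius merge into one detection; this is physical
crowding loss, visible as dilution-series slopes slightly below 1
(≈ 0.93–0.95 at the defaults), mirroring the sub-unity slopes of the
physical instrument.

## Counting and concentrations

`count_area()` implements the subtraction rule:
`n_total = |bright-field detections|`, `n_wbc = |fluorescence
detections|`, `n_rbc = max(n_total − n_wbc, 0)`. A fluorescence count
exceeding the bright-field count is a QC anomaly; the RBC count clamps
at zero and a classed warning is raised. A `matched` mode that pairs
the channels spatially via `match_detections()` (greedy
nearest-neighbour, one-to-one, global-minimum-first) is provided for
robustness studies, but subtraction is the faithful default.

`concentrations()` pools areas and divides by the analysis volume
(1 µL = 1000 nL): 30 cells over 588 nL → 51.02 cells/µL. The CV
(sd/mean of per-area counts) is reported per class and `NA` when the
mean is zero; across-replicate CVs are computed by the evaluation
harness and labelled separately. `poisson_cv()` gives the counting
statistics floor `1/√N` — at 5.2 cells/µL only ≈ 3 cells sit in the
analyzed volume, so a CV near 0.6 is expected from sampling alone.

## Sedimentation

`stokes_velocity()` computes the terminal velocity of the
volume-equivalent sphere, `r = (3 V_c / 4π)^{1/3}`,
`v = 2 Δρ g r² / (9 μ)`, converting g/mL → kg/m³ and cP → Pa·s
internally and returning µm/s. With the red-cell defaults
(V_c = 90 µm³, ρ_c = 1.09, ρ_m = 1.04 g/mL, μ = 1.05 cP) this gives
0.803 µm/s. The instrument's published settling velocity for the same
parameter set is 0.92 µm/s; the standard formula above does not
reproduce that number and the original derivation (effective radius or
shape correction) is not recoverable. The package therefore treats
0.92 µm/s as a citable calibrated parameter — the default
`v_override` in `sedimentation_params()` — so that wait-time
predictions reproduce the published table (6.1 / 9.6 / 12.9 min for
h_c = 337 / 532 / 713 µm), while the first-principles value is always
computed and attached as the `"stokes"` attribute. Setting
`v_override = NULL` switches planning to the derived velocity.

For initial heights uniform in [0, h_c] and constant v, the settled
fraction is `min(1, v t / h_c)` — linear arrivals until complete
sedimentation at `t_s = h_c / v`. `plan_wait_time()` returns
`max(t_s, t_i)` minutes: with the default chamber and the 10 min
staining incubation, staining dominates and imaging starts at 10 min.
No hindered-settling correction is applied; CSF counts are far too
dilute for cell–cell interaction.

## Staining model and SNR

The simulator's staining response is the simplest smooth model with a
saturating signal and an interior SNR maximum:

* cell amplitude `s_max · c_d² / (k_half² + c_d²) · (1 − e^{−t_i/τ})`
  (Hill coefficient 2, `k_half` = 750 µM, τ = 10/3 min),
* background `bg_floor + bg_slope · c_d` (defaults 0 and 0.15 units/µM).

With `bg_floor = 0` the model SNR is proportional to
`c_d / (k_half² + c_d²)`, maximal exactly at `c_d = k_half`, so the
simulated concentration sweep peaks at 750 µM by design. τ = 10/3 puts
the signal within 5% of plateau at 10 min, making the earliest
95%-of-plateau time in the standard sweep equal 10 min. The amplitude
calibration (`s_max` = 3000, `bg_slope` = 0.15) sets the model SNR to
≈ 6 at (k_half, 2 min), so the measured image SNR exceeds 5.4 from
2 min of incubation onward — the early-time behaviour the protocol
relies on. Intensity units are arbitrary camera units; only ratios are
meaningful.

One deliberate simplification: the simulated background depends on dye
concentration but not on incubation time, so simulated SNR rises with
`t_i` and plateaus, whereas the physical system shows roughly
time-constant SNR (background and signal grow together). The optimum
rule — SNR argmax over concentration (ties toward less dye), earliest
time reaching 95% of the plateau signal — selects (750 µM, 10 min)
under either behaviour.

`measure_snr()` defines signal as the mean intensity inside detection
circles and background as the median intensity of pixels farther than
`radius + margin` (margin 2 µm) from every centre — the median resists
contamination by undetected dim cells. SNR is the plain ratio
signal/background (not background-subtracted, not sd-based), matching
the ">5.4" scale; a zero background floors at 1 unit with a warning.
Intensities are integers, so the background estimate resolves the true
level only to one unit. Where the detector finds nothing (very dim
conditions in a sweep), `sweep_conditions()` falls back to ground-truth
WBC positions and records that in its `source` column.

## The synthetic scene

What the simulator emulates, and how:

* **Loading.** Per-class counts are Poisson with mean concentration ×
  frame volume (FOV footprint × chamber height ≈ 0.149 µL); positions
  uniform in the field; initial heights uniform in [0, h_c]; apparent
  diameters uniform per class (cells 9–14 µm, debris 3–7 µm, clumps
  16–30 µm — apparent, optics-scale sizes bracketing the 8.6/14.2 µm
  gate).
* **Bright-field.** Cells are membrane-contrast annuli (Gaussian ring
  centred one ring-width inside the boundary so the outer gradient edge
  sits at the declared apparent radius, with a weak interior shading);
  debris are small irregular specks and clumps multi-lobed blobs, both
  with harmonic boundary modulation — the low radial symmetry the gate
  exploits. A perfectly round debris blob would be a legitimate small
  circle and defeat any symmetry-based filter. The background carries a
  smooth mottle and a faint periodic grid shadow imitating 3D-printing
  layers.
* **Fluorescence.** Soft-edged bright disks at WBC positions only, on
  the dye-dependent background.
* **Defocus.** A single focal plane at the chamber floor; an object at
  height z is blurred with σ = 0.02 · z µm and proportionally reduced
  contrast. This reproduces the in-focus/out-of-focus contrast between
  freshly loaded and settled chambers that motivates the wait time.
* **Noise.** Additive Gaussian per channel (sd 300 bright-field, 8
  fluorescence on the 16-bit scale), clipped and quantized.

Not modelled: physical point-spread functions, filter spectra, camera
gain variation, RBC rouleaux or deformation, photobleaching, and
stain-dependent bright-field contrast. Consequently, passing tests
demonstrate the *algorithmic* correctness of detection, gating,
counting arithmetic, and protocol planning under a realistic scene
geometry — not robustness to the full optical variability of real
micrographs, which are not publicly deposited.

## Evaluation harness and problem sizes

`dilution_series()` runs 5.2–1040 cells/µL (roughly 4-fold steps,
bracketing the clinically relevant viral/bacterial meningitis range)
with 3 replicate chambers × 4 areas per point, WBC and RBC suspensions
separately (the other class absent, as in separately prepared
characterization samples); measured concentration is regressed on
expected by OLS with intercept. `accuracy_vs_truth()` scores
`1 − |pipeline − truth|/truth` per scene on total counts over 40
seeded scenes at (100 RBC, 50 WBC)/µL — moderate pleocytosis with mild
blood contamination — plus a detection F1 against truth positions at
3 µm tolerance. Frames are full sensor scale (1282 × 966 px); the
whole harness is deterministic given one seed, with child seeds drawn
per chamber and area. These sizes are the package's chosen benchmark
scale: large enough that crowding, border effects, and Poisson
dispersion are all exercised, small enough to run on a laptop in
minutes.

## Degenerate inputs and numerical conventions

* Lengths µm, times s (minutes only at reporting boundaries), volumes
  nL, concentrations cells/µL; pixel centres at integer grid points,
  origin at the top-left pixel centre, µm = pixel index × pixel size.
* Constant image → empty edge mask → zero detections. Blank noise
  frames score far below threshold (random votes disperse).
* Images smaller than `d_max` in pixels are rejected with a validation
  error; edge maps require at least 32 × 32 px.
* Zero cells → zero concentration, CV reported `NA`.
* Neutral or negative buoyancy → settling velocity ≤ 0 with a
  flotation warning; `sedimentation_time()` then raises a
  no-sedimentation error rather than returning infinity.
* All ties (peak ordering, NMS, optimum selection) break
  deterministically; identical seeds give bit-identical images,
  detections, and reports.
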