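---
title: "Methods: dosimetry, video heart rate, and serial-section volumetry in fishbeam"
author: "fishbeam maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry, video heart rate, and serial-section volumetry in fishbeam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishbeam)
```

fishbeam packages the computational side of a localized heavy-ion
irradiation experiment in small fish: converting beam fluence to absorbed
dose, modelling where in the body a short-range carbon beam stops,
extracting heart rates from high-speed video, and quantifying organ volume
and blood-cell content from serial histological sections. This vignette
explains each model, its assumptions, the tunable parameters, and the
choices made where the procedure was genuinely open.

## Dosimetry

### Fluence, LET and dose

For a uniform, unidirectional beam the absorbed dose is a bookkeeping
identity: every particle crossing 1 cm² deposits `LET` keV per µm of path,
so

> dose (Gy = J/kg) = fluence (particles/cm²) × LET (keV/µm)
> × 10⁷ (µm·cm²/kg) × 1.602×10⁻¹⁶ (J/keV).

`fluence_to_dose()` implements exactly this product and
`dose_to_fluence()` its algebraic inverse; the pair round-trips to 10⁻¹²
relative precision. At the surface LET of the 26.7 MeV/u ¹²C⁶⁺ beam
(78.4 keV/µm), a delivered dose of 15 Gy corresponds to a fluence of
1.194×10⁸ particles/cm².

### Depth-LET profile

Transport codes produce the full depth-LET curve; the profile here is a
*fit-free interpolant* pinned to the four constants such codes report:
surface LET, peak LET, range, and peak width. The entrance plateau rises as
a power law in residual range with the Bragg-Kleeman exponent
(1 − 1/p, p = 1.77), calibrated so that it carries a configurable fraction
(`shoulder_frac`, default 0.5) of the surface-to-peak rise at the peak
depth; a Gaussian of FWHM equal to the stated peak width, centred half a
width before the end of the range, supplies the remainder, and LET is zero
beyond the range. The plateau is capped at its shoulder value past the peak
depth so that the profile has a unique maximum exactly at
`range − width/2`. The peak width is read as a FWHM; the transport-code
reports that quote "width" do not define it, and FWHM is the reading under
which a "~10 µm" peak on a 2.2 mm range reproduces the published curve
shape.

```{r bragg}
pr <- bragg_profile(range_mm = 2.2, surface_let_kev_um = 78.4,
                    peak_let_kev_um = 800, peak_width_mm = 0.010)
let_at(pr, c(0, 2.0, pr$peak_depth_mm, 2.5))
```

### Range scaling

`ion_range_water()` uses the Bragg-Kleeman power law for protons in water,
R = 0.0022·E^1.77 cm, scaled by A/Z² for heavier ions at the same specific
energy. For ¹²C at 26.7 MeV/u this gives 2.46 mm against the
transport-code value of ~2.2 mm — about +12%, inside the ±15% accuracy we
document for this rule at low specific energies. The approximation ignores
charge-exchange near stopping and any cover-film attenuation (the 8 µm
polyimide film over the specimen is ~0.4% of the range and is not
modelled).

### Irradiated cross-section geometry

The beam is vertical and uniform over a field much larger than the fish,
so the geometry reduces to 2-D: an oval (or polygonal) transverse
cross-section, dorsal side up, sampled at pixel centres on a symmetric
grid. For each parallel ray the depth is counted from the first
inside-pixel on that ray, and a pixel is irradiated iff its depth is `<=`
the range (a closed interval, which makes the mask exactly monotone in
range). With a 4 mm-tall oval and a 2.2 mm range, a dorsal beam covers the
kidney at ~2 mm depth but spares the ventral third; the ventral beam is the
mirror image. `fraction_irradiated()` then quantifies organ/beam overlap on
any congruent organ mask.

## Video heart-rate extraction

The procedure mirrors manual photoplethysmography on high-speed video
(300 frames/s): three rectangular ROIs over the heart are averaged per
frame, a fourth ROI outside the heart captures body movement attributable
to ventilation, and the reference is subtracted frame-by-frame from the
mean of the heart traces. Any strictly common-mode artifact cancels in
exact arithmetic (floating-point association leaves differences at the
10⁻¹² level). The cardiac signal is then smoothed by a 21-frame centred
moving average; at the trace edges the window truncates to the available
frames rather than reflecting data, which preserves trace length without
fabricating samples.

Beats are delimited by the local minima of the smoothed trace — the end of
diastole. The original processing names no detection algorithm, so
`detect_diastole_minima()` uses a parameter-light, noise-robust rule:
plateau-merged strict local minima, filtered by topographic prominence
(default 25% of the trace's interquartile range), kept greedily deepest
first subject to a minimum separation (default `fps/5` frames — a 300 bpm
physiological ceiling). Detection is invariant to adding a constant to the
trace and to positive rescaling (with the prominence threshold scaled
accordingly).

Interbeat intervals are successive minima differences; the beat-by-beat
rate is `fps × 60 / IBI`, and the steady-state rate is the mean (reported
with SD) over a 3-minute window, counting only beats whose *both*
delimiting minima fall inside the window. Which 3-minute segment of a
longer recording is averaged is not fixed by the procedure, so the window
start is a parameter defaulting to 0. Published group tables print
integer rates; the package reports full precision and leaves rounding to
the presentation layer. The "±" spread attached to published group means
is treated as an SD (see the ANOVA section for why).

```{r pipeline}
p <- heart_sim_params(true_hr_bpm = 170, duration_s = 60, seed = 7)
tr <- gen_heart_trace(p)
res <- run_heartrate_traces(tr$heart_traces, tr$reference_trace,
                            fps = 300, window_seconds = 60)
res$summary
```

## Serial-section volumetry

Inputs are ordered stacks of labeled section images (0 background, 1
kidney tissue, 2 blood cell) with an isotropic in-plane pixel size and a
5 µm section thickness: segmentation itself — done by hand on stained
sections in the original workflow — is out of scope.

**Registration.** Sections are registered by translation only. Serial
sections deform non-rigidly in reality, but translation suffices for
voxel-count quantification and keeps the inverse problem well-posed on
binary masks; the transform model of the original alignment plugin is not
public. Each section is registered to its nearest non-empty already-aligned
neighbour (adjacent sections are the most similar), propagating cumulative
shifts outward from a middle reference, by maximizing the FFT
cross-correlation of foreground masks. One numerical subtlety: for
near-concentric shapes of different sizes (an ellipsoid's pole sections)
the binary correlation peak is a *plateau* — any placement of the smaller
section inside the larger scores equally. Ties within the plateau are
broken toward the centroid-difference shift, which is the exact answer for
concentric shapes. Empty sections inherit their neighbour's shift and are
flagged. Applied shifts are integer (nearest-neighbour) so labels are never
interpolated; with a generator margin at least as large as the jitter,
alignment provably never clips foreground, so volume is invariant under
registration.

**Quantification.** Volume is voxel counting times the anisotropic voxel
volume (`pixel² × thickness`). "Blood cell mass" is operationalized both as
the blood-label voxel count and as the blood fraction of organ voxels,
since the original study quantifies neither explicitly. The per-section
profile flags organ-free sections as missing rather than zero. The
dorsal/ventral split plane defaults to the organ's volumetric centroid row
(the original split is undefined) and is exposed as a parameter; supplying
an irradiation mask additionally yields in-field vs out-of-field blood
fractions, the quantity that distinguishes a localized dorsal lesion from
whole-organ depletion.

## Group statistics

`anova_oneway()` is the classical fixed-effects one-way ANOVA at α = 0.05
(delegated to `stats::oneway.test(var.equal = TRUE)`), and `tukey_hsd()`
the all-pairs studentized-range test with the Tukey-Kramer standard error
for unequal group sizes (adjusted p-values via `stats::TukeyHSD`, i.e.
`ptukey`). `anova_from_summary()` recomputes the identical F and p from
per-group (n, mean, sd) alone, which makes printed group tables
re-testable: it agrees *exactly* with the raw-data ANOVA on any data having
those summaries.

Two empirical notes, both reproduced by the test suite from the published
group tables. Reading the printed "±" values as SDs, the day-7 heart-rate
table (171 ± 7.78 n=6, 172 ± 6.99 n=6, 170 ± 6.47 n=4) yields p ≈ 0.91,
matching the published p = 0.90 up to rounding of the printed summaries;
the SEM reading gives ≈0.99, so the SD reading is adopted throughout. The
day-5 table, by contrast, yields p ≈ 0.49 against a published p = 0.24
under either reading — likely computed from unrounded or beat-level data —
and is recorded as a discrepancy rather than asserted.

## Synthetic data: what it does and does not emulate

The generators exist so that every stage has ground truth.

`gen_heart_trace()` / `gen_heart_video()` emulate the *statistical
structure* the pipeline assumes: an asymmetric raised-cosine cardiac pulse
(30% of the cycle descending, 70% recovering, so minima are well-defined
and carry the end-of-diastole meaning; a pure sinusoid is available for
analytic tests), beat times from a gamma renewal process (mean interval
60/HR, beat-to-beat CV 0.02 — renewal jitter keeps the true mean rate
exactly interpretable, unlike phase noise), a 2 Hz ventilation sinusoid
applied common-mode to all four ROIs (amplitude half the cardiac dip, with
an optional gain-mismatch parameter to probe imperfect cancellation), and
Gaussian noise at 10% of the cardiac amplitude. No signal-to-noise figure
is published for the original videos; these defaults make the ±1 bpm
recovery demanding but attainable, and they are parameters, not constants.
The generators do *not* emulate optical blur, heart-shape change,
occasional fish movement, or illumination drift — so passing tests show the
*procedure* is correct and noise-robust, not that any specific video would
be tractable.

`gen_section_stack()` voxelizes an ellipsoidal kidney (defaults: semi-axes
250 × 350 × 150 µm on a 10 µm grid, 70 sections of 5 µm), assigns each
organ voxel a blood-cell label by an independent Bernoulli draw (baseline
probability 0.25, reduced by a depletion factor inside a dorsal band or the
whole organ — the two published lesion patterns), and jitters each section
by integer-rounded Gaussian shifts within a declared margin. Real kidneys
are not ellipsoids and real blood-cell clustering is not Bernoulli; the
generator's role is to make alignment, volumetry and regional statistics
verifiable against analytic truth (4/3·π·abc volume, known shifts, known
per-section probabilities).

All generators draw from one seeded stream per call and restore the
caller's RNG state; identical parameters and seed give bit-identical
output.

## Numerical choices and problem sizes

* Depth grids for the Bragg profile add a dense sub-grid (width/20 spacing)
  around the peak so the 10 µm peak is resolved on a 2.2 mm range.
* The moving average is computed by cumulative sums (O(n)); a 180 s trace
  at 300 fps (54 000 frames) processes in well under a second.
* Registration uses full-frame FFTs; circular wrap-around is harmless
  because jitter is small relative to the frame and a margin is enforced.
* Test and example simulations use 60–120 s recordings and ~100-pixel
  section grids; the recovery sweep (120–200 bpm, 20 seeded replicates per
  rate, ±1 bpm in ≥95%) uses 120 s windows, at which the beat-averaging
  standard error (~0.3 bpm) makes the criterion stable.
* Degenerate inputs are contracts, not crashes: constant traces detect no
  minima; too few beats in a window is an error naming the window; empty
  sections are flagged and inherited, not silently zeroed.

## Known limitations

* The range rule and the parametric Bragg profile are engineering
  approximations pinned to published constants — they are not stopping-power
  physics, and the profile's plateau shape between surface and peak is a
  documented invention.
* Translation-only registration cannot correct rotation or non-rigid
  section deformation.
* The ANOVA assumes equal variances (as the original analysis did); no
  nonparametric fallback is provided.
* The depletion band in the generator is defined in grid coordinates
  (depth from the grid's dorsal edge), a simplification of a true
  per-ray beam range.
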