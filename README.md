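# fishbeam

Quantitative analysis of **localized heavy-ion irradiation experiments in
small fish** (medaka, *Oryzias latipes*). A short-range carbon-ion beam
(26.7 MeV/u ¹²C⁶⁺, range ≈ 2.2 mm in water) irradiates only the dorsal or
ventral part of the body; the biological readouts are heart rate from
high-speed video and 3-D organ morphometry from serial histological
sections. fishbeam implements the computational procedures of such a study
as a tested, reusable R package, with seeded synthetic-data generators
standing in for the original videos and histology so every stage can be
verified against ground truth.

It is intended for radiation biologists and image-analysis engineers who
need to (re)run this style of analysis, audit its intermediate steps, or
benchmark variations of it.

## What is computed

**Dosimetry.** Absorbed dose of a uniform unidirectional beam is

```
Dose (Gy = J/kg) = fluence (/cm²) × LET (keV/µm) × 10⁷ (µm·cm²/kg) × 1.602×10⁻¹⁶ (J/keV)
```

(`fluence_to_dose()` / `dose_to_fluence()`), with a parametric depth-LET
(Bragg) profile pinned to surface LET, peak LET, range and peak width
(`bragg_profile()`), a Bragg-Kleeman range-scaling rule
(`ion_range_water()`), and the irradiated band of an oval body
cross-section for a beam of given range and direction
(`irradiated_mask()`, `fraction_irradiated()`).

**Video heart rate.** Three heart-region ROI traces are averaged and a
reference ROI (body movement from ventilation) is subtracted frame by
frame; the signal is smoothed by a 21-frame centred moving average; local
intensity minima mark the end of diastole; interbeat intervals give
beat-by-beat rates HRᵢ = fps·60/IBIᵢ, averaged over a 3-minute window into
a steady-state heart rate (`run_heartrate_pipeline()` and the individual
stage functions).

**Serial-section 3-D morphometry.** Ordered labeled section images
(background / kidney / blood cell, 5 µm thickness) are registered by
translation (`align_stack()`), organ volume is voxel counting times
pixel² × thickness (`tissue_volume()`), and blood-cell content is profiled
per section and split dorsally/ventrally or in-field/out-of-field
(`blood_cell_profile()`, `regional_split()`, `volume_report()`).

**Group statistics.** One-way fixed-effects ANOVA at α = 0.05 from raw
values (`anova_oneway()`) or from printed per-group n/mean/SD
(`anova_from_summary()`), and Tukey HSD with the Tukey-Kramer correction
(`tukey_hsd()`).

**Synthetic data.** `gen_heart_trace()` / `gen_heart_video()` simulate
beating-heart recordings (renewal-process beats, asymmetric cardiac pulse,
common-mode 2 Hz ventilation artifact, Gaussian noise) and
`gen_section_stack()` simulates jittered ellipsoidal kidney stacks with
optional dorsal-band or whole-organ blood depletion — each returning its
ground truth.

## Worked example

```r
library(fishbeam)

# dose bookkeeping at the surface LET of the carbon beam
fl <- dose_to_fluence(15, 78.4)   # 119429794 particles/cm²
fluence_to_dose(fl, 78.4)         # 15 Gy
ion_range_water(26.7, 12, 6)      # 2.456 mm (transport-code value ~2.2 mm)

# heart rate from a synthetic 60-s recording at a true 170 bpm
p  <- heart_sim_params(true_hr_bpm = 170, duration_s = 60, seed = 7)
tr <- gen_heart_trace(p)
res <- run_heartrate_traces(tr$heart_traces, tr$reference_trace,
                            fps = 300, window_seconds = 60)
res$summary
#> Steady-state heart rate: 169.3 bpm (SD 5.7, 168 beats over 60s)

# the published day-7 group table, retested from its printed summaries
day7 <- data.frame(label = c("control", "DR", "VR"), n = c(6, 6, 4),
                   mean = c(171, 172, 170), sd = c(7.78, 6.99, 6.47))
anova_from_summary(day7)
#> One-way ANOVA: F(2, 13) = 0.09423, p = 0.9107 (not significant at alpha = 0.05)

# a dorsally depleted kidney stack: alignment, volume, regional split
g  <- gen_section_stack(section_sim_params(depletion = "dorsal_band",
                                           depletion_depth_um = 520,
                                           depletion_factor = 1,
                                           jitter_sd_px = 2, seed = 11))
al <- align_stack(g$stack)
rs <- regional_split(al$aligned)
tissue_volume(al$aligned)  # 5.49e7 µm³
c(rs$dorsal_fraction, rs$ventral_fraction)
#> 0.000 0.221
```

The heart-rate summary is the mean and SD of beat-by-beat rates over the
window (169.3 bpm against a generated 170, inside the pipeline's ±1 bpm
recovery tolerance). The ANOVA line shows that the printed day-7 group
summaries reproduce the published non-significant comparison. In the
volumetry example the dorsal half of the kidney has lost its blood-cell
label entirely (fraction 0.000) while the ventral half stays near the
25% baseline — the localized-lesion signature, as opposed to uniform
whole-organ depletion.

A thin command-line wrapper over these functions is installed at
`inst/cli/fishbeam.R` (subcommands `dose`, `heartrate`, `volumetry`,
`stats`, `stats-summary`, `simulate-trace`, `simulate-sections`).

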