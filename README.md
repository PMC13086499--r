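# rangepet

On-line PET measurement of proton-induced **activity range (AR)**, as a
fully synthetic, tested pipeline in R.

Proton therapy places most of its dose at the Bragg peak, so the beam
range must be verified at millimetre precision. Protons activate the
irradiated medium, producing positron emitters whose annihilation
photons a PET scanner around the target can image immediately after beam
delivery. The extent of this activity along the beam axis — the AR,
measured between the proximal and distal 50%-falloff edges of the
beam-axis intensity profile — tracks the beam range, and the difference
between a measured AR (or its distal edge) and a reference is the
**range shift** an adaptive treatment plan would compensate.

`rangepet` is aimed at medical-physics researchers who want to study
this measurement chain — its count statistics, background sensitivity,
and geometric limits — without a scanner or a beam line. It provides:

* **Synthetic data** — a closed (20-panel) / open (18-panel) detector
  ring; gridded attenuation phantoms (water tank, Lucite bar in water,
  head-analog disc, radioactive cylinder); parametric proton-activity
  maps with analytic edge truth (Bragg–Kleeman range law, logistic
  distal falloff); a list-mode coincidence simulator with energy/timing
  resolution smearing (27.2% FWHM at 511 keV, 9.2 ns FWHM), chord
  attenuation thinning, optional scatter, and intrinsic-background
  randoms; blank scans.
* **List-mode operations** — 350–650 keV / 20 ns coincidence window
  selection, equal-count splitting, even temporal sub-sampling into
  dose-equivalent subsets, and blank-scan background injection.
* **Reconstruction** — MLEM/OSEM with a Siddon ray-traced projector
  (Rcpp), geometric sensitivity normalisation, no attenuation/scatter
  corrections (deliberately), and transverse-band profile extraction.
* **Range analysis** — smoothed-profile maximum-curvature turnover
  localisation, 50% edge interpolation, AR and range-shift computation,
  Gaussian FWHM fits for point sources.
* **Experiments** — point positioning, cylinder edge stepping, dose
  series, background series, and planned/overshot/undershot shift
  series, all reproducible from a config and a master seed.

The AR statistic: after Gaussian smoothing and spline refinement, the
"distal peak" is the maximum-curvature turnover at the start of the
final descent; the distal edge is the first outward crossing of half the
intensity at that turnover, and

```
AR = distal_edge50 − proximal_edge50,    shift = distal_edge50(test) − distal_edge50(reference).
```

## Worked example: measuring a range shift at low dose

Simulate a planned (1 range-shifter sheet) and an overshot (0 sheets)
109.4 MeV beam into a head-analog phantom at a 5 MU dose-analog,
reconstruct both without corrections on the open ring, and measure the
shift:

```r
library(rangepet)

geometry <- build_geometry("open_ring")          # 18 panels, beam can pass
phantom  <- build_phantom("head_analog")         # 160 mm head-analog disc
planned  <- build_activity(phantom, beam_spec(energy_mev = 109.4, dose_mu = 5,
                                              entrance_position_mm = -80,
                                              n_sheets = 1))
overshot <- build_activity(phantom, beam_spec(energy_mev = 109.4, dose_mu = 5,
                                              entrance_position_mm = -80,
                                              n_sheets = 0))
planned
#> <activity_map> model=beam: distal50=3.25 mm, proximal50=-79.00 mm, AR=82.25 mm

acq <- acquisition_spec(background_rate_per_s = 2000, seed = 1)
ars <- lapply(list(planned = planned, overshot = overshot), function(act) {
  events <- simulate_listmode(geometry, phantom, act, acq)
  kept   <- select_coincidences(events, window_spec(350, 650, 20))
  image  <- reconstruct_events(kept, geometry,
                               recon_spec(n_subsets = 1, n_iterations = 10))
  measure_ar(combine_band(image, band_halfwidth_mm = 9))
})
ars$planned
#> <ar_estimate> distal50 = 2.45 mm, proximal50 = -79.41 mm, AR = 81.86 mm
ars$overshot
#> <ar_estimate> distal50 = 9.03 mm, proximal50 = -79.44 mm, AR = 88.47 mm
measure_shift(ars$overshot, ars$planned)
#> [1] 6.58
```

The analytic truth of the planned beam puts the distal 50% edge at
+3.25 mm; the measured distal edges sit within the reconstruction's
resolution blur of their truths, the blur cancels in the difference, and
the measured shift of **+6.58 mm** recovers the expected +6.8 mm sheet
shift to ~0.2 mm at roughly 1.2×10⁵ selected coincidences. Across 9
seeds and both shift directions the pipeline recovers shifts with a mean
absolute error of ≈0.4 mm (sd ≈0.2 mm) at the 5 MU-analog level — the
paper-scale accuracy regime for low-dose probing beams.

Higher-level drivers wrap such designs with replicate statistics, e.g.

```r
run_shift_series(dose_mu = 5, seeds = 1:9)$summary
run_dose_series(doses_mu = c(1, 5, 10, 25), seeds = 1:9)$summary
```

A thin CLI over the same functions lives at `inst/cli/rangepet.R`
(`select`, `subsample`, `inject`, `recon`, `measure`, `experiment`
subcommands); the default configuration, with every tunable stated, is
`inst/extdata/rangepet.yaml` (see `default_config()` / `read_config()`).

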