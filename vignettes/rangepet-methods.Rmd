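---
title: "Measuring proton activity range with a partial-ring PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring proton activity range with a partial-ring PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangepet)
```

## The measurement problem

Proton beams deposit most of their dose at the end of their range (the
Bragg peak), so millimetre-level range errors translate directly into
dose delivered to the wrong tissue. Protons also activate tissue: nuclear
interactions along the beam path produce positron emitters whose
annihilation photons can be imaged by a PET scanner placed around the
patient right after (or during) irradiation. The extent of that induced
activity along the beam axis — the **activity range (AR)** — tracks the
beam range, and the difference between a measured AR and its planned or
reference value is the **range shift** that an adaptive treatment would
compensate.

`rangepet` implements this measurement chain end to end on synthetic
data: a parametric model of the proton-induced activity, a list-mode
coincidence simulator for a brain-sized detector ring (including the
open-ring configuration with two detector panels removed so the beam can
pass), an uncorrected MLEM/OSEM reconstruction, and the falloff-edge
statistic that turns beam-axis intensity profiles into AR values and
range shifts. The experiment drivers reproduce the canonical study
designs — point-source positioning, cylinder-edge localisation, dose
series, background series, and range-shift series — with replicate
statistics.

## Scanner geometry

The ring holds 20 flat-panel detector positions (closed ring) of 32
in-plane crystals each, at a nominal 418 mm inner diameter and 2.09 mm
crystal pitch; the open ring removes the two panels straddling the +x
and −x beam ports, leaving 18. The simulation is two-dimensional in the
beam-containing plane; the axial dimension is carried as metadata only.

Each detector occupies an 18° angular sector, and its crystal row is
discretised into equal angular bins whose centres lie exactly on the
nominal ring circle (an *arc* layout). For flat panels of this width the
edge-crystal centres would sit up to ≈2.5 mm outside the ring circle —
more than one crystal pitch — so the arc layout is the self-consistent
reading of "crystals on a 418 mm ring" at this panel count, and it makes
the angular binning of photon directions exact. The geometric
consequences that matter for the AR statistic (gap-induced angular
undersampling in the open ring, crystal-pitch-limited LOR resolution)
are preserved.

## Activity model

Rather than simulating nuclear interactions, the activity is a
parametric stand-in with the features the AR statistic relies on: a
linear entrance ramp of width 2 mm, a unit plateau, and a logistic
distal falloff

$$A(d) \;=\; \mathrm{ramp}(d;w_p)\cdot\frac{1}{1+\exp\!\big((d-d_{50})/w_d\big)},$$

extruded laterally with a Gaussian of width `beam_sigma_mm` (default
4.5 mm, matching a ~9 mm beam radius). The falloff scale $w_d$ defaults
to an 80%→20% span of 4 mm. The 50% depth follows the Bragg–Kleeman
range law $R_\text{water}(\mathrm{cm}) = 0.0022\,E^{1.77}$ divided by
the medium's relative stopping power (Lucite 1.16), minus
`n_sheets × sheet_wet_mm` for inserted range-shifter sheets. The
water-equivalent shift per 6.4 mm Lucite sheet is a configuration
default of 6.8 mm: the physical-to-water-equivalent conversion is a
property of the sheets that the simulation takes as given rather than
derives.

Every activity map carries analytic **truth**: the 50% crossings of the
continuous noiseless template. The reference level for "50%" is the
template value at its maximum-curvature turnover (located by
root-finding), i.e. exactly the convention the edge statistic applies to
measured profiles. Defining truth against the plateau instead would
build a ≈0.6 mm systematic offset into every comparison, because the
turnover of a logistic sits at level $(3+\sqrt3)/6 \approx 0.79$ of the
plateau and the 50%-of-turnover crossing is correspondingly distal of
the plateau-midpoint.

Point sources are stored as continuous coordinates and sampled directly
at emission time, so sub-pixel positioning truth is exact rather than
quantised to the activity grid.

## List-mode simulation

For a dose of $D$ MU the simulator draws
$N \sim \mathrm{Poisson}(D \cdot \texttt{counts\_per\_mu})$ annihilation
events, with positions sampled from the activity map (uniform within a
voxel) and isotropic in-plane LOR directions. Both photons must strike
active crystals; survivors are thinned by the chord attenuation factor
$\exp(-\int \mu\,dl)$ computed by the same Siddon ray tracer the
reconstruction uses, over a 511 keV attenuation map (water 0.0096/mm,
Lucite 0.0111/mm, head-analog 0.0100/mm). Photon energies are Gaussian
around 511 keV with 27.2% FWHM; the coincidence time difference is
Gaussian with 9.2 ns FWHM. Intrinsic scintillator background is modelled
as random coincidences on uniformly drawn active crystal pairs at
`background_rate_per_s`, with a uniform 200–700 keV spectrum and a
uniform ±20 ns pairing spread (the hardware pairing window, wider than
the 20 ns full-width analysis window, so selection suppresses randoms by
roughly 5×). An optional scatter model deflects the second photon by a
10° (σ) Gaussian and draws its energy from a rising triangular
distribution on 250–511 keV; it is off by default since no scatter
correction is applied anywhere.

All stochastic draws derive from named substreams of one master seed
(`emission`, `attenuation`, `energy`, `timing`, `background`, ...), so
paired designs — the same emissions through a filled and an empty water
tank — differ only where they should, and every event list is
byte-reproducible.

**Calibration of `counts_per_mu`.** The scanner's true-coincidence yield
per MU is a property of the physical detector that the simulation cannot
derive. The default (92 000 emitted coincidences per MU) is calibrated
once so that the 25 MU head-analog acquisition yields ≈5×10⁵ selected
coincidences, which puts the 5 MU-analog level near 10⁵ selected
coincidences — the count regime in which reliable shift detection is
claimed. The default background rate (2000/s raw) makes a 60 s blank
comparable, after window selection, to the trues of a 1 MU-equivalent
dataset, so the 0–60 s injection series spans the interesting
degradation range.

## Reconstruction

Events are histogrammed per unordered crystal pair and reconstructed by
multiplicative MLEM/OSEM on a 160×160 grid of 2 mm pixels:

$$x \leftarrow \frac{x}{s_k}\, A_k^{\mathsf T}\!\left(\frac{y_k}{A_k x}\right),$$

where $A$ is the Siddon projector between crystal centres (exact
chord-length weights; the forward/back pair is an exact adjoint, which
the tests verify to numerical precision), $s_k = A_k^{\mathsf T}\mathbf 1$
is the subset sensitivity over *all* existing LORs, and subsets are
formed by projection-angle stride. No attenuation, scatter, randoms or
resolution corrections are applied — deliberately, since the AR
statistic is ratio-based and local to the falloff region, and the
measurement's robustness to the resulting image distortions is exactly
what the experiments probe. With one subset the algorithm is plain MLEM;
the update conserves $\sum_j s_j x_j = \sum_i y_i$ at every iteration
and is monotone in the Poisson log-likelihood, both of which are tested.
LORs whose chord misses the image grid (e.g. randoms between neighbouring
crystals) carry no tomographic information and are dropped from the
data; 2 mm pixels are adequate for a scanner whose intrinsic resolution
is several millimetres, with sub-pixel precision recovered at the
profile level. Division guards use a floor of 10⁻¹² relative to the
forward projection's maximum. The initial image is uniform on the
positive-sensitivity support.

Beam-axis profiles are obtained by summing a transverse band of ±9 mm
(the beam radius) around the beam axis — the 2-D counterpart of
combining similar-intensity coronal slices for count statistics.

## The AR statistic

`measure_ar()` composes four steps:

1. **Smoothing**: Gaussian kernel, σ = 2 mm by default, reflective
   boundaries.
2. **Refinement**: cubic-spline interpolation onto a 0.1 mm grid. This
   supplies the sub-pixel precision of all position outputs; on
   noiseless templates it keeps the distal-edge error below 0.05 mm even
   at 2 mm sampling.
3. **Turnover (the "distal peak")**: on the max-normalised profile, the
   candidate turnovers are local maxima of the concave-down second
   difference; candidates below 25% of the global maximum (tail noise)
   or below 30% of the strongest candidate's curvature are rejected, and
   the most distal survivor is taken (mirrored for the proximal side).
   The level guard and the distal-most rule matter on real profiles:
   uncorrected attenuation produces a hot spot at the beam entrance
   whose shoulder has the globally largest curvature, and the turnover
   of interest is the *last* one before the final descent, not the
   strongest. A profile with no concave-down curvature above numerical
   noise has no turnover and raises an error. When no interior curvature
   peak survives the level guard (an under-resolved edge), the plain
   maximum-curvature sample in the qualified region is used.
4. **Edge**: the reference level is half the profile value at the
   turnover; scanning outward from the turnover, the first crossing is
   located by linear interpolation between bracketing samples.

AR is the distance between the distal and proximal 50% edges. The
statistic is invariant under intensity scaling and equivariant under
translation (tested). Range shifts are reported as distal-edge
differences by default — the proximal edge is pinned by the beam
entrance — with an AR-difference convention available in configuration.

A fixed systematic offset between the measured edge and the analytic
truth (≈0.5–0.7 mm at these counts and pixel sizes) comes from the
reconstruction's resolution blur. It cancels in every shift, step and
paired comparison, which is why the experiment designs are differential.

## Experiment designs and problem sizes

The drivers run at desk-scale sizes chosen to keep a full replicate
suite in minutes while preserving the count regimes of interest; all are
configurable.

* `run_point_positioning()`: 21 positions from −100 to +100 mm, closed
  ring, 3×10⁴ emissions each, OSEM 5×10, Gaussian-fitted centres,
  measured-vs-physical regression. With or without the water tank.
* `run_cylinder_edge()`: 7 positions in 0.5 mm steps, 9 equal-count
  subsets per acquisition, MLEM 1×20, per-position mean ± sd of the
  distal edge and a step regression.
* `run_dose_series()`: one full 25 MU acquisition per seed (including
  its intrinsic background), lower doses derived by even temporal
  sub-sampling (round-robin on the time-sorted events), MLEM 1×10, AR
  per dose level. Sub-sampling a single acquisition mirrors the
  even-sampling construction of dose-equivalent datasets and keeps the
  background proportional.
* `run_background_series()`: reference AR from the full acquisition; the
  test dataset is one 1 MU-equivalent subset plus increasing durations
  (0–60 s) of a separately simulated blank scan, timestamp-remapped into
  the acquisition window.
* `run_shift_series()`: planned/overshot/undershot beams (1/0/2 sheets)
  on the head-analog phantom at a chosen dose-analog, 9 seeds; measured
  shifts against ±6.8 mm.

"Dose" is throughout a count-analog: MU × counts-per-MU expected
coincidences. No absolute dosimetry is claimed.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the measurement
relies on — Poisson counts linear in dose, energy/timing acceptance with
the measured resolutions, attenuation-driven acceptance loss and image
distortion, angularly incomplete open-ring sampling, and a flat randoms
background — under a single effective positron-emitting species with a
stationary, analytically shaped activity profile. It does not model
nuclear-physics production profiles, isotope mixtures with different
half-lives and positron ranges, biological washout, detector dead time,
depth-of-interaction effects, or patient-like heterogeneity. Passing
tests therefore validate the measurement chain and its noise behaviour,
not the radiobiology: on real data the absolute AR carries physics the
template does not contain, while shift-type comparisons transfer most
directly.

## Numerical choices

* Logistic width from an 80→20 span: $w_d = \mathrm{span}/(2\ln 4)$.
* Truth crossings by `uniroot` at 10⁻⁹ mm tolerance; turnover by
  `optimize` on a finite-difference second derivative (h = 10⁻³ mm).
* Ties in the turnover search break distal (proximal side: proximal);
  multiple 50% crossings resolve to the first one outward from the
  turnover.
* The Gaussian point-fit restricts itself to ±8 initial-σ around the
  peak and falls back from `nls` to `minpack.lm::nlsLM` on convergence
  failure.
* `split_equal_count` puts remainder events in the earliest subsets;
  `subsample_temporal` is deterministic index round-robin on time-sorted
  events (an "even sample over the acquisition" rather than random
  thinning, so subsets are exactly interchangeable and reassemble to the
  input). A consequence: subset inter-event times are Erlang-distributed
  rather than exponential; the subsets match a thinned process in rate
  and coverage, not in inter-arrival law.
* The blank-injection remap draws uniform timestamps over the base
  acquisition window (seeded) and preserves each event's internal time
  difference.

## Known limitations

* The proximal edge of a profile whose entrance ramp is narrower than
  the sampling cannot be localised better than the ramp itself; the
  distal statistic is unaffected.
* At 1 MU-analog counts the turnover search can latch onto noise
  structure in the falloff, inflating shift errors — consistent with
  shifts being reported as unreliable below the 5 MU-analog level.
* The 2-D plane cannot represent axial slice selection; the transverse
  band sum is its stand-in.
* Randoms are uniform over crystal pairs; a real scanner's intrinsic
  background has geometric structure that partially survives selection.
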