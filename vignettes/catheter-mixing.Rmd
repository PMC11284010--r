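---
title: "Assessing saline-blood mixing of coronary infusion catheters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing saline-blood mixing of coronary infusion catheters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Continuous-infusion thermodilution estimates absolute coronary blood flow
from the steady-state temperature `T` of saline infused continuously into
the artery: the flow follows from the energy balance between blood at
`Tb` and infusate at `Ti`. The estimate is only meaningful if infusate and
blood are mixed homogeneously where the distal sensor sits — within a few
centimetres of the catheter tip. Two catheter topologies are in clinical
use: a dedicated infusion catheter with four 100 µm *side holes* near the
tip and the pressure/temperature wire running *inside* it, and a generic
microcatheter with a single coaxial *end hole* and the wire *alongside*.

`coromix` implements, as reusable and tested code, the three assessment
pipelines used to compare these topologies, together with a desk-scale
scalar-transport simulator that generates the temperature fields the
pipelines consume:

1. **Cross-section statistics.** At stations distal to the infusion site,
   the time-averaged temperatures `T_m,k` at `n` area-uniform sample
   points (wire points excluded) are reduced to a deviation statistic
   `SD_t = sqrt( sum_k (T_m,k - Tbar)^2 / n )` and a Shannon-entropy
   ratio `E = mean(-P_k ln P_k) / (-P* ln P*)`, where
   `P = (Tb - T)/(Tb - Ti)` is the dilution probability and
   `P* = Qi/(Qb + Qi)` its perfect-mixing value. `SD_t = 0` and `E = 1`
   signal a homogeneous cross-section; `E` is not calculable when no
   tracer has reached any sample point.
2. **Pullback analysis.** A sensor is withdrawn from 6 cm distal to the
   tip while recording temperature; the trace is smoothed with a 2 s
   rolling mean, normalised to N = 1000 points, expressed as percentage
   deviations from the pullback mean, and summarised by the fraction of
   points deviating more than 15% and 20%.
3. **Projectional (ink) classification.** The single-view bench judgement
   "uniform colour over the diameter within 1–3 cm of the tip" is
   operationalised on line-of-sight-averaged dilution images, plus the
   contingency tabulation of replicate pass/fail outcomes.

## Formula renderings

Two of the printed formulas admit more than one reading; the package fixes
them as follows and exposes the alternative for audit:

* The cross-section "standard deviation" is implemented as the RMS
  deviation (default), because that is what the name denotes; the literal
  mean-absolute-deviation rendering is available via `method = "mad"`.
* The raw mean entropy `mean(-P ln P)` cannot reach 1 at homogeneity for
  arbitrary `P*`; normalising by the perfect-mixing entropy `-P* ln P*`
  calibrates `E = 1` exactly at `P_k = P*` for every flow/infusion
  combination, and explains observed values slightly above 1 (the local
  probabilities can sit nearer the entropy maximum at `1/e` than `P*`
  does). The un-normalised mean is returned as `raw_mean_entropy`.
  The ratio is invariant to the logarithm base.

For the pullback deviations the percentages are computed on the recorded
degC scale: that is the scale on which the 15%/20% clinical-variability
bands are defined, and moving to an absolute scale would change every
magnitude.

## The transport simulator

The simulator stands in for a full 3D CFD solve. It advances the energy
equation as a passive scalar on a cell-centred cylindrical lattice
(axial × radial × angular) with:

* a prescribed quasi-steady axial velocity: annular laminar-like profiles
  around the catheter shaft (upstream) and around the central wire or past
  the alongside wire (downstream), renormalised every step so the section
  flux equals the instantaneous coronary flow plus, downstream of the tip,
  the infusion flow. The flux jump at the tip slab is treated
  conservatively: the per-cell flux mismatch is exchanged with a
  flux-weighted donor pool, so the global energy balance closes and the
  update remains a convex combination (the scalar obeys the maximum
  principle exactly);
* a pulsatile inflow waveform: a non-negative diastolic-dominant
  two-harmonic shape with unit mean, scaled by the mean flow and a
  pulsatility index (default 0.7). The waveform shape is a modelling
  choice — only the mean flows are fixed by the study design;
* catheter-specific injection sources at the tip: four equal wall sources
  at 90° spacing (side-hole) or a Gaussian-weighted coaxial jet displaced
  slightly away from the alongside wire (end-hole), applied implicitly so
  the source cells relax boundedly toward `Ti`;
* an effective transverse diffusivity: molecular thermal diffusivity of
  water (0.143 mm²/s) plus a pulsatile background and a near-field
  jet-mixing enhancement decaying downstream of the tip. The enhancement
  is the simulator's main closure: side-hole jets enter the crossflow
  transversely and mix vigorously (default 30 mm²/s, 20 mm decay,
  calibrated so the side-hole entropy ratio reaches at least 0.95 by
  1.2 cm — near-complete homogenisation close to the tip), whereas the
  coaxial end-hole jet mixes at near-molecular rates (0.3 mm²/s, 10 mm
  decay, background 0.05 mm²/s). These constants are named configuration
  values, not hidden numbers;
* a buoyant drift closure for the bench fluid pairing: room-temperature
  saline is ~0.9% denser than the 37 °C blood analog, so infusate-rich
  fluid sinks. The drift is `0.4 v_s + 0.6 v_s P` downward with
  `v_s = 10` mm/s at full contrast — a plume-velocity scale
  `sqrt(g' d) ≈ 5–10 mm/s` — where the uniform 40% share represents the
  bulk downdraft the sinking plume drags with it (without it, a
  momentum-free settling closure leaves an artificial slow-sinking tail
  along the release line). The water-into-water simulation mode treats
  both fluids as identical apart from the transported temperature, so its
  settling is zero, matching the reference simulations' equal-property
  simplification. Transverse drift fluxes use a van Leer flux-limited
  second-order scheme: first-order upwinding would smear the thin
  end-hole cold core at a rate comparable to its physical diffusivity.

Runs start from a uniform `Tb` field and simulate complete cardiac cycles;
only the final cycle is analysed, the earlier ones flush the start-up
transient. Two cycles suffice at medium and high flow; at low coronary
flow the bulk transit time (~0.9 s) does not fit comfortably inside a
single flush cycle, so the spin-up extends itself (transit-aware default)
until the analysed cycle is at periodic steady state — the stored output
remains exactly one cycle. The time step is chosen from the explicit
stability limit (advection, diffusion with the angular metric at the
innermost open ring, drift) with a 0.7 safety factor; a user-supplied
step violating the limit is rejected with a diagnostic.

Default lattices are 140 × 8 × 12 (side-hole; 0.5 mm × 0.25 mm cells) and
140 × 16 × 16 (end-hole): the end-hole cold core is only ~0.6 mm wide and
needs the finer transverse cells to survive discretisation. These sizes
keep a full eight-combination sweep within a few minutes on one core
while leaving the cross-section statistics stable under refinement: the
entropy ratio at the proximal station changes by well under 15% when the
spacing is halved, and the side-hole `SD_t` stays below the 0.05 °C
uniformity floor (0.6% of the 8 °C contrast) at both resolutions — for a
statistic that is essentially zero, a relative comparison is not
meaningful, so the convergence check uses that absolute floor.

### What the generator emulates, and what it does not

The simulator reproduces the features the assessment pipelines rely on:
the topology contrast (distributed transverse injection homogenises
within ~1 cm; a coaxial jet leaves a persistent cold core), energy
conservation (flux-weighted outlet temperature equals the perfect-mixing
temperature to well under 1% of the contrast), scalar bounds, the
pulsatile modulation of the fields, and — on the bench pairing — the
buoyant escape of the cold core from the sensor line that produces the
characteristic pullback signature (cold near the tip, near-blood
temperature distally). It does **not** solve momentum: no secondary-flow
vortices, no turbulence, no vessel curvature or cardiac compression, no
fluid-structure interaction, and the viscosity contrast between blood
and saline enters only through the drift closure. Passing tests
demonstrate the correctness and the qualitative fidelity of the
*pipeline*, not solver-grade accuracy of any individual field value;
exact cross-section values from a full CFD solve depend on unpublished
solver settings and are deliberately out of scope.

## The in-silico sensor

Where the sensor rides during a pullback is not a printed coordinate; the
defaults encode the reading that the end-hole sensor is pulled through
the cold core: side-hole sensors sit just outside the central wire
(radial offset `rw + 0.1` mm, angle arbitrary by symmetry), end-hole
sensors on the initial jet axis (0.1 mm offset toward the side away from
the wire). Both are arguments of `virtual_pullback()`. Sensor noise is
optional, Gaussian, and always explicitly seeded.

## The ink classifier

The bench judgement was human and binary; the classifier makes it
operational: per axial station in the 1–3 cm window, the coefficient of
variation of line-of-sight-averaged dilution across the projected
diameter must stay at or below `cv_threshold` (default 0.35) at every
station. The default threshold was calibrated once so that simulated
side-hole images pass and end-hole images fail at the medium-flow
combination, mirroring the still-frame outcome; simulated side-hole
images score CV ≤ 0.03 and end-hole images CV ≥ 1.4, so the verdict is
insensitive to the threshold over an order of magnitude. A station with
zero mean intensity (no tracer) fails. Raising the threshold can never
turn a pass into a fail.

## Worked example

```{r example}
library(coromix)

p_side <- flow_protocol(150, 15, "side_hole")
p_end  <- flow_protocol(150, 15, "end_hole")
f_side <- simulate_mixing(p_side)
f_end  <- simulate_mixing(p_end)

rbind(side = mixing_measures(f_side, 1.2),
      end  = mixing_measures(f_end, 1.2))

prof <- longitudinal_profile(f_side)
attr(prof, "sd_threshold_station_cm")   # homogenisation distance, cm

classify_mixing(project_field(f_side))  # PASS
classify_mixing(project_field(f_end))   # FAIL

tabulate_pass_fail(ink_bench_counts())$pass_rate
```

The full orchestration — simulate, per-station metrics, longitudinal
profile, virtual pullback, ink verdict, CSV/JSON output with config-hash
and seed stamps — is `run_pipeline()` driven by a YAML configuration
(`read_run_config()`; the bundled default reproduces the study geometry
and flow table).

## Known limitations

* The solver is a scalar-transport emulator with prescribed kinematics;
  all momentum-driven mixing enters through calibrated effective
  diffusivities and the drift closure.
* Cross-section field values are resolution- and closure-dependent;
  ordering and threshold properties (side-hole vs end-hole) are the
  supported conclusions.
* The polar lattice is coarse near the axis; sub-cell core structure is
  represented by at most a few cells even on the finer end-hole lattice.
* Recorded bench pullbacks can be ingested (`read_pullback_csv()`), but
  the packaged validation rests on synthetic traces; the original
  recordings are not distributed.
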