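# coromix

Quantitative assessment of saline–blood mixing by coronary infusion
catheters.

Continuous-infusion thermodilution measures absolute coronary blood flow
and microvascular resistance from the steady-state temperature of saline
infused continuously into the artery. The method presumes that infusate
and blood are mixed homogeneously a few centimetres distal to the
catheter tip — a property that depends strongly on the catheter's
injection topology: four distributed 100 µm **side holes** (sensor wire
inside the catheter) versus a single coaxial **end hole** (wire
alongside). `coromix` provides, for researchers in coronary physiology
and catheter engineering:

* a desk-scale pulsatile **scalar-transport simulator** of the
  catheterised vessel (4 mm × 70 mm, catheter outlet 10 mm in, 0.36 mm
  wire) producing time-resolved temperature fields for both topologies,
  with conservative flux handling, a maximum-principle-exact explicit
  scheme (Rcpp), and a buoyant-settling closure for the bench fluid
  pairing;
* the **cross-section mixing statistics**: time-averaged deviation
  `SD_t = sqrt( Σ_k (T_m,k − T̄)² / n )` and the Shannon-entropy ratio
  `E = mean(−P_k ln P_k) / (−P* ln P*)` with dilution probability
  `P = (T_b − T)/(T_b − T_i)` and perfect-mixing fraction
  `P* = Q_i/(Q_b + Q_i)`, on an area-uniform polar sample lattice with
  wire-point exclusion; `SD_t = 0` and `E = 1` denote homogeneity;
* the **pullback deviation analysis**: 2 s rolling mean, normalisation to
  N = 1000 points, relative deviations `ΔT_rel,i = (T_i − T̄_pb)/T̄_pb·100%`,
  and 15%/20% exceedance fractions;
* the **projectional (ink) classifier**: line-of-sight-averaged dilution
  images, a coefficient-of-variation uniformity criterion over the 1–3 cm
  window, and pass/fail contingency tabulation with per-catheter pass
  rates.

## Worked example

```r
library(coromix)

p_side <- flow_protocol(150, 15, "side_hole")   # MED flow, 15 mL/min
p_end  <- flow_protocol(150, 15, "end_hole")
f_side <- simulate_mixing(p_side)               # ~9 s on one core
f_end  <- simulate_mixing(p_end)                # ~22 s (finer lattice)

rbind(side = mixing_measures(f_side, 1.2),      # 1.2 cm distal to the tip
      end  = mixing_measures(f_end, 1.2))
#>      station_cm      sd_t entropy_ratio n_used calculable
#> side        1.2 0.0091...        1.07      128       TRUE
#> end         1.2 1.07...          0.36      127       TRUE

classify_mixing(project_field(f_side))
#> <mixing_verdict> PASS (max CV 0.010 at 1.0 cm, threshold 0.35)
classify_mixing(project_field(f_end))
#> <mixing_verdict> FAIL (max CV 1.494 at 1.0 cm, threshold 0.35)

tabulate_pass_fail(ink_bench_counts())$pass_rate
#>    catheter pass fail pass_rate_pct pass_rate_pct_rounded
#> 1  end_hole    1   44      2.222222                     2
#> 2 side_hole   40    5     88.888889                    89
```

Reading: at 1.2 cm the side-hole cross-section is already homogeneous
(`SD_t ≈ 0.01 °C`, `E ≈ 1`) while the end-hole section carries an intact
cold core (`SD_t ≈ 1 °C`, `E ≪ 1`); the projected dilution images
classify accordingly, and the bench ink study's 45 replicate outcomes per
catheter tabulate to 89% vs 2% pass.

The full pipeline — simulation, per-station metrics, longitudinal
profiles, virtual sensor pullbacks, ink verdicts, CSV/JSON artifacts
stamped with config hash and seed — is `run_pipeline()`, driven by a YAML
configuration (`read_run_config()`; the bundled default reproduces the
study geometry and the nine clinical flow/infusion combinations, of which
four per catheter are simulated).

See the vignette (`vignettes/catheter-mixing.Rmd`) for the transport
model, its closures and calibration choices, and known limitations.

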