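# Default coromix pipeline configuration: the idealised catheterised
# coronary segment and the four simulated flow/infusion combinations per
# catheter topology.
protocols:
  set: cfd        # cfd | clinical, or an explicit list of combinations
  mode: cfd       # cfd: infusate exits at 29 degC; bench: 23 degC saline
geometry:
  vessel_diameter: 4            # mm
  vessel_length: 70             # mm
  catheter_outer_diameter: 0.84 # mm
  wire_diameter: 0.36           # mm
  outlet_axial_position: 10     # mm from the vessel inlet
  side_hole_diameter_um: 100
  side_hole_count: 4
solver: {}        # solver_config() overrides, e.g. {nz: 140, nr: 8}
stations_cm: [1.2, 4.4]         # prox / dist metric stations
profile_stations_cm: [0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0,
                      2.2, 2.4, 2.6, 2.8, 3.0, 3.2, 3.4, 3.6, 3.8, 4.0,
                      4.2, 4.4, 4.6, 4.8]
pullback:
  duration_s: 20
  sample_rate_hz: 20
  noise_sd: 0.02  # degC sensor noise on virtual pullbacks
ink:
  cv_threshold: 0.35
  window_cm: [1, 3]
seed: 1
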