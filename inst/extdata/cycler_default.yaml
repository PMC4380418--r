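# Default cycler configuration: four-segment rotary-zone wheel with 55 g
# aluminum blocks (73.6 degree arc), FEP 406/794 um sample capillary
# engaged over ~4 uL of sample, and the standard stepper motion settings.
# steps_per_segment is calibrated from the observed 1.32 s single-segment
# transition rather than assumed from microstep resolution.
schema_version: 1
materials:
  water:         {k: 0.606, rho: 997,  cp: 4181}
  FEP:           {k: 0.195, rho: 2150, cp: 1172}
  polycarbonate: {k: 0.20,  rho: 1200, cp: 1200}
  aluminum:      {k: 205,   rho: 2700, cp: 897}
  thermocouple:  {k: 25,    rho: 8700, cp: 450}
capillary:
  inner_diameter_m: 406.0e-6
  outer_diameter_m: 794.0e-6
  material: FEP
  sample_material: water
  inclusions: []
engagement:
  contact_length_m: 0.0309    # engaged length giving ~4 uL of sample in the bore
blocks:                       # wheel position order; position 0 is unheated
  - {mass_kg: 0.055, material: aluminum}
  - {mass_kg: 0.055, material: aluminum, setpoint_C: 60}
  - {mass_kg: 0.055, material: aluminum, setpoint_C: 72}
  - {mass_kg: 0.055, material: aluminum, setpoint_C: 98}
wheel:
  num_segments: 4
  arc_span_deg: 73.6
  harness_twist_limit_deg: 270
  observed_single_transition_s: 1.32
motion:
  acceleration_usteps_s2: 6103.52
  max_velocity_usteps_s: 4000
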