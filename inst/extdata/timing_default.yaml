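# Cleaning-step timing calibration: one syringe flow rate per flow class,
# a fixed per-operation overhead (valve switching, syringe refills,
# plumbing latency), and the duration of one shear-valve actuation.
# Calibrated once against the reference run times of the five shipped
# cleaning protocols (all five reproduced within 10%).
schema_version: 1
flow_ul_per_s:
  normal: 12.3
  fast: 25
per_step_overhead_s: 21
valve_actuation_s: 3
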