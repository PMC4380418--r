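# Baseline (conservative) between-run cleaning protocol.
# Step volumes not individually published were reconstructed so that the
# protocol's reagent totals match the reference feature table
# (270 uL bleach, 4.3 mL water); they can be overridden here.
schema_version: 1
id: A
flags:
  valve_rotation_wash: yes
  final_inlet_flush: yes
  dedicated_wheel_wash: full
  inlet_wash: yes
steps:
  - {action: flush, reagent: water, volume_ul: 500, phase: frame,
     note: full syringe of water through reactor to waste}
  - {action: aspirate, reagent: air, volume_ul: 50, phase: inlet_wash,
     note: air purge of sample introduction line}
  - {action: flush, reagent: water, volume_ul: 500, phase: inlet_wash,
     note: push aspirated liquid to waste through wheel}
  - {action: dispense, reagent: bleach, volume_ul: 30, repetitions: 3,
     phase: inlet_wash, note: bleach to inlet capillary tip}
  - {action: incubate, duration_s: 15, repetitions: 3, phase: inlet_wash}
  - {action: aspirate, reagent: bleach, volume_ul: 30, repetitions: 3,
     phase: inlet_wash, note: withdraw past upstream valve and discard to wheel}
  - {action: flush, reagent: water, volume_ul: 500, phase: inlet_wash,
     note: remaining bleach and syringe water through wheel}
  - {action: dispense, reagent: water, volume_ul: 90, repetitions: 3,
     phase: inlet_wash, note: water rinse of inlet}
  - {action: incubate, duration_s: 15, repetitions: 3, phase: inlet_wash}
  - {action: aspirate, reagent: water, volume_ul: 90, repetitions: 3,
     phase: inlet_wash}
  - {action: manual, duration_s: 75, phase: inlet_wash,
     note: "tip agitation in bleach / water / DNAzap 1 / DNAzap 2 / water"}
  - {action: dispense, reagent: water, volume_ul: 10, repetitions: 3,
     phase: inlet_wash, note: purge droplets from inlet}
  - {action: dispense, reagent: bleach, volume_ul: 30, repetitions: 3,
     phase: wheel_wash, note: bleach through heated capillary in increments}
  - {action: flush, reagent: water, volume_ul: 500, phase: wheel_wash}
  - {action: dispense, reagent: bleach, volume_ul: 90, phase: wheel_wash,
     note: bleach slug spanning both valves}
  - {action: actuate_valve, repetitions: 24, phase: valve_wash}
  - {action: incubate, duration_s: 10, repetitions: 2, phase: valve_wash,
     note: slug advance and incubation between actuation sets}
  - {action: flush, reagent: water, volume_ul: 500, phase: wheel_wash}
  - {action: dispense, reagent: water, volume_ul: 500, phase: wheel_wash,
     note: water slug spanning valves to remove residual bleach}
  - {action: actuate_valve, repetitions: 24, phase: valve_wash}
  - {action: incubate, duration_s: 10, repetitions: 2, phase: valve_wash}
  - {action: manual, duration_s: 75, phase: frame, note: outlet tip clean}
  - {action: flush, reagent: water, volume_ul: 500, phase: frame}
  - {action: flush, reagent: water, volume_ul: 500, phase: final_flush,
     note: final inlet flush}
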