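# Protocol D: inlet washes only; all dedicated wheel-washing
# operations eliminated (90 uL bleach, 2.3 mL water).
schema_version: 1
id: D
flags:
  valve_rotation_wash: no
  final_inlet_flush: no
  dedicated_wheel_wash: none
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
  - {action: manual, duration_s: 75, phase: frame, note: outlet tip clean}
  - {action: flush, reagent: water, volume_ul: 500, phase: frame}
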