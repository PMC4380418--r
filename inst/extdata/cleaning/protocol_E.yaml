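# Protocol E: minimal water-only rinse; no bleach, no inlet wash
# (0 uL bleach, 1.5 mL water from three 500 uL syringe flushes).
schema_version: 1
id: E
flags:
  valve_rotation_wash: no
  final_inlet_flush: no
  dedicated_wheel_wash: none
  inlet_wash: no
steps:
  - {action: flush, reagent: water, volume_ul: 500, phase: frame,
     note: full syringe of water through reactor to waste}
  - {action: manual, duration_s: 75, phase: frame, note: inlet tip clean}
  - {action: flush, reagent: water, volume_ul: 500, phase: frame}
  - {action: manual, duration_s: 75, phase: frame, note: outlet tip clean}
  - {action: flush, reagent: water, volume_ul: 500, phase: frame}
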