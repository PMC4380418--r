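# 32-cycle two-stage STR genotyping protocol (PowerPlex 16 HS): 2 min hot
# start at 96 degC, ten 94/60/70 cycles, twenty-two 90/60/70 cycles, and a
# 30 min final elongation at 60 degC. Five temperatures on a four-segment
# wheel: the hot-start block is re-targeted from 96 to 90 degC after the
# hot start and must stabilize (~18 min) before stage-2 cycling engages it.
schema_version: 1
id: powerplex16
hot_start: {temp_C: 96, duration_s: 120}
stages:
  - cycles: 10
    steps:
      - {temp_C: 94, dwell_s: 30}
      - {temp_C: 60, dwell_s: 30}
      - {temp_C: 70, dwell_s: 45}
  - cycles: 22
    steps:
      - {temp_C: 90, dwell_s: 30}
      - {temp_C: 60, dwell_s: 30}
      - {temp_C: 70, dwell_s: 45}
final_step: {temp_C: 60, duration_s: 1800}
setpoint_changes:
  - {from_temp_C: 96, to_temp_C: 90, after_stage: 0, stabilization_s: 1080}
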