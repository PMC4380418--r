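# Second-strand cDNA synthesis cycling: 60 s initial denature at 95 degC,
# 14 cycles (midpoint of the 10-18 range) of 95/55/68 degC with a 3 min
# extension, and a 7 min final extension at 68 degC.
schema_version: 1
id: cdna_second_strand
hot_start: {temp_C: 95, duration_s: 60}
stages:
  - cycles: 14
    steps:
      - {temp_C: 95, dwell_s: 30}
      - {temp_C: 55, dwell_s: 30}
      - {temp_C: 68, dwell_s: 180}
final_step: {temp_C: 68, duration_s: 420}
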