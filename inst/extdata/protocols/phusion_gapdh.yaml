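# 26-cycle rapid single-plex amplification (Phusion / GAPDH): 30 s initial
# denature, then 98/60/72 degC cycling at the vendor's minimum dwells, and
# a 5 min final elongation. Three heated blocks; the fourth segment is the
# unheated load/unload block.
schema_version: 1
id: phusion_gapdh
hot_start: {temp_C: 98, duration_s: 30}
stages:
  - cycles: 26
    steps:
      - {temp_C: 98, dwell_s: 5}    # denature
      - {temp_C: 60, dwell_s: 10}   # anneal
      - {temp_C: 72, dwell_s: 15}   # extend
final_step: {temp_C: 72, duration_s: 300}
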