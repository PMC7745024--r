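# Example run configuration. Omitted keys take their default_config() values.
seed: 42
collocation:
  max_distance_m: 2000
calibration:
  bandwidth_m: auto
mapping:
  resolution_m: 2000
  power: 2
paths:
  output_dir: pmcalibrate_out
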