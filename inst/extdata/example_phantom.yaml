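# Synthetic two-band lane used by the worked examples: amounts 5 and 2,
# sensitivity (gain) 10, linear baseline drift, moderate pixel noise,
# +/- 1 px replicate jitter.
lanes:
  - - component_id: main
      amount: 5
      mobility_center: 0.42
      width: 0.015
    - component_id: side
      amount: 2
      mobility_center: 0.52
      width: 0.015
image_height: 128
image_width: 24
impulse_response:
  width: 0.02
baseline_model:
  type: polynomial
  coefficients: [8.0, 12.0]
noise_sd: 0.15
replicate_jitter: 1
gain: 10
bias_offset: 0
seed: 42
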