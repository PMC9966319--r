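# End-to-end analysis configuration for the bundled example phantom:
# simulate 8 replicates, align/average, extract lane columns 3..22,
# remove the baseline, deconvolve, and report the main band (mobility
# 0.32..0.47) with its propagated error budget.
seed: 5
out_dir: gelquant_example_out
phantom: example_phantom.yaml
n_replicates: 8
max_shift: 3
lane: [3, 22]
baseline:
  window: 41
  smooth: 7
forbidden: ["0.02:0.20", "0.80:0.98"]
psf:
  width: 0.02
deconvolution:
  lambda: auto
  kind: cosine
  max_iter: 60
quantify:
  min_prominence: 0.05
  target_support: [0.32, 0.47]
  gain: 10
propagate:
  g: 2
  mc_draws: 0
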