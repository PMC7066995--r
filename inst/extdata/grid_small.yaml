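# A desk-scale simulation grid: two parameter sets, two cohort sizes,
# two replications per cell. Short sampler settings for a quick look;
# raise warmup/sampling for publication-grade intervals.
schema_version: 1
simulation_ids: [1, 4]
sizes: [500, 5000]
replications: 2
seed: 11
mcmc:
  chains: 2
  warmup_iterations: 500
  sampling_iterations: 1000
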