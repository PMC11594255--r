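# Canonical cohort-design example.
# biofluid: urine | plasma | csf
# n_per_class: samples per class label
# effect_sizes: multiplicative fold-changes on base concentrations,
#   per class and metabolite (HEALTHY defaults to 1.0 everywhere)
# noise_sd: spectral Gaussian noise SD (intensity units)
# conc_sdlog: log-scale SD of per-sample concentration variation
# dilution_range: spot-urine dilution factor range (urine only)
biofluid: urine
n_per_class:
  HEALTHY: 20
  G12.0: 20
  G12.1: 20
effect_sizes:
  G12.0:
    creatine: 2.5
    citrate: 0.5
    glucose: 1.8
  G12.1:
    creatine: 1.5
    citrate: 0.7
noise_sd: 1.0
conc_sdlog: 0.25
dilution_range: [0.3, 3.0]
seed: 7
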