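# Default run configuration: the Grand Cayman green iguana analysis.
# surveys/harvest left null -> the packaged 2014-2021 series and cull rates.
priors:
  K: [900000, 2000000]
  r_max: [0.5, 2.0]
  sigma_proc: [0.01, 1.0]
mcmc:
  chains: 4
  iter: 50000
  burn: 25000
  thin: 10
  seed: 1
scenarios:
  - {lower: 0.001, upper: 0.100}
  - {lower: 0.101, upper: 0.300}
  - {lower: 0.301, upper: 0.500}
  - {lower: 0.501, upper: 0.700}
  - {lower: 0.701, upper: 0.900}
  - {lower: 0.001, upper: 0.900}
horizon: 9
h_mode: per_year
# The 2018->2019 interval had two reported rates (0.629 to July 2019, 0.568 in
# August 2019); the packaged schedule uses 0.629. To use the alternative,
# point `harvest` at a CSV with 0.568 for 2018.
alternative_first_cull_rate: 0.568
out_dir: iguanaharvest-output
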