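# alknma pipeline configuration (key = value)
outcomes = pfs, os
effect_model = random
chains = 4
burn_in = 10000
kept_iterations = 50000
thin = 2
seed = 20230619
out_dir = alknma_report
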