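# Example ED scenario configuration.
# Any field of scenario_config() may appear here; omitted fields take the
# package defaults. See ?scenario_config for the full schema.
signal_M: 2
noise_lambda: 425
factor_A: 2.8
factor_B: 1
factor_C: 2
factor_D: 2
beds_Bt: 30
horizon_days: 3
warmup_days: 1
seed: 20
service_dists:
  registration: {family: lognormal, mean: 5, sd: 2}
  physician:    {family: lognormal, mean: 15, sd: 8}
  urine:        {family: lognormal, mean: 10, sd: 5}
  ct:           {family: lognormal, mean: 20, sd: 10}
  xray:         {family: lognormal, mean: 10, sd: 4}
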