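{
  "generator": "gamye::simulate_dataset",
  "config": {
    "n_strata": 2,
    "routes_per_stratum": 3,
    "year_range": [2000, 2009],
    "mean_log_abundance": 1.2,
    "stratum_sd": 0.3,
    "annual_trend_pct": -2,
    "year_effect_sd": 0.1,
    "observer_sd": 0.2,
    "first_year_effect": -0.1,
    "overdispersion_sd": 0.15,
    "observer_turnover_prob": 0.1,
    "day_window": [145, 190],
    "seed": 42
  },
  "n_records": 60
}
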