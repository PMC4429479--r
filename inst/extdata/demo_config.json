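{
  "seed": 20150209,
  "out_dir": "hapselect_demo",
  "cohort_spec": {
    "n_cases": 250,
    "n_controls": 1750,
    "n_tracts": 600,
    "tract_sd": 0.3,
    "baseline_logit": -3.5,
    "haps": [
      {"name": "hap01", "median": 1.26, "dispersion": 0.56, "block_id": "b1", "target_rho": 0.9},
      {"name": "hap02", "median": 1.45, "dispersion": 0.48, "block_id": "b1", "target_rho": 0.9},
      {"name": "hap03", "median": 0.48, "dispersion": 0.63, "block_id": "b1", "target_rho": 0.9},
      {"name": "hap04", "median": 0.09, "dispersion": 1.05, "log_or_high": 0.9163},
      {"name": "hap05", "median": 0.09, "dispersion": 0.35, "log_or_medium": 0.6931},
      {"name": "hap06", "median": 2.7e-08, "dispersion": 5.8},
      {"name": "hap07", "median": 0.066, "dispersion": 1.44},
      {"name": "hap08", "median": 0.0083, "dispersion": 1.15},
      {"name": "hap09", "median": 0.0017, "dispersion": 1.4},
      {"name": "hap10", "median": 0.2, "dispersion": 0.89}
    ],
    "covariates": [
      {"name": "year", "levels": ["1999", "2000", "2001", "2002", "2003", "2004"]},
      {"name": "education", "levels": ["lt_high_school", "high_school", "gt_high_school"],
       "probs": [0.317, 0.328, 0.355]},
      {"name": "smoking", "levels": ["no", "yes"], "probs": [0.939, 0.061]},
      {"name": "poverty", "levels": ["low", "medium_low", "medium_high", "high"]}
    ],
    "match_var": "year"
  },
  "binning": {"threshold": 0.8, "max_representatives_per_bin": 1},
  "priors": {"inclusion_prob": 0.25, "spike_variance": 0.001, "slab_variance": 10},
  "mcmc": {"n_chains": 2, "n_iter": 5000, "burn_in": 0.5},
  "mode": {"exposure": "categorical", "selection": true}
}
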