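{
  "seed": 1,
  "groups": [
    {
      "label": "2",
      "n_leaves": 18,
      "length_mean_cm": 4.32,
      "length_sd_cm": 1.075,
      "length_max_cm": 5.85256947642905,
      "family": "quadratic",
      "coefficients": [0.142, 0.005, -0.005],
      "noise_sd_cm": 0
    },
    {
      "label": "5",
      "n_leaves": 18,
      "length_mean_cm": 3.977,
      "length_sd_cm": 0.904,
      "length_max_cm": 6.8034084308295,
      "family": "quadratic",
      "coefficients": [0.147, -0.008, -0.002],
      "noise_sd_cm": 0
    },
    {
      "label": "10",
      "n_leaves": 18,
      "length_mean_cm": 4.518,
      "length_sd_cm": 0.99,
      "length_max_cm": 4.76283507111677,
      "family": "quadratic",
      "coefficients": [0.142, -0.006, -0.005],
      "noise_sd_cm": 0
    },
    {
      "label": "13",
      "n_leaves": 18,
      "length_mean_cm": 4.887,
      "length_sd_cm": 1.169,
      "length_max_cm": 8.06038506929733,
      "family": "quadratic",
      "coefficients": [0.138, -0.001, -0.002],
      "noise_sd_cm": 0
    },
    {
      "label": "23",
      "n_leaves": 18,
      "length_mean_cm": 4.484,
      "length_sd_cm": 0.899,
      "length_max_cm": 5.79214981408608,
      "family": "quadratic",
      "coefficients": [0.119, 0.02, -0.007],
      "noise_sd_cm": 0
    },
    {
      "label": "30",
      "n_leaves": 18,
      "length_mean_cm": 4.024,
      "length_sd_cm": 0.424,
      "length_max_cm": 4.68621550028325,
      "family": "quadratic",
      "coefficients": [0.12, 0.04, -0.014],
      "noise_sd_cm": 0
    }
  ],
  "stages": ["simulate", "fit", "stats", "report"]
}
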