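{
  "description": "Published univariate regression transforms for the nine conventional embryo evaluation (CEE) factors, with cohort marginals (mean/SD/min/max of 977 blastocysts). Families: scaled_logistic k/(1+exp(b0+b1*x)); logistic 1/(1+exp(b0+b1*x)); scaled_gaussian k/sqrt(2*pi*sigma^2)*exp(-(x-m)^2/(2*sigma^2)); linear b0+b1*x. Outputs are clipped to [0,1].",
  "factors": [
    {
      "name": "female_age",
      "label": "Female age (years)",
      "family": "scaled_logistic",
      "coef": {"b0": -12.112, "b1": 0.286, "k": 0.506},
      "se": {"b0": 8.992, "b1": 0.217},
      "marginal": {"type": "continuous", "mean": 35.36, "sd": 4.73, "min": 20, "max": 46}
    },
    {
      "name": "n_prev_transfers",
      "label": "Number of previous embryo transfer procedures",
      "family": "logistic",
      "coef": {"b0": -0.2712, "b1": 0.166},
      "se": {"b0": 1.245, "b1": 0.175},
      "marginal": {"type": "count", "mean": 2.57, "sd": 2.29, "min": 1, "max": 23}
    },
    {
      "name": "amh",
      "label": "Anti-Muellerian hormone concentration (ng/mL)",
      "family": "logistic",
      "coef": {"b0": 0.358, "b1": -0.046},
      "se": {"b0": 2.068, "b1": 0.158},
      "marginal": {"type": "continuous", "mean": 3.0, "sd": 2.83, "min": 0.01, "max": 22.96}
    },
    {
      "name": "day3_blastomeres",
      "label": "Day 3 blastomere numbers",
      "family": "scaled_gaussian",
      "coef": {"sigma": 4.813, "m": 10.063, "k": 6.737},
      "se": {"sigma": 1.142, "m": 0.874, "k": 1.259},
      "marginal": {"type": "count", "mean": 8.56, "sd": 2.01, "min": 3, "max": 16}
    },
    {
      "name": "day3_grade",
      "label": "Grade on day 3 (A:1 B:2 C:3 D:4)",
      "family": "scaled_logistic",
      "coef": {"b0": -8.381, "b1": 2.574, "k": 0.5},
      "se": {"b0": 16.265, "b1": 5.645},
      "marginal": {"type": "ordinal", "support": [1, 2, 3], "mean": 1.97}
    },
    {
      "name": "cryo_day",
      "label": "Embryo cryopreservation day (day5:1 day6:2 day7:3)",
      "family": "linear",
      "coef": {"b0": 0.852, "b1": -0.161},
      "se": {},
      "marginal": {"type": "ordinal", "support": [1, 2, 3], "mean": 1.41,
                   "probs": [0.5997952917093142, 0.38894575230296827, 0.011258955987717503]}
    },
    {
      "name": "icm_grade",
      "label": "Inner cell mass grade (A:1 B:2 C:3)",
      "family": "linear",
      "coef": {"b0": 0.789, "b1": -0.2},
      "se": {"b0": 0.011, "b1": 0.005},
      "marginal": {"type": "ordinal", "support": [1, 2, 3], "mean": 1.59}
    },
    {
      "name": "te_grade",
      "label": "Trophectoderm grade (A:1 B:2 C:3)",
      "family": "linear",
      "coef": {"b0": 0.791, "b1": -0.182},
      "se": {"b0": 0.018, "b1": 0.008},
      "marginal": {"type": "ordinal", "support": [1, 2, 3], "mean": 1.77}
    },
    {
      "name": "avg_diameter",
      "label": "Average diameter of blastocyst (um)",
      "family": "logistic",
      "coef": {"b0": 0.308, "b1": -0.001},
      "se": {"b0": 4.242, "b1": 0.016},
      "marginal": {"type": "continuous", "mean": 180.8, "sd": 27.17, "min": 119.56, "max": 371.59}
    }
  ]
}
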