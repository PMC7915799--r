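{
  "description": "Reference cohort statistics for the five diagnostic indicators (x1 fluid density Hu; x2 ostium opening %; x3 mucosa volume %; x4 fluid volume %; x5 nasal drag kPa/(L/s)) in the five diagnostic groups, with the reported pairwise normalized Euclidean distances and decision-error probabilities of the original clinical study.",
  "indicators": ["x1", "x2", "x3", "x4", "x5"],
  "groups": [
    {
      "group": "conditional_norm",
      "n": 38,
      "mean": [-630, 96, 10, 0, 0.45],
      "sd": [330, 39, 5.7, 0, 0.24]
    },
    {
      "group": "acute_serous",
      "n": 35,
      "mean": [19, 24, 16.2, 52, 1.58],
      "sd": [4.3, 12, 14.5, 30.5, 0.87]
    },
    {
      "group": "acute_purulent",
      "n": 36,
      "mean": [37, 20, 27, 54.3, 2.2],
      "sd": [6.2, 9, 16, 32, 1.12]
    },
    {
      "group": "chronic",
      "n": 38,
      "mean": [39, 64, 62, 15, 1.72],
      "sd": [6.4, 25.5, 25, 9, 1.12]
    },
    {
      "group": "exacerbated_chronic",
      "n": 32,
      "mean": [38.5, 23, 65, 28, 1.94],
      "sd": [6.1, 11.2, 31, 12, 1.28]
    }
  ],
  "reported_comparisons": [
    {"group_a": "conditional_norm", "group_b": "acute_serous",        "delta_reported": 3.34, "per_reported": 0.1,  "per_digits": 1},
    {"group_a": "conditional_norm", "group_b": "acute_purulent",      "delta_reported": 3.78, "per_reported": 0.06, "per_digits": 2},
    {"group_a": "conditional_norm", "group_b": "chronic",             "delta_reported": 3.16, "per_reported": 0.12, "per_digits": 2},
    {"group_a": "conditional_norm", "group_b": "exacerbated_chronic", "delta_reported": 4.29, "per_reported": 0.04, "per_digits": 2},
    {"group_a": "acute_serous",     "group_b": "acute_purulent",      "delta_reported": 3.36, "per_reported": 0.09, "per_digits": 2},
    {"group_a": "chronic",          "group_b": "acute_purulent",      "delta_reported": 2.18, "per_reported": 0.31, "per_digits": 2},
    {"group_a": "acute_purulent",   "group_b": "exacerbated_chronic", "delta_reported": 1.71, "per_reported": 0.4,  "per_digits": 1},
    {"group_a": "chronic",          "group_b": "exacerbated_chronic", "delta_reported": 1.98, "per_reported": 0.32, "per_digits": 2}
  ]
}
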