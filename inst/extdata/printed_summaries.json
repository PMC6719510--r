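{
  "description": "Printed group summaries (load effects: high minus low, in microvolts, with 95% CIs; correlations with working memory capacity) transcribed from the published study's results table and text. Input to reproduce_printed_bfs().",
  "n": 49,
  "erp": [
    {
      "measure": "n1",
      "low": {"mean": -0.49, "ci": [-1.02, 0.03]},
      "high": {"mean": -0.15, "ci": [-0.72, 0.41]},
      "effect": {"mean": 0.34, "ci": [0.04, 0.64]},
      "direction": "positive"
    },
    {
      "measure": "mmn_oddball",
      "low": {"mean": -2.13, "ci": [-2.73, -1.53]},
      "high": {"mean": -2.26, "ci": [-2.82, -1.71]},
      "effect": {"mean": -0.13, "ci": [-0.74, 0.47]},
      "direction": "positive"
    },
    {
      "measure": "mmn_corrected",
      "low": {"mean": -1.38, "ci": [-2.15, -0.61]},
      "high": {"mean": -1.26, "ci": [-2.04, -0.47]},
      "effect": {"mean": 0.12, "ci": [-0.75, 0.99]},
      "direction": "positive"
    },
    {
      "measure": "p3a",
      "low": {"mean": 0.41, "ci": [-0.34, 1.16]},
      "high": {"mean": -0.18, "ci": [-0.89, 0.53]},
      "effect": {"mean": -0.58, "ci": [-1.59, 0.42]},
      "direction": "negative"
    },
    {
      "measure": "p3a_300_400",
      "low": {"mean": 0.68, "ci": [-0.10, 1.45]},
      "high": {"mean": -0.08, "ci": [-0.82, 0.65]},
      "effect": {"mean": -0.76, "ci": [-1.75, 0.23]},
      "direction": "negative"
    },
    {
      "measure": "visual_p3",
      "low": {"mean": 9.29, "ci": [7.57, 11.01]},
      "high": {"mean": 2.73, "ci": [1.70, 3.77]},
      "effect": {"mean": -6.56, "ci": [-7.81, -5.30]},
      "direction": "negative"
    }
  ],
  "correlations": [
    {"measure": "n1_load_wmc", "r": 0.35},
    {"measure": "mmn_oddball_load_wmc", "r": -0.21},
    {"measure": "mmn_corrected_load_wmc", "r": -0.12}
  ]
}
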