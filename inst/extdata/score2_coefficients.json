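{
  "name": "SCORE2 10-year fatal and non-fatal CVD risk, ages 40-69",
  "version": "2021",
  "notes": "Per-sex log-hazard-ratio weights, covariate transformation constants and baseline 10-year survival transcribed from the published SCORE2 derivation; calibration scales for the European low-risk region (appropriate for the UK).",
  "transforms": {
    "age_center": 60, "age_scale": 5,
    "sbp_center": 120, "sbp_scale": 20,
    "tchol_center": 6, "tchol_scale": 1,
    "hdl_center": 1.3, "hdl_scale": 0.5
  },
  "male": {
    "S0_10yr": 0.9605,
    "coefficients": {
      "cage": 0.3742,
      "smoking": 0.6012,
      "csbp": 0.2777,
      "ctchol": 0.1458,
      "chdl": -0.2698,
      "smoking_cage": -0.0755,
      "csbp_cage": -0.0255,
      "ctchol_cage": -0.0281,
      "chdl_cage": 0.0426
    }
  },
  "female": {
    "S0_10yr": 0.9776,
    "coefficients": {
      "cage": 0.4648,
      "smoking": 0.7744,
      "csbp": 0.3131,
      "ctchol": 0.1002,
      "chdl": -0.2606,
      "smoking_cage": -0.1088,
      "csbp_cage": -0.0277,
      "ctchol_cage": -0.0226,
      "chdl_cage": 0.0613
    }
  },
  "calibration": {
    "region": "low",
    "male":   { "scale1": -0.5699, "scale2": 0.7476 },
    "female": { "scale1": -0.7380, "scale2": 0.7019 }
  }
}
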