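{
  "version": "gajic-2008-v1",
  "notes": "Stability and Workload Index for Transfer point table, transcribed from the original 2008 derivation (maximum 64 points). Bins are left-closed [a, b). The sf_ratio component is a parallel bin set for the untransformed SpO2/FiO2 oxygenation proxy, with cut-points mapped from the PaO2/FiO2 cuts by the linear pulse-oximetry conversion.",
  "components": {
    "admission_source": {
      "points": {
        "emergency": 0,
        "operating-room": 0,
        "ward": 8,
        "other-hospital": 8
      }
    },
    "icu_los": {
      "breaks": ["-Inf", 2, 10, "Inf"],
      "points": [0, 1, 14]
    },
    "pf_ratio": {
      "breaks": ["-Inf", 100, 150, 400, "Inf"],
      "points": [13, 10, 5, 0]
    },
    "sf_ratio": {
      "breaks": ["-Inf", 148, 190, 430, "Inf"],
      "points": [13, 10, 5, 0]
    },
    "gcs": {
      "breaks": ["-Inf", 8, 11, 15, "Inf"],
      "points": [24, 14, 6, 0]
    },
    "paco2": {
      "breaks": ["-Inf", 45, "Inf"],
      "points": [0, 5]
    }
  }
}
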