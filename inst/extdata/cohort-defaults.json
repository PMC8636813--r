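{
  "version": "1.0",
  "note": "Default simulation parameters: per-group baseline means/SDs, responder-group pre/post means/SDs, comorbidity prevalences and group sizes for the NPH/AD/HC study design.",
  "group_sizes": {"NPH": 21, "AD": 21, "HC": 21},
  "subtype_sizes": {"Classic": 6, "Complex": 15},
  "responder_sizes": {"Responder": 9, "Non-Responder": 12},
  "responder_fraction": 0.4285714285714286,
  "measure_ranges": {
    "ei": [0, 1], "bci": [0, 1], "z_evans": [0, 1],
    "ca_deg": [0, 180],
    "bvr_ac": [0, null], "bvr_pc": [0, null],
    "bvr_pc_brain_mm": [0, null], "bvr_pc_ventricle_mm": [0, null],
    "ventricle_volume_cm3": [0, null]
  },
  "baseline": {
    "ei":      {"NPH": {"mean": 0.380, "sd": 0.053}, "AD": {"mean": 0.286, "sd": 0.033}, "HC": {"mean": 0.277, "sd": 0.028}},
    "bci":     {"NPH": {"mean": 0.284, "sd": 0.027}, "AD": {"mean": 0.186, "sd": 0.032}, "HC": {"mean": 0.175, "sd": 0.025}},
    "ca_deg":  {"NPH": {"mean": 57.1,  "sd": 20.8},  "AD": {"mean": 109.0, "sd": 15.1},  "HC": {"mean": 106.4, "sd": 11.5}},
    "z_evans": {"NPH": {"mean": 0.448, "sd": 0.056}, "AD": {"mean": 0.294, "sd": 0.037}, "HC": {"mean": 0.273, "sd": 0.043}},
    "bvr_ac":  {"NPH": {"mean": 0.678, "sd": 0.176}, "AD": {"mean": 1.436, "sd": 0.257}, "HC": {"mean": 1.589, "sd": 0.332}},
    "bvr_pc":  {"NPH": {"mean": 0.835, "sd": 0.316}, "AD": {"mean": 2.611, "sd": 0.964}, "HC": {"mean": 3.281, "sd": 1.220}}
  },
  "subtype_baseline": {
    "ei":      {"Classic": {"mean": 0.392, "sd": 0.0577}, "Complex": {"mean": 0.373, "sd": 0.0534}},
    "bci":     {"Classic": {"mean": 0.287, "sd": 0.0261}, "Complex": {"mean": 0.281, "sd": 0.0279}},
    "ca_deg":  {"Classic": {"mean": 67.1,  "sd": 23.9},   "Complex": {"mean": 54.6,  "sd": 18.6}},
    "z_evans": {"Classic": {"mean": 0.436, "sd": 0.0588}, "Complex": {"mean": 0.449, "sd": 0.0565}},
    "bvr_ac":  {"Classic": {"mean": 0.712, "sd": 0.158},  "Complex": {"mean": 0.674, "sd": 0.188}},
    "bvr_pc":  {"Classic": {"mean": 0.922, "sd": 0.356},  "Complex": {"mean": 0.814, "sd": 0.312}}
  },
  "responder_prepost": {
    "ei": {
      "Responder":     {"pre": {"mean": 0.402, "sd": 0.054}, "post": {"mean": 0.399, "sd": 0.045}},
      "Non-Responder": {"pre": {"mean": 0.363, "sd": 0.048}, "post": {"mean": 0.360, "sd": 0.050}}
    },
    "bci": {
      "Responder":     {"pre": {"mean": 0.291, "sd": 0.026}, "post": {"mean": 0.294, "sd": 0.028}},
      "Non-Responder": {"pre": {"mean": 0.278, "sd": 0.027}, "post": {"mean": 0.274, "sd": 0.031}}
    },
    "ca_deg": {
      "Responder":     {"pre": {"mean": 61.6, "sd": 21.0}, "post": {"mean": 61.3, "sd": 19.7}},
      "Non-Responder": {"pre": {"mean": 53.8, "sd": 21.0}, "post": {"mean": 55.8, "sd": 21.1}}
    },
    "z_evans": {
      "Responder":     {"pre": {"mean": 0.461, "sd": 0.061}, "post": {"mean": 0.460, "sd": 0.059}},
      "Non-Responder": {"pre": {"mean": 0.438, "sd": 0.052}, "post": {"mean": 0.424, "sd": 0.049}}
    },
    "bvr_ac": {
      "Responder":     {"pre": {"mean": 0.613, "sd": 0.172}, "post": {"mean": 0.616, "sd": 0.159}},
      "Non-Responder": {"pre": {"mean": 0.726, "sd": 0.170}, "post": {"mean": 0.714, "sd": 0.216}}
    },
    "bvr_pc": {
      "Responder":     {"pre": {"mean": 0.789, "sd": 0.361}, "post": {"mean": 0.773, "sd": 0.295}},
      "Non-Responder": {"pre": {"mean": 0.869, "sd": 0.290}, "post": {"mean": 0.926, "sd": 0.269}}
    },
    "bvr_pc_brain_mm": {
      "Responder":     {"pre": {"mean": 27.36, "sd": 5.583}, "post": {"mean": 27.12, "sd": 5.392}},
      "Non-Responder": {"pre": {"mean": 29.58, "sd": 4.774}, "post": {"mean": 30.23, "sd": 4.335}}
    },
    "bvr_pc_ventricle_mm": {
      "Responder":     {"pre": {"mean": 38.60, "sd": 0.490}, "post": {"mean": 38.22, "sd": 9.639}},
      "Non-Responder": {"pre": {"mean": 35.68, "sd": 5.772}, "post": {"mean": 33.89, "sd": 5.260}}
    },
    "ventricle_volume_cm3": {
      "Responder":     {"pre": {"mean": 160.56, "sd": 89.9}, "post": {"mean": 120.28, "sd": 39.0}},
      "Non-Responder": {"pre": {"mean": 156.05, "sd": 77.5}, "post": {"mean": 114.16, "sd": 38.0}}
    }
  },
  "comorbidity_prevalence": {
    "hypertension": 0.8095238095238095,
    "impaired_sensorium": 0.6190476190476191,
    "diabetes": 0.3333333333333333,
    "adl_dependent": 0.2857142857142857,
    "mi": 0.14285714285714285,
    "pci_angina": 0.14285714285714285,
    "respiratory": 0.09523809523809523,
    "pvd": 0.047619047619047616,
    "chf": 0.0,
    "tia_cva": 0.0,
    "cva_deficit": 0.0
  },
  "flags": {
    "bvr_pc_ventricle_mm_responder_pre_sd": "the printed SD 0.490 is inconsistent with every neighbouring SD (likely a typo for 4.90); kept verbatim here and flagged"
  }
}
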