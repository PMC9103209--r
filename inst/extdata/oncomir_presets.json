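{
  "version": "1.0",
  "description": "Published oncomiR index presets: per-miRNA coefficients of the linear index and ROC-derived decision thresholds (raw scale, log2 in parentheses in the source table) for detecting secondary CNS lymphoma involvement versus systemic-only disease, by diagnosis and compartment.",
  "models": [
    {
      "name": "DLBCL-CSF", "diagnosis": "DLBCL", "compartment": "CSF",
      "coefficients": {"miR-21": 1.83, "miR-20a": 1.31, "miR-155": 1.78},
      "threshold_raw": 8.42, "threshold_log2": 3.07,
      "auc": 0.96, "sensitivity": 91.3, "specificity": 90.4, "youden": 81.7
    },
    {
      "name": "MCL-CSF", "diagnosis": "MCL", "compartment": "CSF",
      "coefficients": {"miR-21": 1.36, "miR-20a": 0.83, "miR-92a": 1.30, "miR-155": 1.84},
      "threshold_raw": 8.86, "threshold_log2": 3.15,
      "auc": 0.93, "sensitivity": 87.5, "specificity": 93.3, "youden": 80.8
    },
    {
      "name": "BL-CSF", "diagnosis": "BL", "compartment": "CSF",
      "coefficients": {"miR-21": 1.57, "miR-155": 1.75},
      "threshold_raw": 6.83, "threshold_log2": 2.77,
      "auc": 1.00, "sensitivity": 100.0, "specificity": 100.0, "youden": 100.0
    },
    {
      "name": "B-NHL-NOS-CSF", "diagnosis": "B-NHL-NOS", "compartment": "CSF",
      "coefficients": {"miR-21": 1.10, "miR-155": 1.64},
      "threshold_raw": 7.14, "threshold_log2": 2.84,
      "auc": 0.94, "sensitivity": 88.9, "specificity": 100.0, "youden": 88.9
    },
    {
      "name": "DLBCL-plasma", "diagnosis": "DLBCL", "compartment": "plasma",
      "coefficients": {"miR-21": 0.07, "miR-19a": 0.03, "miR-20a": 6.93, "miR-155": 0.43},
      "threshold_raw": 6.13, "threshold_log2": 2.62,
      "auc": 0.79, "sensitivity": 83.3, "specificity": 78.3, "youden": 61.6
    },
    {
      "name": "MCL-plasma", "diagnosis": "MCL", "compartment": "plasma",
      "coefficients": {"miR-21": 2.42, "miR-19a": 0.15, "miR-155": 1.25},
      "threshold_raw": 5.82, "threshold_log2": 2.54,
      "auc": 0.84, "sensitivity": 78.6, "specificity": 100.0, "youden": 78.6
    },
    {
      "name": "BL-plasma", "diagnosis": "BL", "compartment": "plasma",
      "coefficients": {"miR-21": 2.12, "miR-19a": 0.08, "miR-155": 0.10},
      "threshold_raw": 3.68, "threshold_log2": 1.88,
      "auc": 1.00, "sensitivity": 100.0, "specificity": 100.0, "youden": 100.0
    },
    {
      "name": "B-NHL-NOS-plasma", "diagnosis": "B-NHL-NOS", "compartment": "plasma",
      "coefficients": {"miR-19a": 5.85, "miR-155": 0.45},
      "threshold_raw": 3.20, "threshold_log2": 1.68,
      "auc": 0.67, "sensitivity": 100.0, "specificity": 66.7, "youden": 66.7
    }
  ]
}
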