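{
  "description": "Printed result tables of the motivating DSPP/ELISA root-resorption study, transcribed for use as evaluation fixtures. Confusion matrices: rows = predicted class, columns = actual class, order normal/mild/severe.",
  "univariate": {
    "confusion": [[9, 0, 0], [1, 10, 6], [0, 0, 4]],
    "printed_truth_table": {
      "TP": [9, 10, 4],
      "FP": [1, 6, 0],
      "TN": [20, 13, 20],
      "FN": [0, 1, 6]
    },
    "printed_metrics": {
      "sensitivity": [1.00, 0.91, 0.40],
      "specificity": [0.95, 0.68, 1.00],
      "precision": [0.90, 0.62, 1.00],
      "accuracy": [0.96, 0.76, 0.80],
      "overall_accuracy": 0.84
    }
  },
  "plsda": {
    "none": {
      "confusion": {
        "calibration": [[7, 1, 0], [0, 2, 1], [0, 4, 6]],
        "validation": [[3, 0, 0], [0, 2, 0], [0, 1, 3]]
      },
      "printed_metrics": {
        "calibration": {
          "sensitivity": [1.00, 0.29, 0.86],
          "specificity": [0.93, 0.93, 0.71],
          "precision": [0.88, 0.67, 0.60],
          "accuracy": [0.95, 0.71, 0.76]
        },
        "validation": {
          "sensitivity": [1.00, 0.67, 1.00],
          "specificity": [1.00, 1.00, 0.83],
          "precision": [1.00, 1.00, 0.75],
          "accuracy": [0.43, 0.38, 0.38],
          "accuracy_anomalous": true
        }
      }
    },
    "autoscale": {
      "confusion": {
        "calibration": [[7, 0, 0], [0, 5, 5], [0, 2, 2]],
        "validation": [[3, 0, 0], [0, 3, 0], [0, 0, 3]]
      },
      "printed_metrics": {
        "calibration": {
          "sensitivity": [1.00, 0.71, 0.29],
          "specificity": [1.00, 0.64, 0.86],
          "precision": [1.00, 0.50, 0.50],
          "accuracy": [1.00, 0.67, 0.67]
        },
        "validation": {
          "sensitivity": [1.00, 1.00, 1.00],
          "specificity": [1.00, 1.00, 1.00],
          "precision": [1.00, 1.00, 1.00],
          "accuracy": [1.00, 1.00, 1.00]
        }
      }
    },
    "snv": {
      "confusion": {
        "calibration": [[6, 0, 1], [0, 4, 4], [1, 3, 2]],
        "validation": [[3, 0, 3], [0, 3, 0], [0, 0, 0]]
      },
      "printed_metrics": {
        "calibration": {
          "sensitivity": [0.86, 0.57, 0.29],
          "specificity": [0.93, 0.71, 0.71],
          "precision": [0.86, 0.50, 0.33],
          "accuracy": [0.90, 0.67, 0.57]
        },
        "validation": {
          "sensitivity": [1.00, 1.00, 0.00],
          "specificity": [0.50, 1.00, 1.00],
          "precision": [0.50, 1.00, 1.00],
          "accuracy": [0.67, 1.00, 0.67]
        }
      }
    },
    "mean_center": {
      "confusion": {
        "calibration": [[7, 0, 0], [0, 3, 1], [0, 4, 6]],
        "validation": [[3, 0, 0], [0, 2, 0], [0, 1, 3]]
      },
      "printed_metrics": {
        "calibration": {
          "sensitivity": [1.00, 0.43, 0.86],
          "specificity": [1.00, 0.93, 0.71],
          "precision": [1.00, 0.75, 0.60],
          "accuracy": [1.00, 0.76, 0.76]
        },
        "validation": {
          "sensitivity": [1.00, 0.67, 1.00],
          "specificity": [1.00, 1.00, 0.83],
          "precision": [1.00, 1.00, 0.75],
          "accuracy": [1.00, 0.89, 0.89]
        }
      }
    }
  }
}
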