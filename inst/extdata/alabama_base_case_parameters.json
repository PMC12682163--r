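{
  "currency": "GBP 2022-23",
  "arms": {
    "paap": {
      "n": 401,
      "event_probabilities": {
        "p_test": {
          "family": "beta",
          "mean": 0.91,
          "sd": 0.082
        },
        "p_positive": {
          "family": "beta",
          "mean": 0.082,
          "sd": 0.075
        },
        "p_delabel_pos": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "p_delabel_neg": {
          "family": "beta",
          "mean": 0.973,
          "sd": 0.026
        },
        "tf_pos_pal": {
          "family": "beta",
          "mean": 0.033,
          "sd": 0.032
        },
        "tf_neg_pal": {
          "family": "beta",
          "mean": 0.111,
          "sd": 0.099
        },
        "tf_neg_nopal": {
          "family": "beta",
          "mean": 0.089,
          "sd": 0.081
        },
        "tf_notest": {
          "family": "beta",
          "mean": 0.083,
          "sd": 0.076
        }
      },
      "first_year_costs": {
        "pos_pal_tf": {
          "family": "fixed",
          "mean": 510.23,
          "sd": 0
        },
        "pos_pal_notf": {
          "family": "lognormal",
          "mean": 1176.55,
          "sd": 1587.1
        },
        "neg_pal_tf": {
          "family": "fixed",
          "mean": 3565.61,
          "sd": 0
        },
        "neg_pal_notf": {
          "family": "lognormal",
          "mean": 501.37,
          "sd": 399.85
        },
        "neg_nopal_tf": {
          "family": "lognormal",
          "mean": 1868.2,
          "sd": 2249.55
        },
        "neg_nopal_notf": {
          "family": "lognormal",
          "mean": 1481.03,
          "sd": 2694.72
        },
        "notest_tf": {
          "family": "lognormal",
          "mean": 432.47,
          "sd": 333.95
        },
        "notest_notf": {
          "family": "lognormal",
          "mean": 604.89,
          "sd": 1063.4
        }
      },
      "annual_qalys": {
        "pos_pal_tf": {
          "family": "fixed",
          "mean": 0.924,
          "sd": 0
        },
        "pos_pal_notf": {
          "family": "beta",
          "mean": 0.828,
          "sd": 0.226
        },
        "neg_pal_tf": {
          "family": "fixed",
          "mean": 0.776,
          "sd": 0
        },
        "neg_pal_notf": {
          "family": "beta",
          "mean": 0.837,
          "sd": 0.132
        },
        "neg_nopal_tf": {
          "family": "beta",
          "mean": 0.808,
          "sd": 0.146
        },
        "neg_nopal_notf": {
          "family": "beta",
          "mean": 0.88,
          "sd": 0.137
        },
        "notest_tf": {
          "family": "beta",
          "mean": 0.689,
          "sd": 0.06
        },
        "notest_notf": {
          "family": "beta",
          "mean": 0.902,
          "sd": 0.082
        }
      },
      "empty": {
        "probs": [],
        "costs": [],
        "qalys": []
      },
      "substituted": {
        "costs": [],
        "qalys": []
      }
    },
    "usual_care": {
      "n": 410,
      "event_probabilities": {
        "p_test": {
          "family": "beta",
          "mean": 0.012,
          "sd": 0.012
        },
        "p_positive": {
          "family": "beta",
          "mean": 0.2,
          "sd": 0.16
        },
        "p_delabel_pos": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "p_delabel_neg": {
          "family": "fixed",
          "mean": 1,
          "sd": 0
        },
        "tf_pos_pal": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "tf_neg_pal": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "tf_neg_nopal": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "tf_notest": {
          "family": "beta",
          "mean": 0.114,
          "sd": 0.101
        }
      },
      "first_year_costs": {
        "pos_pal_tf": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "pos_pal_notf": {
          "family": "fixed",
          "mean": 839.63,
          "sd": 0
        },
        "neg_pal_tf": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "neg_pal_notf": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "neg_nopal_tf": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "neg_nopal_notf": {
          "family": "lognormal",
          "mean": 409.14,
          "sd": 724.91
        },
        "notest_tf": {
          "family": "lognormal",
          "mean": 2077.52,
          "sd": 2760.8
        },
        "notest_notf": {
          "family": "lognormal",
          "mean": 1208.45,
          "sd": 3038.71
        }
      },
      "annual_qalys": {
        "pos_pal_tf": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "pos_pal_notf": {
          "family": "fixed",
          "mean": 0.98,
          "sd": 0
        },
        "neg_pal_tf": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "neg_pal_notf": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "neg_nopal_tf": {
          "family": "fixed",
          "mean": 0,
          "sd": 0
        },
        "neg_nopal_notf": {
          "family": "beta",
          "mean": 0.888,
          "sd": 0.091
        },
        "notest_tf": {
          "family": "beta",
          "mean": 0.755,
          "sd": 0.249
        },
        "notest_notf": {
          "family": "beta",
          "mean": 0.85,
          "sd": 0.175
        }
      },
      "empty": {
        "probs": [],
        "costs": [],
        "qalys": []
      },
      "substituted": {
        "costs": [],
        "qalys": []
      }
    }
  },
  "substitution": {
    "qaly_source": "other_arm",
    "cost_source": "same_arm_no_test"
  }
}
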