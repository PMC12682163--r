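{
  "note": "Printed summary results of the published ALABAMA 5-year cost-effectiveness analysis, bundled for arithmetic validation of the model's identities. Currency GBP, 2022-23 prices.",
  "observed_costs_year1": {
    "components": ["test", "primary_care", "medications", "admissions", "outpatient", "emergency"],
    "paap": {"n": 401, "mean": [169.52, 38.74, 6.07, 643.54, 462.59, 74.25], "sd": [66.31, 76.23, 29.05, 2003.29, 782.71, 234.29], "total": 1394.71, "total_sd": 2632.52},
    "usual_care": {"n": 410, "mean": [1.52, 47.25, 8.87, 748.12, 475.51, 89.72], "sd": [16.29, 85.50, 37.00, 2761.80, 803.88, 223.45], "total": 1370.99, "total_sd": 3218.43}
  },
  "observed_costs_year2": {
    "components": ["primary_care", "medications", "admissions", "outpatient", "emergency"],
    "paap": {"n": 274, "mean": [39.59, 8.30, 848.79, 581.54, 59.11]},
    "usual_care": {"n": 278, "mean": [42.02, 7.29, 888.58, 507.67, 73.18]}
  },
  "per_period": {
    "rows": ["cost_year1", "cost_year2_5_discounted", "qaly_year1", "qaly_year2_5_discounted"],
    "paap": [684.141, 1523.834, 0.429, 1.577],
    "usual_care": [630.854, 1660.246, 0.422, 1.549],
    "difference": [53.287, -136.412, 0.008, 0.028]
  },
  "headline": {
    "base_case": {"n": 811, "delta_cost": -114.959, "delta_qaly": 0.022, "icer": "dominant", "inmb_20000": 563.834, "inmb_30000": 788.272},
    "psa": {"n": 811, "delta_cost": -83.125, "delta_qaly": 0.036, "icer": "dominant", "inmb_20000": 805.723, "inmb_30000": 1167.022, "p_ce_20000": 0.48, "p_ce_30000": 0.48, "p_cost_saving": 0.475}
  },
  "sensitivity": {
    "hes_costing": {"delta_cost": 16.322, "delta_qaly": 0.036, "icer": 451.755, "inmb_20000": 706.276, "inmb_30000": 1067.575, "p_ce": 0.48},
    "as_treated": {"delta_cost": -435.792, "delta_qaly": -0.350, "icer_saving_per_qaly_lost": 1243.559, "inmb_20000": -6572.997, "inmb_30000": -10077.390, "p_ce_20000": 0.20, "p_ce_30000": 0.19},
    "leeds_delivery": {"delta_cost": -84.781, "delta_qaly": 0.036, "icer": "dominant", "inmb_20000": 807.379, "inmb_30000": 1168.678, "p_ce": 0.48},
    "palace_relabelling": {"six_month_rate": 0.066, "deterministic_icer": 1122},
    "relabelling_literature_rate": {"annual_rate": 0.032, "p_below_inmb_zero_threshold": 0.82, "p_below_cost_saving_threshold": 0.59}
  },
  "subgroups": {
    "female": {"n": 584, "delta_cost": -20.051, "delta_qaly": 0.047, "icer": "dominant", "inmb_20000": 967.089, "inmb_30000": 1440.607, "p_ce": 0.52},
    "male": {"n": 227, "delta_cost": -264.00, "delta_qaly": -0.018, "icer_saving_per_qaly_lost": 14893.580, "inmb_20000": -90.514, "inmb_30000": -267.771},
    "age_under_65": {"n": 555, "delta_cost": -79.243, "delta_qaly": -0.005, "inmb_20000": -25.555, "inmb_30000": -77.953},
    "age_65_plus": {"n": 256, "delta_cost": -60.956, "delta_qaly": 0.120, "inmb_20000": 2455.833, "inmb_30000": 3653.272},
    "qof_under_2": {"n": 403, "delta_cost": 117.570, "delta_qaly": 0.262, "icer": 448.397, "inmb_20000": 5126.438, "inmb_30000": 7748.442},
    "qof_2_plus": {"n": 408, "delta_cost": -335.584, "delta_qaly": -0.198, "inmb_20000": -3625.266, "inmb_30000": -5605.690},
    "abx_under_2": {"n": 462, "delta_cost": -220.796, "delta_qaly": -0.111, "inmb_20000": -2006.583, "inmb_30000": -3120.273},
    "abx_2_plus": {"n": 349, "delta_cost": 37.615, "delta_qaly": 0.229, "icer": 164.169, "inmb_20000": 4544.862, "inmb_30000": 6836.101}
  },
  "value_of_information": {
    "followon_90_power": {"n": 1267, "cost": 2370000, "months": 46},
    "followon_80_power": {"n": 769, "cost": 1760000, "months": 30},
    "optimal": {"n": 840, "cost": 1850000, "net_value": 241700000},
    "evsi_per_patient_clinical": 249.15,
    "evsi_per_patient_full": 3097,
    "eligible_population_10y": 79877,
    "population_horizon_years": 10,
    "gross_value_clinical": 19600000,
    "net_value_clinical": 17200000,
    "net_value_full": 241500000
  },
  "unit_costs": {"day_case_tariff": 368, "spt_oral_challenge": 234, "direct_oral_challenge": 155}
}
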