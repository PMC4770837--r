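{
  "panel": [
    {
      "name": "NDMA",
      "istd_name": "NDMA-d6",
      "expected_rt_min": 5.21,
      "expected_rt_istd_min": 5.19,
      "expected_ion_ratio": 0.62,
      "lod_pg_ml": 6.54,
      "blank_limit_pg_ml": 13.08,
      "carryover_prone": true
    },
    {
      "name": "NMEA",
      "istd_name": "NMEA-d3",
      "expected_rt_min": 5.88,
      "expected_rt_istd_min": 5.86,
      "expected_ion_ratio": 0.48,
      "lod_pg_ml": 3.64,
      "blank_limit_pg_ml": 7.28,
      "carryover_prone": true
    },
    {
      "name": "NDEA",
      "istd_name": "NDEA-d10",
      "expected_rt_min": 6.47,
      "expected_rt_istd_min": 6.45,
      "expected_ion_ratio": 0.55,
      "lod_pg_ml": 5.02,
      "blank_limit_pg_ml": 10.04,
      "carryover_prone": true
    },
    {
      "name": "NPIP",
      "istd_name": "NPIP-d10",
      "expected_rt_min": 8.09,
      "expected_rt_istd_min": 8.07,
      "expected_ion_ratio": 0.44,
      "lod_pg_ml": 5.08,
      "blank_limit_pg_ml": 10.16,
      "carryover_prone": false
    },
    {
      "name": "NPYR",
      "istd_name": "NPYR-d8",
      "expected_rt_min": 8.72,
      "expected_rt_istd_min": 8.7,
      "expected_ion_ratio": 0.51,
      "lod_pg_ml": 8.15,
      "blank_limit_pg_ml": 16.3,
      "carryover_prone": false
    },
    {
      "name": "NMOR",
      "istd_name": "NMOR-d8",
      "expected_rt_min": 9.38,
      "expected_rt_istd_min": 9.36,
      "expected_ion_ratio": 0.38,
      "lod_pg_ml": 7.84,
      "blank_limit_pg_ml": 15.68,
      "carryover_prone": false
    }
  ],
  "constants": {
    "istd_mass_pg": 500,
    "sample_volume_ml": 2,
    "extract_volume_ml": 0.1,
    "top_standard_ng_ml": 400,
    "carryover_flag_threshold_pg_ml": 200,
    "repeatability_low_pct": 20,
    "repeatability_high_pct": 10,
    "repeatability_cut_pg_ml": 50
  },
  "qa_rules": {
    "rt_tolerance_min": 0.1,
    "ion_ratio_tolerance_pct": 20,
    "istd_area_min": 20000,
    "check_leading_acn_blank": true
  },
  "westgard_rules": {
    "enabled": ["1_2s", "1_3s", "2_2s", "R_4s"],
    "actions": {
      "1_2s": "warn",
      "1_3s": "reject",
      "2_2s": "reject",
      "R_4s": "reject",
      "4_1s": "reject",
      "10_x": "reject"
    }
  },
  "qc_characterization": [
    {
      "analyte": "NDMA",
      "pool": "qc_low",
      "mean": 50,
      "sd": 4.37586556534629,
      "n_runs": 60
    },
    {
      "analyte": "NMEA",
      "pool": "qc_low",
      "mean": 50,
      "sd": 4.23582068444219,
      "n_runs": 60
    },
    {
      "analyte": "NDEA",
      "pool": "qc_low",
      "mean": 50,
      "sd": 4.17835825246596,
      "n_runs": 60
    },
    {
      "analyte": "NPIP",
      "pool": "qc_low",
      "mean": 50,
      "sd": 4.46177177894695,
      "n_runs": 60
    },
    {
      "analyte": "NPYR",
      "pool": "qc_low",
      "mean": 50,
      "sd": 4.30116263352131,
      "n_runs": 60
    },
    {
      "analyte": "NMOR",
      "pool": "qc_low",
      "mean": 50,
      "sd": 4.5611948291973,
      "n_runs": 60
    },
    {
      "analyte": "NDMA",
      "pool": "qc_high",
      "mean": 200,
      "sd": 14.3752634565765,
      "n_runs": 60
    },
    {
      "analyte": "NMEA",
      "pool": "qc_high",
      "mean": 200,
      "sd": 14.3332542317071,
      "n_runs": 60
    },
    {
      "analyte": "NDEA",
      "pool": "qc_high",
      "mean": 200,
      "sd": 14.3163779527487,
      "n_runs": 60
    },
    {
      "analyte": "NPIP",
      "pool": "qc_high",
      "mean": 200,
      "sd": 14.4016459964619,
      "n_runs": 60
    },
    {
      "analyte": "NPYR",
      "pool": "qc_high",
      "mean": 200,
      "sd": 14.3527000944073,
      "n_runs": 60
    },
    {
      "analyte": "NMOR",
      "pool": "qc_high",
      "mean": 200,
      "sd": 14.4327578192768,
      "n_runs": 60
    }
  ],
  "simulation": {
    "seed": 1,
    "true_conc_pg_ml": {
      "NDMA": 8,
      "NMEA": 0,
      "NDEA": 0,
      "NPIP": 0,
      "NPYR": 6,
      "NMOR": 4
    },
    "qc_low_pg_ml": 50,
    "qc_high_pg_ml": 200,
    "proportional_cv": 0.05,
    "additive_sd_area": 800,
    "istd_area_mean": 100000,
    "istd_area_cv": 0.05,
    "run_cv": 0.05,
    "ndma_blank_contamination_pg_ml": 9.81,
    "carryover_fraction": 0.002,
    "rt_jitter_sd_min": 0.01,
    "ion_ratio_true": {},
    "response_factor": {
      "NDMA": 0.95,
      "NMEA": 1.05,
      "NDEA": 1.1,
      "NPIP": 0.9,
      "NPYR": 1,
      "NMOR": 0.85
    }
  }
}
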