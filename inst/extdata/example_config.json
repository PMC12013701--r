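{
  "run": {
    "years": 5,
    "spinup_years": 3,
    "start_year": 1983,
    "master_seed": 42,
    "anpp_sample_month_day": "08-27",
    "fuel_map_month_day": "12-31",
    "wfps_snapshot_month_day": "07-02",
    "latitude_deg": 39.1
  },
  "grid": {
    "rows": 30,
    "cols": 30,
    "cell_size_m": 30,
    "relief_m": 120
  },
  "climate": {
    "mean_annual_precip_mm": 835,
    "growing_season_fraction": 0.75,
    "wet_prob_growing": 0.36,
    "wet_prob_offseason": 0.26,
    "wet_persistence": 0.35,
    "gamma_shape_growing": 0.85,
    "gamma_shape_offseason": 0.7,
    "temp_mean_C": 12.7,
    "temp_amplitude_C": 14.5,
    "temp_phase_doy": 15,
    "temp_noise_sd_C": 3
  },
  "terrain": {
    "flat_epsilon_m": 1e-05,
    "stream_threshold_cells": 50,
    "position_window_cells": 9
  },
  "hydrology": {
    "infiltration_capacity_mm_d": 100,
    "lateral_mult": 0.6,
    "max_lateral_frac": 0.9,
    "et_base": 0.45,
    "et_max": 1.3,
    "et_leaf_half_sat_gC": 60
  },
  "plant": {
    "nmu_per_day": 0.02,
    "n_half_sat_gNm2": 0.4,
    "tmin_C": 5,
    "topt_C": 24,
    "tmax_C": 38,
    "cn_leaf": 35,
    "cn_agstem": 60,
    "cn_bgstem": 60,
    "cn_root": 45,
    "dw_per_c": 2.22222222222222,
    "alloc": {
      "leaf": 0.4,
      "agstem": 0.2,
      "bgstem": 0.05,
      "root": 0.35
    },
    "root_distribution": [0.45, 0.3, 0.15, 0.1],
    "senescence_daylength_h": 12.5,
    "senescence_doy_min": 172,
    "senescence_rate_per_day": 0.045,
    "standing_dead_fall_rate": 0.01,
    "root_turnover_per_day": 0.0025,
    "bgstem_turnover_per_day": 0.0005
  },
  "soil_carbon": {
    "k_litter": 0.004,
    "k_standing_dead": 0.0015,
    "k_soil": 0.00025,
    "retention_frac": 0.3,
    "q10": 2,
    "tref_C": 20,
    "fT_cap": 1.3,
    "moisture_opt_wfps": 0.6,
    "moisture_width": 0.45,
    "k_nitrify": 0.1,
    "nitrify_opt_wfps": 0.55,
    "nitrify_width": 0.4,
    "k_denitrify": 0.05,
    "mobility_no3": 1,
    "mobility_nh4": 0.1,
    "soil_temp_damping": [0.5, 0.2, 0.1, 0.05],
    "fixation_base_gN": 0.0008,
    "fixation_fire_mult": 5,
    "fixation_window_days": 60
  },
  "fire": {
    "combust_frac_dead": 0.9,
    "combust_frac_live": 0.9,
    "volatilize_frac": 0.8,
    "emit_c_frac": 1
  },
  "graze": {
    "intensity_gN_m2_d": 0.007,
    "mode": "absolute_flux",
    "partition": {
      "gain": 0.15,
      "manure": 0.35,
      "urine": 0.45,
      "volatilized": 0.05
    },
    "schedule": "post_burn_window",
    "lag_days": 14,
    "duration_days": 90
  },
  "treatments": {
    "n_parcels": 4,
    "intervals_yr": [1, 2, 4, 20],
    "burn_month_day": "04-09",
    "grazing": "none",
    "scar_cell_factor": 2
  },
  "cover": {
    "nongrass_cols": []
  },
  "init": {
    "leaf_C": 5,
    "agstem_C": 2,
    "bgstem_C": 120,
    "root_N_total": 9,
    "root_distribution": [0.45, 0.3, 0.15, 0.1],
    "standing_dead_C": 150,
    "litter_C": 100,
    "cn_standing_dead": 70,
    "cn_litter": 60,
    "nh4_g_m2": [0.4, 0.3, 0.2, 0.1],
    "no3_g_m2": [0.3, 0.2, 0.1, 0.05]
  },
  "soils": {
    "upland": {
      "thickness_mm": [130, 190, 240, 290],
      "porosity": [0.45, 0.45, 0.45, 0.45],
      "field_capacity_wfps": [0.58, 0.58, 0.58, 0.58],
      "wilting_wfps": [0.3, 0.3, 0.3, 0.3],
      "ksat_mm_d": [240, 120, 60, 25],
      "soil_C_g_m2": [3200, 2200, 1400, 900],
      "soil_N_g_m2": [266.666666666667, 183.333333333333, 116.666666666667, 75]
    },
    "slope": {
      "thickness_mm": [110, 180, 250, 320],
      "porosity": [0.48, 0.48, 0.48, 0.48],
      "field_capacity_wfps": [0.58, 0.58, 0.58, 0.58],
      "wilting_wfps": [0.3, 0.3, 0.3, 0.3],
      "ksat_mm_d": [280, 140, 70, 30],
      "soil_C_g_m2": [3800, 2600, 1700, 1100],
      "soil_N_g_m2": [316.666666666667, 216.666666666667, 141.666666666667, 91.6666666666667]
    },
    "lowland": {
      "thickness_mm": [120, 190, 260, 330],
      "porosity": [0.5, 0.5, 0.5, 0.5],
      "field_capacity_wfps": [0.56, 0.56, 0.56, 0.56],
      "wilting_wfps": [0.3, 0.3, 0.3, 0.3],
      "ksat_mm_d": [320, 160, 80, 35],
      "soil_C_g_m2": [4500, 3200, 2100, 1400],
      "soil_N_g_m2": [375, 266.666666666667, 175, 116.666666666667]
    }
  }
}
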