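#' Default simulation configuration
#'
#' The full hierarchical parameter set of the model with its calibrated
#' package defaults: a ~60 x 60-cell, 30-m synthetic ridge-valley catchment
#' under Flint Hills-like climate, four burn-treatment parcels (1/2/4/20
#' year intervals, April 9 burns), ungrazed. See the methods vignette for
#' the rationale behind each default.
#'
#' @return nested named list of class `sim_config`.
#' @export
default_config <- function() {
  cfg <- list(
    run = list(
      years = 20L, spinup_years = 3L, start_year = 1983L, master_seed = 42L,
      anpp_sample_month_day = "08-27", fuel_map_month_day = "12-31",
      wfps_snapshot_month_day = "07-02", latitude_deg = 39.1),
    grid = list(rows = 60L, cols = 60L, cell_size_m = 30, relief_m = 120),
    climate = list(
      mean_annual_precip_mm = 835, growing_season_fraction = 0.75,
      wet_prob_growing = 0.36, wet_prob_offseason = 0.26,
      wet_persistence = 0.35, gamma_shape_growing = 0.85,
      gamma_shape_offseason = 0.7, temp_mean_C = 12.7,
      temp_amplitude_C = 14.5, temp_phase_doy = 15, temp_noise_sd_C = 3),
    terrain = list(
      flat_epsilon_m = 1e-5, stream_threshold_cells = 50,
      position_window_cells = 9),
    hydrology = list(
      infiltration_capacity_mm_d = 100, lateral_mult = 0.6,
      max_lateral_frac = 0.9, et_base = 0.45, et_max = 1.25,
      et_leaf_half_sat_gC = 60),
    plant = list(
      nmu_per_day = 0.02, n_half_sat_gNm2 = 0.4,
      tmin_C = 5, topt_C = 24, tmax_C = 38,
      cn_leaf = 35, cn_agstem = 60, cn_bgstem = 60, cn_root = 45,
      dw_per_c = 1 / 0.45,
      alloc = c(leaf = 0.40, agstem = 0.20, bgstem = 0.05, root = 0.35),
      root_distribution = c(0.45, 0.30, 0.15, 0.10),
      senescence_daylength_h = 12.5, senescence_doy_min = 172,
      senescence_rate_per_day = 0.045, n_resorption_frac = 0.5,
      standing_dead_fall_rate = 0.010,
      root_turnover_per_day = 0.0025, bgstem_turnover_per_day = 0.0005),
    soil_carbon = list(
      k_litter = 0.004, k_standing_dead = 0.0015, k_soil = 2.5e-4,
      retention_frac = 0.3, retention_frac_surface = 0.7,
      q10 = 2, tref_C = 20, fT_cap = 1.3,
      moisture_opt_wfps = 0.60, moisture_width = 0.45,
      k_nitrify = 0.10, nitrify_opt_wfps = 0.55, nitrify_width = 0.4,
      k_denitrify = 0.05, mobility_no3 = 1.0, mobility_nh4 = 0.1,
      soil_temp_damping = c(0.5, 0.2, 0.1, 0.05),
      sun_warm_C = 5, shade_half_gC = 150,
      fixation_base_gN = 8e-4, fixation_fire_mult = 50,
      fixation_window_days = 60),
    fire = list(combust_frac_dead = 0.9, combust_frac_live = 0.9,
                volatilize_frac = 0.8, emit_c_frac = 1.0),
    graze = list(
      intensity_gN_m2_d = 0.007, mode = "absolute_flux",
      partition = c(gain = 0.15, manure = 0.35, urine = 0.45,
                    volatilized = 0.05),
      schedule = "post_burn_window", lag_days = 14, duration_days = 90),
    treatments = list(
      n_parcels = 4L, intervals_yr = c(1, 2, 4, 20),
      burn_month_day = "04-09", grazing = "none", scar_cell_factor = 2L),
    cover = list(nongrass_cols = integer(0)),
    init = default_initial_pools(),
    soils = default_soil_library()
  )
  class(cfg) <- c("sim_config", "list")
  cfg
}

# recursive default fill: user values override defaults, unknown keys error
merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown configuration parameter(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      merge_config(defaults[[nm]], user[[nm]], paste0(path, ".", nm))
    else user[[nm]]
  }
  defaults
}

#' Validate (and default-fill) a simulation configuration
#'
#' Merges a partial configuration over [default_config()] and bounds-checks
#' every parameter (fractions in `[0, 1]`, `Tmin < Topt < Tmax`,
#' `wilting < field capacity`, positive scales...). Violations are reported
#' with their parameter path.
#'
#' @param config partial configuration as a nested list (or a `sim_config`).
#' @return a complete, validated `sim_config`.
#' @export
validate_config <- function(config = list()) {
  cfg <- merge_config(unclass(default_config()), unclass(config))
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(all(ok))) errs <<- c(errs, msg)
  chk(cfg$run$years >= 1, "run.years must be >= 1")
  chk(cfg$run$spinup_years >= 0, "run.spinup_years must be >= 0")
  chk(cfg$grid$rows >= 3 && cfg$grid$cols >= 3,
      "grid.rows/cols must be >= 3")
  chk(cfg$grid$cell_size_m > 0, "grid.cell_size_m must be > 0")
  chk(cfg$grid$relief_m >= 0, "grid.relief_m must be >= 0")
  cl <- cfg$climate
  chk(cl$mean_annual_precip_mm >= 0,
      "climate.mean_annual_precip_mm must be >= 0")
  for (f in c("growing_season_fraction", "wet_prob_growing",
              "wet_prob_offseason", "wet_persistence"))
    chk(cl[[f]] >= 0 && cl[[f]] <= 1, paste0("climate.", f, " must be in [0, 1]"))
  chk(cl$gamma_shape_growing > 0 && cl$gamma_shape_offseason > 0,
      "climate gamma shapes must be > 0")
  hy <- cfg$hydrology
  chk(hy$infiltration_capacity_mm_d >= 0,
      "hydrology.infiltration_capacity_mm_d must be >= 0")
  chk(hy$max_lateral_frac >= 0 && hy$max_lateral_frac <= 1,
      "hydrology.max_lateral_frac must be in [0, 1]")
  chk(hy$et_base >= 0 && hy$et_max >= hy$et_base,
      "hydrology.et_base/et_max must satisfy 0 <= base <= max")
  pl <- cfg$plant
  chk(pl$tmin_C < pl$topt_C && pl$topt_C < pl$tmax_C,
      "plant temperature breakpoints must satisfy tmin < topt < tmax")
  chk(pl$nmu_per_day > 0, "plant.nmu_per_day must be > 0")
  chk(pl$n_half_sat_gNm2 > 0, "plant.n_half_sat_gNm2 must be > 0")
  chk(abs(sum(pl$alloc) - 1) < 1e-9 && all(pl$alloc >= 0),
      "plant.alloc must be non-negative and sum to 1")
  chk(all(pl$root_distribution >= 0) && sum(pl$root_distribution) > 0,
      "plant.root_distribution must be non-negative, not all zero")
  for (f in c("senescence_rate_per_day", "standing_dead_fall_rate",
              "root_turnover_per_day", "bgstem_turnover_per_day",
              "n_resorption_frac"))
    chk(pl[[f]] >= 0 && pl[[f]] <= 1, paste0("plant.", f, " must be in [0, 1]"))
  sc <- cfg$soil_carbon
  for (f in c("k_litter", "k_standing_dead", "k_soil", "k_nitrify",
              "k_denitrify"))
    chk(sc[[f]] >= 0, paste0("soil_carbon.", f, " must be >= 0"))
  chk(sc$retention_frac >= 0 && sc$retention_frac <= 1,
      "soil_carbon.retention_frac must be in [0, 1]")
  chk(sc$retention_frac_surface >= 0 && sc$retention_frac_surface <= 1,
      "soil_carbon.retention_frac_surface must be in [0, 1]")
  chk(sc$sun_warm_C >= 0, "soil_carbon.sun_warm_C must be >= 0")
  chk(sc$shade_half_gC > 0, "soil_carbon.shade_half_gC must be > 0")
  fr <- cfg$fire
  for (f in names(fr)) chk(fr[[f]] >= 0 && fr[[f]] <= 1,
                           paste0("fire.", f, " must be in [0, 1]"))
  gz <- cfg$graze
  chk(gz$intensity_gN_m2_d >= 0, "graze.intensity_gN_m2_d must be >= 0")
  chk(abs(sum(gz$partition) - 1) < 1e-9 && all(gz$partition >= 0),
      "graze.partition must be non-negative and sum to 1")
  chk(gz$mode %in% c("absolute_flux", "daily_fraction"),
      "graze.mode must be absolute_flux or daily_fraction")
  tr <- cfg$treatments
  chk(all(tr$intervals_yr >= 1), "treatments.intervals_yr must be >= 1")
  chk(tr$scar_cell_factor %in% c(1, 2),
      "treatments.scar_cell_factor must be 1 or 2")
  ip <- cfg$init
  chk(all(unlist(ip[c("leaf_C", "agstem_C", "bgstem_C", "root_N_total",
                      "standing_dead_C", "litter_C")]) >= 0) &&
        all(ip$nh4_g_m2 >= 0) && all(ip$no3_g_m2 >= 0),
      "init pools must be non-negative")
  if (!is.null(cfg$soils))
    for (nm in names(cfg$soils)) {
      v <- tryCatch({ validate_profile(cfg$soils[[nm]], paste0("soils.", nm))
                      NULL }, error = function(e) conditionMessage(e))
      if (!is.null(v)) errs <- c(errs, v)
    }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Read / write a configuration as JSON
#'
#' The hierarchical text format of the run configuration. Reading merges
#' over the defaults and validates; writing echoes the complete validated
#' configuration, so a round trip is semantically identity.
#'
#' @param path JSON file path.
#' @return [read_config()]: a validated `sim_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # restore named-vector blocks flattened by JSON
  for (blk in c("plant")) if (!is.null(raw[[blk]]$alloc))
    raw[[blk]]$alloc <- unlist(raw[[blk]]$alloc)
  if (!is.null(raw$graze$partition))
    raw$graze$partition <- unlist(raw$graze$partition)
  validate_config(raw)
}

#' @rdname read_config
#' @param config a `sim_config` (validated before writing).
#' @export
write_config <- function(config, path) {
  cfg <- validate_config(unclass(config))
  out <- unclass(cfg)
  # keep the names of named parameter vectors through JSON
  out$plant$alloc <- as.list(cfg$plant$alloc)
  out$graze$partition <- as.list(cfg$graze$partition)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
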