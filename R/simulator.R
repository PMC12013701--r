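#' Build a simulation context
#'
#' Assembles every input of a run from the configuration: synthetic daily
#' weather, the ridge-valley DEM (flat-resolved, flow-routed, watershed
#' delineated), topographic position classes, per-cell soil profiles,
#' treatment parcels with their burn scars and grazing schedule, and the
#' initial cell states. Any of the generated inputs can be overridden (the
#' resolution-comparison harness passes a block-averaged DEM; tests pass
#' hand-built forcing).
#'
#' All randomness derives from `config$run$master_seed` through
#' [derive_seed()], so a context is bit-reproducible.
#'
#' @param config a `sim_config` (validated; partial lists accepted).
#' @param dem optional [eco_grid] elevation override (un-resolved).
#' @param climate optional [climate_series()] override (must cover the
#'   simulated calendar years).
#' @param treatments optional [treatment_map()] override.
#' @param scars optional `burn_scar_set` override (e.g., `NULL` fires for a
#'   fire-toggled twin: pass a set with no scars).
#' @param positions optional per-cell topographic-position override (the
#'   resolution harness passes block-majority classes from the fine grid).
#' @return an object of class `sim_context`.
#' @export
build_simulation <- function(config = default_config(), dem = NULL,
                             climate = NULL, treatments = NULL,
                             scars = NULL, positions = NULL) {
  cfg <- validate_config(unclass(config))
  run <- cfg$run
  years <- seq(run$start_year, run$start_year + run$years - 1L)

  spin_start <- run$start_year - run$spinup_years
  if (is.null(climate)) {
    cp <- do.call(climate_params,
                  c(cfg$climate, list(seed = derive_seed(run$master_seed,
                                                         "climate"))))
    climate <- generate_daily_weather(cp, run$years + run$spinup_years,
                                      spin_start)
  }
  if (is.null(dem))
    dem <- generate_ridge_valley_dem(cfg$grid$rows, cfg$grid$cols,
                                     cfg$grid$cell_size_m, cfg$grid$relief_m,
                                     derive_seed(run$master_seed, "terrain"))
  resolved <- resolve_flats(dem, epsilon = cfg$terrain$flat_epsilon_m)
  flow <- compute_flow_weights(resolved, stream_threshold_cells =
                                 cfg$terrain$stream_threshold_cells)
  flow$edge_csr <- build_edge_csr(flow)
  flow$solute_ops <- build_solute_ops(flow)
  watershed <- delineate_watershed(flow)
  if (is.null(positions))
    positions <- classify_topography(resolved, flow,
                                     window = cfg$terrain$position_window_cells,
                                     area_threshold_cells =
                                       cfg$terrain$stream_threshold_cells)
  n <- flow$n
  grass <- !flow$nodata
  if (!is.null(cfg$cover$nongrass_cols)) {
    nong <- cell_col(seq_len(n), flow$ncol) %in% cfg$cover$nongrass_cols
    grass <- grass & !nong
  }
  if (is.null(treatments))
    treatments <- treatment_map(flow$nrow, flow$ncol, cfg$grid$cell_size_m,
                                intervals_yr = cfg$treatments$intervals_yr,
                                burn_month_day = cfg$treatments$burn_month_day,
                                grazing = cfg$treatments$grazing,
                                n_parcels = cfg$treatments$n_parcels,
                                scar_cell_factor = cfg$treatments$scar_cell_factor,
                                grassland = grass)
  years_all <- seq(spin_start, run$start_year + run$years - 1L)
  if (is.null(scars))
    scars <- generate_burn_scars(treatments, years_all,
                                 seed = derive_seed(run$master_seed, "scars"))
  gparams <- do.call(graze_params, cfg$graze[c("intensity_gN_m2_d", "mode",
                                               "partition", "schedule",
                                               "lag_days", "duration_days")])
  schedule <- schedule_treatments(treatments, scars, years_all, gparams)
  fparams <- do.call(fire_params, cfg$fire)
  soil_lib <- if (is.null(cfg$soils)) default_soil_library() else cfg$soils
  soil <- assign_soil_profiles(positions, soil_lib)

  # forcing calendar: spin-up runs on real antecedent generator years
  # preceding the reporting period (discarded from statistics); if the
  # supplied series does not cover them, fall back to replaying year 1
  clim_years <- as.integer(format(climate$date, "%Y"))
  if (run$spinup_years > 0L && min(clim_years) <= spin_start) {
    keep <- clim_years >= spin_start
    idx <- which(keep)
    spin_flag <- clim_years[idx] < run$start_year
  } else {
    yr1 <- clim_years == run$start_year
    idx <- c(rep(which(yr1), run$spinup_years), seq_len(nrow(climate)))
    spin_flag <- rep(c(TRUE, FALSE),
                     c(sum(yr1) * run$spinup_years, nrow(climate)))
  }
  forcing <- list(date = climate$date[idx],
                  precip = climate$precip_mm[idx],
                  tavg = climate$tavg_C[idx],
                  doy = as.integer(format(climate$date[idx], "%j")),
                  year = as.integer(format(climate$date[idx], "%Y")),
                  spinup = spin_flag)

  # per-day fire cells and grazed parcels (spinup days reuse year-1 events)
  nd <- length(forcing$date)
  fire_by_day <- vector("list", nd)
  for (f in schedule$fires) {
    hit <- which(forcing$date == f$date)
    for (i in hit) fire_by_day[[i]] <- c(fire_by_day[[i]], list(f$cells))
  }
  parcel_cells <- lapply(treatments$table$parcel_id, function(p)
    which(!is.na(treatments$parcel) & treatments$parcel == p))
  graze_by_day <- vector("list", nd)
  gw <- schedule$graze_windows
  if (nrow(gw)) for (k in seq_len(nrow(gw))) {
    hit <- which(forcing$date >= gw$start[k] & forcing$date < gw$end[k])
    for (i in hit) graze_by_day[[i]] <- union(graze_by_day[[i]],
                                              parcel_cells[[gw$parcel_id[k]]])
  }

  state <- init_state(cfg, soil, grass)
  damp_mat <- matrix(cfg$soil_carbon$soil_temp_damping, n, 4, byrow = TRUE)
  structure(list(config = cfg, climate = climate, dem = dem, damp_mat = damp_mat,
                 resolved_dem = resolved, flow = flow, watershed = watershed,
                 positions = positions, grass = grass, soil = soil,
                 treatments = treatments, scars = scars, schedule = schedule,
                 fire_params = fparams, graze_params = gparams,
                 forcing = forcing, fire_by_day = fire_by_day,
                 graze_by_day = graze_by_day, init_state = state,
                 years = years, n = n),
            class = "sim_context")
}

#' @export
print.sim_context <- function(x, ...) {
  cat(sprintf(paste0("<sim_context> %d x %d cells (%g m), %d+%d years, ",
                     "%d grassland cells, %d fire events\n"),
              x$flow$nrow, x$flow$ncol, x$config$grid$cell_size_m,
              x$config$run$years, x$config$run$spinup_years, sum(x$grass),
              length(x$schedule$fires)))
  invisible(x)
}

# initial per-cell state: water at field capacity, soil temperature at the
# annual mean, pools per cover type
init_state <- function(cfg, soil, grass) {
  n <- nrow(soil$thickness_mm)
  water <- soil$fc_mm
  water[is.na(water)] <- 0
  zero <- numeric(n); zero4 <- matrix(0, n, 4)
  st <- list(water = water,
             soil_temp = matrix(cfg$climate$temp_mean_C, n, 4),
             leafC = zero, leafN = zero, agstemC = zero, agstemN = zero,
             bgstemC = zero, bgstemN = zero,
             sdeadC = zero, sdeadN = zero, litterC = zero, litterN = zero,
             rootC = zero4, rootN = zero4,
             soilC = zero4, soilN = zero4, nh4 = zero4, no3 = zero4,
             days_since_fire = rep(Inf, n))
  live <- !is.na(soil$positions)
  st$soilC[live, ] <- soil$soilC0[live, ]
  st$soilN[live, ] <- soil$soilN0[live, ]
  ip <- cfg$init; pl <- cfg$plant
  st$nh4[live, ] <- matrix(ip$nh4_g_m2, sum(live), 4, byrow = TRUE)
  st$no3[live, ] <- matrix(ip$no3_g_m2, sum(live), 4, byrow = TRUE)
  g <- which(grass & live)
  rd <- ip$root_distribution / sum(ip$root_distribution)
  st$leafC[g] <- ip$leaf_C; st$leafN[g] <- ip$leaf_C / pl$cn_leaf
  st$agstemC[g] <- ip$agstem_C; st$agstemN[g] <- ip$agstem_C / pl$cn_agstem
  st$bgstemC[g] <- ip$bgstem_C; st$bgstemN[g] <- ip$bgstem_C / pl$cn_bgstem
  st$rootN[g, ] <- ip$root_N_total * matrix(rd, length(g), 4, byrow = TRUE)
  st$rootC[g, ] <- st$rootN[g, ] * pl$cn_root
  st$sdeadC[g] <- ip$standing_dead_C
  st$sdeadN[g] <- ip$standing_dead_C / ip$cn_standing_dead
  st$litterC[g] <- ip$litter_C
  st$litterN[g] <- ip$litter_C / ip$cn_litter
  st
}

# total stored water (mm-cell), N and C (g/m2-cell) of a state
state_totals <- function(st) {
  c(water = sum(st$water),
    N = sum(st$leafN) + sum(st$agstemN) + sum(st$bgstemN) + sum(st$rootN) +
      sum(st$sdeadN) + sum(st$litterN) + sum(st$soilN) + sum(st$nh4) +
      sum(st$no3),
    C = sum(st$leafC) + sum(st$agstemC) + sum(st$bgstemC) + sum(st$rootC) +
      sum(st$sdeadC) + sum(st$litterC) + sum(st$soilC))
}

#' Advance the simulation by one day
#'
#' The fixed daily sub-step order: disturbance (fires scheduled today);
#' hydrology (infiltration, percolation, topological-order lateral flow,
#' evapotranspiration, same-day streamflow); biogeochemistry (soil
#' temperature, uptake scalars, NPP, allocation, senescence and turnover,
#' decomposition, nitrification/denitrification, dissolved-N advection,
#' N fixation); grazing; flux accounting. Pure: returns the new state plus
#' the day's fluxes; calling it twice from the same state is bit-identical.
#'
#' @param ctx a `sim_context`.
#' @param state a state list (from `ctx$init_state` or a previous day).
#' @param i day index into `ctx$forcing`.
#' @return list `state`, `flux` (named scalars: discharge_mm, et_mm,
#'   precip_mm, npp totals and class means, fixation/denitrification/stream
#'   export/fire/grazing totals...).
#' @export
step_day <- function(ctx, state, i) {
  cfg <- ctx$config
  fz <- ctx$forcing
  tavg <- fz$tavg[i]; precip <- fz$precip[i]; doy <- fz$doy[i]
  soil <- ctx$soil; flow <- ctx$flow
  lat <- cfg$run$latitude_deg
  n <- ctx$n
  fire_C <- 0; fire_N <- 0; fire_ash <- 0; fire_cells_n <- 0

  # --- disturbance: fires are instantaneous, before growth ---
  for (cells in ctx$fire_by_day[[i]] %||% list()) {
    fr <- apply_fire(state, cells, ctx$fire_params, state$days_since_fire)
    state <- fr$pools
    state$days_since_fire <- fr$days_since_fire
    fire_C <- fire_C + fr$emissions$C_combusted
    fire_N <- fire_N + fr$emissions$N_volatilized
    fire_ash <- fire_ash + fr$emissions$ash_N
    fire_cells_n <- fire_cells_n + fr$emissions$cell_count
  }

  # --- hydrology ---
  inf <- infiltrate(precip, state$water, soil,
                    cfg$hydrology$infiltration_capacity_mm_d)
  state$water <- inf$water
  runoff <- inf$runoff_mm
  perc <- percolate(state$water, soil)
  state$water <- perc$water
  lat_res <- lateral_flow(state$water, soil, flow, cfg$hydrology)
  state$water <- lat_res$water
  runoff <- runoff + lat_res$runoff_add_mm
  et <- evapotranspire(state$water, soil, tavg, doy, state$leafC,
                       cfg$hydrology, cfg$plant$root_distribution, lat)
  state$water <- et$water
  discharge <- route_streamflow(runoff, lat_res$stream_mm, ctx$watershed)

  # --- biogeochemistry ---
  # surface fuel shades/insulates the soil: fire-blackened, litter-free
  # cells track a warmer effective surface temperature in the sun, the
  # mechanism behind the post-burn flush of early-season growth
  sc0 <- cfg$soil_carbon
  shade <- (state$sdeadC + state$litterC) /
    (state$sdeadC + state$litterC + sc0$shade_half_gC)
  t_eff <- tavg + sc0$sun_warm_C * (1 - shade)
  ts <- state$soil_temp + (t_eff - state$soil_temp) * ctx$damp_mat
  state$soil_temp <- ts
  wf <- compute_wfps(state$water, soil)
  tnu <- temperature_uptake_scalar(ts, cfg$plant$tmin_C, cfg$plant$topt_C,
                                   cfg$plant$tmax_C)
  wsc <- water_scalar(wf$layer, soil$wilt_wfps, soil$fc_wfps)
  avail <- state$nh4 + state$no3
  nsc <- nitrogen_scalar(avail, cfg$plant$n_half_sat_gNm2)
  npp <- compute_npp(state$rootN, tnu, nsc, wsc, cfg$plant$nmu_per_day, avail)
  up <- npp$uptake
  take_nh4 <- ifelse(avail > 0, up * state$nh4 / pmax(avail, 1e-300), 0)
  state$nh4 <- pmax(state$nh4 - take_nh4, 0)
  state$no3 <- pmax(state$no3 - (up - take_nh4), 0)
  inc <- allocate_growth(npp$npp_gN, cfg$plant$alloc, cfg$plant)
  state$leafN <- state$leafN + inc$leafN
  state$leafC <- state$leafC + inc$leafC
  state$agstemN <- state$agstemN + inc$agstemN
  state$agstemC <- state$agstemC + inc$agstemC
  state$bgstemN <- state$bgstemN + inc$bgstemN
  state$bgstemC <- state$bgstemC + inc$bgstemC
  state$rootN <- state$rootN + inc$rootN
  state$rootC <- state$rootC + inc$rootC
  npp_C <- sum(inc$leafC) + sum(inc$agstemC) + sum(inc$bgstemC) +
    sum(inc$rootC)

  state <- senesce(state, doy, tavg, lat, cfg$plant)
  # standing dead falls to litter at a constant daily rate (unfrozen days)
  if (tavg > 0) {
    fall <- cfg$plant$standing_dead_fall_rate
    state$litterC <- state$litterC + fall * state$sdeadC
    state$litterN <- state$litterN + fall * state$sdeadN
    state$sdeadC <- state$sdeadC * (1 - fall)
    state$sdeadN <- state$sdeadN * (1 - fall)
  }

  sc <- cfg$soil_carbon
  fT_surf <- decomp_temperature_factor(tavg, sc$q10, sc$tref_C, sc$fT_cap)
  fW_surf <- decomp_moisture_factor(wf$layer[, 1], sc$moisture_opt_wfps,
                                    sc$moisture_width)
  # surface fuels decompose at high C:N: most of their N is immobilized
  # into soil organic matter rather than mineralized directly
  d_lit <- decompose_pool(state$litterC, state$litterN, sc$k_litter, fT_surf,
                          fW_surf, sc$retention_frac_surface)
  d_sd <- decompose_pool(state$sdeadC, state$sdeadN, sc$k_standing_dead,
                         fT_surf, fW_surf, sc$retention_frac_surface)
  state$litterC <- state$litterC - d_lit$C_loss
  state$litterN <- state$litterN - d_lit$N_loss
  state$sdeadC <- state$sdeadC - d_sd$C_loss
  state$sdeadN <- state$sdeadN - d_sd$N_loss
  state$nh4[, 1] <- state$nh4[, 1] + d_lit$N_mineralized + d_sd$N_mineralized
  state$soilN[, 1] <- state$soilN[, 1] + d_lit$N_retained + d_sd$N_retained
  fT_soil <- decomp_temperature_factor(ts, sc$q10, sc$tref_C, sc$fT_cap)
  fW_soil <- decomp_moisture_factor(wf$layer, sc$moisture_opt_wfps,
                                    sc$moisture_width)
  d_soil <- decompose_pool(state$soilC, state$soilN, sc$k_soil, fT_soil,
                           fW_soil, sc$retention_frac)
  state$soilC <- state$soilC - d_soil$C_loss
  # retained N stays in the soil organic pool; only the mineralized share
  # leaves
  state$soilN <- state$soilN - d_soil$N_mineralized
  state$nh4 <- state$nh4 + d_soil$N_mineralized
  co2 <- sum(d_lit$C_loss) + sum(d_sd$C_loss) + sum(d_soil$C_loss)

  tr <- transform_mineral_n(state$nh4, state$no3, wf$layer, ts,
                            soil$fc_wfps, sc)
  state$nh4 <- state$nh4 - tr$nitrification
  state$no3 <- state$no3 + tr$nitrification - tr$denitrification
  denit <- sum(tr$denitrification)

  lch <- leach_dissolved_n(state$nh4, state$no3, perc$frac_out,
                           lat_res$frac_out, flow, sc)
  state$nh4 <- lch$nh4; state$no3 <- lch$no3

  fixation <- numeric(n)
  g <- ctx$grass
  fixation[g] <- fix_nitrogen(state$days_since_fire[g], tavg, sc)
  state$nh4[, 1] <- state$nh4[, 1] + fixation
  state$days_since_fire <- state$days_since_fire + 1

  # --- grazing ---
  gz <- list(grazed_N = 0, gain_N = 0, manure_N = 0, urine_N = 0,
             volatilized_N = 0, grazed_C = 0)
  gcells <- ctx$graze_by_day[[i]]
  if (length(gcells)) {
    gres <- graze_daily(state, gcells, ctx$graze_params)
    state <- gres$pools
    gz <- gres$budget
  }

  if (anyNA(state$water) || min(state$water) < -1e-9) {
    bad <- which(is.na(state$water) | state$water < -1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("NaN or negative water at cell %d layer %d on day %d (%s)",
                 bad[1], bad[2], i, format(fz$date[i])))
  }

  list(state = state, flux = list(
    precip_mm = precip, discharge_mm = discharge, et_mm = sum(et$et_total_mm),
    npp_gN = npp$npp_gN, npp_C = npp_C, co2_C = co2,
    fixation_N = sum(fixation), denitrified_N = denit,
    stream_N = lch$stream_export_gN,
    fire_C = fire_C, fire_N = fire_N, fire_ash_N = fire_ash,
    fire_cells = fire_cells_n, graze = gz))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full simulation
#'
#' Drives [step_day()] over the spin-up (replayed first-year forcing,
#' excluded from all reported statistics) and reporting years, samples the
#' declared output products (annual peak-season ANPP rasters on the
#' configured date, December-31 fuel-load rasters masked to grassland,
#' July-2 column-mean WFPS snapshots), accumulates the water/N/C mass
#' ledger, and asserts ledger closure at the end of the run.
#'
#' @param config a `sim_config`, or a prebuilt `sim_context`.
#' @param outdir optional directory: writes daily discharge CSV, ANPP and
#'   fuel rasters (ESRI ASCII) and the fire-emissions CSV.
#' @param progress print per-year progress with ledger summaries.
#' @return an object of class `prairie_run` (see Details) with elements
#'   `daily` (data.frame: date, year, spinup, precip_mm, discharge_mm,
#'   et_mm, domain/class mean NPP, live aboveground C, fuel C), `anpp`
#'   (year-named list of g dw/m2 matrices, NA off-grassland), `fuel`
#'   (year-named list of g C/m2 matrices), `wfps` (year-named list of
#'   column-mean WFPS matrices), `emissions`, `grazer_budget`, `ledger`,
#'   `positions`, `grass`, `treatments`, `watershed`, `config`, `years`,
#'   `final_state`.
#' @export
run_simulation <- function(config = default_config(), outdir = NULL,
                           progress = FALSE) {
  ctx <- if (inherits(config, "sim_context")) config
  else build_simulation(config)
  cfg <- ctx$config
  fz <- ctx$forcing
  nd <- length(fz$date)
  state <- ctx$init_state
  tot0 <- state_totals(state)
  grass <- ctx$grass
  up_cells <- grass & ctx$positions == "upland" & !is.na(ctx$positions)
  low_cells <- grass & ctx$positions == "lowland" & !is.na(ctx$positions)
  n_grass <- max(sum(grass), 1L)
  nlive <- sum(!ctx$flow$nodata)

  v_q <- numeric(nd); v_et <- numeric(nd); v_npp <- numeric(nd)
  v_npp_up <- numeric(nd); v_npp_low <- numeric(nd)
  v_liveag <- numeric(nd); v_fuel <- numeric(nd); v_minN <- numeric(nd)
  n_up <- sum(up_cells); n_low <- sum(low_cells)
  led <- list(w_in = 0, w_et = 0, w_q = 0,
              n_fix = 0, n_fire = 0, n_denit = 0, n_stream = 0,
              n_graze_volat = 0, n_graze_gain = 0,
              c_npp = 0, c_co2 = 0, c_fire = 0, c_graze = 0)
  gz_tot <- list(grazed_N = 0, gain_N = 0, manure_N = 0, urine_N = 0,
                 volatilized_N = 0)
  anpp <- list(); fuel <- list(); wfps_snap <- list(); emis <- list()

  anpp_md <- cfg$run$anpp_sample_month_day
  fuel_md <- cfg$run$fuel_map_month_day
  wfps_md <- cfg$run$wfps_snapshot_month_day
  md <- format(fz$date, "%m-%d")
  nw <- sum(ctx$watershed)

  for (i in seq_len(nd)) {
    res <- step_day(ctx, state, i)
    state <- res$state
    fx <- res$flux
    v_q[i] <- fx$discharge_mm
    v_et[i] <- fx$et_mm / nlive
    v_npp[i] <- sum(fx$npp_gN[grass]) / n_grass
    v_npp_up[i] <- if (n_up) sum(fx$npp_gN[up_cells]) / n_up else 0
    v_npp_low[i] <- if (n_low) sum(fx$npp_gN[low_cells]) / n_low else 0
    v_liveag[i] <- sum(state$leafC[grass] + state$agstemC[grass]) / n_grass
    v_fuel[i] <- sum(state$sdeadC[grass] + state$litterC[grass]) / n_grass
    v_minN[i] <- sum(state$nh4[grass, ] + state$no3[grass, ]) / n_grass
    led$w_in <- led$w_in + fx$precip_mm * nlive
    led$w_et <- led$w_et + fx$et_mm
    led$w_q <- led$w_q + fx$discharge_mm * nw
    led$n_fix <- led$n_fix + fx$fixation_N
    led$n_fire <- led$n_fire + fx$fire_N
    led$n_denit <- led$n_denit + fx$denitrified_N
    led$n_stream <- led$n_stream + fx$stream_N
    led$n_graze_volat <- led$n_graze_volat + fx$graze$volatilized_N
    led$n_graze_gain <- led$n_graze_gain + fx$graze$gain_N
    led$c_npp <- led$c_npp + fx$npp_C
    led$c_co2 <- led$c_co2 + fx$co2_C
    led$c_fire <- led$c_fire + fx$fire_C
    led$c_graze <- led$c_graze + fx$graze$grazed_C
    for (nm in names(gz_tot)) gz_tot[[nm]] <- gz_tot[[nm]] + fx$graze[[nm]]
    if (fx$fire_cells > 0)
      emis[[length(emis) + 1L]] <- data.frame(
        date = fz$date[i], cell_count = fx$fire_cells,
        C_combusted_g_m2 = fx$fire_C / fx$fire_cells,
        N_volatilized_g_m2 = fx$fire_N / fx$fire_cells)
    if (!fz$spinup[i]) {
      yr <- as.character(fz$year[i])
      if (md[i] == anpp_md) {
        dw <- (state$leafC + state$agstemC) * cfg$plant$dw_per_c
        dw[!grass] <- NA
        anpp[[yr]] <- vec_to_mat(dw, ctx$flow$nrow, ctx$flow$ncol)
      }
      if (md[i] == fuel_md) {
        fc <- state$sdeadC + state$litterC
        fc[!grass] <- NA
        fuel[[yr]] <- vec_to_mat(fc, ctx$flow$nrow, ctx$flow$ncol)
      }
      if (md[i] == wfps_md) {
        wfps_snap[[yr]] <- vec_to_mat(compute_wfps(state$water,
                                                   ctx$soil)$column,
                                      ctx$flow$nrow, ctx$flow$ncol)
      }
    }
    if (progress && md[i] == "12-31") {
      sel <- fz$year == fz$year[i] & fz$spinup == fz$spinup[i] &
        seq_len(nd) <= i
      message(sprintf("year %d%s: Q=%.0f mm, ET=%.0f mm", fz$year[i],
                      if (fz$spinup[i]) " (spinup)" else "",
                      sum(v_q[sel]), sum(v_et[sel])))
    }
  }
  daily <- data.frame(
    date = fz$date, year = fz$year, spinup = fz$spinup,
    precip_mm = fz$precip, discharge_mm = v_q, et_mm = v_et,
    npp_gN = v_npp, npp_upland_gN = v_npp_up, npp_lowland_gN = v_npp_low,
    live_ag_C = v_liveag, fuel_C = v_fuel, mineral_N = v_minN)

  tot1 <- state_totals(state)
  water_resid <- led$w_in - led$w_et - led$w_q - (tot1["water"] - tot0["water"])
  n_in <- led$n_fix
  n_out <- led$n_fire + led$n_denit + led$n_stream + led$n_graze_volat +
    led$n_graze_gain
  n_resid <- n_in - n_out - (tot1["N"] - tot0["N"])
  c_in <- led$c_npp
  c_out <- led$c_co2 + led$c_fire + led$c_graze
  c_resid <- c_in - c_out - (tot1["C"] - tot0["C"])
  ledger <- list(
    water = c(inputs = led$w_in, et = led$w_et, discharge = led$w_q,
              dstorage = unname(tot1["water"] - tot0["water"]),
              residual = unname(water_resid),
              rel_residual = unname(water_resid /
                                      max(led$w_in, tot0["water"], 1))),
    nitrogen = c(fixation = led$n_fix, fire_volatilized = led$n_fire,
                 denitrified = led$n_denit, stream_export = led$n_stream,
                 graze_volatilized = led$n_graze_volat,
                 graze_gain = led$n_graze_gain,
                 dstorage = unname(tot1["N"] - tot0["N"]),
                 residual = unname(n_resid),
                 rel_residual = unname(n_resid / max(n_in + tot0["N"], 1e-12))),
    carbon = c(npp = led$c_npp, co2 = led$c_co2, combustion = led$c_fire,
               grazed = led$c_graze,
               dstorage = unname(tot1["C"] - tot0["C"]),
               residual = unname(c_resid),
               rel_residual = unname(c_resid / max(c_in + tot0["C"], 1e-12))))
  for (b in names(ledger))
    if (abs(ledger[[b]]["rel_residual"]) > 1e-6)
      stop(sprintf("%s ledger failed closure: relative residual %.3g", b,
                   ledger[[b]]["rel_residual"]))

  out <- structure(list(
    daily = daily, anpp = anpp, fuel = fuel, wfps = wfps_snap,
    emissions = if (length(emis)) do.call(rbind, emis) else NULL,
    grazer_budget = gz_tot, ledger = ledger, positions = ctx$positions,
    grass = grass, treatments = ctx$treatments, watershed = ctx$watershed,
    config = cfg, years = ctx$years, final_state = state,
    cell_size_m = cfg$grid$cell_size_m,
    nrow = ctx$flow$nrow, ncol = ctx$flow$ncol), class = "prairie_run")
  if (!is.null(outdir)) write_run_outputs(out, outdir)
  out
}

#' @export
print.prairie_run <- function(x, ...) {
  rep_rows <- !x$daily$spinup
  yrs <- unique(x$daily$year[rep_rows])
  q <- tapply(x$daily$discharge_mm[rep_rows], x$daily$year[rep_rows], sum)
  p <- tapply(x$daily$precip_mm[rep_rows], x$daily$year[rep_rows], sum)
  cat(sprintf("<prairie_run> %d reporting years (%d-%d), %d x %d cells\n",
              length(yrs), min(yrs), max(yrs), x$nrow, x$ncol))
  cat(sprintf("  mean annual precip %.0f mm, discharge %.0f mm (ratio %.2f)\n",
              mean(p), mean(q), mean(q) / max(mean(p), 1e-12)))
  cat(sprintf("  ledger rel residuals: water %.1e, N %.1e, C %.1e\n",
              x$ledger$water["rel_residual"],
              x$ledger$nitrogen["rel_residual"],
              x$ledger$carbon["rel_residual"]))
  invisible(x)
}

# write the declared file outputs of a run
write_run_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rep_rows <- !run$daily$spinup
  q <- run$daily[rep_rows, c("date", "discharge_mm", "precip_mm")]
  tmp <- tempfile(tmpdir = outdir, fileext = ".csv.tmp")
  write.csv(q, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, file.path(outdir, "discharge.csv"))
  # daily domain-mean pool time series (reporting period)
  tmp <- tempfile(tmpdir = outdir, fileext = ".csv.tmp")
  write.csv(run$daily[rep_rows, c("date", "precip_mm", "discharge_mm",
                                  "et_mm", "npp_gN", "live_ag_C", "fuel_C",
                                  "mineral_N")],
            tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, file.path(outdir, "daily_pools.csv"))
  cs <- run$cell_size_m
  for (yr in names(run$anpp))
    write_ascii_grid(eco_grid(run$anpp[[yr]], cs),
                     file.path(outdir, paste0("anpp_", yr, ".asc")))
  for (yr in names(run$fuel))
    write_ascii_grid(eco_grid(run$fuel[[yr]], cs),
                     file.path(outdir, paste0("fuel_", yr, ".asc")))
  for (yr in names(run$wfps))
    write_ascii_grid(eco_grid(run$wfps[[yr]], cs),
                     file.path(outdir, paste0("wfps_", yr, ".asc")))
  if (!is.null(run$emissions))
    write_emissions_csv(run$emissions, file.path(outdir, "emissions.csv"))
  invisible(outdir)
}
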