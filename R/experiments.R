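#' Per-treatment annual ANPP means
#'
#' Samples the annual peak-season ANPP rasters of a run by treatment parcel
#' and topographic position, mirroring the GIS sampling of sentinel
#' locations: one row per (year, parcel, position) with the mean ANPP in
#' g dw/m2 and the cell count. Parcels with burn interval of 4 years or
#' less are labelled burned, longer intervals unburned ("infrequently
#' burned").
#'
#' @param run a `prairie_run`.
#' @param positions optional per-cell position override (default the run's).
#' @return data.frame `year`, `parcel_id`, `interval_yr`, `burned`,
#'   `position`, `mean_anpp_dw`, `n_cells`.
#' @export
sample_treatment_anpp <- function(run, positions = run$positions) {
  tr <- run$treatments
  out <- list()
  for (yr in names(run$anpp)) {
    v <- mat_to_vec(run$anpp[[yr]])
    for (p in tr$table$parcel_id) {
      for (pos in c("upland", "slope", "lowland")) {
        idx <- which(!is.na(tr$parcel) & tr$parcel == p &
                       !is.na(positions) & positions == pos & !is.na(v))
        if (!length(idx)) next
        out[[length(out) + 1L]] <- data.frame(
          year = as.integer(yr), parcel_id = p,
          interval_yr = tr$table$interval_yr[p],
          burned = tr$table$interval_yr[p] <= 4,
          position = pos, mean_anpp_dw = mean(v[idx]),
          n_cells = length(idx))
      }
    }
  }
  if (!length(out)) stop("empty treatment class: no sampled cells")
  do.call(rbind, out)
}

#' Annual domain summaries of a run
#'
#' Reporting-year annual totals and means: discharge, precipitation, ET,
#' annual NPP (domain grassland mean, g N/m2/yr) and the class means.
#'
#' @param run a `prairie_run`.
#' @return data.frame, one row per reporting year.
#' @export
annual_summary <- function(run) {
  d <- run$daily[!run$daily$spinup, ]
  yr <- d$year
  data.frame(
    year = as.integer(names(tapply(d$precip_mm, yr, sum))),
    precip_mm = as.numeric(tapply(d$precip_mm, yr, sum)),
    discharge_mm = as.numeric(tapply(d$discharge_mm, yr, sum)),
    et_mm = as.numeric(tapply(d$et_mm, yr, sum)),
    npp_gN = as.numeric(tapply(d$npp_gN, yr, sum)),
    npp_upland_gN = as.numeric(tapply(d$npp_upland_gN, yr, sum)),
    npp_lowland_gN = as.numeric(tapply(d$npp_lowland_gN, yr, sum)))
}

#' Compare simulations at two grid resolutions
#'
#' Simulates the same catchment at the configured (fine) resolution and at
#' an integer-factor coarser resolution whose DEM is the block mean of the
#' fine DEM, under identical forcing and parameters, and reports the
#' per-year relative difference in domain-mean annual NPP.
#'
#' @param config a `sim_config` for the fine run.
#' @param factor integer coarsening factor (default 4, e.g. 30 m vs 120 m);
#'   must divide the grid dimensions.
#' @param progress passed to [run_simulation()].
#' @return list `fine`, `coarse` (`prairie_run`s), `table` (year,
#'   npp_fine, npp_coarse, rel_diff), `max_abs_rel_diff_pct`.
#' @export
compare_resolutions <- function(config = default_config(), factor = 4,
                                progress = FALSE) {
  cfg <- validate_config(unclass(config))
  factor <- as.integer(factor)
  if (factor < 1 || cfg$grid$rows %% factor || cfg$grid$cols %% factor)
    stop("coarse cell size must be an integer multiple of the fine size ",
         "dividing the grid dimensions")
  ctx_f <- build_simulation(cfg)
  run_f <- run_simulation(ctx_f, progress = progress)
  if (factor == 1L) {
    tab <- data.frame(year = annual_summary(run_f)$year,
                      npp_fine = annual_summary(run_f)$npp_gN,
                      npp_coarse = annual_summary(run_f)$npp_gN,
                      rel_diff = 0)
    return(list(fine = run_f, coarse = run_f, table = tab,
                max_abs_rel_diff_pct = 0))
  }
  dem_c <- aggregate_grid(ctx_f$dem, factor)
  attr(dem_c, "outlet") <- NULL  # re-derive: lowest boundary cell
  cfg_c <- cfg
  cfg_c$grid$rows <- cfg$grid$rows %/% factor
  cfg_c$grid$cols <- cfg$grid$cols %/% factor
  cfg_c$grid$cell_size_m <- cfg$grid$cell_size_m * factor
  # coarse inputs are block aggregates of the fine inputs: block-mean DEM,
  # block-majority position and parcel maps. Parameters are identical at
  # both resolutions (including the cell-count stream threshold: an
  # area-rescaled threshold of a few coarse cells would mark most of the
  # coarse grid as channel, a pure scale artifact).
  pos_c <- block_majority(ctx_f$positions, cfg$grid$rows, cfg$grid$cols,
                          factor)
  par_c <- block_majority(ctx_f$treatments$parcel, cfg$grid$rows,
                          cfg$grid$cols, factor)
  tm_c <- ctx_f$treatments
  tm_c$parcel <- as.integer(par_c)
  tm_c$nrow <- cfg_c$grid$rows
  tm_c$ncol <- cfg_c$grid$cols
  tm_c$cell_size_m <- cfg_c$grid$cell_size_m
  # coarse burn scars are block aggregates of the fine scars (a coarse cell
  # burns when at least half its fine cells burn), so the burned-area
  # history matches across resolutions instead of being re-derived from the
  # blocked parcel map with its own edge effects
  scars_c <- list(scars = lapply(ctx_f$scars$scars, function(s) {
    fine_cells <- scar_to_sim_cells(s$mask, ctx_f$scars)
    frac <- aggregate_grid(eco_grid(vec_to_mat(as.numeric(fine_cells),
                                               cfg$grid$rows, cfg$grid$cols),
                                    cfg$grid$cell_size_m), factor)
    list(date = s$date, mask = frac$values >= 0.5, parcel_id = s$parcel_id)
  }), scar_cell_factor = 1L,
  sim_nrow = cfg_c$grid$rows, sim_ncol = cfg_c$grid$cols,
  scar_nrow = cfg_c$grid$rows, scar_ncol = cfg_c$grid$cols)
  class(scars_c) <- "burn_scar_set"
  ctx_c <- build_simulation(cfg_c, dem = dem_c, climate = ctx_f$climate,
                            treatments = tm_c, positions = pos_c,
                            scars = scars_c)
  run_c <- run_simulation(ctx_c, progress = progress)
  sf <- annual_summary(run_f); sc <- annual_summary(run_c)
  rel <- (sc$npp_gN - sf$npp_gN) / sf$npp_gN
  tab <- data.frame(year = sf$year, npp_fine = sf$npp_gN,
                    npp_coarse = sc$npp_gN, rel_diff = rel)
  list(fine = run_f, coarse = run_c, table = tab,
       max_abs_rel_diff_pct = 100 * max(abs(rel)))
}

# block-majority aggregation of a categorical per-cell vector (ties break
# toward the most frequent value in the block as returned by table order)
block_majority <- function(v, nr, nc, f) {
  m <- vec_to_mat(v, nr, nc)
  nrc <- nr %/% f; ncc <- nc %/% f
  out <- matrix(v[1], nrc, ncc)
  for (i in seq_len(nrc)) for (j in seq_len(ncc)) {
    blk <- m[((i - 1L) * f + 1L):(i * f), ((j - 1L) * f + 1L):(j * f)]
    blk <- blk[!is.na(blk)]
    out[i, j] <- if (length(blk)) names(sort(table(blk),
                                             decreasing = TRUE))[1] else NA
  }
  res <- mat_to_vec(out)
  mode(res) <- mode(v)
  res
}

#' Peak-season aboveground biomass by position class
#'
#' Means of the annual ANPP rasters (peak-season standing live biomass,
#' g dw/m2) over grassland cells of each topographic position, per year.
#'
#' @param run a `prairie_run`.
#' @return data.frame `year`, `upland`, `slope`, `lowland` (g dw/m2).
#' @export
peak_biomass_by_position <- function(run) {
  out <- lapply(names(run$anpp), function(yr) {
    v <- mat_to_vec(run$anpp[[yr]])
    means <- vapply(c("upland", "slope", "lowland"), function(pos) {
      idx <- !is.na(v) & !is.na(run$positions) & run$positions == pos
      if (any(idx)) mean(v[idx]) else NA_real_
    }, 0)
    data.frame(year = as.integer(yr), upland = means[["upland"]],
               slope = means[["slope"]], lowland = means[["lowland"]])
  })
  do.call(rbind, out)
}

#' Twin runs with one factor toggled
#'
#' Runs the configured simulation twice under identical seeds and forcing,
#' toggling a single factor: `grazing` (twin A ungrazed, twin B grazed
#' year-round on all parcels at the configured intensity) or `fire`
#' (twin A with the configured burn schedule, twin B with no fires). Reports
#' the per-year percent change in peak-season aboveground live biomass by
#' position class and in domain-mean annual NPP.
#'
#' @param config a `sim_config`.
#' @param factor "grazing" or "fire".
#' @param progress passed to [run_simulation()].
#' @return list `base`, `toggled` (`prairie_run`s), `biomass` (data.frame:
#'   year, position, base, toggled, pct_change), `mean_pct_reduction`
#'   (named: upland, slope, lowland; positive = toggled below base).
#' @export
twin_run <- function(config = default_config(),
                     factor = c("grazing", "fire"), progress = FALSE) {
  factor <- match.arg(factor)
  cfg <- validate_config(unclass(config))
  ctx_a <- build_simulation(cfg)
  run_a <- run_simulation(ctx_a, progress = progress)
  if (factor == "grazing") {
    cfg_b <- cfg
    cfg_b$treatments$grazing <- "year_round"
    cfg_b$graze$schedule <- "year_round"
    ctx_b <- build_simulation(cfg_b, dem = ctx_a$dem, climate = ctx_a$climate)
  } else {
    empty <- ctx_a$scars
    empty$scars <- list()
    ctx_b <- build_simulation(cfg, dem = ctx_a$dem, climate = ctx_a$climate,
                              scars = empty)
  }
  run_b <- run_simulation(ctx_b, progress = progress)
  pa <- peak_biomass_by_position(run_a)
  pb <- peak_biomass_by_position(run_b)
  rows <- list()
  for (pos in c("upland", "slope", "lowland")) {
    rows[[pos]] <- data.frame(
      year = pa$year, position = pos, base = pa[[pos]], toggled = pb[[pos]],
      pct_change = 100 * (pb[[pos]] - pa[[pos]]) / pa[[pos]])
  }
  biomass <- do.call(rbind, rows)
  rownames(biomass) <- NULL
  red <- vapply(c("upland", "slope", "lowland"), function(pos)
    -mean(biomass$pct_change[biomass$position == pos]), 0)
  list(base = run_a, toggled = run_b, biomass = biomass,
       mean_pct_reduction = red)
}

#' Fraction of annual aboveground production accrued by a mid-season date
#'
#' Per reporting year, cumulative NPP from January 1 through `by_month_day`
#' divided by cumulative NPP through the peak-season sampling date, over the
#' chosen cell class; averaged over years. (Allocation fractions are
#' constant, so the aboveground share cancels in the ratio.)
#'
#' @param run a `prairie_run`.
#' @param by_month_day early cutoff, default "07-02" (the mid-season water
#'   stress bench date).
#' @param through_month_day late cutoff, default the run's ANPP sampling
#'   date.
#' @param class_col which daily NPP column to use: "npp_upland_gN",
#'   "npp_lowland_gN" or "npp_gN".
#' @return list `per_year` (data.frame year, fraction) and `mean_pct`.
#' @export
early_season_npp_fraction <- function(run, by_month_day = "07-02",
                                      through_month_day =
                                        run$config$run$anpp_sample_month_day,
                                      class_col = "npp_upland_gN") {
  d <- run$daily[!run$daily$spinup, ]
  md <- format(d$date, "%m-%d")
  out <- list()
  for (yr in unique(d$year)) {
    sel <- d$year == yr
    npp <- d[[class_col]][sel]
    mds <- md[sel]
    cum_by <- sum(npp[mds <= by_month_day])
    cum_through <- sum(npp[mds <= through_month_day])
    if (cum_through > 0)
      out[[length(out) + 1L]] <- data.frame(year = yr,
                                            fraction = cum_by / cum_through)
  }
  per_year <- do.call(rbind, out)
  list(per_year = per_year, mean_pct = 100 * mean(per_year$fraction))
}
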