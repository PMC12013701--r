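#' Water-filled pore space
#'
#' WFPS per layer is layer water divided by total pore volume
#' (thickness x porosity); the column value is the thickness-weighted mean
#' over the four layers. Values are guaranteed to lie in `[0, 1]` for any
#' state the model can produce.
#'
#' @param water `n x 4` matrix of layer water (mm).
#' @param soil a `soil_grid` from [assign_soil_profiles()].
#' @return list with `layer` (`n x 4`) and `column` (length `n`).
#' @export
compute_wfps <- function(water, soil) {
  pore <- soil$sat_mm
  if (any(pore <= 0, na.rm = TRUE)) stop("zero porosity layer")
  wf <- water / pore
  col <- rowSums(wf * soil$thickness_mm) / rowSums(soil$thickness_mm)
  list(layer = wf, column = col)
}

#' Partition precipitation into infiltration and surface runoff
#'
#' Infiltration is the minimum of precipitation, the daily infiltration
#' capacity, and the remaining pore space of the top layer; the excess
#' becomes surface runoff, which is routed to the outlet the same day.
#'
#' @param precip_mm daily precipitation (scalar or per-cell vector, mm).
#' @param water `n x 4` layer water matrix (mm).
#' @param soil a `soil_grid`.
#' @param capacity_mm_d daily infiltration capacity (mm/d).
#' @return list `water` (updated), `infiltration_mm`, `runoff_mm`.
#' @export
infiltrate <- function(precip_mm, water, soil, capacity_mm_d = 80) {
  stopifnot(all(precip_mm >= 0))
  free <- pmax(soil$sat_mm[, 1] - water[, 1], 0)
  inf <- pmin(precip_mm, capacity_mm_d, free)
  water[, 1] <- water[, 1] + inf
  list(water = water, infiltration_mm = inf, runoff_mm = precip_mm - inf)
}

#' Vertical percolation between layers
#'
#' Water above field capacity drains to the layer below, limited by the
#' donor layer's saturated conductivity and by the receiving layer's free
#' pore space. The bottom of layer 4 is closed (no deep groundwater): bottom
#' excess leaves only through lateral flow.
#'
#' @param water `n x 4` layer water matrix (mm).
#' @param soil a `soil_grid`.
#' @return list `water` (updated), `drainage_mm` (`n x 3`, interface fluxes),
#'   `frac_out` (`n x 4`, fraction of pre-step layer water that drained;
#'   used for solute advection, 0 for the bottom layer).
#' @export
percolate <- function(water, soil) {
  n <- nrow(water)
  drain <- matrix(0, n, 3)
  frac <- matrix(0, n, 4)
  for (l in 1:3) {
    pre <- water[, l]
    excess <- pmax(pre - soil$fc_mm[, l], 0)
    free <- pmax(soil$sat_mm[, l + 1] - water[, l + 1], 0)
    d <- pmin(excess, soil$ksat_mm_d[, l], free)
    water[, l] <- water[, l] - d
    water[, l + 1] <- water[, l + 1] + d
    drain[, l] <- d
    frac[, l] <- ifelse(pre > 0, d / pre, 0)
  }
  list(water = water, drainage_mm = drain, frac_out = frac)
}

#' Hamon potential evapotranspiration
#'
#' Temperature-and-daylength potential ET; zero at or below 0 deg C (frozen
#' cutoff).
#'
#' @param tavg_C daily mean air temperature.
#' @param doy day of year.
#' @param lat_deg latitude (degrees).
#' @return potential ET (mm/d).
#' @export
hamon_pet <- function(tavg_C, doy, lat_deg = 39.1) {
  D <- day_length_hours(doy, lat_deg)
  es <- 0.6108 * exp(17.27 * tavg_C / (tavg_C + 237.3))
  ifelse(tavg_C <= 0, 0, 29.8 * D * es / (tavg_C + 273.2))
}

#' Evapotranspiration from the soil column
#'
#' Potential ET (Hamon) is scaled by a leaf-biomass factor that rises from a
#' bare-soil floor toward a plateau (Michaelis form), so high leaf biomass
#' means high water use. Demand is apportioned over layers by the root
#' fraction profile and satisfied only from water above the wilting point,
#' so ET is zero when the column is at or below wilting.
#'
#' @param water `n x 4` layer water matrix (mm).
#' @param soil a `soil_grid`.
#' @param tavg_C daily mean temperature (scalar).
#' @param doy day of year.
#' @param leaf_C per-cell leaf carbon (g C/m2).
#' @param params hydrology parameter block (see [default_config()]):
#'   `et_base`, `et_max`, `et_leaf_half_sat_gC`, and `lat_deg` is passed
#'   separately.
#' @param root_distribution length-4 root fraction profile.
#' @param lat_deg latitude.
#' @return list `water` (updated), `et_mm` (`n x 4` per layer),
#'   `et_total_mm` (length `n`), `pet_mm` (scalar).
#' @export
evapotranspire <- function(water, soil, tavg_C, doy, leaf_C, params,
                           root_distribution = c(0.45, 0.30, 0.15, 0.10),
                           lat_deg = 39.1) {
  pet <- hamon_pet(tavg_C, doy, lat_deg)
  f <- params$et_base + (params$et_max - params$et_base) *
    leaf_C / (leaf_C + params$et_leaf_half_sat_gC)
  rd <- root_distribution / sum(root_distribution)
  demand <- (pet * f) %o% rd
  avail <- pmax(water - soil$wilt_mm, 0)
  et <- pmin(demand, avail)
  et[is.na(et)] <- 0
  water <- water - et
  list(water = water, et_mm = et, et_total_mm = rowSums(et), pet_mm = pet)
}

#' Lateral downslope subsurface flow
#'
#' Per layer, the transferable water is the amount above field capacity
#' times a slope- and conductivity-dependent daily fraction
#' (`ksat x slope / thickness`, clamped to `[0, max_lateral_frac]`), split
#' among downslope neighbors by the flow weights and processed in
#' topological order so each day's transfers are single-pass. Stream cells
#' drain their excess, and receive lateral arrivals, directly into the
#' channel (same-day delivery at the outlet); receiving-layer overflow above
#' saturation cascades upward and ultimately to surface runoff.
#'
#' @param water `n x 4` layer water matrix (mm).
#' @param soil a `soil_grid`.
#' @param flow a `flow_field` (flat-resolved; acyclic by construction).
#' @param params hydrology parameter block (`lateral_mult`,
#'   `max_lateral_frac`).
#' @return list `water` (updated), `moved_mm` (`n x 4` lateral out),
#'   `frac_out` (`n x 4`, moved / pre-step water, for solute advection),
#'   `runoff_add_mm` (length `n`, cascade overflow), `stream_mm`
#'   (total water delivered to the channel, mm summed over cells).
#' @export
lateral_flow <- function(water, soil, flow, params = list(lateral_mult = 1,
                                                          max_lateral_frac = 0.9)) {
  frac <- clamp(soil$ksat_mm_d * flow$slope / soil$thickness_mm *
                  params$lateral_mult, 0, params$max_lateral_frac)
  frac[is.na(frac)] <- 0
  ep <- flow$edge_csr
  if (is.null(ep)) ep <- build_edge_csr(flow)
  w0 <- water
  w0[is.na(w0)] <- 0
  fc <- soil$fc_mm; fc[is.na(fc)] <- Inf
  sat <- soil$sat_mm; sat[is.na(sat)] <- Inf
  res <- .lateral_route_cpp(w0, fc, sat, frac, flow$topo_order,
                            ep$ptr0, ep$to, ep$w, flow$stream)
  pre <- w0
  frac_out <- ifelse(pre > 0, res$moved / pre, 0)
  list(water = res$water, moved_mm = res$moved, frac_out = frac_out,
       runoff_add_mm = res$runoff_add, stream_mm = res$stream_mm)
}

# CSR edge grouping for the C++ kernel: 0-based ptr over 1-based cell ids,
# edges sorted by source cell. Cached on the flow field by the simulator.
build_edge_csr <- function(flow) {
  o <- order(flow$from)
  cnt <- tabulate(flow$from, nbins = flow$n)
  ptr0 <- c(0L, cumsum(cnt))
  list(ptr0 = as.integer(ptr0), to = as.integer(flow$to[o]),
       w = as.numeric(flow$weight[o]))
}

#' Daily outlet discharge
#'
#' All surface runoff in the watershed plus the day's channel arrivals reach
#' the outlet the same day (daily step, no channel storage). Discharge is
#' expressed as depth over the watershed area.
#'
#' @param runoff_mm per-cell surface runoff (mm), including cascade overflow.
#' @param stream_mm total channel arrivals from [lateral_flow()] (mm summed
#'   over cells).
#' @param watershed logical mask of watershed cells.
#' @return discharge in mm over the watershed area for the day.
#' @export
route_streamflow <- function(runoff_mm, stream_mm, watershed) {
  nw <- sum(watershed)
  if (nw == 0) stop("watershed mask is empty")
  (sum(runoff_mm[watershed]) + stream_mm) / nw
}
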