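#' Default soil profile library by topographic position
#'
#' Four-layer profiles keyed by topographic position, following the usual
#' prairie catena: shallow rocky profiles on ridge-top uplands, deep
#' well-drained profiles on valley lowlands, intermediate on side slopes.
#' Values are package calibration defaults (the source landscape publishes
#' no layer table); wilting-point WFPS defaults to 0.3 everywhere.
#'
#' Each profile holds per-layer vectors (length 4, top first):
#' `thickness_mm`, `porosity`, `field_capacity_wfps`, `wilting_wfps`,
#' `ksat_mm_d`, `soil_C_g_m2`, `soil_N_g_m2`.
#'
#' @return named list of profiles (`upland`, `slope`, `lowland`).
#' @export
default_soil_library <- function() {
  prof <- function(th, poros, fc, ksat, soc) {
    list(thickness_mm = th, porosity = rep(poros, 4),
         field_capacity_wfps = rep(fc, 4), wilting_wfps = rep(0.3, 4),
         ksat_mm_d = ksat, soil_C_g_m2 = soc, soil_N_g_m2 = soc / 12)
  }
  list(
    upland = prof(c(130, 190, 240, 290), 0.45, 0.58,
                  c(240, 120, 60, 25), c(3200, 2200, 1400, 900)),
    slope = prof(c(110, 180, 250, 320), 0.48, 0.58,
                 c(280, 140, 70, 30), c(3800, 2600, 1700, 1100)),
    lowland = prof(c(120, 190, 260, 330), 0.50, 0.56,
                   c(320, 160, 80, 35), c(4500, 3200, 2100, 1400))
  )
}

validate_profile <- function(p, name = "profile") {
  need <- c("thickness_mm", "porosity", "field_capacity_wfps", "wilting_wfps",
            "ksat_mm_d", "soil_C_g_m2", "soil_N_g_m2")
  if (!all(need %in% names(p)))
    stop(name, " missing fields: ", paste(setdiff(need, names(p)), collapse = ", "))
  for (f in need) if (length(p[[f]]) != 4) stop(name, "$", f, " must have 4 layers")
  if (any(p$thickness_mm <= 0)) stop(name, ": layer thickness must be > 0")
  if (any(p$porosity <= 0 | p$porosity > 1)) stop(name, ": porosity in (0, 1]")
  if (any(p$wilting_wfps >= p$field_capacity_wfps))
    stop(name, ": wilting_wfps must be < field_capacity_wfps")
  if (any(p$field_capacity_wfps > 1)) stop(name, ": field_capacity_wfps <= 1")
  if (any(p$ksat_mm_d < 0)) stop(name, ": ksat must be >= 0")
  invisible(p)
}

#' Assign soil profiles to cells by topographic position
#'
#' Expands a per-position profile library to per-cell, per-layer parameter
#' matrices. Every cell must be classified; unclassified (non-NA position
#' absent from the library) is an error. Nodata cells get NA parameters.
#'
#' @param positions character vector over cells ("upland" | "slope" |
#'   "lowland", NA for nodata) from [classify_topography()].
#' @param library profile library as from [default_soil_library()].
#' @return an object of class `soil_grid`: list of `n x 4` matrices
#'   `thickness_mm`, `porosity`, `fc_wfps`, `wilt_wfps`, `ksat_mm_d`,
#'   `soilC0`, `soilN0`, plus derived `sat_mm`, `fc_mm`, `wilt_mm` and the
#'   `positions` vector.
#' @export
assign_soil_profiles <- function(positions, library = default_soil_library()) {
  for (nm in names(library)) validate_profile(library[[nm]], nm)
  n <- length(positions)
  live <- !is.na(positions)
  unknown <- setdiff(unique(positions[live]), names(library))
  if (length(unknown))
    stop("unclassified cells: no profile for position ",
         paste(unknown, collapse = ", "))
  fields <- c(thickness_mm = "thickness_mm", porosity = "porosity",
              fc_wfps = "field_capacity_wfps", wilt_wfps = "wilting_wfps",
              ksat_mm_d = "ksat_mm_d", soilC0 = "soil_C_g_m2",
              soilN0 = "soil_N_g_m2")
  out <- lapply(fields, function(f) matrix(NA_real_, n, 4))
  names(out) <- names(fields)
  for (pos in names(library)) {
    idx <- which(live & positions == pos)
    if (!length(idx)) next
    for (nm in names(fields))
      out[[nm]][idx, ] <- matrix(library[[pos]][[fields[nm]]], length(idx), 4,
                                 byrow = TRUE)
  }
  out$sat_mm <- out$thickness_mm * out$porosity
  out$fc_mm <- out$sat_mm * out$fc_wfps
  out$wilt_mm <- out$sat_mm * out$wilt_wfps
  out$positions <- positions
  class(out) <- "soil_grid"
  out
}

#' Default initial pool configuration
#'
#' Mid-winter (January 1) pool sizes for a tallgrass prairie cell, in g/m2.
#' Live aboveground pools start small (post-senescence), root nitrogen
#' carries the regrowth capacity, and surface fuel pools carry the previous
#' season's senesced biomass. Package calibration defaults.
#'
#' @return named list of initial pool parameters.
#' @export
default_initial_pools <- function() {
  list(leaf_C = 5, agstem_C = 2, bgstem_C = 120, root_N_total = 9,
       root_distribution = c(0.45, 0.30, 0.15, 0.10),
       standing_dead_C = 150, litter_C = 100,
       cn_standing_dead = 70, cn_litter = 60,
       nh4_g_m2 = c(0.40, 0.30, 0.20, 0.10),
       no3_g_m2 = c(0.30, 0.20, 0.10, 0.05))
}

#' Initialize the carbon/nitrogen pools of one cell
#'
#' Grassland cells get live plant pools (leaf, aboveground stem, belowground
#' stem, fine roots distributed over the four soil layers by a
#' declining-with-depth profile), surface fuel pools, and mineral N;
#' non-grassland cells get zero plant and fuel pools (they are simulated for
#' hydrologic purposes only). Soil organic pools come from the profile.
#'
#' @param profile a single profile from the soil library (see
#'   [default_soil_library()]).
#' @param cover_type "grassland" or anything else (hydrology-only).
#' @param init initial pool parameters, see [default_initial_pools()].
#' @param plant plant stoichiometry parameters (C:N ratios), see
#'   [default_config()]`$plant`.
#' @return named list of pools: scalars `leafC, leafN, agstemC, agstemN,
#'   bgstemC, bgstemN, sdeadC, sdeadN, litterC, litterN` and length-4 vectors
#'   `rootN, rootC, soilC, soilN, nh4, no3`.
#' @export
initialize_pools <- function(profile, cover_type = "grassland",
                             init = default_initial_pools(),
                             plant = default_config()$plant) {
  validate_profile(profile)
  nums <- unlist(init[c("leaf_C", "agstem_C", "bgstem_C", "root_N_total",
                        "standing_dead_C", "litter_C")])
  if (any(nums < 0)) stop("negative configured pools")
  if (any(init$nh4_g_m2 < 0) || any(init$no3_g_m2 < 0))
    stop("negative configured pools")
  grass <- identical(cover_type, "grassland")
  rd <- init$root_distribution / sum(init$root_distribution)
  rootN <- if (grass) init$root_N_total * rd else rep(0, 4)
  pools <- list(
    leafC = if (grass) init$leaf_C else 0,
    agstemC = if (grass) init$agstem_C else 0,
    bgstemC = if (grass) init$bgstem_C else 0,
    sdeadC = if (grass) init$standing_dead_C else 0,
    litterC = if (grass) init$litter_C else 0,
    rootN = rootN,
    soilC = profile$soil_C_g_m2,
    soilN = profile$soil_N_g_m2,
    nh4 = init$nh4_g_m2,
    no3 = init$no3_g_m2)
  pools$leafN <- pools$leafC / plant$cn_leaf
  pools$agstemN <- pools$agstemC / plant$cn_agstem
  pools$bgstemN <- pools$bgstemC / plant$cn_bgstem
  pools$rootC <- pools$rootN * plant$cn_root
  pools$sdeadN <- pools$sdeadC / init$cn_standing_dead
  pools$litterN <- pools$litterC / init$cn_litter
  pools
}
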