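#' Temperature scalar for plant nitrogen uptake
#'
#' Piecewise-parabolic response of N uptake to soil temperature: 0 at or
#' below `tmin` and at or above `tmax`, 1 at `topt`, continuous in between
#' (`1 - ((T - topt)/(topt - tmin))^2` on the rising limb and the analogous
#' quadratic on the falling limb). The functional form is a declared
#' stand-in; only its 0/1 anchor behavior is prescribed.
#'
#' @param tavg_C temperature (vectorized; soil temperature in the model).
#' @param tmin_C,topt_C,tmax_C breakpoints, `tmin < topt < tmax`.
#' @return scalar(s) in `[0, 1]`.
#' @export
temperature_uptake_scalar <- function(tavg_C, tmin_C = 5, topt_C = 24,
                                      tmax_C = 38) {
  if (!(tmin_C < topt_C && topt_C < tmax_C))
    stop("malformed breakpoints: need tmin < topt < tmax")
  s <- ifelse(tavg_C <= topt_C,
              1 - ((tavg_C - topt_C) / (topt_C - tmin_C))^2,
              1 - ((tavg_C - topt_C) / (tmax_C - topt_C))^2)
  clamp(s, 0, 1)
}

#' Water scalar for plant nitrogen uptake
#'
#' 0 at or below the wilting-point WFPS (default 0.3), 1 at or above the
#' field-capacity WFPS, linear between. Evaluated per soil layer.
#'
#' @param wfps water-filled pore space (0-1), vectorized.
#' @param wilting_wfps wilting point (default 0.3).
#' @param field_capacity_wfps field capacity WFPS.
#' @return scalar(s) in `[0, 1]`.
#' @export
water_scalar <- function(wfps, wilting_wfps = 0.3, field_capacity_wfps = 0.6) {
  if (any(wilting_wfps >= field_capacity_wfps))
    stop("wilting_wfps must be < field_capacity_wfps")
  clamp((wfps - wilting_wfps) / (field_capacity_wfps - wilting_wfps), 0, 1)
}

#' Nitrogen scalar for plant nitrogen uptake
#'
#' Michaelis-Menten saturation in plant-available mineral N
#' (ammonium + nitrate jointly, single half-saturation constant):
#' `N / (k + N)`.
#'
#' @param n_avail available mineral N (g N/m2), vectorized.
#' @param half_saturation `k` (g N/m2), > 0.
#' @return scalar(s) in `[0, 1)`.
#' @export
nitrogen_scalar <- function(n_avail, half_saturation = 0.4) {
  if (half_saturation <= 0) stop("half_saturation must be > 0")
  stopifnot(all(n_avail >= 0, na.rm = TRUE))
  n_avail / (half_saturation + n_avail)
}

#' Daily plant nitrogen uptake and NPP
#'
#' The four-constraint uptake model: per soil layer,
#' `uptake = RBN x TNUscalar x NMU x min(Nscalar, Wscalar)`, where RBN is
#' root biomass N in the layer and NMU the maximum specific uptake rate
#' (g N per g root N per day). The limiting scalar is selected per layer
#' (the lower of the nitrogen and water scalars), and uptake is additionally
#' capped at the layer's available mineral N. Total daily NPP in N units is
#' the sum over layers; C and dry-weight equivalents follow from the
#' configured stoichiometry at allocation.
#'
#' @param root_n `n x 4` root biomass N (g N/m2) by layer.
#' @param tnu `n x 4` (or scalar) temperature scalar by layer.
#' @param nscalar,wscalar `n x 4` nitrogen and water scalars by layer.
#' @param nmu maximum specific uptake rate (per day).
#' @param avail_n `n x 4` available mineral N (g N/m2) by layer.
#' @return list `uptake` (`n x 4` g N/m2/d) and `npp_gN` (length `n` totals).
#' @export
compute_npp <- function(root_n, tnu, nscalar, wscalar, nmu, avail_n) {
  stopifnot(all(nscalar >= 0 & nscalar <= 1, na.rm = TRUE),
            all(wscalar >= 0 & wscalar <= 1, na.rm = TRUE))
  uptake <- root_n * tnu * nmu * pmin(nscalar, wscalar)
  uptake <- pmin(uptake, pmax(avail_n, 0))
  uptake[is.na(uptake)] <- 0
  list(uptake = uptake, npp_gN = rowSums(uptake))
}

#' Allocate daily N uptake to plant pools
#'
#' N increments are the uptake times the allocation fractions (which must
#' sum to 1 over leaf, aboveground stem, belowground stem, root); the root
#' share is further distributed over layers by the root profile. C
#' increments are N times each pool's C:N ratio.
#'
#' @param uptake_gN per-cell total daily uptake (g N/m2/d).
#' @param alloc named fractions `leaf`, `agstem`, `bgstem`, `root` summing
#'   to 1.
#' @param plant plant parameter block (C:N ratios, `root_distribution`).
#' @return list of increments: `leafN, leafC, agstemN, agstemC, bgstemN,
#'   bgstemC` (vectors) and `rootN, rootC` (`n x 4`).
#' @export
allocate_growth <- function(uptake_gN, alloc, plant) {
  if (any(alloc < 0) || abs(sum(alloc) - 1) > 1e-9)
    stop("allocation fractions must be non-negative and sum to 1")
  rd <- plant$root_distribution / sum(plant$root_distribution)
  rootN <- (uptake_gN * alloc[["root"]]) %o% rd
  list(leafN = uptake_gN * alloc[["leaf"]],
       leafC = uptake_gN * alloc[["leaf"]] * plant$cn_leaf,
       agstemN = uptake_gN * alloc[["agstem"]],
       agstemC = uptake_gN * alloc[["agstem"]] * plant$cn_agstem,
       bgstemN = uptake_gN * alloc[["bgstem"]],
       bgstemC = uptake_gN * alloc[["bgstem"]] * plant$cn_bgstem,
       rootN = rootN, rootC = rootN * plant$cn_root)
}

#' Senescence trigger
#'
#' Autumn die-back is active once the day length has fallen below the
#' configured threshold after mid-year (daylength/temperature criterion of
#' the falling season).
#'
#' @param doy day of year.
#' @param lat_deg latitude.
#' @param plant plant parameter block (`senescence_daylength_h`,
#'   `senescence_doy_min`).
#' @return logical.
#' @export
senescence_active <- function(doy, lat_deg = 39.1,
                              plant = default_config()$plant) {
  doy > plant$senescence_doy_min &
    day_length_hours(doy, lat_deg) < plant$senescence_daylength_h
}

#' Senescence and background turnover
#'
#' When the autumn trigger is active, a configured daily fraction of leaf
#' and aboveground stem C moves to standing-dead fuel. A resorption
#' fraction of the accompanying N is retranslocated to the belowground stem
#' (rhizome/crown) store before abscission — the reason dead grass carries
#' roughly twice the C:N of live tissue — and only the remainder enters the
#' fuel pool. Root turnover moves a daily fraction of fine-root C and N to
#' the layer soil organic pools year-round, and belowground stems turn over
#' slowly to the top soil layer. Mass is conserved exactly.
#'
#' @param pools list with `leafC, leafN, agstemC, agstemN, bgstemC, bgstemN`
#'   (vectors), `rootC, rootN, soilC, soilN` (`n x 4`), `sdeadC, sdeadN`
#'   (vectors).
#' @param doy day of year.
#' @param tavg_C daily mean temperature; turnover pauses on frozen days, so
#'   a frozen dormant day is a true fixed point of the state.
#' @param lat_deg latitude.
#' @param plant plant parameter block.
#' @return updated `pools` plus `senesced_C`, `senesced_N` (amounts moved to
#'   standing dead).
#' @export
senesce <- function(pools, doy, tavg_C = 15, lat_deg = 39.1,
                    plant = default_config()$plant) {
  if (tavg_C <= 0) {
    pools$senesced_C <- 0
    pools$senesced_N <- 0
    return(pools)
  }
  active <- senescence_active(doy, lat_deg, plant)
  sC <- 0; sN <- 0
  if (active) {
    r <- plant$senescence_rate_per_day
    res <- plant$n_resorption_frac
    dC <- r * (pools$leafC + pools$agstemC)
    dN <- r * (pools$leafN + pools$agstemN)
    pools$sdeadC <- pools$sdeadC + dC
    pools$sdeadN <- pools$sdeadN + dN * (1 - res)
    pools$bgstemN <- pools$bgstemN + dN * res
    pools$leafC <- pools$leafC * (1 - r); pools$leafN <- pools$leafN * (1 - r)
    pools$agstemC <- pools$agstemC * (1 - r)
    pools$agstemN <- pools$agstemN * (1 - r)
    sC <- dC; sN <- dN * (1 - res)
  }
  rt <- plant$root_turnover_per_day
  pools$soilC <- pools$soilC + rt * pools$rootC
  pools$soilN <- pools$soilN + rt * pools$rootN
  pools$rootC <- pools$rootC * (1 - rt)
  pools$rootN <- pools$rootN * (1 - rt)
  bt <- plant$bgstem_turnover_per_day
  pools$soilC[, 1] <- pools$soilC[, 1] + bt * pools$bgstemC
  pools$soilN[, 1] <- pools$soilN[, 1] + bt * pools$bgstemN
  pools$bgstemC <- pools$bgstemC * (1 - bt)
  pools$bgstemN <- pools$bgstemN * (1 - bt)
  pools$senesced_C <- sC
  pools$senesced_N <- sN
  pools
}

#' Temperature factor for decomposition and mineral N transformations
#'
#' Q10 response referenced to 20 deg C, zero on frozen days, capped so hot
#' summer days do not run away.
#'
#' @param t_C temperature (vectorized).
#' @param q10 Q10 coefficient (default 2).
#' @param tref_C reference temperature.
#' @param cap upper cap on the factor.
#' @return factor(s) >= 0.
#' @export
decomp_temperature_factor <- function(t_C, q10 = 2, tref_C = 20, cap = 1.3) {
  ifelse(t_C <= 0, 0, pmin(q10^((t_C - tref_C) / 10), cap))
}

#' Moisture factor for decomposition
#'
#' Parabolic response peaking at an intermediate WFPS (too dry and too wet
#' both slow aerobic decomposition).
#'
#' @param wfps water-filled pore space (0-1), vectorized.
#' @param opt WFPS at the optimum.
#' @param width half-width of the parabola.
#' @return factor(s) in `[0, 1]`.
#' @export
decomp_moisture_factor <- function(wfps, opt = 0.6, width = 0.45) {
  pmax(1 - ((wfps - opt) / width)^2, 0)
}

#' First-order decomposition of a C/N pool
#'
#' `C loss = k x f(T) x f(WFPS) x C`; N decomposes at the same fractional
#' rate, with a microbial retention fraction returned to (or kept in) soil
#' organic N and the remainder mineralized to ammonium. The decomposed C
#' leaves as CO2.
#'
#' @param C,N pool sizes (vectorized, g/m2).
#' @param k rate constant (per day).
#' @param fT,fW temperature and moisture factors.
#' @param retention microbial N retention fraction (default 0.3).
#' @return list `C_loss` (CO2), `N_loss` (leaves the pool), `N_mineralized`
#'   (to ammonium), `N_retained` (to soil organic N).
#' @export
decompose_pool <- function(C, N, k, fT, fW, retention = 0.3) {
  fr <- clamp(k * fT * fW, 0, 0.5)
  fr[is.na(fr)] <- 0
  closs <- fr * C
  nloss <- fr * N
  list(C_loss = closs, N_loss = nloss,
       N_mineralized = nloss * (1 - retention),
       N_retained = nloss * retention)
}

#' Nitrification and denitrification
#'
#' Nitrification is first-order in ammonium with an aerobic moisture optimum;
#' denitrification is first-order in nitrate, negligible below field
#' capacity and rising sharply above it. Both respond to temperature and are
#' capped by their source pools.
#'
#' @param nh4,no3 mineral N pools (`n x 4`, g N/m2).
#' @param wfps layer WFPS (`n x 4`).
#' @param t_C layer soil temperature (`n x 4` or scalar).
#' @param fc_wfps field-capacity WFPS (`n x 4` or scalar).
#' @param params soil-carbon parameter block (`k_nitrify`,
#'   `nitrify_opt_wfps`, `nitrify_width`, `k_denitrify`, `q10`, `tref_C`,
#'   `fT_cap`).
#' @return list `nitrification`, `denitrification` (`n x 4` g N/m2/d).
#' @export
transform_mineral_n <- function(nh4, no3, wfps, t_C, fc_wfps,
                                params = default_config()$soil_carbon) {
  stopifnot(all(nh4 >= 0, na.rm = TRUE), all(no3 >= 0, na.rm = TRUE))
  fT <- decomp_temperature_factor(t_C, params$q10, params$tref_C, params$fT_cap)
  f_aer <- decomp_moisture_factor(wfps, params$nitrify_opt_wfps,
                                  params$nitrify_width)
  nit <- pmin(params$k_nitrify * fT * f_aer * nh4, nh4)
  g <- pmax((wfps - fc_wfps) / pmax(1 - fc_wfps, 1e-9), 0)^2
  den <- pmin(params$k_denitrify * fT * g * no3, no3)
  nit[is.na(nit)] <- 0; den[is.na(den)] <- 0
  list(nitrification = nit, denitrification = den)
}

#' Advect dissolved mineral N with the day's water fluxes
#'
#' Dissolved N moves in proportion to the fraction of mobile layer water
#' that moved, times a per-species mobility coefficient (nitrate mobile,
#' ammonium strongly sorbed). Percolation carries N to the layer below;
#' lateral flow carries N along the flow edges, and N arriving at (or
#' leaving from) stream cells is exported from the system as stream N.
#'
#' @param nh4,no3 mineral N pools (`n x 4`).
#' @param perc_frac `n x 4` fraction of layer water that percolated down.
#' @param lat_frac `n x 4` fraction of layer water that left laterally.
#' @param flow a `flow_field` (with cached solute-scatter operators, see
#'   [build_solute_ops()]).
#' @param params soil-carbon parameter block (`mobility_nh4`,
#'   `mobility_no3`).
#' @return list `nh4`, `no3` (updated) and `stream_export_gN` (total over
#'   cells).
#' @export
leach_dissolved_n <- function(nh4, no3, perc_frac, lat_frac, flow,
                              params = default_config()$soil_carbon) {
  ops <- flow$solute_ops
  if (is.null(ops)) ops <- build_solute_ops(flow)
  export <- 0
  move_species <- function(pool, mobility) {
    # vertical advection with percolation
    down <- pool * clamp(perc_frac * mobility, 0, 1)
    pool <- pool - down
    pool[, 2:4] <- pool[, 2:4] + down[, 1:3]
    # lateral advection along flow edges
    out <- pool * clamp(lat_frac * mobility, 0, 1)
    pool <- pool - out
    # W_land rows already exclude the stream-bound weight share, so the raw
    # outflow scatters losslessly: row sum + export fraction = 1 per donor
    if (length(ops$W_land@x))
      pool <- pool + as.matrix(Matrix::crossprod(ops$W_land, out))
    export <<- export + sum(out * ops$export_frac)
    pool
  }
  nh4 <- move_species(nh4, params$mobility_nh4)
  no3 <- move_species(no3, params$mobility_no3)
  list(nh4 = nh4, no3 = no3, stream_export_gN = export)
}

#' Build the solute scatter operators for a flow field
#'
#' `W_land` scatters each cell's lateral export to its non-stream receivers;
#' `export_frac` is, per cell, the weight share going to stream cells (1 for
#' stream cells themselves, which drain to the channel directly).
#'
#' @param flow a `flow_field`.
#' @return list `W_land` (sparse `n x n`), `export_frac` (length `n`).
#' @export
build_solute_ops <- function(flow) {
  n <- flow$n
  to_stream <- flow$stream[flow$to]
  keep <- !to_stream & !flow$stream[flow$from]
  W_land <- Matrix::sparseMatrix(i = flow$from[keep], j = flow$to[keep],
                                 x = flow$weight[keep], dims = c(n, n))
  export_frac <- numeric(n)
  agg <- tapply(flow$weight[to_stream], flow$from[to_stream], sum)
  export_frac[as.integer(names(agg))] <- as.numeric(agg)
  export_frac[flow$stream] <- 1
  list(W_land = W_land, export_frac = export_frac)
}

#' Non-symbiotic nitrogen fixation
#'
#' A baseline daily fixation input to top-layer ammonium, boosted by a
#' configured multiplier for a window after fire (post-burn flush of
#' free-living fixers on the blackened, warmed surface).
#'
#' @param days_since_fire per-cell days since the last burn (`Inf` if never
#'   burned).
#' @param tavg_C daily mean temperature (fixation pauses on frozen days).
#' @param params soil-carbon parameter block (`fixation_base_gN`,
#'   `fixation_fire_mult`, `fixation_window_days`).
#' @return per-cell fixation flux (g N/m2/d) to be added to top-layer
#'   ammonium.
#' @export
fix_nitrogen <- function(days_since_fire, tavg_C,
                         params = default_config()$soil_carbon) {
  base <- if (tavg_C <= 0) 0 else params$fixation_base_gN
  boost <- ifelse(days_since_fire <= params$fixation_window_days,
                  params$fixation_fire_mult, 1)
  base * boost
}
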