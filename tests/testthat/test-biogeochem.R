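# Uptake scalars, NPP, allocation, senescence, decomposition, mineral N.

test_that("temperature scalar anchors and quadratic midpoint", {
  expect_equal(temperature_uptake_scalar(24), 1)
  expect_equal(temperature_uptake_scalar(0), 0)   # Tmin - 5
  expect_equal(temperature_uptake_scalar(5), 0)
  expect_equal(temperature_uptake_scalar(38), 0)
  expect_equal(temperature_uptake_scalar(45), 0)
  # midway Tmin -> Topt: closed-form quadratic gives 0.75
  mid <- (5 + 24) / 2
  expect_equal(temperature_uptake_scalar(mid), 1 - 0.25)
  # continuity near the optimum
  expect_lt(abs(temperature_uptake_scalar(24 - 1e-8) -
                  temperature_uptake_scalar(24 + 1e-8)), 1e-6)
  expect_error(temperature_uptake_scalar(10, 20, 15, 30), "malformed")
})

test_that("water scalar is the stated linear ramp", {
  expect_equal(water_scalar(0.3, 0.3, 0.7), 0)     # uptake ceases at wilting
  expect_equal(water_scalar(0.1, 0.3, 0.7), 0)
  expect_equal(water_scalar(0.7, 0.3, 0.7), 1)
  expect_equal(water_scalar(0.95, 0.3, 0.7), 1)
  expect_equal(water_scalar(0.5, 0.3, 0.7), 0.5)   # hand interpolation
  expect_error(water_scalar(0.5, 0.7, 0.6), "wilting")
})

test_that("nitrogen scalar is Michaelis-Menten", {
  k <- 0.4
  expect_equal(nitrogen_scalar(0, k), 0)
  expect_equal(nitrogen_scalar(k, k), 0.5)
  expect_equal(nitrogen_scalar(3 * k, k), 0.75)
  expect_error(nitrogen_scalar(1, 0), "> 0")
})

test_that("NPP selects the lower scalar and multiplies through", {
  rootn <- matrix(c(10, 0, 0, 0), 1, 4)
  avail <- matrix(10, 1, 4)
  # worked case: Nscalar 0.2 vs Wscalar 0.6 -> the 0.2 applies
  r1 <- compute_npp(rootn, 0.5, matrix(0.2, 1, 4), matrix(0.6, 1, 4),
                    0.02, avail)
  expect_equal(r1$npp_gN, 10 * 0.5 * 0.02 * 0.2)
  r2 <- compute_npp(rootn, 0.5, matrix(0.6, 1, 4), matrix(0.2, 1, 4),
                    0.02, avail)
  expect_equal(r2$npp_gN, r1$npp_gN)  # min() is symmetric
  # hand product: RBN 10, TNU 0.5, NMU 0.02, min-scalar 0.2 -> 0.02
  expect_equal(r1$npp_gN, 0.02)
  # any zero scalar annihilates
  expect_equal(compute_npp(rootn, 0, matrix(1, 1, 4), matrix(1, 1, 4),
                           0.02, avail)$npp_gN, 0)
  # uptake capped at available mineral N
  tiny <- matrix(c(0.001, 1, 1, 1), 1, 4)
  r3 <- compute_npp(rootn, 1, matrix(1, 1, 4), matrix(1, 1, 4), 0.5, tiny)
  expect_equal(r3$uptake[1, 1], 0.001)
})

test_that("NPP is monotone non-decreasing in each scalar", {
  rootn <- matrix(2.5, 1, 4)
  avail <- matrix(5, 1, 4)
  grid <- seq(0, 1, by = 0.1)
  for (fix in c(0.3, 0.8)) {
    n_sweep <- vapply(grid, function(s)
      compute_npp(rootn, 0.9, matrix(s, 1, 4), matrix(fix, 1, 4),
                  0.02, avail)$npp_gN, 0)
    w_sweep <- vapply(grid, function(s)
      compute_npp(rootn, 0.9, matrix(fix, 1, 4), matrix(s, 1, 4),
                  0.02, avail)$npp_gN, 0)
    t_sweep <- vapply(grid, function(s)
      compute_npp(rootn, s, matrix(fix, 1, 4), matrix(fix, 1, 4),
                  0.02, avail)$npp_gN, 0)
    expect_true(all(diff(n_sweep) >= -1e-15))
    expect_true(all(diff(w_sweep) >= -1e-15))
    expect_true(all(diff(t_sweep) >= -1e-15))
  }
})

test_that("allocation conserves N exactly and applies C:N ratios", {
  plant <- default_config()$plant
  alloc <- c(leaf = 0.4, agstem = 0.2, bgstem = 0.1, root = 0.3)
  inc <- allocate_growth(1, alloc, plant)
  gains <- c(inc$leafN, inc$agstemN, inc$bgstemN, sum(inc$rootN))
  expect_equal(unname(gains), c(0.4, 0.2, 0.1, 0.3))
  expect_equal(sum(gains), 1, tolerance = 1e-12)
  expect_equal(inc$leafC, 0.4 * plant$cn_leaf)
  # zero uptake: no change
  inc0 <- allocate_growth(0, alloc, plant)
  expect_equal(sum(unlist(inc0)), 0)
  expect_error(allocate_growth(1, c(leaf = 0.5, agstem = 0.5, bgstem = 0.2,
                                    root = -0.2), plant), "sum to 1")
})

test_that("senescence trigger and fraction arithmetic", {
  plant <- default_config()$plant
  expect_false(senescence_active(196, 39.1, plant))  # mid-July
  expect_true(senescence_active(280, 39.1, plant))   # early October
  pools <- list(leafC = 140, leafN = 4, agstemC = 60, agstemN = 1,
                bgstemC = 100, bgstemN = 100 / 60,
                rootC = matrix(100, 1, 4), rootN = matrix(2, 1, 4),
                soilC = matrix(0, 1, 4), soilN = matrix(0, 1, 4),
                sdeadC = 0, sdeadN = 0)
  plant2 <- modifyList(plant, list(senescence_rate_per_day = 0.02,
                                   root_turnover_per_day = 0,
                                   bgstem_turnover_per_day = 0,
                                   n_resorption_frac = 0.4))
  tot_before <- pools$leafN + pools$agstemN + pools$sdeadN + pools$bgstemN
  out <- senesce(pools, 280, tavg_C = 12, plant = plant2)
  # leaf N 4 + stem N 1 senesce at 0.02/d; 40% resorbed to the rhizome
  # store, 60% to standing-dead fuel
  expect_equal(out$senesced_N, 0.02 * 5 * 0.6)
  expect_equal(out$bgstemN - pools$bgstemN, 0.02 * 5 * 0.4)
  expect_equal(out$leafN + out$agstemN + out$sdeadN + out$bgstemN,
               tot_before, tolerance = 1e-12)
  # trigger inactive mid-July: only root turnover occurs
  plant3 <- modifyList(plant, list(root_turnover_per_day = 0.01,
                                   bgstem_turnover_per_day = 0))
  out2 <- senesce(pools, 196, tavg_C = 25, plant = plant3)
  # frozen day: no turnover at all
  outf <- senesce(pools, 280, tavg_C = -4, plant = plant3)
  expect_equal(outf$leafC, pools$leafC)
  expect_equal(outf$rootN, pools$rootN)
  expect_equal(out2$leafC, pools$leafC)
  expect_equal(sum(out2$soilN), sum(pools$rootN) * 0.01, tolerance = 1e-12)
})

test_that("decomposition is first-order with environmental gates", {
  # frozen day: nothing decomposes
  expect_equal(decomp_temperature_factor(-5), 0)
  d0 <- decompose_pool(100, 2, 0.002, decomp_temperature_factor(-5), 1)
  expect_equal(d0$C_loss, 0)
  # fuel C 100, k 0.002, f(T) = f(W) = 1 -> 0.2 g C/m2/d
  d1 <- decompose_pool(100, 2, 0.002, 1, 1, retention = 0.3)
  expect_equal(d1$C_loss, 0.2)
  expect_equal(d1$N_mineralized + d1$N_retained, d1$N_loss, tolerance = 1e-15)
  expect_equal(d1$N_mineralized, 0.002 * 2 * 0.7)
  # moisture factor peaks at the optimum
  w <- seq(0, 1, 0.05)
  f <- decomp_moisture_factor(w, 0.6, 0.45)
  expect_equal(w[which.max(f)], 0.6)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("winter decomposition is slower than summer under the sinusoid", {
  p <- climate_params(seed = 1, temp_noise_sd_C = 0)
  clim <- generate_daily_weather(p, 1)
  fT <- decomp_temperature_factor(clim$tavg_C)
  m <- as.integer(format(clim$date, "%m"))
  expect_lt(mean(fT[m %in% c(1, 2, 3)]), mean(fT[m %in% c(6, 7, 8)]))
})

test_that("nitrification and denitrification behave as specified", {
  params <- default_config()$soil_carbon
  z <- matrix(0, 1, 4)
  r0 <- transform_mineral_n(z, z, matrix(0.5, 1, 4), 20, 0.6, params)
  expect_true(all(r0$nitrification == 0) && all(r0$denitrification == 0))
  # first-order arithmetic: k 0.1, modifiers 1, NH4 2 -> 0.2
  p1 <- modifyList(params, list(nitrify_opt_wfps = 0.5, nitrify_width = 1e6,
                                fT_cap = 1))
  r1 <- transform_mineral_n(matrix(2, 1, 4), z, matrix(0.5, 1, 4), 20, 0.9, p1)
  expect_equal(r1$nitrification[1, 1], 0.2)
  # denitrification strictly greater at WFPS 0.95 than 0.5 at equal NO3
  no3 <- matrix(1, 1, 4)
  rdry <- transform_mineral_n(z, no3, matrix(0.5, 1, 4), 20, 0.6, params)
  rwet <- transform_mineral_n(z, no3, matrix(0.95, 1, 4), 20, 0.6, params)
  expect_true(all(rwet$denitrification > rdry$denitrification))
})

test_that("dissolved N advection is proportional and bounded", {
  v <- matrix(c(0, 1, 2), 1, 3)
  flow <- compute_flow_weights(eco_grid(v, 30), outlet = 1L,
                               stream_threshold_cells = 99)
  flow$stream[] <- FALSE; flow$stream[1] <- TRUE
  flow$solute_ops <- build_solute_ops(flow)
  params <- default_config()$soil_carbon
  nh4 <- matrix(1, 3, 4); no3 <- matrix(2, 3, 4)
  zero <- matrix(0, 3, 4)
  # zero water flux: zero transport
  r0 <- leach_dissolved_n(nh4, no3, zero, zero, flow, params)
  expect_equal(r0$nh4, nh4)
  expect_equal(r0$stream_export_gN, 0)
  # half the mobile water leaves cell 2 laterally at mobility 1:
  # half its nitrate arrives at the stream cell 1 and is exported
  lat <- zero; lat[2, 1] <- 0.5
  r1 <- leach_dissolved_n(nh4, no3, zero, lat, flow, params)
  expect_equal(r1$no3[2, 1], 1)
  expect_equal(r1$stream_export_gN,
               0.5 * 2 + 0.5 * params$mobility_nh4 * 1)
  # export bounded by the mineral N present
  tot_before <- sum(nh4) + sum(no3)
  expect_lte(r1$stream_export_gN, tot_before)
  expect_equal(sum(r1$nh4) + sum(r1$no3) + r1$stream_export_gN, tot_before,
               tolerance = 1e-12)
})

test_that("post-fire fixation boost and baseline", {
  params <- default_config()$soil_carbon
  expect_equal(fix_nitrogen(Inf, 20, params), params$fixation_base_gN)
  expect_equal(fix_nitrogen(10, 20, params),
               params$fixation_fire_mult * params$fixation_base_gN)
  # a bespoke 5x multiplier behaves the same way
  p5 <- modifyList(params, list(fixation_fire_mult = 5))
  expect_equal(fix_nitrogen(10, 20, p5), 5 * p5$fixation_base_gN)
  expect_equal(fix_nitrogen(10, -2, params), 0)
  expect_equal(fix_nitrogen(params$fixation_window_days + 1, 20, params),
               params$fixation_base_gN)
})
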