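# Flat resolution, flow weights, watershed delineation, classification.

test_that("resolve_flats returns strictly draining terrain unchanged", {
  dem <- tilted_dem_3x3()
  res <- resolve_flats(dem)
  expect_equal(res$values, dem$values)
})

test_that("a plateau beside a lower outlet acquires strict downslope paths", {
  v <- matrix(5, 4, 4)
  v[4, 1] <- 0  # outlet corner below a 15-cell plateau
  dem <- eco_grid(v, 30)
  res <- resolve_flats(dem, outlet = cell_id(4L, 1L, 4L))
  ev <- mat_to_vec(res$values)
  # oracle: breadth-first reachability to the outlet over strictly
  # descending 8-neighbor edges
  nb <- tallgrass:::neighbor_ids(4, 4)
  reach <- rep(FALSE, 16); reach[cell_id(4L, 1L, 4L)] <- TRUE
  repeat {
    new <- FALSE
    for (i in which(!reach)) {
      lower <- nb[i, ][!is.na(nb[i, ])]
      if (any(reach[lower] & ev[lower] < ev[i])) { reach[i] <- TRUE; new <- TRUE }
    }
    if (!new) break
  }
  expect_true(all(reach))
  # minimality: the originally non-flat cell (outlet) is unchanged
  expect_equal(res$values[4, 1], 0)
})

test_that("undrainable basins fail naming the pit cell", {
  # center cell fenced off from the outlet by a full nodata ring
  v <- matrix(5, 5, 5)
  v[2:4, 2:4] <- NA
  v[3, 3] <- 1
  v[5, 5] <- 0
  dem <- eco_grid(v, 30)
  expect_error(resolve_flats(dem, outlet = cell_id(5L, 5L, 5L)),
               "undrainable basin: cell 13")
})

test_that("flow weights match hand-computed gradient normalization", {
  # center cell with one cardinal and one diagonal neighbor both 2 m lower,
  # cell size 30: gradients 2/30 and 2/(30*sqrt(2)), normalized; the grid
  # drains strictly so flat resolution is an identity
  v <- matrix(c(9, 9, 9, 9,
                9, 8, 6, 9,
                9, 9, 6, 4), nrow = 3, byrow = TRUE)
  dem <- eco_grid(v, 30)
  outlet <- cell_id(3L, 4L, 4L)
  res <- resolve_flats(dem, outlet = outlet)
  expect_equal(res$values, v)  # identity on strictly draining terrain
  flow <- compute_flow_weights(res, stream_threshold_cells = 99)
  ctr <- cell_id(2L, 2L, 4L)
  sel <- flow$from == ctr
  g_card <- 2 / 30; g_diag <- 2 / (30 * sqrt(2))
  expect_equal(sort(flow$weight[sel]),
               sort(c(g_card, g_diag) / (g_card + g_diag)), tolerance = 1e-12)
  expect_equal(sum(flow$weight[sel]), 1, tolerance = 1e-12)
})

test_that("single lower neighbor takes weight 1; symmetric drops split 0.5", {
  dem <- tilted_dem_3x3()
  res <- resolve_flats(dem)
  flow <- compute_flow_weights(res, stream_threshold_cells = 99)
  # cell (3,2) of the tilted plane has exactly one lower neighbor (west)
  sel1 <- flow$from == cell_id(3L, 2L, 3L)
  expect_equal(sum(sel1), 1L)
  expect_equal(unname(flow$weight[sel1]), 1)
  # symmetric case: center cell (2,2) has equal 2-m cardinal drops east and
  # south and nothing else lower; strictly draining grid throughout
  v <- matrix(c(9, 9, 9, 9,
                9, 8, 6, 5,
                9, 6, 8, 4,
                9, 5, 4, 3), nrow = 4, byrow = TRUE)
  dem2 <- eco_grid(v, 30)
  flow2 <- compute_flow_weights(dem2, outlet = cell_id(4L, 4L, 4L),
                                stream_threshold_cells = 99)
  sel <- flow2$from == cell_id(2L, 2L, 4L)
  expect_equal(unname(flow2$weight[sel]), c(0.5, 0.5))
})

test_that("weights normalize and the flow graph conserves a tracer", {
  dem <- generate_ridge_valley_dem(20, 20, seed = 4)
  res <- resolve_flats(dem)
  flow <- compute_flow_weights(res, stream_threshold_cells = 20)
  ws <- rowsum(flow$weight, flow$from)
  expect_true(all(abs(ws - 1) < 1e-12))
  expect_true(all(mat_to_vec(res$values)[flow$from] >
                    mat_to_vec(res$values)[flow$to]))
  # inject 1 unit at arbitrary cells; route in topological order; outlet
  # receives exactly 1
  for (start in c(1L, 57L, 211L, 390L)) {
    tracer <- numeric(flow$n)
    tracer[start] <- 1
    ep <- tallgrass:::edge_pointers(flow)
    for (cell in flow$topo_order) {
      a <- ep$ptr[cell]; b <- ep$ptr[cell + 1L] - 1L
      if (b >= a && tracer[cell] > 0) {
        idx <- ep$order[a:b]
        tracer[flow$to[idx]] <- tracer[flow$to[idx]] +
          tracer[cell] * flow$weight[idx]
        tracer[cell] <- 0
      }
    }
    expect_equal(tracer[flow$outlet], 1, tolerance = 1e-9)
  }
})

test_that("non-flat-resolved input is rejected", {
  v <- matrix(c(5, 5, 5,
                5, 5, 5,
                5, 5, 0), nrow = 3, byrow = TRUE)
  expect_error(compute_flow_weights(eco_grid(v, 30),
                                    outlet = cell_id(3L, 3L, 3L)),
               "not flat-resolved")
})

test_that("watershed delineation partitions a two-basin DEM", {
  # two parallel valleys separated by a ridge wall; no cross-ridge flow
  v <- matrix(0, 6, 5)
  for (r in 1:6) v[r, ] <- c(2, 1, 10, 1, 2) + 0.1 * (6 - r)
  dem <- eco_grid(v, 30)
  resA <- resolve_flats(dem, outlet = cell_id(6L, 2L, 5L))
  flow <- compute_flow_weights(resA, outlet = cell_id(6L, 2L, 5L),
                               stream_threshold_cells = 99)
  wsA <- delineate_watershed(flow, cell_id(6L, 2L, 5L))
  wsB <- delineate_watershed(flow, cell_id(6L, 4L, 5L))
  # oracle: per-cell graph traversal down any positive-weight edge chain
  reaches <- function(i, target) {
    seen <- logical(flow$n); stack <- i
    while (length(stack)) {
      c0 <- stack[[1]]; stack <- stack[-1]
      if (c0 == target) return(TRUE)
      if (seen[c0]) next
      seen[c0] <- TRUE
      stack <- c(stack, flow$to[flow$from == c0])
    }
    FALSE
  }
  for (i in seq_len(flow$n)) {
    expect_equal(wsA[i], reaches(i, cell_id(6L, 2L, 5L)))
    expect_equal(wsB[i], reaches(i, cell_id(6L, 4L, 5L)))
  }
  expect_error(delineate_watershed(flow, 9999L), "outside")
})

test_that("an outlet with no upslope cells has a singleton watershed", {
  dem <- tilted_dem_3x3()
  res <- resolve_flats(dem)
  flow <- compute_flow_weights(res, stream_threshold_cells = 99)
  top <- cell_id(1L, 3L, 3L)  # highest corner: nothing drains into it
  expect_equal(which(delineate_watershed(flow, top)), top)
})

test_that("topographic classification matches the template geometry", {
  dem <- generate_ridge_valley_dem(40, 41, seed = 2)  # odd cols: exact axis
  res <- resolve_flats(dem)
  flow <- compute_flow_weights(res)
  pos <- classify_topography(res, flow)
  m <- vec_to_mat(pos, 40, 41)
  # generator's known coordinates: valley axis column (lowland),
  # ridge plateau columns at the edges (upland)
  expect_true(all(m[5:35, 21] == "lowland"))
  expect_true(all(m[5:35, c(1, 41)] == "upland"))
  # translation invariance
  res2 <- res; res2$values <- res2$values + 1000
  flow2 <- compute_flow_weights(res2)
  expect_identical(pos, classify_topography(res2, flow2))
  # flat grid: all one class (lowland by convention)
  flat <- resolve_flats(generate_ridge_valley_dem(8, 8, relief_m = 0))
  fl <- compute_flow_weights(flat, stream_threshold_cells = 5)
  expect_true(all(classify_topography(flat, fl) == "lowland"))
})

test_that("topological order exists and routing touches each cell once", {
  dem <- generate_ridge_valley_dem(15, 15, seed = 3)
  res <- resolve_flats(dem)
  flow <- compute_flow_weights(res, stream_threshold_cells = 20)
  pos_in_order <- integer(flow$n)
  pos_in_order[flow$topo_order] <- seq_along(flow$topo_order)
  expect_true(all(pos_in_order[flow$from] < pos_in_order[flow$to]))
  expect_equal(sort(flow$topo_order), seq_len(flow$n))
})

test_that("flow edge CSV serialization round trips", {
  dem <- tilted_dem_3x3()
  flow <- compute_flow_weights(resolve_flats(dem), stream_threshold_cells = 99)
  path <- file.path(tempdir(), "edges.csv")
  write_flow_edges_csv(flow, path)
  back <- read.csv(path)
  expect_equal(back$from_cell, flow$from)
  expect_equal(back$weight, flow$weight, tolerance = 1e-12)
  unlink(path)
})
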