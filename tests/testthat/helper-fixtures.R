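# Shared fixtures, all built in code.

# a tiny, fast configuration for smoke/closure tests
small_config <- function(rows = 10L, cols = 10L, years = 1L, spinup = 0L,
                         seed = 42L) {
  cfg <- default_config()
  cfg$grid$rows <- rows
  cfg$grid$cols <- cols
  cfg$run$years <- years
  cfg$run$spinup_years <- spinup
  cfg$run$master_seed <- seed
  cfg$terrain$stream_threshold_cells <- 8
  cfg
}

# a hand-made 3x3 strictly draining DEM: plane tilted toward the SW corner,
# outlet at (3, 1)
tilted_dem_3x3 <- function() {
  v <- matrix(c(4, 5, 6,
                2, 3, 4,
                0, 1, 2), nrow = 3, byrow = TRUE)
  g <- eco_grid(v, cell_size_m = 30)
  attr(g, "outlet") <- cell_id(3L, 1L, 3L)
  g
}

# uniform single-position soil grid over n cells
uniform_soil <- function(n, position = "lowland") {
  assign_soil_profiles(rep(position, n))
}

# a one-cell pool "grid" from initialize_pools (vectors of length 1,
# matrices 1 x 4), as the disturbance operators expect
one_cell_pools <- function(cover = "grassland",
                           init = default_initial_pools()) {
  p <- initialize_pools(default_soil_library()$lowland, cover, init)
  for (nm in c("rootN", "rootC", "soilC", "soilN", "nh4", "no3"))
    p[[nm]] <- matrix(p[[nm]], 1, 4)
  p
}
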