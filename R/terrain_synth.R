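#' Generate a dissected ridge-valley elevation grid
#'
#' Builds a synthetic catchment in the style of a dissected limestone-prairie
#' landscape: flat-topped ridges along the east and west edges, side slopes
#' descending to a central valley, and a valley floor tilted toward a single
#' boundary outlet at the south edge. Low-amplitude correlated noise dissects
#' the side slopes; the flat ridge tops are deliberate so downstream flat
#' processing is exercised. `max - min` elevation equals `relief_m` exactly
#' and, for positive relief, exactly one boundary cell (the outlet) attains
#' the global minimum.
#'
#' @param rows,cols grid dimensions (>= 3).
#' @param cell_size_m cell size in metres (default 30).
#' @param relief_m total relief in metres (default 120, ridge-to-valley drop
#'   typical of the modeled landscape).
#' @param seed integer seed controlling the dissection noise.
#' @return an [eco_grid] of elevations; the outlet cell id (row-major) is
#'   attached as attribute `outlet`.
#' @export
generate_ridge_valley_dem <- function(rows = 60, cols = 60, cell_size_m = 30,
                                      relief_m = 120, seed = 1L) {
  if (rows < 3 || cols < 3) stop("degenerate dimensions: need rows, cols >= 3")
  if (relief_m < 0) stop("relief_m must be >= 0")
  valley_col <- as.integer(ceiling(cols / 2))
  r <- matrix(rep(seq_len(rows), cols), rows, cols)
  cc <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  # cross-valley coordinate: 0 on the valley axis, 1 at the far ridge edge
  d <- abs(cc - valley_col) / max(valley_col - 1, cols - valley_col)
  plateau <- d >= 0.8
  base <- pmin((d / 0.8), 1)^1.6
  # down-valley tilt confined to the non-plateau interior; outlet row has 0
  y <- (rows - r) / (rows - 1)
  elev <- base + 0.12 * y * (1 - base)
  # correlated dissection noise, largest mid-slope, zero on plateau and
  # vanishing on the valley axis so the outlet stays the unique minimum
  noise <- with_seed(seed, {
    z <- matrix(0, rows, cols)
    for (k in 1:6) {
      fr <- runif(1, 1, 4); fc2 <- runif(1, 1, 4)
      ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
      z <- z + sin(2 * pi * fr * r / rows + ph1) *
        sin(2 * pi * fc2 * cc / cols + ph2) / k
    }
    z / max(abs(z))
  })
  elev <- elev + 0.05 * noise * base * (1 - base) * 4 * (!plateau)
  elev[plateau] <- 1
  elev <- pmin(elev, 1)
  elev <- elev - min(elev)
  rng <- max(elev)
  if (relief_m > 0 && rng > 0) elev <- elev * (relief_m / rng)
  if (relief_m == 0) elev[] <- 0
  outlet <- cell_id(rows, valley_col, cols)
  # guarantee a unique boundary minimum for positive relief
  if (relief_m > 0) {
    ev <- mat_to_vec(elev)
    if (sum(ev == min(ev)) > 1 || which.min(ev) != outlet) {
      ev[outlet] <- min(ev[-outlet]) - 1e-6 * relief_m
      ev <- ev - min(ev)
      ev <- ev * (relief_m / max(ev))
      elev <- vec_to_mat(ev, rows, cols)
    }
  }
  g <- eco_grid(elev, cell_size_m = cell_size_m)
  attr(g, "outlet") <- outlet
  g
}
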