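#' @useDynLib tallgrass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rgamma runif
#' @importFrom utils head read.csv write.csv
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' generator calls are reproducible without disturbing the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a component seed from a master seed
#'
#' One master seed drives every stochastic component; each component gets its
#' own deterministic sub-stream so that, e.g., regenerating the terrain does
#' not perturb the weather.
#'
#' @param master integer master seed.
#' @param label character tag naming the component.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(master) * 7919 + h * 104729) %% 2147483629 + 1)
}

#' Day length from day-of-year and latitude
#'
#' Standard solar-declination day length used by the Hamon potential
#' evapotranspiration formulation and the autumn senescence trigger.
#'
#' @param doy day of year (1-366).
#' @param lat_deg latitude in decimal degrees (default 39.1, Flint Hills).
#' @return day length in hours.
#' @export
day_length_hours <- function(doy, lat_deg = 39.1) {
  lat <- lat_deg * pi / 180
  decl <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  x <- clamp(-tan(lat) * tan(decl), -1, 1)
  24 / pi * acos(x)
}

# month-day string ("04-09") -> day-of-year for a given year (leap-aware)
month_day_to_doy <- function(month_day, year) {
  d <- as.Date(paste0(year, "-", month_day))
  as.integer(format(d, "%j"))
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
}

# row-major cell id (row 1 = north edge) <-> (row, col)
cell_id <- function(row, col, ncol) (row - 1L) * ncol + col
cell_row <- function(id, ncol) ((id - 1L) %/% ncol) + 1L
cell_col <- function(id, ncol) ((id - 1L) %% ncol) + 1L

# neighbor offsets in documented order: E, NE, N, NW, W, SW, S, SE
NEIGHBOR_DR <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
NEIGHBOR_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
NEIGHBOR_DIST <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

# matrix of the 8 neighbor ids for every cell (NA outside the grid), n x 8
neighbor_ids <- function(nrow, ncol) {
  n <- nrow * ncol
  id <- seq_len(n)
  r <- cell_row(id, ncol); c <- cell_col(id, ncol)
  out <- matrix(NA_integer_, n, 8)
  for (k in 1:8) {
    rr <- r + NEIGHBOR_DR[k]; cc <- c + NEIGHBOR_DC[k]
    ok <- rr >= 1 & rr <= nrow & cc >= 1 & cc <= ncol
    out[ok, k] <- cell_id(rr[ok], cc[ok], ncol)
  }
  out
}

# vector (row-major, row 1 north) <-> matrix [nrow, ncol]
vec_to_mat <- function(v, nrow, ncol) matrix(v, nrow = nrow, ncol = ncol, byrow = TRUE)
mat_to_vec <- function(m) as.vector(t(m))
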