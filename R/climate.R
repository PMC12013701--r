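#' Daily weather generator parameters
#'
#' Parameters of the two-season stochastic weather generator. Precipitation
#' occurrence follows a two-state (wet/dry) Markov chain and wet-day depths
#' are gamma distributed, with separate parameters for the April-September
#' growing season and the October-March off season, so that the configured
#' growing-season share of annual precipitation is structural rather than
#' incidental. Temperature is an annual sinusoid plus white noise; there is
#' no precipitation-temperature coupling because the model consumes only
#' daily means.
#'
#' The gamma scale parameters are derived internally from
#' `mean_annual_precip_mm`, `growing_season_fraction`, the wet-day
#' probabilities and the shapes, so the long-run mean annual total and
#' growing-season share converge to the configured values.
#'
#' @param mean_annual_precip_mm long-run mean annual precipitation (default
#'   835 mm, a Flint Hills-like 35-year mean).
#' @param growing_season_fraction share of annual precipitation falling
#'   April 1 - September 30 (default 0.75).
#' @param wet_prob_growing,wet_prob_offseason stationary wet-day probability
#'   per season.
#' @param wet_persistence lag-1 autocorrelation of the wet/dry chain.
#' @param gamma_shape_growing,gamma_shape_offseason gamma shape of wet-day
#'   depth per season.
#' @param temp_mean_C annual mean temperature (default 12.7 C, declared
#'   package default for a temperate midcontinental site, not a measured
#'   site statistic).
#' @param temp_amplitude_C half-range of the annual temperature sinusoid.
#' @param temp_phase_doy day-of-year of the coldest day (default 15).
#' @param temp_noise_sd_C sd of daily white noise around the sinusoid.
#' @param seed integer seed.
#' @return an object of class `climate_gen_params`.
#' @export
climate_params <- function(mean_annual_precip_mm = 835,
                           growing_season_fraction = 0.75,
                           wet_prob_growing = 0.36,
                           wet_prob_offseason = 0.26,
                           wet_persistence = 0.35,
                           gamma_shape_growing = 0.85,
                           gamma_shape_offseason = 0.7,
                           temp_mean_C = 12.7,
                           temp_amplitude_C = 14.5,
                           temp_phase_doy = 15,
                           temp_noise_sd_C = 3,
                           seed = 1L) {
  p <- list(mean_annual_precip_mm = mean_annual_precip_mm,
            growing_season_fraction = growing_season_fraction,
            wet_prob_growing = wet_prob_growing,
            wet_prob_offseason = wet_prob_offseason,
            wet_persistence = wet_persistence,
            gamma_shape_growing = gamma_shape_growing,
            gamma_shape_offseason = gamma_shape_offseason,
            temp_mean_C = temp_mean_C, temp_amplitude_C = temp_amplitude_C,
            temp_phase_doy = temp_phase_doy, temp_noise_sd_C = temp_noise_sd_C,
            seed = as.integer(seed))
  if (mean_annual_precip_mm < 0) stop("mean_annual_precip_mm must be >= 0")
  for (f in c("growing_season_fraction", "wet_prob_growing",
              "wet_prob_offseason", "wet_persistence"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (gamma_shape_growing <= 0 || gamma_shape_offseason <= 0)
    stop("gamma shapes must be > 0")
  class(p) <- "climate_gen_params"
  p
}

#' Daily climate series
#'
#' @param dates `Date` vector, one entry per calendar day, no gaps.
#' @param precip_mm non-negative daily precipitation (mm/d).
#' @param tavg_C daily mean air temperature (mean of min and max, deg C).
#' @return a `data.frame` of class `climate_series` with columns `date`,
#'   `precip_mm`, `tavg_C`.
#' @export
climate_series <- function(dates, precip_mm, tavg_C) {
  stopifnot(inherits(dates, "Date"),
            length(dates) == length(precip_mm),
            length(dates) == length(tavg_C))
  if (any(precip_mm < 0)) stop("precipitation must be non-negative")
  d <- as.integer(diff(dates))
  if (length(d) && any(d != 1L)) {
    gap <- dates[which(d != 1L)[1]] + 1
    stop("climate series has a gap or duplicate at ", format(gap))
  }
  structure(data.frame(date = dates, precip_mm = as.numeric(precip_mm),
                       tavg_C = as.numeric(tavg_C)),
            class = c("climate_series", "data.frame"))
}

# TRUE for dates in the April 1 - September 30 growing season
in_growing_season <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  m >= 4L & m <= 9L
}

#' Generate synthetic daily weather
#'
#' Emits a gap-free daily series over `n_years` real calendar years
#' (leap-aware) from the two-season Markov-chain/gamma generator described in
#' [climate_params()]. Reproducible for a fixed `params$seed`.
#'
#' @param params a [climate_params()] object.
#' @param n_years number of whole calendar years (>= 1).
#' @param start_year first calendar year (default 1983).
#' @return a [climate_series()].
#' @export
generate_daily_weather <- function(params, n_years, start_year = 1983L) {
  stopifnot(inherits(params, "climate_gen_params"))
  if (!is.numeric(n_years) || n_years < 1) stop("n_years must be >= 1")
  n_years <- as.integer(n_years)
  dates <- seq(as.Date(paste0(start_year, "-01-01")),
               as.Date(paste0(start_year + n_years - 1L, "-12-31")), by = "day")
  nd <- length(dates)
  growing <- in_growing_season(dates)

  # gamma scales chosen so the structural seasonal totals hit the configured
  # mean and share; 183 growing days always, 182.25 off-season days on average
  tot_g <- params$mean_annual_precip_mm * params$growing_season_fraction
  tot_o <- params$mean_annual_precip_mm * (1 - params$growing_season_fraction)
  scale_g <- if (params$wet_prob_growing > 0 && tot_g > 0)
    tot_g / (183 * params$wet_prob_growing * params$gamma_shape_growing) else 0
  scale_o <- if (params$wet_prob_offseason > 0 && tot_o > 0)
    tot_o / (182.25 * params$wet_prob_offseason * params$gamma_shape_offseason) else 0

  doy <- as.integer(format(dates, "%j"))
  with_seed(params$seed, {
    pi_s <- ifelse(growing, params$wet_prob_growing, params$wet_prob_offseason)
    r <- params$wet_persistence
    p11 <- pi_s + r * (1 - pi_s)   # wet -> wet
    p01 <- pi_s * (1 - r)          # dry -> wet
    u <- runif(nd)
    wet <- logical(nd)
    wet[1] <- u[1] < pi_s[1]
    for (i in 2:nd) wet[i] <- u[i] < (if (wet[i - 1]) p11[i] else p01[i])
    precip <- numeric(nd)
    wg <- wet & growing; wo <- wet & !growing
    if (scale_g > 0 && any(wg))
      precip[wg] <- rgamma(sum(wg), shape = params$gamma_shape_growing,
                           scale = scale_g)
    if (scale_o > 0 && any(wo))
      precip[wo] <- rgamma(sum(wo), shape = params$gamma_shape_offseason,
                           scale = scale_o)
    tavg <- params$temp_mean_C -
      params$temp_amplitude_C *
        cos(2 * pi * (doy - params$temp_phase_doy) / 365.25) +
      rnorm(nd, sd = params$temp_noise_sd_C)
    climate_series(dates, precip, tavg)
  })
}

#' Annual precipitation totals and growing-season shares of a climate series
#'
#' @param clim a [climate_series()].
#' @return data.frame with one row per calendar year: `year`, `precip_mm`,
#'   `growing_mm`, `growing_share`.
#' @export
annual_climate_summary <- function(clim) {
  yr <- as.integer(format(clim$date, "%Y"))
  g <- in_growing_season(clim$date)
  tot <- tapply(clim$precip_mm, yr, sum)
  gtot <- tapply(clim$precip_mm * g, yr, sum)
  data.frame(year = as.integer(names(tot)), precip_mm = as.numeric(tot),
             growing_mm = as.numeric(gtot),
             growing_share = as.numeric(ifelse(tot > 0, gtot / tot, NA)))
}

#' Read a daily climate CSV
#'
#' Expects columns `date` (ISO-8601), `precip_mm`, `tavg_C`. Validates
#' continuity and reports any missing dates by name; rejects duplicates and
#' negative precipitation.
#'
#' @param path CSV path.
#' @return a [climate_series()].
#' @export
read_climate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "precip_mm", "tavg_C")
  if (!all(need %in% names(df)))
    stop("climate CSV must have columns ", paste(need, collapse = ", "))
  dates <- as.Date(df$date)
  if (anyNA(dates)) stop("unparseable dates in ", path)
  if (anyDuplicated(dates))
    stop("duplicate dates in ", path, ": ",
         format(dates[duplicated(dates)][1]))
  full <- seq(min(dates), max(dates), by = "day")
  if (length(full) != length(dates)) {
    missing <- setdiff(format(full), format(dates))
    stop("climate CSV has gaps; missing dates: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ..." else "")
  }
  o <- order(dates)
  if (any(df$precip_mm < 0)) stop("negative precipitation in ", path)
  climate_series(dates[o], df$precip_mm[o], df$tavg_C[o])
}

#' Write a daily climate CSV
#'
#' @param clim a [climate_series()].
#' @param path destination path (written atomically).
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(clim, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  df <- data.frame(date = format(clim$date), precip_mm = clim$precip_mm,
                   tavg_C = clim$tavg_C)
  write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
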