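#' Treatment parcel map
#'
#' Divides the grassland domain into management parcels (horizontal strips
#' aligned to scar-grid rows), each with a prescribed burn interval in
#' years, a burn month-day, and a grazing mode. Every grassland cell
#' belongs to exactly one parcel. Strips run across the valley axis of the
#' synthetic catchment, so every parcel spans upland, slope, and lowland
#' positions and treatment is not confounded with topography.
#'
#' @param nrow,ncol simulation grid dimensions.
#' @param cell_size_m simulation cell size.
#' @param intervals_yr burn interval per parcel (recycled over parcels;
#'   default `c(1, 2, 4, 20)`, the classic long-term treatment set).
#' @param burn_month_day burn date as "MM-DD" (default "04-09", an early
#'   April prescribed burn).
#' @param grazing grazing mode per parcel: "none", "year_round" or
#'   "post_burn_window" (recycled).
#' @param n_parcels number of parcels (default `length(intervals_yr)`).
#' @param scar_cell_factor scar cell size as a multiple of the simulation
#'   cell size (1 or 2); parcel strip edges are aligned to scar columns.
#' @param grassland logical vector over cells (default all TRUE); non-
#'   grassland cells get parcel NA.
#' @return an object of class `treatment_map`: list with `parcel` (integer
#'   per cell, NA off-grassland), `table` (one row per parcel: `parcel_id`,
#'   `interval_yr`, `burn_month_day`, `grazing`), grid geometry, and
#'   `scar_cell_factor`.
#' @export
treatment_map <- function(nrow, ncol, cell_size_m = 30,
                          intervals_yr = c(1, 2, 4, 20),
                          burn_month_day = "04-09",
                          grazing = "none",
                          n_parcels = length(intervals_yr),
                          scar_cell_factor = 2,
                          grassland = NULL) {
  if (any(intervals_yr < 1)) stop("burn interval must be >= 1 year")
  if (!scar_cell_factor %in% c(1, 2))
    stop("scar_cell_factor must be 1 or 2")
  if (is.null(grassland)) grassland <- rep(TRUE, nrow * ncol)
  # strip edges on scar-cell boundaries so scars cover whole scar cells
  scar_rows <- ceiling(nrow / scar_cell_factor)
  strip_of_scar_row <- ceiling(seq_len(scar_rows) / (scar_rows / n_parcels))
  strip_of_scar_row <- pmin(strip_of_scar_row, n_parcels)
  row_parcel <- strip_of_scar_row[ceiling(seq_len(nrow) / scar_cell_factor)]
  parcel <- row_parcel[cell_row(seq_len(nrow * ncol), ncol)]
  parcel[!grassland] <- NA_integer_
  tab <- data.frame(parcel_id = seq_len(n_parcels),
                    interval_yr = rep_len(intervals_yr, n_parcels),
                    burn_month_day = rep_len(burn_month_day, n_parcels),
                    grazing = rep_len(grazing, n_parcels),
                    stringsAsFactors = FALSE)
  bad <- setdiff(tab$grazing, c("none", "year_round", "post_burn_window"))
  if (length(bad)) stop("unknown grazing mode: ", paste(bad, collapse = ", "))
  structure(list(parcel = as.integer(parcel), table = tab, nrow = nrow,
                 ncol = ncol, cell_size_m = cell_size_m,
                 scar_cell_factor = as.integer(scar_cell_factor)),
            class = "treatment_map")
}

#' @export
print.treatment_map <- function(x, ...) {
  cat(sprintf("<treatment_map> %d x %d cells, %d parcels, scar factor %d\n",
              x$nrow, x$ncol, nrow(x$table), x$scar_cell_factor))
  print(x$table)
  invisible(x)
}

#' Generate burn scars from the treatment schedule
#'
#' Each parcel burns on its month-day every interval-th year (parcel
#' `p` burns in years where `(year - start_year + p - 1) %% interval == 0`,
#' the per-parcel phase staggering burns across parcels). Scars are emitted
#' as boolean masks at the scar resolution (`scar_cell_factor` x coarser
#' than the simulation grid); a scar cell burns when at least half of its
#' simulation cells belong to a burning parcel, and a burning scar cell
#' ignites all of its nested simulation cells.
#'
#' @param treatments a [treatment_map()].
#' @param years integer vector of calendar years.
#' @param scar_cell_factor scar/sim cell ratio (default from `treatments`).
#' @param seed integer seed (reserved; the default schedule is
#'   deterministic).
#' @return an object of class `burn_scar_set`: list of records with `date`
#'   (`Date`), `mask` (logical matrix at scar resolution), plus geometry
#'   fields.
#' @export
generate_burn_scars <- function(treatments, years,
                                scar_cell_factor = treatments$scar_cell_factor,
                                seed = 1L) {
  stopifnot(inherits(treatments, "treatment_map"))
  if (any(treatments$table$interval_yr < 1)) stop("interval < 1")
  f <- as.integer(scar_cell_factor)
  nr <- treatments$nrow; nc <- treatments$ncol
  snr <- ceiling(nr / f); snc <- ceiling(nc / f)
  # per scar cell, the modal parcel among its sim cells (NA off-grassland)
  id <- seq_len(nr * nc)
  srow <- (cell_row(id, nc) - 1L) %/% f + 1L
  scol <- (cell_col(id, nc) - 1L) %/% f + 1L
  sid <- (srow - 1L) * snc + scol
  scars <- list()
  start_year <- min(years)
  for (yr in sort(years)) {
    for (p in treatments$table$parcel_id) {
      iv <- treatments$table$interval_yr[p]
      if ((yr - start_year + p - 1L) %% iv != 0L) next
      in_parcel <- !is.na(treatments$parcel) & treatments$parcel == p
      # scar cells with >= half their sim cells in the burning parcel
      cnt <- tabulate(sid[in_parcel], nbins = snr * snc)
      tot <- tabulate(sid, nbins = snr * snc)
      burn_scar <- cnt >= pmax(tot, 1) / 2 & cnt > 0
      if (!any(burn_scar)) next
      date <- as.Date(paste0(yr, "-", treatments$table$burn_month_day[p]))
      mask <- matrix(burn_scar, snr, snc, byrow = TRUE)
      scars[[length(scars) + 1L]] <- list(date = date, mask = mask,
                                          parcel_id = p)
    }
  }
  o <- order(vapply(scars, function(s) as.numeric(s$date), 0))
  structure(list(scars = scars[o], scar_cell_factor = f,
                 sim_nrow = nr, sim_ncol = nc, scar_nrow = snr,
                 scar_ncol = snc),
            class = "burn_scar_set")
}

#' @export
print.burn_scar_set <- function(x, ...) {
  cat(sprintf("<burn_scar_set> %d scars, %d x %d scar cells (factor %d)\n",
              length(x$scars), x$scar_nrow, x$scar_ncol, x$scar_cell_factor))
  invisible(x)
}

#' Expand a scar mask to simulation cells
#'
#' A burning scar cell ignites all of its nested simulation cells.
#'
#' @param mask logical matrix at scar resolution.
#' @param scar_set the owning `burn_scar_set` (for geometry).
#' @return logical vector over simulation cells (row-major).
#' @export
scar_to_sim_cells <- function(mask, scar_set) {
  f <- scar_set$scar_cell_factor
  nr <- scar_set$sim_nrow; nc <- scar_set$sim_ncol
  id <- seq_len(nr * nc)
  srow <- (cell_row(id, nc) - 1L) %/% f + 1L
  scol <- (cell_col(id, nc) - 1L) %/% f + 1L
  mask[cbind(srow, scol)]
}

#' Per-cell fire-return-interval statistics
#'
#' Re-tabulates burn dates per simulation cell from the emitted scars and
#' reports, for each cell burned at least twice, the modal interval between
#' successive burns (in years).
#'
#' @param scar_set a `burn_scar_set`.
#' @return list `burn_count` (integer per cell), `modal_interval_yr`
#'   (numeric per cell, NA where fewer than 2 burns), and
#'   `share_le_3yr` (share of burned-at-least-once cells whose modal
#'   interval is 3 years or less, NA intervals excluded).
#' @export
scar_return_intervals <- function(scar_set) {
  n <- scar_set$sim_nrow * scar_set$sim_ncol
  burn_years <- vector("list", n)
  for (s in scar_set$scars) {
    cells <- which(scar_to_sim_cells(s$mask, scar_set))
    yr <- as.integer(format(s$date, "%Y"))
    for (i in cells) burn_years[[i]] <- c(burn_years[[i]], yr)
  }
  burn_count <- vapply(burn_years, length, 0L)
  modal <- rep(NA_real_, n)
  for (i in which(burn_count >= 2L)) {
    iv <- diff(sort(unique(burn_years[[i]])))
    if (length(iv)) {
      tb <- table(iv)
      modal[i] <- as.numeric(names(tb)[which.max(tb)])
    }
  }
  burned <- burn_count > 0L
  share <- if (any(!is.na(modal[burned])))
    mean(modal[burned] <= 3, na.rm = TRUE) else NA_real_
  list(burn_count = burn_count, modal_interval_yr = modal,
       share_le_3yr = share)
}
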