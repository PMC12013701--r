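#' Resolve flats and pits so every cell drains
#'
#' Priority-flood from the designated outlet: cells are visited in order of
#' increasing resolved elevation and any cell not strictly above its already
#' resolved downslope neighbor is raised to that neighbor's resolved
#' elevation plus a small epsilon (default 1e-5 m per step). Only flat or pit
#' cells change; strictly draining terrain is returned unchanged. Cells that
#' cannot reach the outlet through the 8-neighbor graph (e.g., basins fenced
#' off by nodata) trigger an error naming the first such cell.
#'
#' @param dem an [eco_grid] of elevations.
#' @param outlet row-major cell id of the outlet (defaults to the grid's
#'   `outlet` attribute, else the lowest boundary cell).
#' @param epsilon monotone increment in metres (default 1e-5).
#' @return an [eco_grid] with the same geometry, `outlet` attribute set.
#' @export
resolve_flats <- function(dem, outlet = NULL, epsilon = 1e-5) {
  stopifnot(inherits(dem, "eco_grid"))
  nr <- nrow(dem$values); nc <- ncol(dem$values); n <- nr * nc
  ev <- mat_to_vec(dem$values)
  if (is.null(outlet)) outlet <- attr(dem, "outlet")
  if (is.null(outlet)) {
    boundary <- which(cell_row(seq_len(n), nc) %in% c(1L, nr) |
                        cell_col(seq_len(n), nc) %in% c(1L, nc))
    boundary <- boundary[!is.na(ev[boundary])]
    outlet <- boundary[which.min(ev[boundary])]
  }
  outlet <- as.integer(outlet)
  if (outlet < 1 || outlet > n || is.na(ev[outlet]))
    stop("outlet must be a valid (non-nodata) cell id")
  nb <- neighbor_ids(nr, nc)
  resolved <- ev
  closed <- is.na(ev)           # nodata never processed
  # frontier min-heap emulated with flat arrays + which.min (grids are small)
  f_cell <- integer(0); f_key <- numeric(0)
  push <- function(cell, key) {
    f_cell[[length(f_cell) + 1L]] <<- cell
    f_key[[length(f_key) + 1L]] <<- key
    closed[cell] <<- TRUE
  }
  push(outlet, ev[outlet])
  while (length(f_cell)) {
    i <- which.min(f_key)
    cell <- f_cell[i]; key <- f_key[i]
    f_cell <- f_cell[-i]; f_key <- f_key[-i]
    resolved[cell] <- key
    for (k in 1:8) {
      nbk <- nb[cell, k]
      if (is.na(nbk) || closed[nbk]) next
      newkey <- if (ev[nbk] > key) ev[nbk] else key + epsilon
      push(nbk, newkey)
    }
  }
  unreached <- which(!closed)
  if (length(unreached)) {
    rc <- c(cell_row(unreached[1], nc), cell_col(unreached[1], nc))
    stop(sprintf("undrainable basin: cell %d (row %d, col %d) cannot reach the outlet",
                 unreached[1], rc[1], rc[2]))
  }
  out <- eco_grid(vec_to_mat(resolved, nr, nc), dem$cell_size_m,
                  dem$xllcorner, dem$yllcorner, dem$nodata_value)
  attr(out, "outlet") <- outlet
  out
}

#' Multi-direction gradient-weighted flow field
#'
#' For every cell, the elevation gradient to each strictly lower 8-neighbor
#' is `drop / distance` (distance = cell size for cardinal neighbors, cell
#' size times sqrt(2) for diagonals); positive gradients are normalized to
#' flow weights summing to 1. The input must be flat-resolved: any non-outlet
#' cell without a lower neighbor is an error. The returned field carries the
#' edge list, a per-cell mean downslope gradient (weight-averaged, used by
#' the lateral-flow closure), a topological order (descending resolved
#' elevation; all flow edges point down it), and flow accumulation / stream
#' mask at a configurable contributing-area threshold.
#'
#' @param dem flat-resolved [eco_grid] (with `outlet` attribute or explicit
#'   `outlet`).
#' @param outlet row-major outlet cell id.
#' @param stream_threshold_cells contributing area (in cells) at and above
#'   which a cell is part of the stream network (default 50).
#' @return an object of class `flow_field`.
#' @export
compute_flow_weights <- function(dem, outlet = NULL, stream_threshold_cells = 50) {
  stopifnot(inherits(dem, "eco_grid"))
  nr <- nrow(dem$values); nc <- ncol(dem$values); n <- nr * nc
  ev <- mat_to_vec(dem$values)
  if (is.null(outlet)) outlet <- attr(dem, "outlet")
  if (is.null(outlet)) stop("outlet must be supplied")
  outlet <- as.integer(outlet)
  nb <- neighbor_ids(nr, nc)
  dist <- dem$cell_size_m * NEIGHBOR_DIST
  from <- integer(0); to <- integer(0); grad <- numeric(0)
  for (k in 1:8) {
    nbk <- nb[, k]
    nbk2 <- ifelse(is.na(nbk), 1L, nbk)
    ok <- !is.na(nbk) & !is.na(ev) & !is.na(ev[nbk2]) & (ev - ev[nbk2] > 0)
    ok[is.na(ok)] <- FALSE
    idx <- which(ok)
    if (length(idx)) {
      from <- c(from, idx)
      to <- c(to, nbk[idx])
      grad <- c(grad, (ev[idx] - ev[nbk[idx]]) / dist[k])
    }
  }
  live <- which(!is.na(ev))
  has_out <- live %in% from
  bad <- live[!has_out & live != outlet]
  if (length(bad))
    stop(sprintf("input is not flat-resolved: cell %d has no lower neighbor (and is not the outlet)",
                 bad[1]))
  wsum <- numeric(n)
  agg <- tapply(grad, from, sum)
  wsum[as.integer(names(agg))] <- as.numeric(agg)
  weight <- grad / wsum[from]
  slope <- numeric(n)
  sagg <- tapply(grad * weight, from, sum)
  slope[as.integer(names(sagg))] <- as.numeric(sagg)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; weight <- weight[o]; grad <- grad[o]
  topo <- live[order(ev[live], decreasing = TRUE)]
  ff <- structure(list(
    nrow = nr, ncol = nc, n = n, cell_size_m = dem$cell_size_m,
    from = from, to = to, weight = weight, gradient = grad,
    slope = slope, outlet = outlet, topo_order = topo,
    nodata = is.na(ev)), class = "flow_field")
  acc <- flow_accumulation(ff)
  ff$accumulation <- acc
  ff$stream <- !ff$nodata & (acc >= stream_threshold_cells | seq_len(n) == outlet)
  ff
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d cells, %d edges, outlet %d, %d stream cells\n",
              x$nrow, x$ncol, length(x$from), x$outlet, sum(x$stream)))
  invisible(x)
}

#' Flow accumulation (contributing area in cells)
#'
#' Routes one unit per cell down the weighted flow graph in topological
#' order; the result counts each cell itself plus its weighted upslope area.
#'
#' @param flow a `flow_field`.
#' @return numeric vector of contributing areas (cells), NA for nodata.
#' @export
flow_accumulation <- function(flow) {
  acc <- rep(1, flow$n)
  acc[flow$nodata] <- NA
  # edges grouped by source cell; sources visited high to low
  ptr <- edge_pointers(flow)
  for (cell in flow$topo_order) {
    a <- ptr$ptr[cell]; b <- ptr$ptr[cell + 1L] - 1L
    if (b >= a) {
      idx <- ptr$order[a:b]
      tt <- flow$to[idx]
      acc[tt] <- acc[tt] + acc[cell] * flow$weight[idx]
    }
  }
  acc
}

# CSR-style grouping of edges by their source cell (cached on the flow field
# by the simulator; cheap to recompute for small grids)
edge_pointers <- function(flow) {
  n <- flow$n
  cnt <- tabulate(flow$from, nbins = n)
  ptr <- c(1L, 1L + cumsum(cnt))
  list(ptr = as.integer(ptr), order = order(flow$from), counts = cnt)
}

#' Delineate the watershed of an outlet
#'
#' @param flow a `flow_field`.
#' @param outlet row-major cell id (defaults to the field's outlet).
#' @return logical vector: TRUE for cells whose flow reaches the outlet.
#' @export
delineate_watershed <- function(flow, outlet = flow$outlet) {
  if (outlet < 1 || outlet > flow$n) stop("outlet outside grid")
  reach <- logical(flow$n)
  reach[outlet] <- TRUE
  repeat {
    newly <- flow$from[reach[flow$to] & !reach[flow$from]]
    if (!length(newly)) break
    reach[newly] <- TRUE
  }
  reach
}

#' Classify topographic position
#'
#' Three-class topographic position from relative elevation within a moving
#' window and contributing area: lowland = contributing area at or above the
#' stream threshold or bottom relative-elevation tercile; upland = top
#' tercile with small contributing area; everything else slope. A perfectly
#' flat grid is all lowland by convention. The classification is invariant to
#' adding a constant to all elevations.
#'
#' @param dem flat-resolved [eco_grid].
#' @param flow matching `flow_field`.
#' @param window odd moving-window width in cells (default 9).
#' @param area_threshold_cells contributing area marking valley-bottom cells
#'   (default the flow field's stream threshold behavior, 50 cells).
#' @param flat_tol_m windows with less total relief than this are treated as
#'   flat (lowland by convention; default 0.5 m, comfortably above the
#'   epsilon gradients imposed by flat resolution).
#' @return character vector over cells: "upland", "slope", "lowland" (NA for
#'   nodata).
#' @export
classify_topography <- function(dem, flow, window = 9,
                                area_threshold_cells = 50,
                                flat_tol_m = 0.5) {
  stopifnot(inherits(dem, "eco_grid"), inherits(flow, "flow_field"))
  v <- dem$values
  h <- (window - 1) %/% 2
  mn <- running_extreme(v, h, min)
  mx <- running_extreme(v, h, max)
  rel <- (v - mn) / ifelse(mx > mn, mx - mn, 1)
  # locally flat windows (ridge plateaus, valley flats) fall back to the
  # grid-wide relative elevation; a globally flat grid is lowland by
  # convention
  gmin <- suppressWarnings(min(v, na.rm = TRUE))
  gmax <- suppressWarnings(max(v, na.rm = TRUE))
  flatwin <- mx - mn < flat_tol_m
  if (is.finite(gmax) && gmax - gmin >= flat_tol_m) {
    relg <- (v - gmin) / (gmax - gmin)
    rel[flatwin] <- relg[flatwin]
  } else rel[] <- 0
  relv <- mat_to_vec(rel)
  acc <- flow$accumulation
  cls <- rep(NA_character_, flow$n)
  live <- !flow$nodata
  lowland <- live & (acc >= area_threshold_cells | relv <= 1 / 3)
  upland <- live & !lowland & relv >= 2 / 3
  cls[live] <- "slope"
  cls[lowland] <- "lowland"
  cls[upland] <- "upland"
  cls
}

# separable moving-window min/max with edge clipping
running_extreme <- function(m, h, fun) {
  nr <- nrow(m); nc <- ncol(m)
  h_r <- min(h, nr - 1L); h_c <- min(h, nc - 1L)
  tmp <- m
  for (d in seq_len(h_r)) {
    up <- rbind(m[-seq_len(d), , drop = FALSE],
                matrix(m[nr, ], d, nc, byrow = TRUE))
    dn <- rbind(matrix(m[1, ], d, nc, byrow = TRUE),
                m[seq_len(nr - d), , drop = FALSE])
    tmp <- if (identical(fun, min)) pmin(tmp, up, dn) else pmax(tmp, up, dn)
  }
  out <- tmp
  for (d in seq_len(h_c)) {
    lf <- cbind(tmp[, -seq_len(d), drop = FALSE],
                matrix(tmp[, nc], nr, d))
    rt <- cbind(matrix(tmp[, 1], nr, d),
                tmp[, seq_len(nc - d), drop = FALSE])
    out <- if (identical(fun, min)) pmin(out, lf, rt) else pmax(out, lf, rt)
  }
  out
}

#' Serialize a flow field to a CSV edge list
#'
#' @param flow a `flow_field`.
#' @param path destination CSV (`from_cell,to_cell,weight`, 1-based row-major
#'   ids).
#' @return `path`, invisibly.
#' @export
write_flow_edges_csv <- function(flow, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  write.csv(data.frame(from_cell = flow$from, to_cell = flow$to,
                       weight = flow$weight),
            tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
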