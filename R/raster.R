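#' Rectangular grid raster
#'
#' Lightweight container for the model's rasters: a numeric matrix with row 1
#' at the north edge, a cell size in metres, a lower-left corner, and a nodata
#' value. Elevation grids, categorical maps (parcels, land cover, topographic
#' position) and output maps (ANPP, fuel load, WFPS) all use this container.
#'
#' @param values numeric matrix (`NA` marks nodata cells).
#' @param cell_size_m cell edge length in metres (> 0).
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param nodata_value value used to encode `NA` on disk.
#' @return an object of class `eco_grid`.
#' @export
eco_grid <- function(values, cell_size_m, xllcorner = 0, yllcorner = 0,
                     nodata_value = -9999) {
  stopifnot(is.matrix(values), is.numeric(cell_size_m), cell_size_m > 0)
  structure(list(values = values, cell_size_m = as.numeric(cell_size_m),
                 xllcorner = as.numeric(xllcorner),
                 yllcorner = as.numeric(yllcorner),
                 nodata_value = as.numeric(nodata_value)),
            class = "eco_grid")
}

#' @export
print.eco_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<eco_grid> %d rows x %d cols, cell %g m, range [%g, %g], %d nodata\n",
              nrow(v), ncol(v), x$cell_size_m,
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.eco_grid <- function(x) dim(x$values)

#' Read an ESRI ASCII grid
#'
#' Parses the six-line `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by row-major (north-up) values. The value count must match
#' the header; nodata values become `NA`.
#'
#' @param path file path.
#' @return an [eco_grid].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("ASCII grid too short: ", path)
  hdr <- list()
  for (i in 1:6) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2) stop("malformed header line ", i, " in ", path)
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (nc <= 0 || nr <= 0 || hdr$cellsize <= 0)
    stop("ASCII grid header has non-positive dimensions or cell size")
  raw <- unlist(strsplit(trimws(lines[-(1:6)]), "\\s+"))
  raw <- raw[nzchar(raw)]
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) stop("unparseable tokens in ", path)
  if (length(vals) != nr * nc)
    stop(sprintf("value count %d does not match header %d x %d in %s",
                 length(vals), nr, nc, path))
  vals[vals == hdr$nodata_value] <- NA_real_
  eco_grid(matrix(vals, nrow = nr, ncol = nc, byrow = TRUE),
           cell_size_m = hdr$cellsize, xllcorner = hdr$xllcorner,
           yllcorner = hdr$yllcorner, nodata_value = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' Writes atomically (temp file in the destination directory, then rename) so
#' no partially written raster is left behind on error.
#'
#' @param grid an [eco_grid].
#' @param path destination path.
#' @param digits significant digits for values (default 10, round-trip safe
#'   relative to 1e-10 for typical magnitudes).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "eco_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata_value
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".asc.tmp")
  con <- file(tmp, "w")
  ok <- FALSE
  tryCatch({
    writeLines(c(
      paste("ncols", ncol(v)), paste("nrows", nrow(v)),
      paste("xllcorner", format(grid$xllcorner, digits = 15)),
      paste("yllcorner", format(grid$yllcorner, digits = 15)),
      paste("cellsize", format(grid$cell_size_m, digits = 15)),
      paste("NODATA_value", format(grid$nodata_value, digits = 15))), con)
    for (r in seq_len(nrow(v)))
      writeLines(paste(format(v[r, ], digits = digits, trim = TRUE,
                              scientific = FALSE), collapse = " "), con)
    ok <- TRUE
  }, finally = {
    close(con)
    if (ok) file.rename(tmp, path) else unlink(tmp)
  })
  invisible(path)
}

# shared-geometry check used by modules that combine rasters
same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$cell_size_m - b$cell_size_m) < tol &&
    abs(a$xllcorner - b$xllcorner) < tol &&
    abs(a$yllcorner - b$yllcorner) < tol
}

#' Block-mean aggregation of a raster
#'
#' Coarsens a grid by an integer factor, each coarse cell taking the mean of
#' its `factor x factor` fine cells (NA-aware). Used by the resolution
#' comparison harness.
#'
#' @param grid an [eco_grid].
#' @param factor integer aggregation factor; must divide both dimensions.
#' @param fun summary function applied per block (default `mean`).
#' @return an [eco_grid] with `factor`-times larger cells.
#' @export
aggregate_grid <- function(grid, factor, fun = mean) {
  stopifnot(inherits(grid, "eco_grid"))
  factor <- as.integer(factor)
  v <- grid$values
  if (factor < 1L || nrow(v) %% factor != 0L || ncol(v) %% factor != 0L)
    stop("aggregation factor must divide both grid dimensions")
  nr <- nrow(v) %/% factor; nc <- ncol(v) %/% factor
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- v[((i - 1L) * factor + 1L):(i * factor),
             ((j - 1L) * factor + 1L):(j * factor)]
    if (!all(is.na(blk))) out[i, j] <- fun(blk[!is.na(blk)])
  }
  eco_grid(out, cell_size_m = grid$cell_size_m * factor,
           xllcorner = grid$xllcorner, yllcorner = grid$yllcorner,
           nodata_value = grid$nodata_value)
}
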