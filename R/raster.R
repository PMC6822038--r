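#' Bioclimatic raster grids
#'
#' A `climate_raster` is a plain in-memory container for one bioclimatic
#' variable on a regular geographic (longitude/latitude, WGS84) grid:
#' a numeric matrix whose first row is the northernmost row, an extent
#' `c(lon_min, lat_min, lon_max, lat_max)` in decimal degrees, a square
#' cell size in degrees, and `NA` for nodata cells. Nodata cells are never
#' used in any downstream statistic.
#'
#' Values keep the units of the source grid (typically degrees Celsius for
#' temperature and millimetres for precipitation). No unit rescaling is
#' applied; WorldClim-version conventions (e.g. temperatures stored as
#' degrees x 10) are the caller's responsibility.
#'
#' @param values numeric matrix, row 1 = northernmost row; `NA` = nodata.
#' @param extent numeric length-4: `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param resolution cell size in degrees (cells are square).
#' @param variable_id variable label, e.g. `"BIO5"`.
#' @return An object of class `climate_raster`.
#' @export
climate_raster <- function(values, extent, resolution, variable_id = NA_character_) {
  values <- as.matrix(values)
  extent <- as.numeric(extent)
  if (length(extent) != 4L) stop("extent must be c(lon_min, lat_min, lon_max, lat_max)")
  ncols <- (extent[3] - extent[1]) / resolution
  nrows <- (extent[4] - extent[2]) / resolution
  if (abs(ncols - ncol(values)) > 1e-6 || abs(nrows - nrow(values)) > 1e-6) {
    stop(sprintf(
      "grid dimensions (%d x %d) inconsistent with extent/resolution (%.6g x %.6g cells)",
      nrow(values), ncol(values), nrows, ncols
    ))
  }
  structure(
    list(values = values, extent = extent, resolution = resolution,
         variable_id = variable_id),
    class = "climate_raster"
  )
}

#' @export
print.climate_raster <- function(x, ...) {
  cat(sprintf(
    "climate_raster %s: %d x %d cells at %.6g deg, extent [%g, %g] x [%g, %g], %d nodata\n",
    x$variable_id, nrow(x$values), ncol(x$values), x$resolution,
    x$extent[1], x$extent[3], x$extent[2], x$extent[4], sum(is.na(x$values))
  ))
  invisible(x)
}

# Cell-centre coordinate vectors. Longitudes increase with column index,
# latitudes DECREASE with row index (row 1 = north).
raster_lon_centers <- function(r) {
  r$extent[1] + (seq_len(ncol(r$values)) - 0.5) * r$resolution
}
raster_lat_centers <- function(r) {
  r$extent[4] - (seq_len(nrow(r$values)) - 0.5) * r$resolution
}

# Half-open cell lookup [x, x + res): a point exactly on an interior edge
# belongs to the higher-index cell. Returns a matrix of (row, col) indices,
# NA where the point falls outside the extent.
raster_cell_of <- function(r, lon, lat) {
  col <- floor((lon - r$extent[1]) / r$resolution) + 1L
  j <- floor((lat - r$extent[2]) / r$resolution) + 1L # index from south
  row <- nrow(r$values) - j + 1L
  bad <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Read a single-band climate raster
#'
#' Reads an ESRI ASCII grid (`.asc`/`.txt`; `ncols`/`nrows`/`xllcorner` or
#' `xllcenter`/`cellsize`/`NODATA_value` header followed by values north row
#' first). GeoTIFF input is not supported by this reader and raises an error
#' asking for conversion; grids must be in geographic lon/lat coordinates
#' (no reprojection is performed).
#'
#' @param path file path.
#' @param variable_id variable label attached to the result (defaults to the
#'   file name without extension).
#' @return A [climate_raster].
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, variable_id = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("GeoTIFF input is not supported by this reader; ",
         "convert to an ESRI ASCII grid (.asc), e.g. `gdal_translate -of AAIGrid`")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("not an ESRI ASCII grid (too short): ", path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed ASCII grid header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header missing: ", paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  res <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) xll <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xll <- hdr$xllcenter - res / 2
  else stop("ASCII grid header missing xllcorner/xllcenter")
  if (!is.null(hdr$yllcorner)) yll <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) yll <- hdr$yllcenter - res / 2
  else stop("ASCII grid header missing yllcorner/yllcenter")
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nrows * ncols) {
    stop(sprintf("ASCII grid has %d values, expected %d", length(vals), nrows * ncols))
  }
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (is.null(variable_id)) {
    variable_id <- sub("\\.[^.]*$", "", basename(path))
  }
  climate_raster(m, c(xll, yll, xll + ncols * res, yll + nrows * res),
                 res, variable_id)
}

#' Write a climate raster as an ESRI ASCII grid
#'
#' @param r a [climate_raster].
#' @param path output file path.
#' @param nodata sentinel written for `NA` cells.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "climate_raster"))
  m <- r$values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", r$extent[1]),
    sprintf("yllcorner %.10g", r$extent[2]),
    sprintf("cellsize %.10g", r$resolution),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(m, 1L, function(v) paste(format(v, trim = TRUE, digits = 15), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Check a list of rasters for a shared grid; returns the first raster.
check_raster_stack <- function(rasters) {
  stopifnot(length(rasters) >= 1L)
  r1 <- rasters[[1L]]
  for (r in rasters) {
    stopifnot(inherits(r, "climate_raster"))
    if (max(abs(r$extent - r1$extent)) > 1e-9 || abs(r$resolution - r1$resolution) > 1e-12) {
      stop("all rasters must share the same extent and resolution")
    }
  }
  r1
}

#' Sample climate rasters at occurrence points
#'
#' Looks up, for every occurrence record, the raster cell containing the
#' point (nearest-cell, no interpolation; half-open cells so a point on an
#' interior edge belongs to the higher-index cell) in each variable.
#' Records outside the raster extent or hitting nodata in any variable are
#' dropped with a logged count.
#'
#' @param rasters list of [climate_raster] objects sharing extent and
#'   resolution; names (or the rasters' `variable_id`s) become the value
#'   columns.
#' @param occ occurrence table (`species`, `lon`, `lat`).
#' @return A data frame with `species`, `lon`, `lat` and one column per
#'   variable; attributes `n_dropped_outside` and `n_dropped_nodata` record
#'   the filtering.
#' @export
extract_at_points <- function(rasters, occ) {
  r1 <- check_raster_stack(rasters)
  nms <- names(rasters)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(rasters, function(r) r$variable_id, character(1))
  }
  idx <- raster_cell_of(r1, occ$lon, occ$lat)
  outside <- is.na(idx[, "row"])
  vals <- matrix(NA_real_, nrow(occ), length(rasters), dimnames = list(NULL, nms))
  ok <- which(!outside)
  if (length(ok)) {
    flat <- (idx[ok, "col"] - 1L) * nrow(r1$values) + idx[ok, "row"]
    for (k in seq_along(rasters)) {
      vals[ok, k] <- rasters[[k]]$values[flat]
    }
  }
  hit_nodata <- !outside & apply(vals, 1L, anyNA)
  keep <- !outside & !hit_nodata
  if (any(outside)) pn_log("extract: dropped %d record(s) outside raster extent", sum(outside))
  if (any(hit_nodata)) pn_log("extract: dropped %d record(s) hitting nodata", sum(hit_nodata))
  out <- cbind(occ[keep, c("species", "lon", "lat"), drop = FALSE],
               as.data.frame(vals[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "n_dropped_outside") <- sum(outside)
  attr(out, "n_dropped_nodata") <- sum(hit_nodata)
  out
}

# All valid cell centres (valid in every raster) with their values,
# optionally restricted to a rectangle c(lon_min, lat_min, lon_max, lat_max)
# (cell-centre inclusion). Used for backgrounds and suitability sampling.
raster_cell_table <- function(rasters, rect = NULL) {
  r1 <- check_raster_stack(rasters)
  nms <- names(rasters)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(rasters, function(r) r$variable_id, character(1))
  }
  lon <- raster_lon_centers(r1)
  lat <- raster_lat_centers(r1)
  lon_g <- rep(lon, each = nrow(r1$values))
  lat_g <- rep(lat, times = ncol(r1$values))
  vals <- vapply(rasters, function(r) as.numeric(r$values), numeric(length(lon_g)))
  colnames(vals) <- nms
  keep <- !apply(vals, 1L, anyNA)
  if (!is.null(rect)) {
    keep <- keep & lon_g >= rect[1] & lon_g <= rect[3] &
      lat_g >= rect[2] & lat_g <= rect[4]
  }
  data.frame(lon = lon_g[keep], lat = lat_g[keep],
             vals[keep, , drop = FALSE], check.names = FALSE)
}
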