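#' Regular latitude-longitude grid specification
#'
#' Defines a regular geographic grid by its bounds and angular resolution.
#' Cells are half-open intervals `[lat, lat + res) x [lon, lon + res)` and all
#' cell coordinates refer to cell centers. Row 1 is the northernmost row
#' (matching the on-disk layout of most gridded products); column 1 is the
#' westernmost column.
#'
#' @param lat_min,lat_max Latitude bounds in decimal degrees, within
#'   \[-90, 90\], `lat_min < lat_max`.
#' @param lon_min,lon_max Longitude bounds in decimal degrees, within
#'   \[-180, 180\].
#' @param resolution_arcsec Angular cell size in arc-seconds (1/3600 degree).
#'   The default 30 arc-seconds is roughly 1 km at the equator.
#' @return An object of class `grid_spec` with fields `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max`, `resolution_arcsec`, `nrow`, `ncol`.
#' @examples
#' g <- grid_spec(-25, 25, -180, 180, resolution_arcsec = 3600)
#' g$nrow # 50 rows of 1 degree
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max,
                      resolution_arcsec = 30) {
  stopifnot(is.numeric(lat_min), is.numeric(lat_max),
            is.numeric(lon_min), is.numeric(lon_max),
            is.numeric(resolution_arcsec), resolution_arcsec > 0)
  if (lat_min < -90 || lat_max > 90) {
    stop("latitude bounds must lie within [-90, 90]")
  }
  if (lon_min < -180 || lon_max > 180) {
    stop("longitude bounds must lie within [-180, 180]")
  }
  if (lat_min >= lat_max) stop("lat_min must be strictly less than lat_max")
  if (lon_min >= lon_max) stop("lon_min must be strictly less than lon_max")
  res_deg <- resolution_arcsec / 3600
  nr <- (lat_max - lat_min) / res_deg
  nc <- (lon_max - lon_min) / res_deg
  if (abs(nr - round(nr)) > 1e-9 * max(1, abs(nr)) ||
      abs(nc - round(nc)) > 1e-9 * max(1, abs(nc))) {
    stop("grid span is not an integral number of cells at this resolution")
  }
  structure(
    list(lat_min = lat_min, lat_max = lat_max,
         lon_min = lon_min, lon_max = lon_max,
         resolution_arcsec = resolution_arcsec,
         nrow = as.integer(round(nr)), ncol = as.integer(round(nc))),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g arcsec, lat [%g, %g], lon [%g, %g]\n",
              x$nrow, x$ncol, x$resolution_arcsec,
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

grid_res_deg <- function(grid) grid$resolution_arcsec / 3600

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return `lat_centers()`: latitudes of the row centers, row 1 (northernmost)
#'   first. `lon_centers()`: longitudes of the column centers, west first.
#' @export
lat_centers <- function(grid) {
  res <- grid_res_deg(grid)
  grid$lat_max - (seq_len(grid$nrow) - 0.5) * res
}

#' @rdname lat_centers
#' @export
lon_centers <- function(grid) {
  res <- grid_res_deg(grid)
  grid$lon_min + (seq_len(grid$ncol) - 0.5) * res
}

grid_equal <- function(a, b, tol = 1e-9) {
  abs(a$lat_min - b$lat_min) < tol && abs(a$lat_max - b$lat_max) < tol &&
    abs(a$lon_min - b$lon_min) < tol && abs(a$lon_max - b$lon_max) < tol &&
    abs(a$resolution_arcsec - b$resolution_arcsec) < tol
}

#' Gridded field with missing-data mask
#'
#' The universal carrier for every gridded quantity in the pipeline:
#' temperature change, forest cover, elevation, population, administrative
#' IDs. Values are stored as a numeric matrix with `NA` marking masked
#' (missing) cells; row 1 is the northernmost row.
#'
#' @param values Numeric matrix of dimension `grid$nrow x grid$ncol`; `NA`
#'   entries are masked.
#' @param grid A [grid_spec()].
#' @return An object of class `dh_raster` with fields `values` and `grid`.
#' @export
dh_raster <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.logical(values)) values <- values + 0
  if (!is.matrix(values)) {
    values <- matrix(as.numeric(values), grid$nrow, grid$ncol)
  }
  if (nrow(values) != grid$nrow || ncol(values) != grid$ncol) {
    stop(sprintf("values are %d x %d but grid declares %d x %d",
                 nrow(values), ncol(values), grid$nrow, grid$ncol))
  }
  structure(list(values = values, grid = grid), class = "dh_raster")
}

#' @export
print.dh_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<dh_raster> %d x %d, %d masked, range [%s, %s]\n",
              nrow(v), ncol(v), sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

#' @rdname dh_raster
#' @param x A `dh_raster`.
#' @return `raster_values()`: the value matrix; `raster_mask()`: a logical
#'   matrix, `TRUE` where the cell is masked.
#' @export
raster_values <- function(x) {
  stopifnot(inherits(x, "dh_raster"))
  x$values
}

#' @rdname dh_raster
#' @export
raster_mask <- function(x) {
  stopifnot(inherits(x, "dh_raster"))
  is.na(x$values)
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!grid_equal(a$grid, b$grid)) {
    stop(sprintf("%s are on different grids", what))
  }
  invisible(TRUE)
}

#' Latitude-dependent relative cell areas
#'
#' On a regular geographic grid the surface area of a cell is proportional to
#' the cosine of its center latitude and is constant along a row. Weights are
#' normalized so that their mean over the grid is 1.
#'
#' @param grid A [grid_spec()].
#' @return An object of class `area_weights`: list with `grid` and `weight`
#'   (matrix, constant along rows).
#' @export
cell_area_weights <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lat <- lat_centers(grid)
  if (grid$lat_max >= 90 || grid$lat_min <= -90) {
    stop("grid touches a pole; cos(latitude) area weighting is not supported there")
  }
  w <- cos(lat * pi / 180)
  w <- w / mean(w)
  structure(
    list(grid = grid,
         weight = matrix(rep(w, grid$ncol), grid$nrow, grid$ncol)),
    class = "area_weights"
  )
}
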