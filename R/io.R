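#' Read and write rasters as ESRI ASCII grids
#'
#' Rasters are serialized in the plain-text ESRI ASCII grid format (`.asc`):
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, northernmost row first. Values
#' are written with 17 significant digits so that a write/read round trip
#' reproduces IEEE doubles bit-exactly; masked cells map to the file's nodata
#' value and back.
#'
#' @param path File path.
#' @param variable Optional variable name. ASCII grids are single-band, so
#'   any value other than `NULL` raises a descriptive error; the argument
#'   exists so callers can fail loudly rather than silently read the wrong
#'   layer.
#' @return `read_raster()` returns a [dh_raster()].
#' @export
read_raster <- function(path, variable = NULL) {
  if (!file.exists(path)) stop(sprintf("raster file does not exist: %s", path))
  if (!is.null(variable)) {
    stop(sprintf("ASCII grids are single-band; unknown variable '%s'", variable))
  }
  lines <- readLines(path, n = 6L, warn = FALSE)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop(sprintf("malformed ASCII grid header line: '%s'", ln))
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need]))) {
    stop("ASCII grid header is missing or non-numeric; not a regular lat/lon grid file")
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  res_deg <- hdr$cellsize
  grid <- grid_spec(lat_min = hdr$yllcorner,
                    lat_max = hdr$yllcorner + nr * res_deg,
                    lon_min = hdr$xllcorner,
                    lon_max = hdr$xllcorner + nc * res_deg,
                    resolution_arcsec = res_deg * 3600)
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  dh_raster(m, grid)
}

#' @rdname read_raster
#' @param raster A [dh_raster()] to serialize.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "dh_raster"))
  g <- raster$grid
  v <- raster$values
  nodata <- -9999
  if (any(v == nodata, na.rm = TRUE)) nodata <- -3.4028234663852886e+38
  hdr <- c(
    sprintf("ncols %d", g$ncol),
    sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.17g", g$lon_min),
    sprintf("yllcorner %.17g", g$lat_min),
    sprintf("cellsize %.17g", grid_res_deg(g)),
    sprintf("NODATA_value %.17g", nodata)
  )
  out <- v
  out[is.na(out)] <- nodata
  body <- apply(out, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
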