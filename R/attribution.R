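#' Matching and smoothing parameters
#'
#' Tunable parameters of the moving-window counterfactual matching. Defaults
#' are the production values: controls searched within a 0.25 degree radius
#' (about 27 km), extended to 0.50 degrees when empty, elevation matched to
#' within +/-50 m; the per-point warming field is smoothed over a 0.10 degree
#' rolling circle using only pixels with at least 5 percentage points of loss
#' and discarding members more than 3 standard deviations from the window
#' mean.
#'
#' @param primary_radius,fallback_radius Search radii in degrees;
#'   `0 < primary_radius < fallback_radius`.
#' @param elevation_band Half-width of the elevation match in meters.
#' @param smooth_radius Rolling-circle smoothing radius in degrees.
#' @param min_loss_for_smoothing Minimum percentage-point loss for a pixel to
#'   enter a smoothing window.
#' @param z_threshold Strict z-score limit for the one-pass outlier screen
#'   (population standard deviation).
#' @param distance `"greatcircle"` (default): great-circle central angle in
#'   degrees; `"degree"`: plain Euclidean distance in degree space.
#' @param include_center Whether the central pixel may appear in its own
#'   smoothing window when it meets the loss rule (default `TRUE`).
#' @return An object of class `match_params`.
#' @export
match_params <- function(primary_radius = 0.25, fallback_radius = 0.50,
                         elevation_band = 50, smooth_radius = 0.10,
                         min_loss_for_smoothing = 5, z_threshold = 3,
                         distance = c("greatcircle", "degree"),
                         include_center = TRUE) {
  distance <- match.arg(distance)
  stopifnot(primary_radius > 0, fallback_radius > 0, elevation_band > 0,
            smooth_radius > 0, min_loss_for_smoothing > 0, z_threshold > 0)
  if (primary_radius >= fallback_radius) {
    stop("primary_radius must be strictly smaller than fallback_radius")
  }
  structure(list(primary_radius = primary_radius,
                 fallback_radius = fallback_radius,
                 elevation_band = elevation_band,
                 smooth_radius = smooth_radius,
                 min_loss_for_smoothing = min_loss_for_smoothing,
                 z_threshold = z_threshold,
                 distance = distance,
                 include_center = include_center),
            class = "match_params")
}

# Rectangular index window guaranteed to contain the circle of `radius`
# degrees around (row, col), plus the distance (same units as radius) from
# the center to every window cell. Distances are great-circle central angles
# in degrees by default.
search_window <- function(grid, row, col, radius, distance = "greatcircle") {
  res <- grid_res_deg(grid)
  latc <- lat_centers(grid)
  lonc <- lon_centers(grid)
  lat0 <- latc[row]; lon0 <- lonc[col]
  dr <- ceiling(radius / res) + 1L
  rows <- max(1L, row - dr):min(grid$nrow, row + dr)
  if (distance == "greatcircle") {
    cosmin <- min(cos(latc[rows] * pi / 180))
    dc <- ceiling(radius / (res * max(cosmin, 1e-6))) + 1L
  } else {
    dc <- dr
  }
  cols <- max(1L, col - dc):min(grid$ncol, col + dc)
  if (distance == "greatcircle") {
    phi0 <- lat0 * pi / 180
    phi <- latc[rows] * pi / 180
    dlam <- (lonc[cols] - lon0) * pi / 180
    a <- outer(sin((phi - phi0) / 2)^2, rep(1, length(cols))) +
      outer(cos(phi0) * cos(phi), sin(dlam / 2)^2)
    a <- pmin(pmax(a, 0), 1)
    dist <- 2 * asin(sqrt(a)) * 180 / pi
  } else {
    dist <- sqrt(outer((latc[rows] - lat0)^2, rep(1, length(cols))) +
                   outer(rep(1, length(rows)), (lonc[cols] - lon0)^2))
  }
  list(rows = rows, cols = cols, dist = dist)
}

#' Select control pixels for one deforested pixel
#'
#' Controls are non-deforested pixels with valid temperature change, within
#' the primary search radius of the center and within the elevation band of
#' the center's elevation. If none exist, the search is retried at the
#' fallback radius (same elevation constraint); if still empty, the pixel is
#' reported unmatched (`radius_used = "none"`).
#'
#' @param row,col Center cell indices (row 1 = north).
#' @param classes [dh_raster()] of [pixel_classes()] codes; the center must
#'   be classified `deforested`.
#' @param elevation [dh_raster()] of elevation in meters.
#' @param dt [dh_raster()] of temperature change.
#' @param params A [match_params()].
#' @return List with `rows`, `cols` (parallel integer vectors of control
#'   indices, empty when unmatched), `radius_used` (`"primary"`,
#'   `"fallback"` or `"none"`) and `n_controls`.
#' @export
find_controls <- function(row, col, classes, elevation, dt, params = match_params()) {
  stop_if_grid_mismatch(classes, dt, "class and dt rasters")
  stop_if_grid_mismatch(classes, elevation, "class and elevation rasters")
  cls <- pixel_classes()
  if (is.na(classes$values[row, col]) ||
      classes$values[row, col] != cls[["deforested"]]) {
    stop("center pixel is not classified as deforested")
  }
  e0 <- elevation$values[row, col]
  if (is.na(e0) || is.na(dt$values[row, col])) {
    stop("center pixel must have valid temperature change and elevation")
  }
  for (radius in c(params$primary_radius, params$fallback_radius)) {
    win <- search_window(classes$grid, row, col, radius, params$distance)
    cl <- classes$values[win$rows, win$cols, drop = FALSE]
    dtv <- dt$values[win$rows, win$cols, drop = FALSE]
    el <- elevation$values[win$rows, win$cols, drop = FALSE]
    ok <- !is.na(cl) & cl == cls[["non_deforested"]] &
      !is.na(dtv) & !is.na(el) &
      abs(el - e0) <= params$elevation_band &
      win$dist <= radius
    if (any(ok)) {
      idx <- which(ok)  # column-major within the window
      nr <- length(win$rows)
      return(list(rows = win$rows[(idx - 1L) %% nr + 1L],
                  cols = win$cols[(idx - 1L) %/% nr + 1L],
                  radius_used = if (radius == params$primary_radius)
                    "primary" else "fallback",
                  n_controls = length(idx)))
    }
  }
  list(rows = integer(0), cols = integer(0), radius_used = "none",
       n_controls = 0L)
}

#' Raw deforestation-induced temperature change
#'
#' For every deforested pixel with valid temperature change and elevation,
#' subtracts the mean temperature change of its matched control pixels from
#' the pixel's own change. Pixels without controls at either radius are
#' retained but masked. The subtraction removes the shared background signal
#' (global and regional climate change) under the assumption that the
#' background climate is uniform over the search radius.
#'
#' @inheritParams find_controls
#' @return An `attribution_result` with the raw stage populated:
#'   `dt_defor_raw` ([dh_raster()]) and `provenance` (list of matrices
#'   `radius_used` coded 0 = none / 1 = primary / 2 = fallback with `NA` off
#'   the treated set, `n_controls`, plus placeholders for the smoothing
#'   stage).
#' @export
raw_attribution <- function(dt, classes, elevation, params = match_params()) {
  stop_if_grid_mismatch(classes, dt, "class and dt rasters")
  stop_if_grid_mismatch(classes, elevation, "class and elevation rasters")
  cls <- pixel_classes()
  cv <- classes$values
  raw <- matrix(NA_real_, nrow(cv), ncol(cv))
  radius_used <- matrix(NA_integer_, nrow(cv), ncol(cv))
  n_controls <- matrix(NA_integer_, nrow(cv), ncol(cv))
  defor <- which(!is.na(cv) & cv == cls[["deforested"]])
  for (k in defor) {
    r <- (k - 1L) %% nrow(cv) + 1L
    c <- (k - 1L) %/% nrow(cv) + 1L
    radius_used[r, c] <- 0L
    n_controls[r, c] <- 0L
    if (is.na(dt$values[r, c]) || is.na(elevation$values[r, c])) next
    ctl <- find_controls(r, c, classes, elevation, dt, params)
    n_controls[r, c] <- ctl$n_controls
    if (ctl$radius_used == "none") next
    radius_used[r, c] <- if (ctl$radius_used == "primary") 1L else 2L
    vals <- dt$values[cbind(ctl$rows, ctl$cols)]
    raw[r, c] <- dt$values[r, c] - sum(vals) / length(vals)
  }
  structure(list(
    dt_defor_raw = dh_raster(raw, dt$grid),
    dt_per_point = NULL,
    dt_per_point_smoothed = NULL,
    dt_defor = NULL,
    provenance = list(radius_used = radius_used,
                      n_controls = n_controls,
                      regional_fallback = NULL,
                      n_smooth_neighbors = NULL)
  ), class = "attribution_result")
}

#' Warming per percentage point of forest loss
#'
#' Divides the raw attributed warming by the positive percentage-point loss.
#' Classification guarantees strictly positive loss wherever a raw value
#' exists; this is asserted, not silently patched.
#'
#' @param raw [dh_raster()] of raw attributed warming (degrees C).
#' @param change [dh_raster()] from [cover_change()] (negative = loss).
#' @return A [dh_raster()] in degrees C per percentage point.
#' @export
normalize_per_point <- function(raw, change) {
  stop_if_grid_mismatch(raw, change, "raw and change rasters")
  loss <- -change$values
  have <- !is.na(raw$values)
  if (any(have & (is.na(loss) | loss <= 0))) {
    stop("internal error: attributed pixel with non-positive forest loss")
  }
  out <- raw$values / loss
  out[!have] <- NA_real_
  dh_raster(out, raw$grid)
}

#' Regional mean warming per point of loss
#'
#' Fallback value for pixels whose smoothing window is empty: the
#' area-weighted mean of the per-point field over deforested pixels with at
#' least `min_loss` percentage points of loss, per macro-region.
#'
#' @param per_point [dh_raster()] from [normalize_per_point()].
#' @param change [dh_raster()] from [cover_change()].
#' @param regions [dh_raster()] of integer region codes.
#' @param min_loss Qualifying loss threshold (percentage points, default 5).
#' @return Named numeric vector, one entry per region code.
#' @export
regional_mean_per_point <- function(per_point, change, regions, min_loss = 5) {
  stop_if_grid_mismatch(per_point, change, "per-point and change rasters")
  stop_if_grid_mismatch(per_point, regions, "per-point and region rasters")
  w <- cell_area_weights(per_point$grid)$weight
  loss <- -change$values
  qual <- !is.na(per_point$values) & !is.na(loss) & loss >= min_loss
  ids <- sort(unique(regions$values[!is.na(regions$values)]))
  out <- vapply(ids, function(id) {
    sel <- qual & !is.na(regions$values) & regions$values == id
    if (!any(sel)) {
      stop(sprintf("region %s has no qualifying deforested pixels for the regional mean", id))
    }
    sum(w[sel] * per_point$values[sel]) / sum(w[sel])
  }, numeric(1))
  names(out) <- as.character(ids)
  out
}

# Permissive variant used inside attribute_warming(): regions with no
# qualifying pixel get NA and only fail if a pixel actually needs them.
regional_mean_per_point_safe <- function(per_point, change, regions, min_loss = 5) {
  w <- cell_area_weights(per_point$grid)$weight
  loss <- -change$values
  qual <- !is.na(per_point$values) & !is.na(loss) & loss >= min_loss
  ids <- sort(unique(regions$values[!is.na(regions$values)]))
  out <- vapply(ids, function(id) {
    sel <- qual & !is.na(regions$values) & regions$values == id
    if (!any(sel)) return(NA_real_)
    sum(w[sel] * per_point$values[sel]) / sum(w[sel])
  }, numeric(1))
  names(out) <- as.character(ids)
  out
}

#' Rolling-circle smoothing of the per-point warming field
#'
#' For each deforested pixel with a valid per-point value, collects the
#' deforested pixels within `smooth_radius` whose loss is at least
#' `min_loss_for_smoothing` points and whose per-point value is valid
#' (the center itself included when it qualifies, unless
#' `include_center = FALSE`), computes the window mean and population
#' standard deviation, drops members with `|v - mean|/sd` strictly greater
#' than `z_threshold` (one pass, no re-screening), and returns the mean of
#' the survivors. When the qualifying window is empty the regional mean is
#' substituted and flagged.
#'
#' @inheritParams regional_mean_per_point
#' @param classes [dh_raster()] of [pixel_classes()] codes.
#' @param params A [match_params()].
#' @param regional_mean Scalar, or named vector keyed by region code (then
#'   `regions` is required), or `NULL` (failure if any pixel needs it).
#' @param regions Optional [dh_raster()] of region codes.
#' @return List: `smoothed` ([dh_raster()]), `regional_fallback` (logical
#'   matrix), `n_smooth_neighbors` (integer matrix of surviving window
#'   members).
#' @export
smooth_per_point <- function(per_point, change, classes,
                             params = match_params(),
                             regional_mean = NULL, regions = NULL) {
  stop_if_grid_mismatch(per_point, change, "per-point and change rasters")
  stop_if_grid_mismatch(per_point, classes, "per-point and class rasters")
  cls <- pixel_classes()
  cv <- classes$values
  pp <- per_point$values
  loss <- -change$values
  out <- matrix(NA_real_, nrow(cv), ncol(cv))
  fallback <- matrix(FALSE, nrow(cv), ncol(cv))
  nneigh <- matrix(NA_integer_, nrow(cv), ncol(cv))
  qual_cell <- !is.na(cv) & cv == cls[["deforested"]] &
    !is.na(pp) & !is.na(loss) & loss >= params$min_loss_for_smoothing
  targets <- which(!is.na(cv) & cv == cls[["deforested"]] & !is.na(pp))
  for (k in targets) {
    r <- (k - 1L) %% nrow(cv) + 1L
    c <- (k - 1L) %/% nrow(cv) + 1L
    win <- search_window(per_point$grid, r, c, params$smooth_radius,
                         params$distance)
    q <- qual_cell[win$rows, win$cols, drop = FALSE] & win$dist <= params$smooth_radius
    if (!params$include_center) {
      q[match(r, win$rows), match(c, win$cols)] <- FALSE
    }
    if (!any(q)) {
      rv <- lookup_regional_mean(regional_mean, regions, r, c)
      out[r, c] <- rv
      fallback[r, c] <- TRUE
      nneigh[r, c] <- 0L
      next
    }
    v <- pp[win$rows, win$cols, drop = FALSE][q]  # column-major window order
    n <- length(v)
    m <- sum(v) / n
    s <- sqrt(sum((v - m)^2) / n)
    keep <- if (s > 0) abs(v - m) / s <= params$z_threshold else rep(TRUE, n)
    if (!any(keep)) keep <- rep(TRUE, n)  # degenerate; cannot happen for n <= 9
    vk <- v[keep]
    out[r, c] <- sum(vk) / length(vk)
    nneigh[r, c] <- length(vk)
  }
  list(smoothed = dh_raster(out, per_point$grid),
       regional_fallback = fallback,
       n_smooth_neighbors = nneigh)
}

lookup_regional_mean <- function(regional_mean, regions, r, c) {
  if (is.null(regional_mean)) {
    stop("regional mean required for a pixel with an empty smoothing window, but none supplied")
  }
  if (length(regional_mean) == 1 && is.null(names(regional_mean))) {
    return(as.numeric(regional_mean))
  }
  if (is.null(regions)) {
    stop("a region raster is required to look up per-region fallback means")
  }
  id <- regions$values[r, c]
  if (is.na(id) || !(as.character(id) %in% names(regional_mean)) ||
      is.na(regional_mean[[as.character(id)]])) {
    stop(sprintf("no regional mean available for region '%s'", id))
  }
  as.numeric(regional_mean[[as.character(id)]])
}

#' Reconstruct the attributed warming from the smoothed per-point field
#'
#' Multiplies the smoothed warming-per-point by each pixel's percentage-point
#' loss, undoing the normalization on the robustified field.
#'
#' @param per_point_smoothed [dh_raster()] from [smooth_per_point()].
#' @param change [dh_raster()] from [cover_change()].
#' @return A [dh_raster()] of attributed warming in degrees C.
#' @export
reconstruct <- function(per_point_smoothed, change) {
  stop_if_grid_mismatch(per_point_smoothed, change,
                        "smoothed and change rasters")
  dh_raster(per_point_smoothed$values * (-change$values),
            per_point_smoothed$grid)
}

#' Full attribution chain
#'
#' Runs matching, normalization, rolling smoothing and reconstruction in
#' order and returns a complete `attribution_result`. Regional fallback
#' means are computed from the data when a region raster is supplied and any
#' pixel needs them.
#'
#' @inheritParams raw_attribution
#' @param change [dh_raster()] from [cover_change()].
#' @param regions Optional [dh_raster()] of macro-region codes for the
#'   smoothing fallback.
#' @return An `attribution_result`: rasters `dt_defor_raw`, `dt_per_point`,
#'   `dt_per_point_smoothed`, `dt_defor`, and `provenance` matrices
#'   (`radius_used`, `n_controls`, `regional_fallback`,
#'   `n_smooth_neighbors`).
#' @export
attribute_warming <- function(dt, classes, elevation, change,
                              params = match_params(), regions = NULL) {
  res <- raw_attribution(dt, classes, elevation, params)
  res$dt_per_point <- normalize_per_point(res$dt_defor_raw, change)
  rmean <- NULL
  if (!is.null(regions)) {
    rmean <- regional_mean_per_point_safe(res$dt_per_point, change, regions,
                                          min_loss = params$min_loss_for_smoothing)
  }
  sm <- smooth_per_point(res$dt_per_point, change, classes, params,
                         regional_mean = rmean, regions = regions)
  res$dt_per_point_smoothed <- sm$smoothed
  res$dt_defor <- reconstruct(sm$smoothed, change)
  res$provenance$regional_fallback <- sm$regional_fallback
  res$provenance$n_smooth_neighbors <- sm$n_smooth_neighbors
  res
}

#' @export
print.attribution_result <- function(x, ...) {
  ru <- x$provenance$radius_used
  n_def <- sum(!is.na(ru))
  cat(sprintf("<attribution_result> %d treated pixels: %d primary, %d fallback, %d unmatched\n",
              n_def, sum(ru == 1L, na.rm = TRUE), sum(ru == 2L, na.rm = TRUE),
              sum(ru == 0L, na.rm = TRUE)))
  invisible(x)
}
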