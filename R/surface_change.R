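#' Land surface temperature observation stack
#'
#' Holds a stack of 8-day (or monthly) land surface temperature composites
#' together with their per-cell quality fields: the estimated emissivity
#' error (dimensionless) and the LST error (kelvin). Layers are indexed by
#' the start date of their compositing period; an 8-day period straddling a
#' month boundary belongs to the month containing its start date.
#'
#' @param lst 3-d numeric array `[nrow, ncol, nlayer]` of temperatures in
#'   kelvin (`NA` = missing).
#' @param emissivity_error,lst_error 3-d arrays aligned with `lst`, or `NULL`
#'   if the quality fields are absent (in which case [qc_filter()] refuses to
#'   run rather than silently passing data through).
#' @param dates `Date` vector of layer period start dates, length `nlayer`.
#' @param grid A [grid_spec()].
#' @return An object of class `lst_stack`.
#' @export
lst_stack <- function(lst, dates, grid, emissivity_error = NULL,
                      lst_error = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.array(lst), length(dim(lst)) == 3)
  if (dim(lst)[1] != grid$nrow || dim(lst)[2] != grid$ncol) {
    stop("lst array does not match grid dimensions")
  }
  dates <- as.Date(dates)
  if (length(dates) != dim(lst)[3]) stop("one date per layer is required")
  for (qc in list(emissivity_error, lst_error)) {
    if (!is.null(qc) && !identical(dim(qc), dim(lst))) {
      stop("QC arrays must be aligned with the LST array")
    }
  }
  bad <- !is.na(lst) & (lst < 200 | lst > 350)
  if (any(bad)) stop("LST values outside the physically plausible 200-350 K range")
  structure(list(lst = lst, dates = dates, grid = grid,
                 emissivity_error = emissivity_error, lst_error = lst_error,
                 qc_applied = FALSE),
            class = "lst_stack")
}

#' @export
print.lst_stack <- function(x, ...) {
  cat(sprintf("<lst_stack> %d x %d x %d layers, %s .. %s, QC %s\n",
              dim(x$lst)[1], dim(x$lst)[2], dim(x$lst)[3],
              min(x$dates), max(x$dates),
              if (x$qc_applied) "applied" else "pending"))
  invisible(x)
}

#' Quality-screen an LST stack
#'
#' Masks every observation whose estimated emissivity error exceeds 0.02 or
#' whose LST error exceeds 1 K. Both thresholds are strict: values exactly at
#' the threshold are retained. Filtering is idempotent. A stack without QC
#' layers is an error -- data are never passed through unscreened.
#'
#' @param stack An [lst_stack()].
#' @param emissivity_threshold,lst_error_threshold Strict upper limits
#'   (defaults 0.02 and 1 K).
#' @return The stack with failing observations masked and `qc_applied` set.
#' @export
qc_filter <- function(stack, emissivity_threshold = 0.02,
                      lst_error_threshold = 1.0) {
  stopifnot(inherits(stack, "lst_stack"))
  if (is.null(stack$emissivity_error) || is.null(stack$lst_error)) {
    stop("QC layers (emissivity_error, lst_error) are missing; refusing to pass data through unscreened")
  }
  drop <- (!is.na(stack$emissivity_error) &
             stack$emissivity_error > emissivity_threshold) |
          (!is.na(stack$lst_error) & stack$lst_error > lst_error_threshold) |
          is.na(stack$emissivity_error) | is.na(stack$lst_error)
  stack$lst[drop] <- NA_real_
  stack$qc_applied <- TRUE
  stack
}

#' Composite 8-day layers to a calendar month
#'
#' Per-cell mean over the available (unmasked) 8-day layers assigned to the
#' month; missing periods are simply ignored, with no gap filling. A cell is
#' masked only when every contributing layer is masked.
#'
#' @param stack An [lst_stack()].
#' @param year,month Calendar year and month (1-12) to composite.
#' @return A [dh_raster()] of mean temperature (kelvin).
#' @export
monthly_composite <- function(stack, year, month) {
  stopifnot(inherits(stack, "lst_stack"))
  sel <- which(as.integer(format(stack$dates, "%Y")) == year &
                 as.integer(format(stack$dates, "%m")) == month)
  if (length(sel) == 0) {
    stop(sprintf("no 8-day layers assigned to %d-%02d", year, month))
  }
  sub <- stack$lst[, , sel, drop = FALSE]
  n <- rowSums(!is.na(sub), dims = 2)
  s <- rowSums(sub, na.rm = TRUE, dims = 2)
  out <- s / n
  out[n == 0] <- NA_real_
  dh_raster(out, stack$grid)
}

#' Composite every month present in a stack
#'
#' @param stack An [lst_stack()].
#' @return An object of class `monthly_stack`: list with `values`
#'   (`[nrow, ncol, nmonth]`), `year`, `month`, `grid`.
#' @export
monthly_stack <- function(stack) {
  stopifnot(inherits(stack, "lst_stack"))
  ym <- unique(format(stack$dates, "%Y-%m"))
  ym <- sort(ym)
  yrs <- as.integer(substr(ym, 1, 4))
  mos <- as.integer(substr(ym, 6, 7))
  vals <- array(NA_real_, c(stack$grid$nrow, stack$grid$ncol, length(ym)))
  for (k in seq_along(ym)) {
    vals[, , k] <- monthly_composite(stack, yrs[k], mos[k])$values
  }
  structure(list(values = vals, year = yrs, month = mos, grid = stack$grid),
            class = "monthly_stack")
}

#' Multi-year mean of monthly composites
#'
#' Unweighted mean over all available (unmasked) months of the listed years;
#' equal weight per month regardless of month length or of how many 8-day
#' periods survived screening. A cell is masked only when no month is
#' available.
#'
#' @param monthly A `monthly_stack` from [monthly_stack()].
#' @param years Integer vector of calendar years, e.g. `2001:2003`.
#' @return A [dh_raster()] (kelvin).
#' @export
period_mean <- function(monthly, years) {
  stopifnot(inherits(monthly, "monthly_stack"))
  if (length(years) == 0) stop("the year set must be nonempty")
  sel <- which(monthly$year %in% years)
  if (length(sel) == 0) {
    stop(sprintf("monthly stack has no months in years %s",
                 paste(years, collapse = ", ")))
  }
  sub <- monthly$values[, , sel, drop = FALSE]
  n <- rowSums(!is.na(sub), dims = 2)
  s <- rowSums(sub, na.rm = TRUE, dims = 2)
  out <- s / n
  out[n == 0] <- NA_real_
  dh_raster(out, monthly$grid)
}

#' Temperature change between two period means
#'
#' Per-cell end-period mean minus start-period mean. Kelvin differences are
#' degree-Celsius differences, so the result is reported in degrees C.
#' Masked wherever either period mean is missing.
#'
#' @param start,end [dh_raster()]s on the same grid (kelvin or Celsius; only
#'   the difference matters).
#' @return A [dh_raster()] of temperature change in degrees C.
#' @export
delta_t <- function(start, end) {
  stop_if_grid_mismatch(start, end, "period means")
  dh_raster(end$values - start$values, start$grid)
}

#' Linear surface-to-air temperature adjustment
#'
#' Rescales a land-surface temperature change into a 2-m air temperature
#' change using an externally supplied linear relationship per region
#' (slope > 0; the intercept cancels when differencing two period means).
#' Disabled by default in the pipeline.
#'
#' @param dt A [dh_raster()] of temperature change.
#' @param adjustments Data frame with columns `region` (label) and `slope`,
#'   or a single numeric slope applied everywhere.
#' @param regions A [dh_raster()] of integer region codes matching the
#'   `region` column, required when `adjustments` is a table.
#' @return A [dh_raster()] of adjusted temperature change.
#' @export
apply_air_adjustment <- function(dt, adjustments, regions = NULL) {
  stopifnot(inherits(dt, "dh_raster"))
  if (is.numeric(adjustments) && length(adjustments) == 1) {
    if (adjustments <= 0) stop("adjustment slope must be positive")
    return(dh_raster(dt$values * adjustments, dt$grid))
  }
  stopifnot(is.data.frame(adjustments),
            all(c("region", "slope") %in% names(adjustments)))
  if (any(adjustments$slope <= 0)) stop("adjustment slopes must be positive")
  if (is.null(regions)) stop("a region raster is required for per-region adjustment")
  stop_if_grid_mismatch(dt, regions, "dt and region rasters")
  ids <- regions$values
  present <- unique(ids[!is.na(ids) & !is.na(dt$values)])
  unknown <- setdiff(present, adjustments$region)
  if (length(unknown)) {
    stop(sprintf("no air adjustment for region label(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  slope <- adjustments$slope[match(ids, adjustments$region)]
  slope <- matrix(slope, nrow(ids), ncol(ids))
  dh_raster(dt$values * slope, dt$grid)
}
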