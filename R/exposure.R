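#' Population-weighted mean of a field
#'
#' `sum(pop * field) / sum(pop)` over the unmasked cells of `mask`.
#'
#' @param field [dh_raster()].
#' @param pop [dh_raster()] of population count.
#' @param mask Logical matrix selecting the cells to pool (default: all
#'   cells with valid field and population).
#' @return Scalar mean; error if the selected population sums to zero.
#' @export
population_weighted_mean <- function(field, pop, mask = NULL) {
  stop_if_grid_mismatch(field, pop, "field and population rasters")
  sel <- !is.na(field$values) & !is.na(pop$values)
  if (!is.null(mask)) sel <- sel & mask
  tot <- sum(pop$values[sel])
  if (!any(sel) || tot <= 0) {
    stop("population-weighted mean undefined: zero total population on the mask")
  }
  sum(pop$values[sel] * field$values[sel]) / tot
}

#' Area-weighted mean of a field
#'
#' `sum(w * field) / sum(w)` with `w` proportional to cos(latitude).
#'
#' @param field [dh_raster()].
#' @param weights An `area_weights` object from [cell_area_weights()], or
#'   `NULL` to compute from the field's grid.
#' @param mask Logical matrix selecting cells (default all valid cells).
#' @return Scalar mean; error on an empty mask.
#' @export
area_weighted_mean <- function(field, weights = NULL, mask = NULL) {
  stopifnot(inherits(field, "dh_raster"))
  if (is.null(weights)) weights <- cell_area_weights(field$grid)
  stopifnot(inherits(weights, "area_weights"))
  if (!grid_equal(field$grid, weights$grid)) {
    stop("field and weights are on different grids")
  }
  sel <- !is.na(field$values)
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("area-weighted mean undefined on an empty mask")
  sum(weights$weight[sel] * field$values[sel]) / sum(weights$weight[sel])
}

#' Population exposure to attributed warming
#'
#' Counts people living on deforested pixels with valid attributed warming
#' (the only pixels where exposure is defined: the extent-gain exclusion and
#' quality screening have already removed invalid cells from the warming
#' field), the subset exposed to strictly positive warming, and the subsets
#' above each threshold (strict `>`).
#'
#' @param dt_defor [dh_raster()] of final attributed warming.
#' @param pop [dh_raster()] of population count.
#' @param classes [dh_raster()] of [pixel_classes()] codes.
#' @param thresholds Ascending numeric thresholds in degrees C (default
#'   `c(0, 1, 2, 3)`).
#' @param scope Region label recorded in the summary.
#' @return An `exposure_summary`: list with `pop_total_forest_loss`,
#'   `pop_exposed`, `pop_above` (named by threshold), `popwgt_dt`,
#'   `areawgt_dt`, `scope`.
#' @export
exposure_counts <- function(dt_defor, pop, classes,
                            thresholds = c(0, 1, 2, 3), scope = "all") {
  stop_if_grid_mismatch(dt_defor, pop, "dt and population rasters")
  stop_if_grid_mismatch(dt_defor, classes, "dt and class rasters")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be sorted strictly ascending")
  }
  cls <- pixel_classes()
  valid <- !is.na(classes$values) & classes$values == cls[["deforested"]] &
    !is.na(dt_defor$values) & !is.na(pop$values)
  p <- pop$values
  d <- dt_defor$values
  pop_above <- vapply(thresholds,
                      function(t) sum(p[valid & d > t]), numeric(1))
  names(pop_above) <- format(thresholds)
  structure(list(
    pop_total_forest_loss = sum(p[valid]),
    pop_exposed = sum(p[valid & d > 0]),
    pop_above = pop_above,
    popwgt_dt = if (any(valid) && sum(p[valid]) > 0)
      sum(p[valid] * d[valid]) / sum(p[valid]) else NA_real_,
    areawgt_dt = if (any(valid))
      area_weighted_mean(dt_defor, mask = valid) else NA_real_,
    scope = scope
  ), class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("<exposure_summary> [%s] %.0f people in forest-loss pixels, %.0f exposed (%.0f%%)\n",
              x$scope, x$pop_total_forest_loss, x$pop_exposed,
              100 * x$pop_exposed / max(x$pop_total_forest_loss, 1)))
  for (t in names(x$pop_above)) {
    cat(sprintf("  > %s degC: %.0f people\n", t, x$pop_above[[t]]))
  }
  cat(sprintf("  pop-wgtd dT %.3f degC, area-wgtd dT %.3f degC\n",
              x$popwgt_dt, x$areawgt_dt))
  invisible(x)
}
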