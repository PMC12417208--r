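#' Pixel classification codes
#'
#' Integer codes used in the categorical class map that drives the
#' counterfactual matching. Exactly one category applies per unmasked cell.
#'
#' @return Named integer vector: `non_forest` (0), `deforested` (1),
#'   `non_deforested` (2), `buffer` (3), `excluded_gain` (4).
#' @export
pixel_classes <- function() {
  c(non_forest = 0L, deforested = 1L, non_deforested = 2L,
    buffer = 3L, excluded_gain = 4L)
}

#' Annual forest cover from year-2000 cover and first-loss year
#'
#' At the fine (pre-regrid) resolution, loss is binary per cell: a cell keeps
#' its year-2000 canopy-cover fraction until its recorded loss year and is
#' zero afterwards. Aggregation to the analysis grid is done separately with
#' [regrid_area_weighted()].
#'
#' @param cover2000 Fine-resolution [dh_raster()] of canopy cover in percent
#'   (0-100).
#' @param loss_year Fine-resolution [dh_raster()] of the calendar year of
#'   first loss, 0 where no loss occurred.
#' @param year Query year, within 2000-2020.
#' @return A [dh_raster()] of cover percent in `year`.
#' @export
annual_cover <- function(cover2000, loss_year, year) {
  stop_if_grid_mismatch(cover2000, loss_year, "cover and loss-year rasters")
  if (length(year) != 1 || year < 2000 || year > 2020) {
    stop("year must lie within the 2000-2020 record")
  }
  cv <- cover2000$values
  if (any(cv < 0 | cv > 100, na.rm = TRUE)) {
    stop("cover fractions must lie within [0, 100] percent")
  }
  ly <- loss_year$values
  out <- ifelse(!is.na(ly) & ly != 0 & ly <= year, 0, cv)
  out[is.na(cv)] <- NA_real_
  dh_raster(out, cover2000$grid)
}

#' Percentage-point forest-cover change
#'
#' `c2020 - c2001`, in percentage points; negative values are loss.
#'
#' @param c2001,c2020 [dh_raster()]s of cover percent on the analysis grid.
#' @return A [dh_raster()] of change in percentage points.
#' @export
cover_change <- function(c2001, c2020) {
  stop_if_grid_mismatch(c2001, c2020, "cover rasters")
  dh_raster(c2020$values - c2001$values, c2001$grid)
}

#' Forest-extent gain exclusion mask
#'
#' Flags cells whose tall-vegetation extent increased by strictly more than
#' `threshold` percentage points between 2000 and 2020; regrowth cooling in
#' such cells would contaminate the warming attribution, so their temperature
#' change is discarded. Cells exactly at the threshold are retained.
#'
#' @param extent2000,extent2020 [dh_raster()]s of forest-extent percent on
#'   the analysis grid.
#' @param threshold Percentage points, in (0, 100\]; default 50 with 20 as
#'   the sensitivity alternative.
#' @return A [dh_raster()] with values 1 (exclude) / 0 (keep).
#' @export
extent_gain_mask <- function(extent2000, extent2020, threshold = 50) {
  stop_if_grid_mismatch(extent2000, extent2020, "extent rasters")
  if (length(threshold) != 1 || threshold <= 0 || threshold > 100) {
    stop("gain threshold must lie in (0, 100] percentage points")
  }
  gain <- extent2020$values - extent2000$values
  dh_raster((gain > threshold) + 0, extent2000$grid)
}

#' Classify analysis-grid pixels for matching
#'
#' Assigns every unmasked cell exactly one category:
#' * `non_forest`: 2001 cover below 10 percent -- outside the study set;
#' * `excluded_gain`: forest cover present but flagged by the extent-gain
#'   mask;
#' * `deforested`: net loss of at least `loss_threshold` points (default 2,
#'   sensitivity 1) -- the treated pixels;
#' * `non_deforested`: net loss below 0.5 points (gains included) -- the
#'   control pool;
#' * `buffer`: loss between 0.5 and `loss_threshold` points -- neither
#'   treated nor control.
#'
#' @param c2001 [dh_raster()] of 2001 cover percent.
#' @param change [dh_raster()] from [cover_change()].
#' @param gain [dh_raster()] from [extent_gain_mask()].
#' @param loss_threshold Percentage points of net loss defining deforestation
#'   (inclusive; default 2).
#' @param cover_threshold Minimum 2001 cover percent for a forest pixel
#'   (inclusive; default 10).
#' @param control_threshold Strict upper limit on loss for control pixels
#'   (default 0.5).
#' @return A [dh_raster()] of [pixel_classes()] codes.
#' @export
classify_pixels <- function(c2001, change, gain, loss_threshold = 2,
                            cover_threshold = 10, control_threshold = 0.5) {
  stop_if_grid_mismatch(c2001, change, "cover and change rasters")
  stop_if_grid_mismatch(c2001, gain, "cover and gain rasters")
  if (control_threshold > loss_threshold) {
    stop("control_threshold cannot exceed loss_threshold")
  }
  cls <- pixel_classes()
  cv <- c2001$values
  loss <- -change$values
  g <- gain$values
  out <- matrix(NA_real_, nrow(cv), ncol(cv))
  forest <- !is.na(cv) & cv >= cover_threshold
  out[!is.na(cv) & cv < cover_threshold] <- cls[["non_forest"]]
  out[forest & !is.na(g) & g > 0] <- cls[["excluded_gain"]]
  open <- forest & (is.na(g) | g <= 0) & !is.na(loss)
  out[open & loss >= loss_threshold] <- cls[["deforested"]]
  out[open & loss < control_threshold] <- cls[["non_deforested"]]
  out[open & loss >= control_threshold & loss < loss_threshold] <-
    cls[["buffer"]]
  dh_raster(out, c2001$grid)
}
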