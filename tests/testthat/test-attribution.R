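# A hand-built 11x11 landscape with one deforested pixel in the middle of a
# non-deforested matrix (cells are 0.05 degrees).
one_pixel_world <- function(loss_pct = 20, n = 11) {
  block_landscape(n = n, res = 180, loss_pct = loss_pct)
}

test_that("find_controls applies the elevation band around the center", {
  w <- one_pixel_world()
  center <- c(6, 6)
  ev <- w$elevation$values
  # make only three candidates eligible class-wise; elevations relative to
  # the center: +10, -60, +49
  cls <- pixel_classes()
  cm <- w$classes$values
  cm[cm == cls[["non_deforested"]]] <- cls[["buffer"]]  # knock out the rest
  cm[6, 5] <- cls[["non_deforested"]]; ev[6, 5] <- 110
  cm[5, 6] <- cls[["non_deforested"]]; ev[5, 6] <- 40
  cm[7, 6] <- cls[["non_deforested"]]; ev[7, 6] <- 149
  classes <- dh_raster(cm, w$grid)
  elev <- dh_raster(ev, w$grid)
  dt <- dh_raster(matrix(0.5, 11, 11), w$grid)
  ctl <- find_controls(6, 6, classes, elev, dt)
  expect_equal(ctl$n_controls, 2)
  expect_equal(ctl$radius_used, "primary")
  got <- sort(paste(ctl$rows, ctl$cols))
  expect_equal(got, sort(c("6 5", "7 6")))
})

test_that("find_controls extends to the fallback radius, then reports none", {
  # 0.05-degree cells: controls at distance ~0.3 deg are outside 0.25 but
  # inside 0.50
  w <- block_landscape(n = 15, res = 180, loss_rc = cbind(8, 8))
  cls <- pixel_classes()
  cm <- w$classes$values
  cm[cm == cls[["non_deforested"]]] <- cls[["buffer"]]
  cm[8, 14] <- cls[["non_deforested"]]  # 6 cells = 0.30 degrees away
  classes <- dh_raster(cm, w$grid)
  dt <- dh_raster(matrix(0.5, 15, 15), w$grid)
  ctl <- find_controls(8, 8, classes, w$elevation, dt)
  expect_equal(ctl$radius_used, "fallback")
  expect_equal(ctl$n_controls, 1)

  cm[8, 14] <- cls[["buffer"]]
  ctl2 <- find_controls(8, 8, dh_raster(cm, w$grid), w$elevation, dt)
  expect_equal(ctl2$radius_used, "none")
  expect_equal(ctl2$n_controls, 0)

  expect_error(find_controls(1, 1, classes, w$elevation, dt),
               "not classified as deforested")
})

test_that("raw attribution subtracts the control mean", {
  w <- one_pixel_world()
  cls <- pixel_classes()
  cm <- w$classes$values
  cm[cm == cls[["non_deforested"]]] <- cls[["buffer"]]
  cm[6, 5] <- cls[["non_deforested"]]
  cm[6, 7] <- cls[["non_deforested"]]
  cm[5, 6] <- cls[["non_deforested"]]
  classes <- dh_raster(cm, w$grid)
  dtv <- matrix(0, 11, 11)
  dtv[6, 6] <- 1.2
  dtv[6, 5] <- 0.2; dtv[6, 7] <- 0.3; dtv[5, 6] <- 0.1
  dt <- dh_raster(dtv, w$grid)
  res <- raw_attribution(dt, classes, w$elevation)
  expect_equal(res$dt_defor_raw$values[6, 6], 1.2 - mean(c(0.2, 0.3, 0.1)))
  expect_equal(res$provenance$n_controls[6, 6], 3L)
  expect_equal(res$provenance$radius_used[6, 6], 1L)
})

test_that("a uniform trend self-cancels and a beta-world is recovered exactly", {
  w <- make_exact_world(seed = 3, n = 50)
  gain <- extent_gain_mask(w$extent2000, w$extent2020)
  classes <- classify_pixels(w$c2001, w$change, gain)
  # uniform-trend world with no signal: dt constant
  dt_const <- dh_raster(matrix(0.37, 50, 50), w$grid)
  res0 <- raw_attribution(dt_const, classes, w$elevation)
  expect_lt(max(abs(res0$dt_defor_raw$values), na.rm = TRUE), 1e-12)

  # trend + beta * loss: raw attribution returns beta * loss exactly
  dt <- dh_raster(w$truth$dt_expected$values, w$grid)
  res <- raw_attribution(dt, classes, w$elevation)
  matched <- !is.na(res$dt_defor_raw$values)
  loss <- -w$change$values
  expect_gt(sum(matched), 0)
  expect_lt(max(abs(res$dt_defor_raw$values[matched] -
                      0.04 * loss[matched])), 1e-10)
})

test_that("normalization divides by positive loss and asserts otherwise", {
  g <- grid_spec(0, 1, 0, 3, 3600)
  raw <- dh_raster(matrix(c(1.0, -0.3, 0.9), 1, 3), g)
  change <- dh_raster(matrix(c(-20, -10, -2), 1, 3), g)
  pp <- normalize_per_point(raw, change)
  expect_equal(as.vector(pp$values), c(0.05, -0.03, 0.45))
  bad <- dh_raster(matrix(c(0, -10, -2), 1, 3), g)
  expect_error(normalize_per_point(raw, bad), "non-positive forest loss")
})

test_that("smoothing averages the qualifying window and drops z outliers", {
  # 20 deforested pixels in a row, loss 10 points, all within 0.1 degrees
  g <- grid_spec(0, 0.005, 0, 0.1, 18)
  cls <- pixel_classes()
  classes <- dh_raster(matrix(cls[["deforested"]], 1, 20), g)
  change <- dh_raster(matrix(-10, 1, 20), g)
  ppv <- matrix(0, 1, 20); ppv[1, 20] <- 100
  per_point <- dh_raster(ppv, g)
  out <- smooth_per_point(per_point, change, classes)
  # at pixel 1 the window spans all 20 values: z(100) = 95/21.79 = 4.36 > 3
  expect_equal(out$smoothed$values[1, 1], 0)
  expect_equal(out$n_smooth_neighbors[1, 1], 19L)

  # constant qualifying set is a fixed point
  pp2 <- dh_raster(matrix(0.05, 1, 20), g)
  out2 <- smooth_per_point(pp2, change, classes)
  expect_equal(out2$smoothed$values, matrix(0.05, 1, 20))
})

test_that("empty smoothing windows fall back to the regional mean", {
  w <- one_pixel_world(loss_pct = 3)  # below the 5-point smoothing rule
  change <- w$change
  pp <- normalize_per_point(
    dh_raster(ifelse(w$classes$values == pixel_classes()[["deforested"]],
                     0.12, NA), w$grid), change)
  out <- smooth_per_point(pp, change, w$classes,
                          regional_mean = 0.07)
  expect_equal(out$smoothed$values[6, 6], 0.07)
  expect_true(out$regional_fallback[6, 6])
  # without a regional mean this is an error
  expect_error(smooth_per_point(pp, change, w$classes), "regional mean")
})

test_that("regional means are area-weighted over qualifying pixels", {
  g <- grid_spec(-0.5, 0.5, 0, 2, 1800)  # two rows symmetric about equator
  cls <- pixel_classes()
  cm <- matrix(cls[["non_deforested"]], 2, 4)
  cm[1, 1] <- cls[["deforested"]]; cm[2, 1] <- cls[["deforested"]]
  cm[1, 3] <- cls[["deforested"]]
  classes <- dh_raster(cm, g)
  ch <- matrix(0, 2, 4); ch[1, 1] <- -10; ch[2, 1] <- -10; ch[1, 3] <- -8
  change <- dh_raster(ch, g)
  ppv <- matrix(NA_real_, 2, 4)
  ppv[1, 1] <- 0.02; ppv[2, 1] <- 0.04; ppv[1, 3] <- 0.10
  per_point <- dh_raster(ppv, g)
  regions <- dh_raster(matrix(rep(c(1, 1, 2, 2), each = 2), 2, 4), g)
  rm <- regional_mean_per_point(per_point, change, regions)
  # equator-symmetric rows have equal areas -> plain mean in region 1
  expect_equal(unname(rm["1"]), 0.03)
  expect_equal(unname(rm["2"]), 0.10)  # single-pixel region
  # region with no qualifying pixel errors
  regions2 <- dh_raster(matrix(rep(c(1, 2, 3, 3), each = 2), 2, 4), g)
  expect_error(regional_mean_per_point(per_point, change, regions2),
               "no qualifying")
})

test_that("reconstruct inverts normalization", {
  g <- grid_spec(0, 1, 0, 1, 3600)
  sm <- dh_raster(matrix(0.05, 1, 1), g)
  change <- dh_raster(matrix(-20, 1, 1), g)
  expect_equal(reconstruct(sm, change)$values[1, 1], 1.0)
})

test_that("the full chain is translation invariant", {
  w <- make_test_world(seed = 13, n = 40)
  gain <- extent_gain_mask(w$extent2000, w$extent2020)
  classes <- classify_pixels(w$c2001, w$change, gain)
  dt1 <- dh_raster(w$truth$dt_expected$values, w$grid)
  dt2 <- dh_raster(w$truth$dt_expected$values + 3.21, w$grid)
  a1 <- attribute_warming(dt1, classes, w$elevation, w$change,
                          regions = w$regions)
  a2 <- attribute_warming(dt2, classes, w$elevation, w$change,
                          regions = w$regions)
  expect_equal(a1$dt_defor$values, a2$dt_defor$values, tolerance = 1e-12)
})

test_that("elevation matching beats no matching in an elevation-lapse world", {
  wp_base <- list(n = 50, seed = 17, noise = 0,
                  layer_noise_sd = 0, qc_bad_frac = 0,
                  n_nonforest_pockets = 0, n_gain_patches = 0,
                  trend = list(type = "elevation", value = 0.2, lapse = 0.01))
  w <- do.call(make_test_world, wp_base)
  gain <- extent_gain_mask(w$extent2000, w$extent2020)
  classes <- classify_pixels(w$c2001, w$change, gain)
  dt <- dh_raster(w$truth$dt_expected$values, w$grid)
  truth <- w$truth$true_dt_defor$values
  err <- function(params) {
    res <- raw_attribution(dt, classes, w$elevation, params)
    both <- !is.na(res$dt_defor_raw$values) & !is.na(truth)
    sqrt(mean((res$dt_defor_raw$values[both] - truth[both])^2))
  }
  e_matched <- err(match_params(elevation_band = 50))
  e_unmatched <- err(match_params(elevation_band = 1e9))
  expect_lt(e_matched, e_unmatched)
})

test_that("provenance flags unmatched pixels and the final field is masked there", {
  w <- one_pixel_world()
  cls <- pixel_classes()
  cm <- w$classes$values
  cm[cm == cls[["non_deforested"]]] <- cls[["non_forest"]]  # no controls at all
  classes <- dh_raster(cm, w$grid)
  dt <- dh_raster(matrix(0.5, 11, 11), w$grid)
  res <- attribute_warming(dt, classes, w$elevation, w$change,
                           regions = dh_raster(matrix(1, 11, 11), w$grid))
  expect_equal(res$provenance$radius_used[6, 6], 0L)
  expect_true(is.na(res$dt_defor$values[6, 6]))
  # masked exactly where radius_used == none
  expect_identical(is.na(res$dt_defor$values) &
                     !is.na(res$provenance$radius_used),
                   !is.na(res$provenance$radius_used) &
                     res$provenance$radius_used == 0L)
})
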