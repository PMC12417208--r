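test_that("grid_spec validates bounds and integral spans", {
  g <- grid_spec(-25, 25, -180, 180, resolution_arcsec = 3600)
  expect_equal(g$nrow, 50L)
  expect_equal(g$ncol, 360L)
  expect_error(grid_spec(-91, 25, 0, 10), "latitude")
  expect_error(grid_spec(10, -10, 0, 10), "strictly less")
  expect_error(grid_spec(0, 1, 0, 1.0001, resolution_arcsec = 3600),
               "integral")
})

test_that("lat/lon centers follow the north-first, west-first convention", {
  g <- grid_spec(0, 1, 10, 12, resolution_arcsec = 1800)
  expect_equal(lat_centers(g), c(0.75, 0.25))
  expect_equal(lon_centers(g), c(10.25, 10.75, 11.25, 11.75))
})

test_that("area weights are cosine-of-latitude, row-constant, mean one", {
  g <- grid_spec(-25, 25, 0, 10, resolution_arcsec = 3600)
  aw <- cell_area_weights(g)
  expect_equal(mean(aw$weight), 1)
  # row-constant
  expect_true(all(apply(aw$weight, 1, function(r) all(r == r[1]))))
  # ratio between any two rows equals the cosine ratio
  lat <- lat_centers(g)
  expect_equal(aw$weight[1, 1] / aw$weight[25, 1],
               cos(lat[1] * pi / 180) / cos(lat[25] * pi / 180))
  # symmetric about the equator for a symmetric grid
  expect_equal(aw$weight[, 1], rev(aw$weight[, 1]))
  expect_error(cell_area_weights(grid_spec(89, 90, 0, 1, 3600)), "pole")
})

test_that("raster round trip through ASCII grid is bit-exact", {
  g <- grid_spec(0, 10, 0, 10, resolution_arcsec = 3600)
  r <- dh_raster(matrix(1.0, 10, 10), g)
  f <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, f)
  back <- read_raster(f)
  expect_identical(back$values, r$values)
  expect_equal(sum(raster_mask(back)), 0)

  # irrational-ish doubles survive exactly
  g2 <- grid_spec(0, 2, 0, 2, resolution_arcsec = 3600)
  v <- matrix(c(0.1, 0.2, 0.3, 0.4) + pi * 1e-10, 2, 2)
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_raster(dh_raster(v, g2), f2)
  expect_identical(read_raster(f2)$values, v)
})

test_that("masked cells map to nodata and back", {
  g <- grid_spec(0, 5, 0, 5, resolution_arcsec = 3600)
  v <- matrix(rnorm(25), 5, 5)
  v[c(2, 10, 17)] <- NA
  f <- withr::local_tempfile(fileext = ".asc")
  write_raster(dh_raster(v, g), f)
  body <- readLines(f)[-(1:6)]
  expect_equal(sum(lengths(regmatches(body, gregexpr("-9999", body)))), 3)
  back <- read_raster(f)
  expect_equal(sum(raster_mask(back)), 3)
  expect_identical(is.na(back$values), is.na(v))
})

test_that("read_raster fails descriptively", {
  expect_error(read_raster("/nonexistent/file.asc"), "does not exist")
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("not a header", "x"), f)
  expect_error(read_raster(f), "header")
  g <- grid_spec(0, 2, 0, 2, 3600)
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_raster(dh_raster(matrix(0, 2, 2), g), f2)
  expect_error(read_raster(f2, variable = "lst"), "single-band")
})

test_that("bilinear regridding preserves constants and affine fields", {
  src_g <- grid_spec(0, 10, 0, 10, resolution_arcsec = 7200)
  dst_g <- grid_spec(2, 8, 2, 8, resolution_arcsec = 1800)
  const <- dh_raster(matrix(300, src_g$nrow, src_g$ncol), src_g)
  out <- regrid_bilinear(const, dst_g)
  expect_equal(out$values, matrix(300, dst_g$nrow, dst_g$ncol))

  lin <- dh_raster(outer(lat_centers(src_g), lon_centers(src_g),
                         function(a, b) 2 * a + 3 * b), src_g)
  out2 <- regrid_bilinear(lin, dst_g)
  expected <- outer(lat_centers(dst_g), lon_centers(dst_g),
                    function(a, b) 2 * a + 3 * b)
  expect_equal(out2$values, expected, tolerance = 1e-12)
})

test_that("bilinear midpoint of four centers is their plain mean", {
  src_g <- grid_spec(0, 2, 0, 2, resolution_arcsec = 3600)
  # rows north-first: values {1,2; 3,4}
  src <- dh_raster(matrix(c(1, 3, 2, 4), 2, 2), src_g)
  dst_g <- grid_spec(0.5, 1.5, 0.5, 1.5, resolution_arcsec = 3600)
  expect_equal(regrid_bilinear(src, dst_g)$values[1, 1], 2.5)
})

test_that("bilinear masks any cell with a masked contributor and stays in range", {
  src_g <- grid_spec(0, 4, 0, 4, resolution_arcsec = 3600)
  v <- matrix(seq_len(16) + 0, 4, 4)
  v[2, 2] <- NA
  dst_g <- grid_spec(0.5, 3.5, 0.5, 3.5, resolution_arcsec = 1800)
  out <- regrid_bilinear(dh_raster(v, src_g), dst_g)
  # cells interpolating from the masked center are masked
  expect_true(any(is.na(out$values)))
  # range bound: no value outside the source range
  expect_true(all(out$values >= min(v, na.rm = TRUE) - 1e-12, na.rm = TRUE))
  expect_true(all(out$values <= max(v, na.rm = TRUE) + 1e-12, na.rm = TRUE))
  expect_error(regrid_bilinear(dh_raster(v, src_g),
                               grid_spec(-1, 5, 0, 4, 3600)),
               "coverage")
})

test_that("area-weighted regridding averages fine cells correctly", {
  # 2x2 fine cells centred on the equator -> equal band areas
  fine_g <- grid_spec(-0.5, 0.5, 0, 1, resolution_arcsec = 1800)
  coarse_g <- grid_spec(-0.5, 0.5, 0, 1, resolution_arcsec = 3600)
  f <- dh_raster(matrix(c(100, 0, 0, 0), 2, 2), fine_g)
  expect_equal(regrid_area_weighted(f, coarse_g)$values[1, 1], 25)

  const <- dh_raster(matrix(42, 2, 2), fine_g)
  expect_equal(regrid_area_weighted(const, coarse_g)$values[1, 1], 42,
               tolerance = 1e-14)

  # off-equator: rows have different areas, but a column-constant pattern
  # {1,0;1,0} still averages to 0.5
  fine_g2 <- grid_spec(10, 11, 0, 1, resolution_arcsec = 1800)
  coarse_g2 <- grid_spec(10, 11, 0, 1, resolution_arcsec = 3600)
  f2 <- dh_raster(matrix(c(1, 1, 0, 0), 2, 2), fine_g2)
  expect_equal(regrid_area_weighted(f2, coarse_g2)$values[1, 1], 0.5,
               tolerance = 1e-12)

  expect_error(regrid_area_weighted(
    dh_raster(matrix(0, 1, 1), coarse_g), fine_g), "bilinear")
})

test_that("area-weighted regridding conserves the domain total", {
  set.seed(11)
  fine_g <- grid_spec(-2, 2, 0, 4, resolution_arcsec = 600)
  coarse_g <- grid_spec(-2, 2, 0, 4, resolution_arcsec = 1800)
  v <- matrix(runif(fine_g$nrow * fine_g$ncol), fine_g$nrow, fine_g$ncol)
  f <- dh_raster(v, fine_g)
  out <- regrid_area_weighted(f, coarse_g)
  area_tot <- function(r) {
    g <- r$grid
    res <- g$resolution_arcsec / 3600
    hi <- g$lat_max - (seq_len(g$nrow) - 1) * res
    band <- sin(hi * pi / 180) - sin((hi - res) * pi / 180)
    sum(band * rowSums(r$values)) * res
  }
  expect_equal(area_tot(out) / area_tot(f), 1, tolerance = 1e-9)
})
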