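test_that("baseline mortality is pop x rate / 100k with admin lookup", {
  s <- two_admin_setup()
  base <- baseline_mortality(s$pop, s$rates, s$admin)
  expect_equal(as.vector(base$values), c(700, 0, 10, 250))
  # brute-force per-pixel check
  brute <- mapply(function(p, a) p * c(`1` = 700, `2` = 500)[[as.character(a)]] / 1e5,
                  as.vector(s$pop$values), as.vector(s$admin$values))
  expect_equal(as.vector(base$values), unname(brute))
  # unmapped admin on a populated pixel fails
  bad_admin <- dh_raster(matrix(c(1, 1, 9, 2), 1, 4), s$g)
  expect_error(baseline_mortality(s$pop, s$rates, bad_admin), "unmapped")
})

test_that("mortality table validation enforces CI ordering", {
  expect_error(mortality_table(data.frame(admin_id = 1, rate_per_100k = 700,
                                          ci_low = 750, ci_high = 800)),
               "ci_low <= rate")
  expect_error(hvi_table(data.frame(key = "x", hvi_pct_per_C = -1)),
               "positive")
})

test_that("hvi resolution walks country then continent", {
  s <- two_admin_setup()
  hv <- hvi_for_admin(s$meta, s$hvi)
  expect_equal(unname(hv["1"]), 5.29)  # country match (Vietnam)
  expect_equal(unname(hv["2"]), 2.34)  # falls through to continent
  bad_meta <- data.frame(admin_id = 3, country = "x", continent = "y")
  expect_error(hvi_for_admin(bad_meta, s$hvi), "resolvable")
  # packaged defaults carry the published continental values
  def <- read_hvi_table()
  expect_equal(def$hvi_pct_per_C[def$key == "Africa"], 2.34)
  expect_equal(def$hvi_pct_per_C[def$key == "Southeast Asia"], 5.29)
})

test_that("fractional increase follows HVI and the positive-warming rule", {
  s <- two_admin_setup()
  dt <- dh_raster(matrix(c(1.0, 0.5, -0.2, 0.27), 1, 4), s$g)
  f <- pct_increase(dt, s$hvi, s$admin, s$meta)
  expect_equal(f$values[1, 1], 0.0529)          # 1.0 degC x 5.29 %p/degC
  expect_equal(f$values[1, 3], 0)               # negative warming -> 0
  expect_equal(f$values[1, 4], 0.006318)        # 0.27 x 2.34 / 100
  flit <- pct_increase(dt, s$hvi, s$admin, s$meta, literal_percent = TRUE)
  expect_equal(flit$values[1, 1], 5.29)
})

test_that("counterfactual and attributable mortality reproduce the algebra", {
  g <- grid_spec(0, 1, 0, 1, 3600)
  base <- dh_raster(matrix(700, 1, 1), g)
  f <- dh_raster(matrix(0.0529, 1, 1), g)
  cf <- counterfactual_mortality(base, f)
  expect_equal(cf$values[1, 1], 700 / 1.0529)
  expect_equal(cf$values[1, 1], 664.83, tolerance = 1e-4)
  hm <- attributable_mortality(base, cf)
  expect_equal(hm$values[1, 1], 35.17, tolerance = 1e-3)
  # identities
  f0 <- dh_raster(matrix(0, 1, 1), g)
  expect_equal(counterfactual_mortality(base, f0)$values, base$values)
  fbig <- dh_raster(matrix(1e9, 1, 1), g)
  expect_lt(counterfactual_mortality(base, fbig)$values[1, 1], 1e-6)
  expect_error(counterfactual_mortality(base, dh_raster(matrix(-1.5, 1, 1), g)),
               "impossible")
})

test_that("heat_mort equals baseline x f/(1+f) on random fields", {
  set.seed(41)
  g <- grid_spec(0, 5, 0, 5, 3600)
  base <- dh_raster(matrix(runif(25, 0, 1000), 5, 5), g)
  f <- dh_raster(matrix(runif(25, 0, 0.3), 5, 5), g)
  hm <- attributable_mortality(base, counterfactual_mortality(base, f))
  expect_equal(hm$values, base$values * f$values / (1 + f$values),
               tolerance = 1e-12)
  af <- hm$values / base$values
  expect_true(all(af >= 0 & af < 1))
})

test_that("bounds scale linearly in the mortality rate and bracket the center", {
  s <- two_admin_setup()
  dt <- dh_raster(matrix(c(1.0, 0.5, 0.3, 0.27), 1, 4), s$g)
  mb <- mortality_with_bounds(s$pop, s$rates, s$hvi, s$admin, s$meta, dt)
  hm <- function(b) sum(mb[[b]]$heat_mort$values, na.rm = TRUE)
  expect_lte(hm("low"), hm("central"))
  expect_lte(hm("central"), hm("high"))
  # admin 1 rates are 600/700/800: low/central = 6/7 exactly
  a1 <- mb$low$heat_mort$values[1, 1] / mb$central$heat_mort$values[1, 1]
  expect_equal(a1, 6 / 7, tolerance = 1e-12)
  # degenerate CI gives three identical fields
  degen <- mortality_table(data.frame(admin_id = c(1, 2),
                                      rate_per_100k = c(700, 500),
                                      ci_low = c(700, 500),
                                      ci_high = c(700, 500)))
  mb2 <- mortality_with_bounds(s$pop, degen, s$hvi, s$admin, s$meta, dt)
  expect_identical(mb2$low$heat_mort$values, mb2$high$heat_mort$values)
})

test_that("attributable mortality is monotone in its drivers", {
  s <- two_admin_setup()
  dt1 <- dh_raster(matrix(0.5, 1, 4), s$g)
  dt2 <- dh_raster(matrix(1.0, 1, 4), s$g)
  hm <- function(dt, hvi = s$hvi, pop = s$pop) {
    sum(mortality_field(pop, s$rates, hvi, s$admin, s$meta, dt)$heat_mort$values)
  }
  expect_lt(hm(dt1), hm(dt2))
  hvi2 <- hvi_table(transform(as.data.frame(s$hvi),
                              hvi_pct_per_C = hvi_pct_per_C * 2))
  expect_lt(hm(dt1), hm(dt1, hvi = hvi2))
  pop2 <- dh_raster(s$pop$values * 2, s$g)
  expect_lt(hm(dt1), hm(dt1, pop = pop2))
})

test_that("doubling rates doubles attributable deaths exactly", {
  s <- two_admin_setup()
  dt <- dh_raster(matrix(c(1.0, 0.5, 0.3, 0.27), 1, 4), s$g)
  m1 <- mortality_field(s$pop, s$rates, s$hvi, s$admin, s$meta, dt)
  r2 <- as.data.frame(s$rates)
  r2$rate_per_100k <- r2$rate_per_100k * 2
  r2$ci_low <- r2$ci_low * 2; r2$ci_high <- r2$ci_high * 2
  m2 <- mortality_field(s$pop, mortality_table(r2), s$hvi, s$admin, s$meta, dt)
  expect_equal(m2$heat_mort$values, 2 * m1$heat_mort$values, tolerance = 1e-12)
})

test_that("the total-warming variant supports shares above 100 percent", {
  s <- two_admin_setup()
  cls <- pixel_classes()
  classes <- dh_raster(matrix(cls[["deforested"]], 1, 4), s$g)
  dt_defor <- dh_raster(matrix(c(1.0, 1.0, 1.0, 1.0), 1, 4), s$g)
  dt_total <- dh_raster(matrix(c(0.5, 1.0, 2.0, 1.0), 1, 4), s$g)
  md <- mortality_field(s$pop, s$rates, s$hvi, s$admin, s$meta, dt_defor,
                        classes)
  mt <- total_heat_mortality(dt_total, s$pop, s$rates, s$hvi, s$admin, s$meta,
                             classes, valid_mask = !is.na(dt_defor$values))
  # pixel 1: attributed warming exceeds total -> more attributed deaths
  expect_gt(md$heat_mort$values[1, 1], mt$heat_mort$values[1, 1])
  # identical fields -> share exactly 100%
  expect_equal(md$heat_mort$values[1, 2], mt$heat_mort$values[1, 2])
  # zero attributed warming -> zero share
  dt0 <- dh_raster(matrix(0, 1, 4), s$g)
  m0 <- mortality_field(s$pop, s$rates, s$hvi, s$admin, s$meta, dt0, classes)
  expect_equal(sum(m0$heat_mort$values), 0)
})
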