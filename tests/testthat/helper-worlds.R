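# Small synthetic worlds used across the suite. Periods are shortened to one
# calendar year each and two 8-day layers per month to keep the default test
# run fast; the compositing logic is exercised identically.

tiny_grid <- function(n = 60, res = 60) {
  half <- n * res / 3600 / 2
  grid_spec(-half, half, 20, 20 + n * res / 3600, res)
}

make_test_world <- function(seed = 1, n = 60, beta = 0.04, noise = 0.2,
                            ...) {
  generate_world(world_params(
    grid = tiny_grid(n),
    beta = beta, noise_sigma = noise,
    n_loss_clusters = 6, cluster_radius = 0.05,
    n_pop_clusters = 4,
    start_years = 2001, end_years = 2020, layers_per_month = 2,
    seed = seed, ...))
}

# Noise-free world with exact ground truth: no pixel noise, no layer noise,
# no QC flags, no regrowth patches, no non-forest pockets (so control pixels
# have exactly zero loss).
make_exact_world <- function(seed = 3, n = 60, beta = 0.04, ...) {
  make_test_world(seed = seed, n = n, beta = beta, noise = 0,
                  layer_noise_sd = 0, qc_bad_frac = 0,
                  n_nonforest_pockets = 0, n_gain_patches = 0, ...)
}

# Two admin units on a four-cell strip, with country- and continent-level
# vulnerability indices.
two_admin_setup <- function() {
  g <- grid_spec(0, 1, 0, 4, 3600)
  pop <- dh_raster(matrix(c(100000, 0, 2000, 50000), 1, 4), g)
  admin <- dh_raster(matrix(c(1, 1, 2, 2), 1, 4), g)
  rates <- mortality_table(data.frame(
    admin_id = c(1, 2), rate_per_100k = c(700, 500),
    ci_low = c(600, 450), ci_high = c(800, 560)))
  meta <- data.frame(admin_id = c(1, 2),
                     country = c("Vietnam", "nowhere"),
                     continent = c("Southeast Asia", "South America"))
  hvi <- hvi_table(data.frame(key = c("Vietnam", "South America",
                                      "Southeast Asia"),
                              hvi_pct_per_C = c(5.29, 2.34, 5.29)))
  list(g = g, pop = pop, admin = admin, rates = rates, meta = meta, hvi = hvi)
}

# Minimal hand-built landscape: a deforested block in a forest matrix, for
# constructed boundary cases. Returns co-gridded rasters.
block_landscape <- function(n = 11, res = 180, loss_rc = NULL,
                            loss_pct = 20, cover = 80) {
  g <- grid_spec(-n * res / 7200, n * res / 7200, 30, 30 + n * res / 3600, res)
  c01 <- dh_raster(matrix(cover, n, n), g)
  ch <- matrix(0, n, n)
  if (is.null(loss_rc)) loss_rc <- cbind(ceiling(n / 2), ceiling(n / 2))
  ch[loss_rc] <- -loss_pct
  change <- dh_raster(ch, g)
  gain <- dh_raster(matrix(0, n, n), g)
  classes <- classify_pixels(c01, change, gain)
  elev <- dh_raster(matrix(100, n, n), g)
  list(grid = g, c2001 = c01, change = change, gain = gain,
       classes = classes, elevation = elev)
}
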