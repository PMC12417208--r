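#' Parameters of a synthetic tropical landscape
#'
#' Describes a complete synthetic input world with known ground truth: a
#' smooth background warming trend, clustered forest loss imprinting a
#' warming signal proportional to percentage-point loss (`beta`), independent
#' per-pixel noise on the temperature change, clustered population, vertical
#' macro-regions split into admin bands, per-admin mortality rates with 95%
#' CIs, and per-region heat vulnerability indices. The defaults are the
#' desk-scale world used throughout the test suite: a 2.5 x 2.5 degree
#' equatorial domain of 300 x 300 cells at 30 arc-seconds with 15 loss
#' clusters, three regions of three admin units each, a 0.2 degree C
#' constant background trend, 0.04 degC per percentage point of loss, and
#' 0.2 degC temperature-change noise.
#'
#' @param grid Analysis [grid_spec()].
#' @param beta True warming per percentage point of forest loss (degC/%-pt).
#' @param trend Background temperature-change field: list with `type` one of
#'   `"constant"` (field = `value`), `"gradient"` (smooth plane across the
#'   domain from `value` to `value + range`), or `"elevation"` (field =
#'   `value + lapse * (elevation - domain mean elevation)`).
#' @param noise_sigma Standard deviation of per-pixel temperature-change
#'   noise (degC).
#' @param n_loss_clusters,cluster_radius,cluster_peak Number of circular
#'   forest-loss clusters, their radius in degrees, and the range of their
#'   peak clearing probability.
#' @param fine_factor Fine (pre-regrid) grid refinement factor for the
#'   forest fields.
#' @param n_regions,n_admins Macro-regions (vertical longitude blocks) and
#'   admin bands per region.
#' @param rate_range,rate_ci_frac Range of per-admin annual non-accidental
#'   mortality rates (per 100,000) and the half-width of their 95% CI as a
#'   fraction of the rate.
#' @param hvi_range Range of per-region heat vulnerability indices
#'   (%p/degC).
#' @param pop_meanlog,pop_sdlog Log-normal background population per cell.
#' @param n_pop_clusters,pop_cluster_scale Population settlement clusters
#'   and their scale multiplier.
#' @param start_years,end_years Calendar years of the two averaging periods.
#' @param layers_per_month 8-day layers generated per month.
#' @param layer_noise_sd Independent per-layer LST noise (kelvin).
#' @param qc_bad_frac Fraction of observations given failing QC values (and
#'   a +2 K bias, so unscreened use is detectable).
#' @param lst_factor Integer >= 1; LST native grid coarsening relative to
#'   the analysis grid (1 = co-gridded).
#' @param n_gain_patches Circular regrowth patches with a ~70 %-pt extent
#'   increase, exercising the gain exclusion.
#' @param elev_amplitude Amplitude of the smooth elevation field (m).
#' @param seed Integer seed; identical seeds give bit-identical worlds.
#' @return An object of class `world_params`.
#' @export
world_params <- function(grid = grid_spec(-1.25, 1.25, 20, 22.5, 30),
                         beta = 0.04,
                         trend = list(type = "constant", value = 0.2),
                         noise_sigma = 0.2,
                         n_loss_clusters = 15,
                         cluster_radius = 0.05,
                         cluster_peak = c(0.4, 0.95),
                         fine_factor = 2L,
                         n_regions = 3L,
                         n_admins = 3L,
                         rate_range = c(600, 900),
                         rate_ci_frac = 0.12,
                         hvi_range = c(2.2, 5.5),
                         pop_meanlog = log(10),
                         pop_sdlog = 1.2,
                         n_pop_clusters = 10,
                         pop_cluster_scale = 40,
                         start_years = 2001:2003,
                         end_years = 2018:2020,
                         layers_per_month = 4L,
                         layer_noise_sd = 0.3,
                         qc_bad_frac = 0.08,
                         lst_factor = 1L,
                         n_gain_patches = 2L,
                         n_nonforest_pockets = 3L,
                         elev_amplitude = 80,
                         seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), beta >= 0, noise_sigma >= 0,
            fine_factor >= 1, n_regions >= 1, n_admins >= 1,
            layers_per_month >= 1, lst_factor >= 1,
            trend$type %in% c("constant", "gradient", "elevation"))
  span_lat <- grid$lat_max - grid$lat_min
  span_lon <- grid$lon_max - grid$lon_min
  if (2 * cluster_radius > min(span_lat, span_lon)) {
    stop("cluster radius exceeds the grid extent")
  }
  structure(as.list(environment()), class = "world_params")
}

# Smooth random field in [-1, 1]-ish: sum of K random cosine waves over the
# unit square, normalized to unit max amplitude.
smooth_field <- function(nr, nc, k = 4, max_freq = 3) {
  x <- (seq_len(nc) - 0.5) / nc
  y <- (seq_len(nr) - 0.5) / nr
  f <- matrix(0, nr, nc)
  for (i in seq_len(k)) {
    p <- stats::runif(1, 0.5, max_freq)
    q <- stats::runif(1, 0.5, max_freq)
    phi <- stats::runif(2, 0, 2 * pi)
    a <- stats::runif(1, 0.3, 1)
    f <- f + a * outer(cos(2 * pi * q * y + phi[1]),
                       cos(2 * pi * p * x + phi[2]))
  }
  f / max(abs(f))
}

# Distance (degrees, Euclidean in degree space -- generator-internal) from
# every cell center to a point.
center_distance <- function(grid, lat0, lon0) {
  sqrt(outer((lat_centers(grid) - lat0)^2, rep(1, grid$ncol)) +
         outer(rep(1, grid$nrow), (lon_centers(grid) - lon0)^2))
}

#' Generate a complete synthetic input world
#'
#' Builds every input the pipeline consumes -- fine-resolution forest cover
#' and loss-year rasters, forest-extent rasters, quality-flagged 8-day LST
#' stacks for the start and end periods, elevation, population, admin and
#' region rasters, mortality-rate and HVI tables -- together with the ground
#' truth implied by the construction (`dt = trend + beta * loss_pct +
#' noise`). Deforestation clusters sit in a continuous forest matrix, so in
#' default configurations essentially all treated pixels find controls at
#' the primary radius.
#'
#' @param params A [world_params()].
#' @return An object of class `synthetic_world`; see Details. Ground truth
#'   (`$truth`) holds `true_dt_defor` (`beta * loss_pct` on treated pixels),
#'   `dt_expected` (noise-free total change), `true_exposed_pop` and
#'   `true_heat_mort` computed from the true warming through the mortality
#'   chain.
#' @export
generate_world <- function(params = world_params()) {
  stopifnot(inherits(params, "world_params"))
  p <- params
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(p$seed)

  g <- p$grid
  fg <- grid_spec(g$lat_min, g$lat_max, g$lon_min, g$lon_max,
                  g$resolution_arcsec / p$fine_factor)

  ## --- forest cover and loss (fine grid) ---------------------------------
  base_cover <- 65 + 20 * smooth_field(fg$nrow, fg$ncol)
  cover2000 <- pmin(pmax(base_cover + stats::rnorm(fg$nrow * fg$ncol, 0, 3), 0), 95)
  cover2000 <- matrix(cover2000, fg$nrow, fg$ncol)
  # a few non-forest pockets
  for (i in seq_len(p$n_nonforest_pockets)) {
    lat0 <- stats::runif(1, g$lat_min, g$lat_max)
    lon0 <- stats::runif(1, g$lon_min, g$lon_max)
    d <- center_distance(fg, lat0, lon0)
    r <- stats::runif(1, 0.05, 0.15)
    cover2000[d < r] <- stats::runif(sum(d < r), 0, 8)
  }

  margin <- p$cluster_radius
  loss_year <- matrix(0, fg$nrow, fg$ncol)
  cluster_centers <- data.frame(lat = numeric(0), lon = numeric(0))
  for (i in seq_len(p$n_loss_clusters)) {
    lat0 <- stats::runif(1, g$lat_min + margin, g$lat_max - margin)
    lon0 <- stats::runif(1, g$lon_min + margin, g$lon_max - margin)
    cluster_centers <- rbind(cluster_centers, data.frame(lat = lat0, lon = lon0))
    d <- center_distance(fg, lat0, lon0)
    peak <- stats::runif(1, p$cluster_peak[1], p$cluster_peak[2])
    prob <- peak * exp(-(d / (p$cluster_radius / 1.5))^2)
    prob[d > p$cluster_radius] <- 0  # loss strictly inside the cluster circle
    hit <- stats::runif(fg$nrow * fg$ncol) < prob
    yr <- sample(2002:2019, 1)
    sel <- hit & loss_year == 0
    loss_year[sel] <- yr
  }
  cover2000_fine <- dh_raster(cover2000, fg)
  loss_year_fine <- dh_raster(loss_year, fg)

  c2001 <- regrid_area_weighted(annual_cover(cover2000_fine, loss_year_fine, 2001), g)
  c2020 <- regrid_area_weighted(annual_cover(cover2000_fine, loss_year_fine, 2020), g)
  change <- cover_change(c2001, c2020)
  loss_pct <- pmax(-change$values, 0)

  ## --- forest extent and regrowth patches --------------------------------
  extent2000_fine <- cover2000_fine
  ext2020 <- annual_cover(cover2000_fine, loss_year_fine, 2020)$values
  for (i in seq_len(p$n_gain_patches)) {
    lat0 <- stats::runif(1, g$lat_min + margin, g$lat_max - margin)
    lon0 <- stats::runif(1, g$lon_min + margin, g$lon_max - margin)
    d <- center_distance(fg, lat0, lon0)
    sel <- d < 0.04
    ext2020[sel] <- pmin(extent2000_fine$values[sel] + 70, 100)
  }
  extent2000 <- regrid_area_weighted(extent2000_fine, g)
  extent2020 <- regrid_area_weighted(dh_raster(ext2020, fg), g)

  ## --- elevation and background trend ------------------------------------
  elevation <- dh_raster(
    200 + p$elev_amplitude * smooth_field(g$nrow, g$ncol) +
      matrix(stats::rnorm(g$nrow * g$ncol, 0, 2), g$nrow, g$ncol), g)
  trend_field <- switch(p$trend$type,
    constant = matrix(p$trend$value, g$nrow, g$ncol),
    gradient = {
      rng <- if (!is.null(p$trend$range)) p$trend$range else 0.3
      p$trend$value + rng * outer(seq(0, 1, length.out = g$nrow),
                                  seq(0, 1, length.out = g$ncol), function(a, b) (a + b) / 2)
    },
    elevation = {
      lapse <- if (!is.null(p$trend$lapse)) p$trend$lapse else 0.002
      p$trend$value + lapse * (elevation$values - mean(elevation$values))
    })

  dt_expected <- trend_field + p$beta * loss_pct
  dt_noise <- matrix(stats::rnorm(g$nrow * g$ncol, 0, p$noise_sigma),
                     g$nrow, g$ncol)
  dt_realized <- dt_expected + dt_noise

  ## --- LST stacks with QC fields -----------------------------------------
  lg <- if (p$lst_factor == 1) g else
    grid_spec(g$lat_min, g$lat_max, g$lon_min, g$lon_max,
              g$resolution_arcsec * p$lst_factor)
  to_native <- function(m) {
    if (p$lst_factor == 1) return(m)
    regrid_area_weighted(dh_raster(m, g), lg)$values
  }
  base_lst <- 300 + 3 * smooth_field(lg$nrow, lg$ncol)
  dt_native <- to_native(dt_realized)
  seasonal <- 2 * cos(2 * pi * (seq_len(12) - 1) / 12)

  make_stack <- function(years, offset) {
    dates <- as.Date(unlist(lapply(years, function(y) {
      unlist(lapply(1:12, function(m) {
        sprintf("%d-%02d-%02d", y, m,
                round(seq(1, 25, length.out = p$layers_per_month)))
      }))
    })), format = "%Y-%m-%d")
    nl <- length(dates)
    lst <- array(NA_real_, c(lg$nrow, lg$ncol, nl))
    months <- as.integer(format(dates, "%m"))
    ncell <- lg$nrow * lg$ncol
    for (k in seq_len(nl)) {
      layer <- base_lst + seasonal[months[k]] + offset
      if (p$layer_noise_sd > 0) {
        layer <- layer + matrix(stats::rnorm(ncell, 0, p$layer_noise_sd),
                                lg$nrow, lg$ncol)
      }
      lst[, , k] <- layer
    }
    emis <- array(0.01, dim(lst))
    lerr <- array(0.5, dim(lst))
    if (p$qc_bad_frac > 0) {
      bad <- stats::runif(length(lst)) < p$qc_bad_frac
      emis[bad] <- 0.03
      lst[bad] <- lst[bad] + 2  # biased when quality screening is skipped
      bad2 <- stats::runif(length(lst)) < p$qc_bad_frac / 2
      lerr[bad2] <- 1.5
      lst[bad2] <- lst[bad2] + 2
    }
    lst_stack(lst, dates, lg, emissivity_error = emis, lst_error = lerr)
  }
  lst_start <- make_stack(p$start_years, 0)
  lst_end <- make_stack(p$end_years, dt_native)

  ## --- population, admin units, regions ----------------------------------
  pop <- exp(stats::rnorm(g$nrow * g$ncol, p$pop_meanlog, p$pop_sdlog))
  pop <- matrix(pop, g$nrow, g$ncol)
  for (i in seq_len(p$n_pop_clusters)) {
    if (i <= nrow(cluster_centers) && i %% 2 == 0) {
      lat0 <- cluster_centers$lat[i]; lon0 <- cluster_centers$lon[i]
    } else {
      lat0 <- stats::runif(1, g$lat_min, g$lat_max)
      lon0 <- stats::runif(1, g$lon_min, g$lon_max)
    }
    d <- center_distance(g, lat0, lon0)
    pop <- pop * (1 + p$pop_cluster_scale * exp(-(d / 0.08)^2))
  }
  pop <- round(pop)
  population <- dh_raster(pop, g)

  lon_idx <- matrix(rep(seq_len(g$ncol), each = g$nrow), g$nrow, g$ncol)
  lat_idx <- matrix(rep(seq_len(g$nrow), g$ncol), g$nrow, g$ncol)
  region <- pmin(ceiling(lon_idx / (g$ncol / p$n_regions)), p$n_regions)
  band <- pmin(ceiling(lat_idx / (g$nrow / p$n_admins)), p$n_admins)
  admin <- (region - 1L) * p$n_admins + band
  regions <- dh_raster(region, g)
  admin_r <- dh_raster(admin, g)

  n_admin_total <- p$n_regions * p$n_admins
  rate <- stats::runif(n_admin_total, p$rate_range[1], p$rate_range[2])
  rates <- mortality_table(data.frame(
    admin_id = seq_len(n_admin_total),
    rate_per_100k = rate,
    ci_low = rate * (1 - p$rate_ci_frac),
    ci_high = rate * (1 + p$rate_ci_frac),
    year = 2019))
  admin_meta <- data.frame(
    admin_id = seq_len(n_admin_total),
    country = paste0("country_", seq_len(n_admin_total)),
    continent = paste0("region_", rep(seq_len(p$n_regions), each = p$n_admins)))
  hvi <- hvi_table(data.frame(
    key = paste0("region_", seq_len(p$n_regions)),
    hvi_pct_per_C = stats::runif(p$n_regions, p$hvi_range[1], p$hvi_range[2]),
    basis = "non_accidental"))

  ## --- ground truth -------------------------------------------------------
  gain <- extent_gain_mask(extent2000, extent2020)
  classes <- classify_pixels(c2001, change, gain)
  defor <- classes$values == pixel_classes()[["deforested"]]
  true_dtd <- matrix(NA_real_, g$nrow, g$ncol)
  true_dtd[defor] <- p$beta * loss_pct[defor]
  true_dt_defor <- dh_raster(true_dtd, g)
  true_mort <- mortality_field(population, rates, hvi, admin_r, admin_meta,
                               true_dt_defor, classes)
  truth <- list(
    true_dt_defor = true_dt_defor,
    dt_expected = dh_raster(dt_expected, g),
    trend_field = dh_raster(trend_field, g),
    loss_pct = dh_raster(loss_pct, g),
    true_exposed_pop = sum(pop[defor & !is.na(true_dtd) & true_dtd > 0]),
    true_heat_mort = sum(true_mort$heat_mort$values[defor], na.rm = TRUE))

  structure(list(
    grid = g, fine_grid = fg,
    cover2000_fine = cover2000_fine, loss_year_fine = loss_year_fine,
    c2001 = c2001, c2020 = c2020, change = change,
    extent2000 = extent2000, extent2020 = extent2020,
    elevation = elevation, population = population,
    admin = admin_r, regions = regions,
    lst_start = lst_start, lst_end = lst_end,
    rates = rates, hvi = hvi, admin_meta = admin_meta,
    classes_truth = classes,
    truth = truth, params = p
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells, beta = %g degC/%%-pt, noise = %g degC, seed = %d\n",
              x$grid$nrow, x$grid$ncol, x$params$beta, x$params$noise_sigma,
              x$params$seed))
  invisible(x)
}

#' Recovery metrics against ground truth
#'
#' Compares the pipeline's attributed warming (and optionally exposure and
#' mortality summaries) with the generator's ground truth.
#'
#' @param world A `synthetic_world`.
#' @param attribution An `attribution_result` on the same grid.
#' @param exposure Optional `exposure_summary`.
#' @param heat_mort_total Optional scalar: estimated attributable deaths.
#' @return Data frame with `bias_dt_defor`, `rmse_dt_defor`, `n_compared`,
#'   and when supplied, `rel_err_exposed_pop`, `rel_err_heat_mort`.
#' @export
recovery_metrics <- function(world, attribution, exposure = NULL,
                             heat_mort_total = NULL) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(attribution, "attribution_result"))
  truth <- world$truth$true_dt_defor
  est <- attribution$dt_defor
  stop_if_grid_mismatch(truth, est, "truth and estimate")
  both <- !is.na(truth$values) & !is.na(est$values)
  err <- est$values[both] - truth$values[both]
  out <- data.frame(
    bias_dt_defor = mean(err),
    rmse_dt_defor = sqrt(mean(err^2)),
    n_compared = sum(both))
  if (!is.null(exposure)) {
    out$rel_err_exposed_pop <-
      (exposure$pop_exposed - world$truth$true_exposed_pop) /
      max(world$truth$true_exposed_pop, 1)
  }
  if (!is.null(heat_mort_total)) {
    out$rel_err_heat_mort <-
      (heat_mort_total - world$truth$true_heat_mort) /
      max(world$truth$true_heat_mort, 1e-12)
  }
  out
}
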