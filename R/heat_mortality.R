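#' Heat vulnerability index table
#'
#' An HVI is the percentage-point increase in excess mortality per 1 degree C
#' of warming (%p/degC). Indices are resolved per administrative unit by
#' walking a fallback chain country -> continent; proxy assignments (for
#' example a neighbouring country's index standing in where none exists) are
#' expressed by entering the proxy value under the country key. A default
#' table with the published continental values (South America 2.34, also
#' applied to Africa as the lowest continental average; Southeast Asia 5.29)
#' ships in `inst/extdata/hvi_defaults.csv`.
#'
#' @param df Data frame with columns `key`, `hvi_pct_per_C`, and optionally
#'   `basis` (`"non_accidental"` or `"all_cause"`) and `source_note`.
#' @return A validated `hvi_table` (data frame).
#' @export
hvi_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("key", "hvi_pct_per_C") %in% names(df)))
  if (any(is.na(df$hvi_pct_per_C)) || any(df$hvi_pct_per_C <= 0)) {
    stop("heat vulnerability indices must be positive")
  }
  if (anyDuplicated(df$key)) stop("duplicate HVI keys")
  if (is.null(df$basis)) df$basis <- "non_accidental"
  class(df) <- c("hvi_table", "data.frame")
  df
}

#' @rdname hvi_table
#' @param path CSV file path (defaults to the packaged table).
#' @export
read_hvi_table <- function(path = system.file("extdata", "hvi_defaults.csv",
                                              package = "deforheat")) {
  hvi_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Per-admin mortality rate table
#'
#' Annual non-accidental (or all-cause) mortality rates per 100,000 persons
#' with their 95% confidence interval.
#'
#' @param df Data frame with columns `admin_id`, `rate_per_100k`, `ci_low`,
#'   `ci_high` (and optionally `country`, `continent`, `year`).
#' @return A validated `mortality_table` (data frame).
#' @export
mortality_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("admin_id", "rate_per_100k", "ci_low", "ci_high") %in% names(df)))
  with(df, {
    if (any(ci_low <= 0) || any(ci_low > rate_per_100k) ||
        any(rate_per_100k > ci_high)) {
      stop("mortality table must satisfy 0 < ci_low <= rate <= ci_high")
    }
  })
  if (anyDuplicated(df$admin_id)) stop("duplicate admin_id in mortality table")
  class(df) <- c("mortality_table", "data.frame")
  df
}

#' @rdname mortality_table
#' @param path CSV file path.
#' @export
read_mortality_table <- function(path) {
  mortality_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Resolve heat vulnerability indices for admin units
#'
#' @param admin_meta Data frame mapping `admin_id` to `country` and
#'   `continent`.
#' @param hvi An [hvi_table()].
#' @return Named numeric vector of HVIs keyed by `admin_id` (as character).
#'   Resolution order: country key, then continent key; unresolvable units
#'   are an error.
#' @export
hvi_for_admin <- function(admin_meta, hvi) {
  stopifnot(is.data.frame(admin_meta),
            all(c("admin_id", "country", "continent") %in% names(admin_meta)))
  out <- numeric(nrow(admin_meta))
  for (i in seq_len(nrow(admin_meta))) {
    k <- match(admin_meta$country[i], hvi$key)
    if (is.na(k)) k <- match(admin_meta$continent[i], hvi$key)
    if (is.na(k)) {
      stop(sprintf("no heat vulnerability index resolvable for admin '%s' (country '%s', continent '%s')",
                   admin_meta$admin_id[i], admin_meta$country[i],
                   admin_meta$continent[i]))
    }
    out[i] <- hvi$hvi_pct_per_C[k]
  }
  names(out) <- as.character(admin_meta$admin_id)
  out
}

rate_lookup <- function(rates, bound = c("central", "low", "high")) {
  bound <- match.arg(bound)
  col <- switch(bound, central = "rate_per_100k", low = "ci_low",
                high = "ci_high")
  stats::setNames(rates[[col]], as.character(rates$admin_id))
}

#' Baseline non-accidental mortality per pixel
#'
#' Deaths per year = population x rate / 100,000, with rates looked up by
#' admin unit. Every populated pixel must map to a rate.
#'
#' @param pop [dh_raster()] of population count.
#' @param rates A [mortality_table()].
#' @param admin [dh_raster()] of integer admin IDs.
#' @param bound Which rate column to use: `"central"` (default), `"low"`, or
#'   `"high"`.
#' @return A [dh_raster()] of deaths per year.
#' @export
baseline_mortality <- function(pop, rates, admin, bound = "central") {
  stop_if_grid_mismatch(pop, admin, "population and admin rasters")
  rt <- rate_lookup(rates, bound)
  ids <- admin$values
  p <- pop$values
  populated <- !is.na(p) & p > 0
  key <- as.character(ids)
  miss <- populated & (is.na(ids) | !(key %in% names(rt)))
  if (any(miss)) {
    bad <- unique(key[miss])
    stop(sprintf("populated pixels with unmapped admin ID(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  rate <- matrix(rt[key], nrow(p), ncol(p))
  out <- p * rate / 1e5
  out[is.na(p)] <- NA_real_
  out[!is.na(p) & p == 0] <- 0
  dh_raster(out, pop$grid)
}

#' Fractional increase in heat-attributable mortality
#'
#' `f = (HVI/100) x dT` on deforested pixels with strictly positive
#' attributed warming; zero elsewhere (negative-warming pixels contribute no
#' attributable deaths -- cooling benefits are out of scope). With
#' `literal_percent = TRUE` the increase is kept in raw percentage points
#' (`f = HVI x dT`), reproducing a literal reading of the published formula
#' for comparison.
#'
#' @param dt_defor [dh_raster()] of attributed warming (degrees C).
#' @param hvi An [hvi_table()].
#' @param admin [dh_raster()] of admin IDs.
#' @param admin_meta Data frame mapping `admin_id` to `country`/`continent`.
#' @param classes Optional [dh_raster()] of [pixel_classes()] codes; when
#'   supplied, `f` is restricted to deforested pixels.
#' @param literal_percent Logical (default `FALSE`).
#' @return A [dh_raster()] of the fractional increase `f` (dimensionless).
#' @export
pct_increase <- function(dt_defor, hvi, admin, admin_meta, classes = NULL,
                         literal_percent = FALSE) {
  stop_if_grid_mismatch(dt_defor, admin, "dt and admin rasters")
  hv <- hvi_for_admin(admin_meta, hvi)
  ids <- as.character(admin$values)
  active <- !is.na(dt_defor$values) & dt_defor$values > 0
  if (!is.null(classes)) {
    stop_if_grid_mismatch(dt_defor, classes, "dt and class rasters")
    active <- active & !is.na(classes$values) &
      classes$values == pixel_classes()[["deforested"]]
  }
  miss <- active & (is.na(admin$values) | !(ids %in% names(hv)))
  if (any(miss)) stop("warming pixels with unresolvable heat vulnerability index")
  h <- matrix(hv[ids], nrow(dt_defor$values), ncol(dt_defor$values))
  scale <- if (literal_percent) 1 else 1 / 100
  f <- ifelse(active, h * scale * dt_defor$values, 0)
  dh_raster(f, dt_defor$grid)
}

#' Counterfactual mortality absent the attributed warming
#'
#' `cf = baseline / (1 + f)`: the deaths that would occur without the
#' warming-attributable excess already embedded in the observed rates.
#'
#' @param baseline [dh_raster()] from [baseline_mortality()].
#' @param f [dh_raster()] from [pct_increase()].
#' @return A [dh_raster()] of deaths per year.
#' @export
counterfactual_mortality <- function(baseline, f) {
  stop_if_grid_mismatch(baseline, f, "baseline and f rasters")
  if (any(f$values <= -1, na.rm = TRUE)) {
    stop("fractional increase below -1 is impossible")
  }
  dh_raster(baseline$values / (1 + f$values), baseline$grid)
}

#' Warming-attributable mortality
#'
#' `heat_mort = baseline - counterfactual`, algebraically equal to
#' `baseline x f / (1 + f)`; the attributable fraction `f/(1+f)` always lies
#' in \[0, 1).
#'
#' @param baseline,cf [dh_raster()]s.
#' @return A [dh_raster()] of attributable deaths per year.
#' @export
attributable_mortality <- function(baseline, cf) {
  stop_if_grid_mismatch(baseline, cf, "baseline and counterfactual rasters")
  dh_raster(baseline$values - cf$values, baseline$grid)
}

mortality_field <- function(pop, rates, hvi, admin, admin_meta, dt,
                            classes = NULL, bound = "central",
                            literal_percent = FALSE) {
  base <- baseline_mortality(pop, rates, admin, bound)
  f <- pct_increase(dt, hvi, admin, admin_meta, classes, literal_percent)
  cf <- counterfactual_mortality(base, f)
  hm <- attributable_mortality(base, cf)
  structure(list(nonacc_mort = base, pct_increase = f, cf_mort = cf,
                 heat_mort = hm, bound = bound),
            class = "mortality_field")
}

#' Attributable mortality with confidence bounds
#'
#' Evaluates the full baseline -> fractional increase -> counterfactual ->
#' attributable chain three times, with the mortality rate set to its 95% CI
#' low, central and high values. The chain is linear in the rate, so the
#' bounds bracket the central estimate exactly.
#'
#' @inheritParams pct_increase
#' @param pop [dh_raster()] of population count.
#' @param rates A [mortality_table()].
#' @return List of three `mortality_field`s named `low`, `central`, `high`.
#' @export
mortality_with_bounds <- function(pop, rates, hvi, admin, admin_meta, dt,
                                  classes = NULL, literal_percent = FALSE) {
  out <- lapply(c(low = "low", central = "central", high = "high"),
                function(b) mortality_field(pop, rates, hvi, admin, admin_meta,
                                            dt, classes, b, literal_percent))
  out
}

#' Total heat-attributable mortality from the full warming field
#'
#' Runs the same mortality chain on the total (not deforestation-only)
#' temperature change, restricted to the same deforested pixel set with the
#' same positive-warming rule, supporting the share statistic
#' attributable/total. Where controls cooled on balance, the attributed
#' warming exceeds the total warming and the share can exceed 100%.
#'
#' @inheritParams mortality_with_bounds
#' @param dt_total [dh_raster()] of total temperature change.
#' @param valid_mask Optional logical matrix restricting to pixels where the
#'   attributed field is defined (so both variants share a pixel set).
#' @return A `mortality_field` for the central rate.
#' @export
total_heat_mortality <- function(dt_total, pop, rates, hvi, admin, admin_meta,
                                 classes = NULL, valid_mask = NULL,
                                 literal_percent = FALSE, bound = "central") {
  dt <- dt_total
  if (!is.null(valid_mask)) {
    v <- dt$values
    v[!valid_mask] <- NA_real_
    dt <- dh_raster(v, dt$grid)
  }
  mortality_field(pop, rates, hvi, admin, admin_meta, dt, classes, bound,
                  literal_percent)
}
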