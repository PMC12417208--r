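#' Aggregate a pixel field by admin unit
#'
#' One row per admin ID present on valid pixels; units with no valid pixel
#' are absent from the table (they render as no-data in maps). Sums are
#' exact pixel sums -- no double counting, and splitting a unit into two IDs
#' preserves the total.
#'
#' @param field [dh_raster()] to aggregate.
#' @param admin [dh_raster()] of integer admin IDs.
#' @param statistic `"sum"`, `"popwgt_mean"` or `"areawgt_mean"`.
#' @param pop [dh_raster()] of population (required for `popwgt_mean`).
#' @param mask Optional logical matrix restricting the pixel set.
#' @return Data frame with columns `admin_id`, `value`, `n_pixels`.
#' @export
aggregate_by_admin <- function(field, admin,
                               statistic = c("sum", "popwgt_mean", "areawgt_mean"),
                               pop = NULL, mask = NULL) {
  statistic <- match.arg(statistic)
  stop_if_grid_mismatch(field, admin, "field and admin rasters")
  if (statistic == "popwgt_mean" && is.null(pop)) {
    stop("popwgt_mean requires a population raster")
  }
  sel <- !is.na(field$values) & !is.na(admin$values)
  if (!is.null(mask)) sel <- sel & mask
  if (statistic == "popwgt_mean") sel <- sel & !is.na(pop$values)
  ids <- sort(unique(admin$values[sel]))
  w <- switch(statistic,
              sum = NULL,
              popwgt_mean = pop$values,
              areawgt_mean = cell_area_weights(field$grid)$weight)
  rows <- lapply(ids, function(id) {
    s <- sel & admin$values == id
    v <- field$values[s]
    val <- switch(statistic,
                  sum = sum(v),
                  popwgt_mean = if (sum(w[s]) > 0) sum(w[s] * v) / sum(w[s])
                                else NA_real_,
                  areawgt_mean = sum(w[s] * v) / sum(w[s]))
    data.frame(admin_id = id, value = val, n_pixels = sum(s))
  })
  do.call(rbind, rows)
}

#' Mortality rate per 100,000 people
#'
#' @param deaths Deaths per year (scalar or vector).
#' @param pop Population at risk; must be strictly positive.
#' @return `deaths / pop * 1e5`, full precision (reporting rounds to the
#'   nearest whole number at presentation only).
#' @export
rate_per_100k <- function(deaths, pop) {
  if (any(pop <= 0)) stop("rate per 100,000 undefined for non-positive population")
  deaths / pop * 1e5
}

#' Share of total warming attributable to deforestation
#'
#' @param defor Attributed warming (degrees C).
#' @param total Total warming (degrees C); must be nonzero.
#' @return `100 * defor / total`, full precision (reporting rounds to a
#'   whole percent). The share can exceed 100 where controls cooled.
#' @export
warming_shares <- function(defor, total) {
  if (any(total == 0)) stop("warming share undefined for zero total warming")
  100 * defor / total
}

#' Build a per-region summary table
#'
#' Aggregates the pixel-level fields into one row per region plus a pooled
#' row over all regions, mirroring the tables of a regional assessment:
#' population in forest-loss locations, population exposed, attributable
#' deaths (central, low, high), mortality rates, shares of total heat
#' mortality and of baseline non-accidental mortality, and area-/population-
#' weighted warming (total, non-deforested, attributed). The pooled row is
#' computed from the pooled pixel set, not by averaging region rows, so
#' deaths and population are exactly additive.
#'
#' @param regions [dh_raster()] of region codes.
#' @param region_names Optional named character vector mapping codes to
#'   labels.
#' @param classes [dh_raster()] of [pixel_classes()] codes.
#' @param dt [dh_raster()] of total temperature change.
#' @param attribution An `attribution_result` from [attribute_warming()].
#' @param pop [dh_raster()] of population.
#' @param mortality List of `mortality_field`s from
#'   [mortality_with_bounds()].
#' @param total_mortality A `mortality_field` from [total_heat_mortality()].
#' @param pooled_label Label for the pooled row (default `"all"`).
#' @return Data frame of class `region_report`, one row per region plus the
#'   pooled row, full precision; see [format_region_report()] for the
#'   rounded presentation.
#' @export
region_report <- function(regions, classes, dt, attribution, pop, mortality,
                          total_mortality = NULL, region_names = NULL,
                          pooled_label = "all") {
  stop_if_grid_mismatch(regions, classes, "region and class rasters")
  cls <- pixel_classes()
  dtd <- attribution$dt_defor
  valid <- !is.na(classes$values) & classes$values == cls[["deforested"]] &
    !is.na(dtd$values) & !is.na(pop$values)
  nondef <- !is.na(classes$values) & classes$values == cls[["non_deforested"]]
  ids <- sort(unique(regions$values[!is.na(regions$values)]))
  scopes <- c(as.list(ids), list(NULL))  # NULL = pooled
  aw <- cell_area_weights(dt$grid)

  one_row <- function(id) {
    inreg <- if (is.null(id)) !is.na(regions$values)
             else !is.na(regions$values) & regions$values == id
    v <- valid & inreg
    nd <- nondef & inreg & !is.na(dt$values)
    pfl <- sum(pop$values[v])
    pexp <- sum(pop$values[v & dtd$values > 0])
    deaths <- vapply(c("central", "low", "high"), function(b)
      sum(mortality[[b]]$heat_mort$values[v], na.rm = TRUE), numeric(1))
    total_deaths <- if (!is.null(total_mortality))
      sum(total_mortality$heat_mort$values[v], na.rm = TRUE) else NA_real_
    baseline_deaths <- sum(mortality$central$nonacc_mort$values[v], na.rm = TRUE)
    wmean <- function(field, m) {
      if (!any(m)) return(NA_real_)
      sum(aw$weight[m] * field[m]) / sum(aw$weight[m])
    }
    pmean <- function(field, m) {
      tp <- sum(pop$values[m & !is.na(pop$values)])
      if (tp <= 0) return(NA_real_)
      m2 <- m & !is.na(pop$values)
      sum(pop$values[m2] * field[m2]) / tp
    }
    label <- if (is.null(id)) pooled_label
             else if (!is.null(region_names) &&
                      as.character(id) %in% names(region_names))
               region_names[[as.character(id)]] else as.character(id)
    data.frame(
      scope = label,
      pop_forest_loss = pfl,
      pop_exposed = pexp,
      deaths_central = deaths[["central"]],
      deaths_low = deaths[["low"]],
      deaths_high = deaths[["high"]],
      rate_per_100k = if (pfl > 0) rate_per_100k(deaths[["central"]], pfl)
                      else NA_real_,
      share_of_total_heat_mortality =
        if (!is.na(total_deaths) && total_deaths != 0)
          100 * deaths[["central"]] / total_deaths else NA_real_,
      share_of_nonacc_mortality =
        if (baseline_deaths > 0) 100 * deaths[["central"]] / baseline_deaths
        else NA_real_,
      areawgt_dt_total = wmean(dt$values, v),
      popwgt_dt_total = pmean(dt$values, v),
      areawgt_dt_nondefor = wmean(dt$values, nd),
      popwgt_dt_nondefor = pmean(dt$values, nd),
      areawgt_dt_defor = wmean(dtd$values, v),
      popwgt_dt_defor = pmean(dtd$values, v)
    )
  }
  out <- do.call(rbind, lapply(scopes, one_row))
  class(out) <- c("region_report", "data.frame")
  out
}

#' Rounded presentation of a region report
#'
#' Applies the reporting rounding contract: deaths to the nearest ten, rates
#' and shares to the nearest whole number, warming to two decimals. Internal
#' pipelines keep full precision; rounding happens only here.
#'
#' @param report A `region_report` from [region_report()].
#' @return Data frame of formatted character columns.
#' @export
format_region_report <- function(report) {
  stopifnot(inherits(report, "region_report"))
  data.frame(
    scope = report$scope,
    pop_forest_loss = sprintf("%.3g", report$pop_forest_loss),
    pop_exposed = sprintf("%.3g", report$pop_exposed),
    deaths = sprintf("%d (%d-%d)",
                     round(report$deaths_central / 10) * 10,
                     round(report$deaths_low / 10) * 10,
                     round(report$deaths_high / 10) * 10),
    rate_per_100k = ifelse(is.na(report$rate_per_100k), "",
                           sprintf("%d", round(report$rate_per_100k))),
    share_total_heat = ifelse(is.na(report$share_of_total_heat_mortality), "",
                              sprintf("%.1f%%", report$share_of_total_heat_mortality)),
    share_nonacc = ifelse(is.na(report$share_of_nonacc_mortality), "",
                          sprintf("%.2f%%", report$share_of_nonacc_mortality)),
    areawgt_dt_defor = sprintf("%.2f", report$areawgt_dt_defor),
    popwgt_dt_defor = sprintf("%.2f", report$popwgt_dt_defor)
  )
}
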