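# Independent brute-force implementation of the attribution chain:
# exhaustive distance and elevation checks over the whole grid, explicit
# mean/sd, no windowing. Kept deliberately simple and separate from the
# package internals so it can serve as an oracle.

oracle_distance <- function(lat1, lon1, lat2, lon2, metric) {
  if (metric == "degree") {
    return(sqrt((lat1 - lat2)^2 + (lon1 - lon2)^2))
  }
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- min(max(a, 0), 1)
  2 * asin(sqrt(a)) * 180 / pi
}

# Raw stage: for each deforested pixel, scan every cell of the grid
# (column-major, matching R's native element order) for eligible controls.
oracle_raw <- function(dt, classes, elevation, params) {
  cls <- pixel_classes()
  lat <- lat_centers(dt$grid); lon <- lon_centers(dt$grid)
  nr <- dt$grid$nrow; nc <- dt$grid$ncol
  raw <- matrix(NA_real_, nr, nc)
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (is.na(classes$values[rr, cc]) ||
          classes$values[rr, cc] != cls[["deforested"]]) next
      if (is.na(dt$values[rr, cc]) || is.na(elevation$values[rr, cc])) next
      e0 <- elevation$values[rr, cc]
      for (radius in c(params$primary_radius, params$fallback_radius)) {
        vals <- numeric(0)
        for (c2 in seq_len(nc)) {
          for (r2 in seq_len(nr)) {
            if (is.na(classes$values[r2, c2]) ||
                classes$values[r2, c2] != cls[["non_deforested"]]) next
            if (is.na(dt$values[r2, c2]) || is.na(elevation$values[r2, c2])) next
            if (abs(elevation$values[r2, c2] - e0) > params$elevation_band) next
            d <- oracle_distance(lat[rr], lon[cc], lat[r2], lon[c2],
                                 params$distance)
            if (d <= radius) vals <- c(vals, dt$values[r2, c2])
          }
        }
        if (length(vals) > 0) {
          raw[rr, cc] <- dt$values[rr, cc] - sum(vals) / length(vals)
          break
        }
      }
    }
  }
  raw
}

# Smoothing stage on an explicit per-point matrix.
oracle_smooth <- function(per_point, change, classes, params, regional_mean,
                          regions) {
  cls <- pixel_classes()
  lat <- lat_centers(classes$grid); lon <- lon_centers(classes$grid)
  nr <- classes$grid$nrow; nc <- classes$grid$ncol
  loss <- -change$values
  out <- matrix(NA_real_, nr, nc)
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (is.na(classes$values[rr, cc]) ||
          classes$values[rr, cc] != cls[["deforested"]]) next
      if (is.na(per_point[rr, cc])) next
      vals <- numeric(0)
      for (c2 in seq_len(nc)) {
        for (r2 in seq_len(nr)) {
          if (is.na(classes$values[r2, c2]) ||
              classes$values[r2, c2] != cls[["deforested"]]) next
          if (is.na(per_point[r2, c2])) next
          if (is.na(loss[r2, c2]) ||
              loss[r2, c2] < params$min_loss_for_smoothing) next
          if (!params$include_center && r2 == rr && c2 == cc) next
          d <- oracle_distance(lat[rr], lon[cc], lat[r2], lon[c2],
                               params$distance)
          if (d <= params$smooth_radius) vals <- c(vals, per_point[r2, c2])
        }
      }
      if (length(vals) == 0) {
        id <- as.character(regions$values[rr, cc])
        out[rr, cc] <- regional_mean[[id]]
        next
      }
      n <- length(vals)
      m <- sum(vals) / n
      s <- sqrt(sum((vals - m)^2) / n)
      keep <- if (s > 0) abs(vals - m) / s <= params$z_threshold
              else rep(TRUE, n)
      out[rr, cc] <- sum(vals[keep]) / sum(keep)
    }
  }
  out
}

oracle_full_chain <- function(dt, classes, elevation, change, params,
                              regions) {
  raw <- oracle_raw(dt, classes, elevation, params)
  per_point <- raw / (-change$values)
  per_point[is.na(raw)] <- NA_real_
  # area-weighted regional means over qualifying pixels
  w <- cell_area_weights(dt$grid)$weight
  loss <- -change$values
  qual <- !is.na(per_point) & !is.na(loss) &
    loss >= params$min_loss_for_smoothing
  ids <- sort(unique(regions$values[!is.na(regions$values)]))
  rmean <- sapply(ids, function(id) {
    sel <- qual & regions$values == id
    if (!any(sel)) return(NA_real_)
    sum(w[sel] * per_point[sel]) / sum(w[sel])
  })
  names(rmean) <- as.character(ids)
  smoothed <- oracle_smooth(per_point, change, classes, params, rmean, regions)
  final <- smoothed * loss
  list(raw = raw, per_point = per_point, smoothed = smoothed, final = final)
}
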