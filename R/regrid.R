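#' Bilinear regridding between regular lat/lon grids
#'
#' Interpolates a source raster onto the cell centers of a destination grid
#' using bilinear interpolation between the four surrounding source cell
#' centers. Destination cells with any masked contributor are masked
#' (conservative policy: no renormalization over partial neighbourhoods).
#' Constant fields are preserved and affine fields `a*lat + b*lon` are
#' reproduced to floating-point tolerance.
#'
#' @param src A [dh_raster()].
#' @param dst_grid Destination [grid_spec()]; every destination cell center
#'   must lie within the convex hull of source cell centers.
#' @return A [dh_raster()] on `dst_grid`.
#' @export
regrid_bilinear <- function(src, dst_grid) {
  stopifnot(inherits(src, "dh_raster"), inherits(dst_grid, "grid_spec"))
  sg <- src$grid
  slat <- lat_centers(sg)   # decreasing
  slon <- lon_centers(sg)   # increasing
  dlat <- lat_centers(dst_grid)
  dlon <- lon_centers(dst_grid)
  eps <- 1e-9
  if (max(dlat) > max(slat) + eps || min(dlat) < min(slat) - eps ||
      max(dlon) > max(slon) + eps || min(dlon) < min(slon) - eps) {
    stop("destination grid exceeds source coverage; bilinear regridding needs full support")
  }

  # Index of the bracketing source rows/cols and interpolation fractions.
  res_lat <- slat[1] - slat[2]  # positive for >1 row
  bracket <- function(dcoord, scoord, increasing) {
    n <- length(scoord)
    if (n == 1L) {
      return(list(i0 = rep(1L, length(dcoord)), i1 = rep(1L, length(dcoord)),
                  w = rep(0, length(dcoord))))
    }
    step <- scoord[2] - scoord[1]
    pos <- (dcoord - scoord[1]) / step  # in [0, n-1]
    pos <- pmin(pmax(pos, 0), n - 1)
    i0 <- pmin(floor(pos + 1e-12), n - 2)
    w <- pos - i0
    w[abs(w) < 1e-12] <- 0
    w[abs(w - 1) < 1e-12] <- 1
    list(i0 = as.integer(i0 + 1L), i1 = as.integer(i0 + 2L), w = w)
  }
  blat <- bracket(dlat, slat)
  blon <- bracket(dlon, slon)
  # Collapse the unused neighbour when a destination center coincides with a
  # source center, so its mask state cannot leak in.
  blat$i1[blat$w == 0] <- blat$i0[blat$w == 0]
  blon$i1[blon$w == 0] <- blon$i0[blon$w == 0]
  blat$i0[blat$w == 1] <- blat$i1[blat$w == 1]
  blat$w[blat$w == 1] <- 0
  blon$i0[blon$w == 1] <- blon$i1[blon$w == 1]
  blon$w[blon$w == 1] <- 0

  V <- src$values
  # Interpolate along latitude (rows) first, then longitude (columns); the
  # v0 + w*(v1-v0) form keeps constants exact.
  M0 <- V[blat$i0, , drop = FALSE]
  M1 <- V[blat$i1, , drop = FALSE]
  Tm <- M0 + blat$w * (M1 - M0)          # vector recycles down rows
  R0 <- Tm[, blon$i0, drop = FALSE]
  R1 <- Tm[, blon$i1, drop = FALSE]
  out <- R0 + rep(blon$w, each = nrow(R0)) * (R1 - R0)

  nam <- is.na(V)
  rowbad <- nam[blat$i0, , drop = FALSE] | nam[blat$i1, , drop = FALSE]
  bad <- rowbad[, blon$i0, drop = FALSE] | rowbad[, blon$i1, drop = FALSE]
  out[bad] <- NA_real_
  dh_raster(out, dst_grid)
}

# Exact relative area of a latitude band [lat1, lat2]: proportional to
# sin(lat2) - sin(lat1).
band_area <- function(lat1, lat2) sin(lat2 * pi / 180) - sin(lat1 * pi / 180)

# Overlap weight matrix between destination intervals (rows) and source
# intervals (cols), given interval edges. `area_fun` maps an interval to its
# weight (length for longitude, spherical band area for latitude).
overlap_matrix <- function(dst_lo, dst_hi, src_lo, src_hi, area_fun) {
  nd <- length(dst_lo); ns <- length(src_lo)
  W <- matrix(0, nd, ns)
  for (d in seq_len(nd)) {
    lo <- pmax(dst_lo[d], src_lo)
    hi <- pmin(dst_hi[d], src_hi)
    hit <- which(hi - lo > 1e-12)
    if (length(hit)) W[d, hit] <- area_fun(lo[hit], hi[hit])
  }
  W
}

#' Area-weighted (conservative) regridding
#'
#' Aggregates a fine-resolution raster onto a coarser grid: each destination
#' cell is the spherical-area-weighted mean of the source cells overlapping
#' it (half-open cell intervals; exact band areas from sine differences).
#' For a gap-free field whose domain the destination tiles, the domain total
#' of value x area is conserved to 1e-9 relative. Masked source cells are
#' excluded; a destination cell is masked only when all contributors are.
#'
#' @param src A [dh_raster()] at strictly finer resolution than `dst_grid`.
#' @param dst_grid Destination [grid_spec()].
#' @return A [dh_raster()] on `dst_grid`.
#' @export
regrid_area_weighted <- function(src, dst_grid) {
  stopifnot(inherits(src, "dh_raster"), inherits(dst_grid, "grid_spec"))
  sg <- src$grid
  if (sg$resolution_arcsec >= dst_grid$resolution_arcsec) {
    stop(paste("source grid is not strictly finer than destination;",
               "use regrid_bilinear() for refinement"))
  }
  sres <- grid_res_deg(sg); dres <- grid_res_deg(dst_grid)
  # Edges, north-to-south for rows and west-to-east for columns.
  s_lat_hi <- sg$lat_max - (seq_len(sg$nrow) - 1) * sres
  s_lat_lo <- s_lat_hi - sres
  d_lat_hi <- dst_grid$lat_max - (seq_len(dst_grid$nrow) - 1) * dres
  d_lat_lo <- d_lat_hi - dres
  s_lon_lo <- sg$lon_min + (seq_len(sg$ncol) - 1) * sres
  s_lon_hi <- s_lon_lo + sres
  d_lon_lo <- dst_grid$lon_min + (seq_len(dst_grid$ncol) - 1) * dres
  d_lon_hi <- d_lon_lo + dres

  Wlat <- overlap_matrix(d_lat_lo, d_lat_hi, s_lat_lo, s_lat_hi, band_area)
  Wlon <- overlap_matrix(d_lon_lo, d_lon_hi, s_lon_lo, s_lon_hi,
                         function(lo, hi) hi - lo)

  V <- src$values
  ok <- !is.na(V)
  V0 <- ifelse(ok, V, 0)
  num <- Wlat %*% V0 %*% t(Wlon)
  den <- Wlat %*% (ok + 0) %*% t(Wlon)
  out <- num / den
  out[den <= 0] <- NA_real_
  dh_raster(out, dst_grid)
}
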