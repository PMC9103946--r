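#' Boundary pixels of a region mask
#'
#' A mask pixel is a boundary pixel when at least one of its 8 neighbours lies
#' outside the mask; pixels on the grid edge count as boundary (conservative
#' convention).
#'
#' @param mask a non-empty [RegionMask-class].
#' @return a [RegionMask-class] marking the boundary pixels.
#' @export
maskBoundary <- function(mask) {
  stopifnot(is(mask, "RegionMask"))
  m <- mask@values
  if (!any(m)) stop("mask is empty; it has no boundary", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  # pad with FALSE so grid-edge TRUE pixels see an outside neighbour
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  allNeigh <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    allNeigh <- allNeigh & pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  regionMask(m & !allNeigh, mask)
}

#' Disturbance distances of an SRMD
#'
#' For every boundary pixel of the SRMD, the shortest Euclidean distance (km,
#' centre-to-centre; 0 for pixels inside the mining region) to the mining
#' area, plus summary statistics. The package uses this single distance
#' definition throughout; polygon inputs are rasterized to the SRMD grid
#' first.
#'
#' @param srmd the disturbance [RegionMask-class].
#' @param mineRegion the mining area ([RegionMask-class] or
#'   `srmdPolygonSet`).
#' @return list with `distances` (one per boundary pixel), `boundary` (the
#'   boundary [RegionMask-class]) and `stats` (mean, median, q25, q75, min,
#'   max, n).
#' @export
disturbanceDistances <- function(srmd, mineRegion) {
  stopifnot(is(srmd, "RegionMask"))
  if (!any(srmd@values)) stop("SRMD mask is empty", call. = FALSE)
  bnd <- maskBoundary(srmd)
  dist <- distanceToRegion(srmd, mineRegion, units = "km")
  d <- dist@values[bnd@values]
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  list(distances = d, boundary = bnd,
       stats = data.frame(mean = mean(d), median = q[2], q25 = q[1],
                          q75 = q[3], min = min(d), max = max(d),
                          n = length(d)))
}

#' Fraction of the SRMD inside a buffer around the mining area
#'
#' Share of SRMD pixels whose distance to the mining area (0 inside it) is at
#' most `radiusKm` -- i.e. lying in the mine plus its `radiusKm` buffer.
#' Non-decreasing in the radius.
#'
#' @param srmd the disturbance [RegionMask-class].
#' @param mineRegion the mining area (mask or polygons).
#' @param radiusKm non-negative buffer radius in km (classically 3 km).
#' @return a number in \[0, 1\].
#' @export
bufferFraction <- function(srmd, mineRegion, radiusKm = 3) {
  stopifnot(is(srmd, "RegionMask"))
  if (!any(srmd@values)) stop("SRMD mask is empty", call. = FALSE)
  if (radiusKm < 0) stop("radiusKm must be non-negative", call. = FALSE)
  dist <- distanceToRegion(srmd, mineRegion, units = "km")
  mean(dist@values[srmd@values] <= radiusKm)
}

# azimuth in degrees from north, clockwise, of (x, y) seen from (cx, cy)
azimuthDeg <- function(x, y, cx, cy) {
  (atan2(x - cx, y - cy) * 180 / pi) %% 360
}

#' Directional ranges of the disturbance distance
#'
#' Assigns the SRMD boundary pixels to `nSectors` equal azimuth sectors seen
#' from the mining centroid (sector 1 starts at north, proceeding clockwise;
#' the sector labels are a package convention, not compass claims), and
#' reports the per-sector minimum and maximum disturbance distance.
#'
#' @param srmd the disturbance [RegionMask-class].
#' @param mineRegion the mining area (mask or polygons); its mask centroid is
#'   the sector origin.
#' @param nSectors number of sectors (default 8, i.e. 45 degrees each).
#' @return data.frame with one row per sector: `sector`, `azimuthFrom`,
#'   `azimuthTo`, `n`, `min`, `max` (NA for empty sectors).
#' @export
directionalRanges <- function(srmd, mineRegion, nSectors = 8L) {
  stopifnot(is(srmd, "RegionMask"), nSectors >= 1L)
  dd <- disturbanceDistances(srmd, mineRegion)
  mine <- rasterizePolygons(mineRegion, srmd)
  if (!any(mine@values)) stop("mining region is empty", call. = FALSE)
  ctr <- cellCenters(srmd)
  cen <- colMeans(ctr[as.vector(mine@values), , drop = FALSE])
  if (any(!is.finite(cen))) stop("mining centroid is undefined", call. = FALSE)
  bxy <- ctr[as.vector(dd$boundary@values), , drop = FALSE]
  az <- azimuthDeg(bxy[, 1], bxy[, 2], cen[1], cen[2])
  width <- 360 / nSectors
  sec <- pmin(nSectors, floor(az / width) + 1L)
  out <- data.frame(sector = seq_len(nSectors),
                    azimuthFrom = (seq_len(nSectors) - 1L) * width,
                    azimuthTo = seq_len(nSectors) * width,
                    n = 0L, min = NA_real_, max = NA_real_)
  for (k in seq_len(nSectors)) {
    sel <- sec == k
    out$n[k] <- sum(sel)
    if (any(sel)) {
      out$min[k] <- min(dd$distances[sel])
      out$max[k] <- max(dd$distances[sel])
    }
  }
  out
}

#' Summarise an identified SRMD
#'
#' Bundles the geometric summaries of a disturbance mask: boundary-pixel
#' disturbance distances and their statistics, the fraction inside the buffer,
#' and the eight-sector directional ranges.
#'
#' @param srmd the disturbance [RegionMask-class].
#' @param mineRegion the mining area (mask or polygons).
#' @param bufferKm buffer radius in km.
#' @param nSectors number of azimuth sectors.
#' @return list of class `srmdResult` with `mask`, `distances`, `stats`,
#'   `bufferFraction`, `bufferKm`, `directions`.
#' @export
srmdMetrics <- function(srmd, mineRegion, bufferKm = 3, nSectors = 8L) {
  dd <- disturbanceDistances(srmd, mineRegion)
  structure(list(
    mask = srmd,
    distances = dd$distances,
    stats = dd$stats,
    bufferFraction = bufferFraction(srmd, mineRegion, bufferKm),
    bufferKm = bufferKm,
    directions = directionalRanges(srmd, mineRegion, nSectors)),
    class = "srmdResult")
}

#' @export
print.srmdResult <- function(x, ...) {
  s <- x$stats
  cat(sprintf("SRMD: %d pixels, %d boundary pixels\n",
              sum(x$mask@values), s$n))
  cat(sprintf(
    "  disturbance distance (km): mean %.3g, median %.3g, IQR [%.3g, %.3g], max %.3g\n",
    s$mean, s$median, s$q25, s$q75, s$max))
  cat(sprintf("  fraction inside the %g km buffer: %.3f\n",
              x$bufferKm, x$bufferFraction))
  invisible(x)
}
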