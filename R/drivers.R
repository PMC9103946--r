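# exact 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher);
# f holds squared distances (Inf = no feature), positions are 1..n
edt1dSq <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) return(rep(Inf, n))
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- fin[1L]; z[1L] <- -Inf; z[2L] <- Inf
  for (q in fin[-1L]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * (q - p))
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# exact Euclidean distance transform of a logical matrix, in cell units
distanceTransformCells <- function(mask) {
  f <- matrix(Inf, nrow(mask), ncol(mask))
  f[mask] <- 0
  for (i in seq_len(nrow(f))) f[i, ] <- edt1dSq(f[i, ])
  for (j in seq_len(ncol(f))) f[, j] <- edt1dSq(f[, j])
  sqrt(f)
}

#' Shortest Euclidean distance to a region
#'
#' Per-cell shortest centre-to-centre Euclidean distance from the grid to the
#' region's cells, computed with an exact two-pass distance transform. Cells
#' inside the region get distance 0; for outside cells the nearest region cell
#' necessarily lies on the region boundary, so this is the distance to the
#' boundary. Polygon regions are rasterized to the grid first.
#'
#' @param ref reference [Grid-class] defining the lattice.
#' @param region a non-empty [RegionMask-class] aligned to `ref`, or an
#'   `srmdPolygonSet`.
#' @param units `"km"` (default) or `"m"`.
#' @return a [Grid-class] of distances.
#' @export
distanceToRegion <- function(ref, region, units = c("km", "m")) {
  units <- match.arg(units)
  mask <- rasterizePolygons(region, ref)
  if (!any(mask@values))
    stop("region is empty on this grid; cannot compute distances",
         call. = FALSE)
  d <- distanceTransformCells(mask@values) * ref@cellSize
  if (units == "km") d <- d / 1000
  # always a plain value Grid, even when `ref` is a RegionMask
  new("Grid", values = d, cellSize = ref@cellSize, origin = ref@origin,
      nodata = -9999, crs = ref@crs)
}

#' Quantify an activity driver from magnitude and distance
#'
#' The activity intensity felt at a pixel is `magnitude / (distance + 1)`:
#' the full magnitude at the source boundary (distance 0), hyperbolically
#' decaying with the distance (in km by convention, so that "+1" means
#' +1 km).
#'
#' @param magnitude non-negative activity magnitude (population for urban
#'   activity, coal production for mining activity).
#' @param distance a [Grid-class] of non-negative distances from
#'   [distanceToRegion()].
#' @return a [Grid-class] of quantified activity.
#' @export
quantifyActivity <- function(magnitude, distance) {
  stopifnot(is(distance, "Grid"))
  if (!is.finite(magnitude) || magnitude < 0)
    stop("activity magnitude must be non-negative", call. = FALSE)
  setGridValues(distance, magnitude / (distance@values + 1))
}

#' Quantify the virtual mining factor of a no-mining year
#'
#' Applies the mining-period activity to a year without mining:
#' `vx_mine = MI_u / (D_VM + 1)`, with `MI_u` an assumed coal production and
#' `D_VM` the distance to the assumed (mining-period) boundary. The virtual
#' factor feeds the attribution of the no-mining years, whose mining
#' "contribution" is pure noise of the differential method.
#'
#' @param assumedProduction non-negative assumed coal production `MI_u`.
#' @param assumedBoundary the mining-period boundary (polygons or mask).
#' @param ref reference [Grid-class].
#' @param units distance units, as [distanceToRegion()].
#' @return list of class `driverField` with `factorId = "mine"`, the `raw`
#'   quantified grid, the `distance` grid and `virtual = TRUE`.
#' @export
quantifyVirtualMining <- function(assumedProduction, assumedBoundary, ref,
                                  units = "km") {
  d <- distanceToRegion(ref, assumedBoundary, units = units)
  structure(list(factorId = "mine",
                 raw = quantifyActivity(assumedProduction, d),
                 distance = d, virtual = TRUE),
            class = "driverField")
}

#' Min-max normalization of a driving factor
#'
#' `(x - xmin) / (xmax - xmin)` with bounds taken over the stated scope:
#' spatially varying factors over the year's pixels, spatially constant
#' factors (station precipitation and temperature) across the study years.
#' The minimum maps to exactly 0 and the maximum to exactly 1.
#'
#' @param x numeric vector or [Grid-class] of quantified factor values.
#' @param bounds optional `c(min, max)` to reuse (e.g. cross-year bounds);
#'   `NULL` computes them from `x`.
#' @param factorId name used in error messages.
#' @return list with `values` (same shape as `x`) and `bounds`.
#' @export
normalizeFactor <- function(x, bounds = NULL, factorId = "factor") {
  v <- if (is(x, "Grid")) x@values else x
  if (is.null(bounds)) bounds <- range(v, na.rm = TRUE)
  if (!all(is.finite(bounds)) || diff(bounds) <= 0)
    stop(sprintf(
      "factor '%s' is constant over its normalization scope; cannot min-max normalize",
      factorId), call. = FALSE)
  out <- (v - bounds[1]) / (bounds[2] - bounds[1])
  if (is(x, "Grid")) out <- setGridValues(x, out)
  list(values = out, bounds = bounds)
}

#' Meteorological window selection by Pearson correlation
#'
#' Correlates a per-year FVC summary with candidate monthly aggregation
#' windows of station meteorology, ranking windows by `|r|`. Precipitation
#' windows are accumulated (sums), temperature windows averaged (means),
#' matching how the station series are reported.
#'
#' @param fvcSeries per-year scalar FVC summaries (e.g. study-area means).
#' @param meteoMonthly numeric matrix or data.frame, one row per year, twelve
#'   monthly columns.
#' @param windows list of integer month vectors (e.g. `list(7, 6:8)`).
#' @param variable `"precipitation"` (sum) or `"temperature"` (mean).
#' @return data.frame with `window`, `r`, `absR`, ordered by decreasing
#'   `|r|`; zero-variance windows get `NA`.
#' @export
pearsonWindowSelection <- function(fvcSeries, meteoMonthly, windows,
                                   variable = c("precipitation",
                                                "temperature")) {
  variable <- match.arg(variable)
  m <- as.matrix(meteoMonthly)
  if (length(fvcSeries) < 3L)
    stop("need at least three years for a correlation", call. = FALSE)
  stopifnot(nrow(m) == length(fvcSeries), ncol(m) == 12L)
  if (any(vapply(windows, function(w) any(w < 1L | w > 12L), logical(1))))
    stop("windows must lie within months 1..12", call. = FALSE)
  agg <- vapply(windows, function(w) {
    sub <- m[, w, drop = FALSE]
    if (variable == "precipitation") rowSums(sub) else rowMeans(sub)
  }, numeric(length(fvcSeries)))
  rs <- apply(agg, 2L, function(a) {
    if (stats::sd(a) == 0 || stats::sd(fvcSeries) == 0) NA_real_
    else stats::cor(fvcSeries, a)
  })
  out <- data.frame(
    window = vapply(windows, function(w) paste(range(w), collapse = "-"),
                    character(1)),
    r = rs, absR = abs(rs))
  out[order(-out$absR, na.last = TRUE), , drop = FALSE]
}

#' Assemble one year's normalized driver stack
#'
#' Builds the five normalized factors of a year: station precipitation and
#' temperature enter as spatially constant grids normalized with the supplied
#' cross-year bounds; topography, urban activity and mining activity are
#' normalized over the year's pixels. For a no-mining year the mining factor
#' is the virtual one (assumed production and boundary), flagged by
#' `miningIsVirtual`.
#'
#' @param year integer year.
#' @param dem the DEM [Grid-class] (also the reference geometry).
#' @param pre,temp the year's station precipitation and temperature scalars.
#' @param preBounds,tempBounds cross-year `c(min, max)` normalization bounds.
#' @param population,coalProduction the year's activity magnitudes;
#'   `coalProduction` is the *assumed* production for a no-mining year.
#' @param urbanBoundary,mineBoundary boundary polygons (or aligned masks).
#' @param miningIsVirtual is the mining factor the virtual one?
#' @param units distance units inside the activity quantification.
#' @return a [DriverStack-class].
#' @seealso [buildDriverStacks()] for the multi-year convenience wrapper.
#' @export
buildDriverStack <- function(year, dem, pre, temp, preBounds, tempBounds,
                             population, coalProduction,
                             urbanBoundary, mineBoundary,
                             miningIsVirtual = FALSE, units = "km") {
  stopifnot(is(dem, "Grid"))
  const <- function(val, bounds, id) {
    nv <- normalizeFactor(val, bounds, factorId = id)$values
    setGridValues(dem, matrix(nv, gridDim(dem)[1], gridDim(dem)[2]))
  }
  xPre <- const(pre, preBounds, "pre")
  xTemp <- const(temp, tempBounds, "temp")
  xDem <- normalizeFactor(dem, factorId = "dem")$values
  dU <- distanceToRegion(dem, urbanBoundary, units = units)
  xUrbanRaw <- quantifyActivity(population, dU)
  xUrban <- normalizeFactor(xUrbanRaw, factorId = "urban")$values
  mineField <- quantifyVirtualMining(coalProduction, mineBoundary, dem,
                                     units = units)
  xMine <- normalizeFactor(mineField$raw, factorId = "mine")$values
  bounds <- list(
    pre = preBounds, temp = tempBounds,
    dem = range(dem@values, na.rm = TRUE),
    urban = range(xUrbanRaw@values, na.rm = TRUE),
    mine = range(mineField$raw@values, na.rm = TRUE))
  new("DriverStack", year = as.integer(year),
      factors = list(pre = xPre, temp = xTemp, dem = xDem,
                     urban = xUrban, mine = xMine),
      bounds = bounds, miningIsVirtual = isTRUE(miningIsVirtual))
}

#' Assemble normalized driver stacks for all study years
#'
#' Computes the cross-year normalization bounds for the spatially constant
#' station factors, then builds one [DriverStack-class] per year. Years in
#' `config$noMiningYears` receive the virtual mining factor built from the
#' assumed (mining-period) production and boundary; other years use their own
#' production and the same boundary.
#'
#' @param dem the DEM [Grid-class].
#' @param meteo data.frame with columns `year`, `precipitation`,
#'   `temperature` (one row per study year).
#' @param activity data.frame with columns `year`, `population`,
#'   `coalProduction`.
#' @param urbanBoundary,mineBoundary boundary polygons (or aligned masks).
#' @param config an [srmdConfig()] with `years` and `noMiningYears` set.
#' @param assumedProduction production used for the virtual factor; default:
#'   the production of the latest mining year.
#' @return named list of [DriverStack-class], one per `config$years`.
#' @export
buildDriverStacks <- function(dem, meteo, activity, urbanBoundary,
                              mineBoundary, config,
                              assumedProduction = NULL) {
  years <- config$years
  if (!length(years)) stop("config$years is empty", call. = FALSE)
  meteo <- meteo[match(years, meteo$year), , drop = FALSE]
  activity <- activity[match(years, activity$year), , drop = FALSE]
  if (anyNA(meteo$year) || anyNA(activity$year))
    stop("meteo/activity records missing for some study years", call. = FALSE)
  preBounds <- range(meteo$precipitation)
  tempBounds <- range(meteo$temperature)
  miningYears <- setdiff(years, config$noMiningYears)
  if (is.null(assumedProduction)) {
    if (!length(miningYears))
      stop("no mining year to take the assumed production from", call. = FALSE)
    assumedProduction <-
      activity$coalProduction[match(max(miningYears), activity$year)]
  }
  units <- config$distanceUnits
  out <- lapply(seq_along(years), function(i) {
    y <- years[i]
    isVirtual <- y %in% config$noMiningYears
    buildDriverStack(
      year = y, dem = dem,
      pre = meteo$precipitation[i], temp = meteo$temperature[i],
      preBounds = preBounds, tempBounds = tempBounds,
      population = activity$population[i],
      coalProduction = if (isVirtual) assumedProduction else
        activity$coalProduction[i],
      urbanBoundary = urbanBoundary, mineBoundary = mineBoundary,
      miningIsVirtual = isVirtual, units = units)
  })
  names(out) <- as.character(years)
  out
}
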