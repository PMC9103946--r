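#' NDVI from a red/NIR reflectance pair
#'
#' `NDVI = (rho_NIR - rho_Red) / (rho_NIR + rho_Red)` per cell. Cells where
#' the band sum is zero (and nodata cells) become nodata.
#'
#' @param nir,red aligned [Grid-class]s of unitless surface reflectance.
#' @return a [Grid-class] of NDVI in \[-1, 1\].
#' @export
computeNDVI <- function(nir, red) {
  stopIfUnaligned(nir, red)
  a <- nir@values; b <- red@values
  s <- a + b
  ndvi <- (a - b) / s
  ndvi[!is.na(s) & s == 0] <- NA_real_
  setGridValues(nir, ndvi)
}

#' Per-cell maximum-value composite
#'
#' The per-pixel maximum of an NDVI stack over a seasonal window (classically
#' July-September), suppressing clouds and off-peak phenology. Nodata is
#' ignored per cell; a cell that is nodata in every layer stays nodata.
#'
#' @param ndviStack non-empty list of aligned [Grid-class]s.
#' @return a [Grid-class].
#' @export
maxComposite <- function(ndviStack) {
  stopifnot(is.list(ndviStack))
  if (!length(ndviStack)) stop("empty composite stack", call. = FALSE)
  do.call(stopIfUnaligned, ndviStack)
  out <- do.call(pmax, c(lapply(ndviStack, gridValues), list(na.rm = TRUE)))
  setGridValues(ndviStack[[1]], out)
}

#' Cross-sensor NDVI harmonization by ordinary least squares
#'
#' Fits `reference = slope * source + intercept` over paired NDVI samples from
#' overlapping acquisitions, mapping one sensor's NDVI onto another's scale.
#' Chains support using an intermediate sensor (e.g. TM -> ETM+ -> OLI) when
#' two sensors never overlapped in time.
#'
#' @param sourceVals,referenceVals paired NDVI samples (equal length, >= 2
#'   distinct source values).
#' @param sourceSensor,referenceSensor free-text sensor tags.
#' @return an object of class `sensorHarmonization` with fields `slope`,
#'   `intercept`, `sourceSensor`, `referenceSensor`.
#' @export
fitSensorHarmonization <- function(sourceVals, referenceVals,
                                   sourceSensor = "source",
                                   referenceSensor = "reference") {
  keep <- !is.na(sourceVals) & !is.na(referenceVals)
  x <- sourceVals[keep]; y <- referenceVals[keep]
  if (length(x) < 2L)
    stop("need at least two paired samples to fit a harmonization",
         call. = FALSE)
  if (stats::var(x) == 0)
    stop("source NDVI has zero variance; slope is unidentifiable",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 sourceSensor = sourceSensor,
                 referenceSensor = referenceSensor),
            class = "sensorHarmonization")
}

#' @describeIn fitSensorHarmonization Compose two harmonizations
#'   (`source -> mid`, then `mid -> reference`): slope `a1*a2`, intercept
#'   `a2*b1 + b2`.
#' @param h1,h2 `sensorHarmonization` objects to chain, in order.
#' @export
chainHarmonization <- function(h1, h2) {
  stopifnot(inherits(h1, "sensorHarmonization"),
            inherits(h2, "sensorHarmonization"))
  structure(list(slope = h1$slope * h2$slope,
                 intercept = h2$slope * h1$intercept + h2$intercept,
                 sourceSensor = h1$sourceSensor,
                 referenceSensor = h2$referenceSensor),
            class = "sensorHarmonization")
}

#' @describeIn fitSensorHarmonization Apply a harmonization to an NDVI grid
#'   or numeric vector.
#' @param h a `sensorHarmonization`.
#' @param ndvi a [Grid-class] or numeric vector of NDVI on the source scale.
#' @export
applyHarmonization <- function(h, ndvi) {
  stopifnot(inherits(h, "sensorHarmonization"))
  if (is(ndvi, "Grid"))
    setGridValues(ndvi, h$slope * ndvi@values + h$intercept)
  else h$slope * ndvi + h$intercept
}

#' @export
print.sensorHarmonization <- function(x, ...) {
  cat(sprintf("NDVI harmonization %s -> %s: reference = %.6g * source + %.6g\n",
              x$sourceSensor, x$referenceSensor, x$slope, x$intercept))
  invisible(x)
}

#' FVC inversion endpoints
#'
#' The pure-soil (`ndviMin`) and pure-vegetation (`ndviMax`) NDVI endpoints of
#' the pixel dichotomy model.
#'
#' @param ndviMin,ndviMax endpoints with `-1 <= ndviMin < ndviMax <= 1`.
#' @param soilPercentile,vegPercentile the cumulative-percentage positions the
#'   endpoints were read from (bookkeeping).
#' @return an object of class `fvcEndpoints`.
#' @export
fvcEndpoints <- function(ndviMin, ndviMax,
                         soilPercentile = 5, vegPercentile = 95) {
  if (!(ndviMin >= -1 && ndviMax <= 1 && ndviMin < ndviMax))
    stop("endpoints must satisfy -1 <= ndviMin < ndviMax <= 1", call. = FALSE)
  structure(list(ndviMin = ndviMin, ndviMax = ndviMax,
                 soilPercentile = soilPercentile,
                 vegPercentile = vegPercentile),
            class = "fvcEndpoints")
}

# nearest-rank percentile: value at the ceil(p/100 * n)-th position of the
# ascending sort (a cumulative-count reading, not interpolated)
nearestRankPercentile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (!n) stop("empty sample set", call. = FALSE)
  x[max(1L, min(n, as.integer(ceiling(p / 100 * n))))]
}

#' Select FVC endpoints from pure-pixel NDVI samples
#'
#' Sorts the pure-soil samples ascending and takes the value at the
#' `soilPercentile` cumulative-percentage position as `ndviMin`; likewise the
#' `vegPercentile` position of the pure-vegetation samples as `ndviMax`
#' (nearest-rank, not interpolated). The defaults 5 and 95 guard both
#' endpoints against extreme anomalous values.
#'
#' @param pureSoilNDVI,pureVegNDVI non-empty NDVI sample vectors from pixels
#'   of completely bare soil / complete vegetation cover across the study
#'   years.
#' @param soilPercentile,vegPercentile cumulative-percentage positions.
#' @return an `fvcEndpoints` object.
#' @export
selectEndpoints <- function(pureSoilNDVI, pureVegNDVI,
                            soilPercentile = 5, vegPercentile = 95) {
  lo <- nearestRankPercentile(pureSoilNDVI, soilPercentile)
  hi <- nearestRankPercentile(pureVegNDVI, vegPercentile)
  if (lo >= hi)
    stop(sprintf(
      "degenerate endpoints: soil NDVI %.4g >= vegetation NDVI %.4g", lo, hi),
      call. = FALSE)
  fvcEndpoints(lo, hi, soilPercentile, vegPercentile)
}

#' Fractional vegetation cover by the pixel dichotomy model
#'
#' `FVC = (NDVI - ndviMin) / (ndviMax - ndviMin)`, clipped to \[0, 1\] (the
#' linear mixing inversion can leave the physical range when NDVI lies outside
#' the endpoints). Nodata propagates.
#'
#' @param ndvi a [Grid-class] of NDVI.
#' @param endpoints an `fvcEndpoints` object.
#' @return a [Grid-class] of FVC in \[0, 1\].
#' @export
computeFVC <- function(ndvi, endpoints) {
  stopifnot(is(ndvi, "Grid"), inherits(endpoints, "fvcEndpoints"))
  span <- endpoints$ndviMax - endpoints$ndviMin
  if (span == 0) stop("ndviMin equals ndviMax", call. = FALSE)
  fvc <- (ndvi@values - endpoints$ndviMin) / span
  fvc <- pmin(pmax(fvc, 0), 1)
  setGridValues(ndvi, fvc)
}
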