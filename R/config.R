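#' Study configuration
#'
#' Central parameter bundle for the whole pipeline. Every field has a default;
#' the statistically meaningful ones follow the published method: significance
#' level `alpha = 0.05` and relative perturbation `biasFactor = 0.001`.
#'
#' @param years integer study years.
#' @param noMiningYears subset of `years` with no mining activity (the noise
#'   calibration period).
#' @param alpha one-sided significance level of the disturbance test.
#' @param biasFactor relative bias applied to a normalized factor in the
#'   finite-difference attribution (`dX = biasFactor * X`).
#' @param kernel geographic weighting kernel; only `"gaussian"`.
#' @param bandwidthM kernel bandwidth in metres; `NULL` = one quarter of the
#'   grid diagonal at training time.
#' @param hidden integer vector of hidden-layer widths.
#' @param eta learning rate of gradient descent.
#' @param maxEpochs maximum training epochs.
#' @param tolerance stop when the epoch-over-epoch loss change drops below
#'   this value.
#' @param seed integer seed controlling every random draw.
#' @param trainingScope `"per_year"` (one model per year, the default) or
#'   `"pooled"` (one model over all years).
#' @param anchorBudget maximum number of anchor locations (output neurons);
#'   above it, anchors are a regular stride subsample of the pixels and other
#'   pixels read their nearest anchor's neuron.
#' @param mreFloor cells with observed FVC below this are excluded from the
#'   mean relative error (it divides by the observation).
#' @param denomFloor contribution shares with `|sum(C_i)|` below this floor
#'   become nodata instead of blowing up.
#' @param biasFloor absolute perturbation used where a factor is exactly 0
#'   (there `biasFactor * X` would vanish and the difference quotient be
#'   undefined).
#' @param absDenominator use `sum(|C_i|)` instead of the signed `sum(C_i)` in
#'   the share denominator (off by default: the signed form is the published
#'   formula).
#' @param distanceUnits units of boundary distances inside the activity
#'   quantification; `"km"` (default) or `"m"` for sensitivity checks.
#' @param soilPercentile,vegPercentile cumulative-percentage positions of the
#'   pure-soil and pure-vegetation NDVI endpoints.
#' @return a validated list of class `srmdConfig`.
#' @export
srmdConfig <- function(years = integer(0), noMiningYears = integer(0),
                       alpha = 0.05, biasFactor = 0.001,
                       kernel = "gaussian", bandwidthM = NULL,
                       hidden = 16L, eta = 0.05, maxEpochs = 500L,
                       tolerance = 1e-6, seed = 1L,
                       trainingScope = c("per_year", "pooled"),
                       anchorBudget = 4096L, mreFloor = 0.01,
                       denomFloor = 1e-9, biasFloor = 1e-6,
                       absDenominator = FALSE,
                       distanceUnits = c("km", "m"),
                       soilPercentile = 5, vegPercentile = 95) {
  cfg <- list(
    years = as.integer(years), noMiningYears = as.integer(noMiningYears),
    alpha = alpha, biasFactor = biasFactor, kernel = kernel,
    bandwidthM = bandwidthM, hidden = as.integer(hidden), eta = eta,
    maxEpochs = as.integer(maxEpochs), tolerance = tolerance,
    seed = as.integer(seed), trainingScope = match.arg(trainingScope),
    anchorBudget = as.integer(anchorBudget), mreFloor = mreFloor,
    denomFloor = denomFloor, biasFloor = biasFloor,
    absDenominator = isTRUE(absDenominator),
    distanceUnits = match.arg(distanceUnits),
    soilPercentile = soilPercentile, vegPercentile = vegPercentile)
  class(cfg) <- "srmdConfig"
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  if (!(cfg$alpha > 0 && cfg$alpha < 1))
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  if (cfg$biasFactor <= 0)
    stop("biasFactor must be positive", call. = FALSE)
  if (!is.null(cfg$bandwidthM) && cfg$bandwidthM <= 0)
    stop("bandwidthM must be positive", call. = FALSE)
  if (!identical(cfg$kernel, "gaussian"))
    stop("only the gaussian kernel is implemented", call. = FALSE)
  if (any(cfg$hidden < 1L))
    stop("hidden layer sizes must be positive", call. = FALSE)
  if (cfg$eta <= 0) stop("learning rate eta must be positive", call. = FALSE)
  if (cfg$maxEpochs < 1L) stop("maxEpochs must be >= 1", call. = FALSE)
  if (length(cfg$noMiningYears) &&
      !all(cfg$noMiningYears %in% cfg$years))
    stop("noMiningYears must be a subset of years", call. = FALSE)
  invisible(cfg)
}

#' Load a study configuration from YAML
#'
#' Unset fields take the [srmdConfig()] defaults; the result is validated
#' against the configuration invariants.
#'
#' @param path path to a YAML document whose keys match [srmdConfig()]
#'   arguments.
#' @return an `srmdConfig`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file does not exist: '%s'", path), call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  known <- names(formals(srmdConfig))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(srmdConfig, doc)
}

#' @export
print.srmdConfig <- function(x, ...) {
  cat("srmdConfig:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (is.null(v)) "<auto>" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

# Evaluate expr with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
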