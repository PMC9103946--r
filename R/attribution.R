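#' Perturb one driving factor by a relative bias
#'
#' The finite-difference attribution adds `dX = biasFactor * X` (default
#' 0.001, i.e. a 0.1% relative bias) to exactly one normalized factor; all
#' other factors stay bit-identical. Where the factor is exactly 0 the
#' relative bias would vanish and the difference quotient be undefined, so
#' those cells receive the absolute floor `biasFloor` instead.
#'
#' @param stack a [DriverStack-class].
#' @param factorId one of `"pre"`, `"temp"`, `"dem"`, `"urban"`, `"mine"`.
#' @param biasFactor positive relative bias.
#' @param biasFloor absolute bias used at zero-valued cells.
#' @return list with `stack` (the perturbed [DriverStack-class]) and `bias`
#'   (the [Grid-class] of applied `dX`).
#' @export
perturbFactor <- function(stack, factorId, biasFactor = 0.001,
                          biasFloor = 1e-6) {
  stopifnot(is(stack, "DriverStack"))
  if (!factorId %in% driverNames)
    stop(sprintf("unknown factor '%s'", factorId), call. = FALSE)
  if (biasFactor <= 0) stop("biasFactor must be positive", call. = FALSE)
  g <- stack@factors[[factorId]]
  x <- g@values
  dx <- biasFactor * x
  dx[!is.na(x) & x == 0] <- biasFloor
  pert <- stack
  pert@factors[[factorId]] <- setGridValues(g, x + dx)
  list(stack = pert, bias = setGridValues(g, dx))
}

#' Per-pixel partial derivative of predicted FVC w.r.t. one factor
#'
#' The differential method: feed the already-trained network the stack with
#' one factor biased, and form `C_i = (Y_biased - Y) / dX_i` per pixel from
#' the unclipped predictions.
#'
#' @param model a trained [GWANNModel-class].
#' @param stack the unperturbed [DriverStack-class].
#' @param factorId factor to differentiate.
#' @param biasFactor,biasFloor see [perturbFactor()].
#' @return a [Grid-class] of `C_i`.
#' @export
partialDerivative <- function(model, stack, factorId, biasFactor = 0.001,
                              biasFloor = 1e-6) {
  stopifnot(is(model, "GWANNModel"))
  if (!model@trained) stop("model is not trained", call. = FALSE)
  p <- perturbFactor(stack, factorId, biasFactor, biasFloor)
  y0 <- predictFVC(model, stack, clip = FALSE)
  y1 <- predictFVC(model, p$stack, clip = FALSE)
  setGridValues(y0, (y1@values - y0@values) / p$bias@values)
}

#' Contribution shares from the five partial derivatives
#'
#' `W_i = C_i / sum_k C_k` per pixel, with the signed denominator of the
#' published formula (set `absDenominator = TRUE` for `sum |C_k|` as a
#' sensitivity variant). Cells where the denominator magnitude falls below
#' `denomFloor` become nodata rather than producing unbounded shares. Where
#' defined, the signed shares sum to exactly 1 per pixel.
#'
#' @param C named list of the five partial-derivative [Grid-class]s.
#' @param year integer year label.
#' @param denomFloor denominator magnitude floor.
#' @param absDenominator use `sum(|C_k|)` in the denominator.
#' @return a [ContributionMaps-class].
#' @export
contributionShares <- function(C, year = NA_integer_, denomFloor = 1e-9,
                               absDenominator = FALSE) {
  if (!identical(sort(names(C)), sort(driverNames)))
    stop(sprintf("C must hold exactly the five factors {%s}",
                 paste(driverNames, collapse = ", ")), call. = FALSE)
  do.call(stopIfUnaligned, unname(C))
  denom <- Reduce(`+`, lapply(C, function(g)
    if (absDenominator) abs(g@values) else g@values))
  denom[abs(denom) < denomFloor] <- NA_real_
  W <- lapply(C, function(g) setGridValues(g, g@values / denom))
  # Class= must be named exactly: a bare `C =` would partial-match it
  new(Class = "ContributionMaps", C = C[driverNames], W = W[driverNames],
      year = as.integer(year))
}

setMethod("show", "ContributionMaps", function(object) {
  cat(sprintf("ContributionMaps (year %s):\n",
              ifelse(is.na(object@year), "?", object@year)))
  for (nm in driverNames) {
    w <- object@W[[nm]]@values
    cat(sprintf("  W_%-6s median %+.4g  [%.4g, %.4g]\n", nm,
                stats::median(w, na.rm = TRUE),
                min(w, na.rm = TRUE), max(w, na.rm = TRUE)))
  }
})

#' Full finite-difference attribution of one year
#'
#' Computes all five partial derivatives with [partialDerivative()] and turns
#' them into contribution shares.
#'
#' @param model a trained [GWANNModel-class].
#' @param stack the year's [DriverStack-class].
#' @param config an [srmdConfig()] (supplies `biasFactor`, `biasFloor`,
#'   `denomFloor`, `absDenominator`).
#' @return a [ContributionMaps-class].
#' @export
computeContributions <- function(model, stack, config = srmdConfig()) {
  y0 <- predictFVC(model, stack, clip = FALSE)  # shared baseline prediction
  C <- lapply(driverNames, function(nm) {
    p <- perturbFactor(stack, nm, config$biasFactor, config$biasFloor)
    y1 <- predictFVC(model, p$stack, clip = FALSE)
    setGridValues(y0, (y1@values - y0@values) / p$bias@values)
  })
  names(C) <- driverNames
  contributionShares(C, year = stack@year, denomFloor = config$denomFloor,
                     absDenominator = config$absDenominator)
}

#' Virtual mining contributions of the no-mining years
#'
#' For each no-mining year: trains a GWANN on the five factors (with the
#' virtual mining factor), runs the differential attribution, and returns the
#' per-pixel virtual mining contribution V-W_mine. Pooled over years and
#' pixels, these samples are the empirical noise of the mining contribution.
#'
#' @param stacks list of [DriverStack-class]s flagged `miningIsVirtual`.
#' @param fvc list of observed FVC [Grid-class]s matching `stacks`.
#' @param config an [srmdConfig()].
#' @return list with `wMine` (named list of V-W_mine [Grid-class]s, one per
#'   year), `models`, `contributions` and `accuracy` (per-year training
#'   accuracy).
#' @export
virtualContribution <- function(stacks, fvc, config = srmdConfig()) {
  stopifnot(is.list(stacks), is.list(fvc), length(stacks) == length(fvc))
  for (s in stacks) {
    stopifnot(is(s, "DriverStack"))
    if (!s@miningIsVirtual)
      stop(sprintf(
        "year %d carries a real mining factor; virtual contribution is only defined for no-mining years",
        s@year), call. = FALSE)
  }
  wMine <- list(); models <- list(); contribs <- list()
  preds <- list(); obs <- list()
  for (i in seq_along(stacks)) {
    fit <- trainGWANN(stacks[[i]], fvc[[i]], config)
    cm <- computeContributions(fit$model, stacks[[i]], config)
    y <- as.character(stacks[[i]]@year)
    models[[y]] <- fit$model
    contribs[[y]] <- cm
    wMine[[y]] <- cm@W[["mine"]]
    preds[[y]] <- predictFVC(fit$model, stacks[[i]], clip = TRUE)
    obs[[y]] <- fvc[[i]]
  }
  acc <- evaluateAccuracy(preds, obs,
                          years = vapply(stacks, slot, integer(1), "year"),
                          mreFloor = config$mreFloor)
  list(wMine = wMine, models = models, contributions = contribs,
       accuracy = acc)
}

#' Fit the empirical noise model of the mining contribution
#'
#' Pools the virtual contributions, computes sample mean and SD, fits a
#' Gaussian curve to the histogram (a normality diagnostic mirroring the
#' published workflow; the fit never enters the test), and sets the critical
#' value to the empirical `(1 - alpha)` cumulative-frequency point of the
#' pooled samples.
#'
#' @param samples pooled V-W_mine values (grids or numeric; NA dropped;
#'   >= 100 samples required).
#' @param alpha one-sided significance level.
#' @return a [NoiseModel-class].
#' @export
fitNoise <- function(samples, alpha = 0.05) {
  if (is.list(samples))
    samples <- unlist(lapply(samples, function(g)
      if (is(g, "Grid")) as.vector(g@values) else as.numeric(g)))
  if (is(samples, "Grid")) samples <- as.vector(samples@values)
  samples <- samples[!is.na(samples)]
  if (length(samples) < 100L)
    stop(sprintf("need at least 100 noise samples, got %d", length(samples)),
         call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  m <- mean(samples); s <- stats::sd(samples)
  fit <- c(amplitude = NA_real_, centre = NA_real_, width = NA_real_)
  # Freedman-Diaconis bin count, capped: heavy-tailed pools would otherwise
  # explode the (purely diagnostic) histogram fit
  nb <- min(200L, max(20L, grDevices::nclass.FD(samples)))
  h <- graphics::hist(samples, breaks = nb, plot = FALSE)
  try({
    nl <- stats::nls(
      counts ~ a * exp(-(mids - c0)^2 / (2 * w^2)),
      data = data.frame(counts = h$counts, mids = h$mids),
      start = list(a = max(h$counts), c0 = m, w = s))
    cf <- stats::coef(nl)
    fit <- c(amplitude = unname(cf["a"]), centre = unname(cf["c0"]),
             width = abs(unname(cf["w"])))
  }, silent = TRUE)
  crit <- unname(stats::quantile(samples, 1 - alpha, names = FALSE))
  new("NoiseModel", samples = samples, mean = m, sd = s, gaussianFit = fit,
      criticalValue = crit, alpha = alpha)
}

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: n = %d, mean = %.4g, sd = %.4g, V_%.2f = %.4g\n",
    length(object@samples), object@mean, object@sd,
    1 - object@alpha, object@criticalValue))
  if (!anyNA(object@gaussianFit))
    cat(sprintf("  histogram Gaussian fit: centre %.4g, width %.4g\n",
                object@gaussianFit["centre"], object@gaussianFit["width"]))
})

#' @describeIn fitNoise Accessor for the critical value `V_(1-alpha)`.
#' @param noise a [NoiseModel-class].
#' @export
criticalValue <- function(noise) {
  stopifnot(is(noise, "NoiseModel"))
  noise@criticalValue
}

#' One-sided significance mask of the mining disturbance
#'
#' Flags exactly the pixels whose mining contribution exceeds the noise
#' critical value (`W_mine > V_(1-alpha)`, strict: the alternative hypothesis
#' is a strict inequality, so a pixel sitting exactly at the critical value is
#' retained under the null). Nodata contributions are never flagged.
#'
#' @param wMine [Grid-class] of the tested year's mining contribution.
#' @param noise a fitted [NoiseModel-class].
#' @return a [RegionMask-class]: the SRMD.
#' @export
significanceMask <- function(wMine, noise) {
  stopifnot(is(wMine, "Grid"), is(noise, "NoiseModel"))
  if (!length(noise@samples)) stop("noise model is unfitted", call. = FALSE)
  flag <- !is.na(wMine@values) & wMine@values > noise@criticalValue
  regionMask(flag, wMine)
}
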