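#' Run the full SRMD pipeline
#'
#' Executes the whole method in order: (optionally) simulate a synthetic
#' scene, invert FVC from reflectance, assemble the driver stacks, train the
#' per-year GWANNs, attribute the tested (mining) year, calibrate the noise
#' from the no-mining years' virtual contributions, apply the significance
#' test and summarise the disturbance geometry. Every stage is a pure
#' function of (inputs, config, seed); a rerun with the same seed is
#' identical.
#'
#' @param config an [srmdConfig()]; its `years`/`noMiningYears` are taken
#'   from the scene when a scene is supplied.
#' @param scene a `sceneBundle` from [generateScene()]; `NULL` reads real
#'   inputs from `inputDir` instead (files as written by
#'   [writeSceneBundle()]).
#' @param inputDir directory of input files when `scene` is `NULL`.
#' @param outDir optional output directory; when set, all interface files
#'   (rasters, CSVs, the run manifest) are written there.
#' @param testYear the year whose mining contribution is tested; default: the
#'   latest mining year.
#' @return list of class `srmdRun`: `config`, `accuracy` (per-year RMSE/MRE),
#'   `noise` ([NoiseModel-class]), `contributions`
#'   ([ContributionMaps-class] of the tested year), `wMine`, `srmd`
#'   ([RegionMask-class]), `metrics` (`srmdResult`), `manifest`.
#' @export
runAll <- function(config = srmdConfig(), scene = NULL, inputDir = NULL,
                   outDir = NULL, testYear = NULL) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start,
                                             units = "secs"))
    logStage(stage, timings[[stage]])
  }

  s <- Sys.time()
  if (is.null(scene)) {
    if (is.null(inputDir))
      stop("either a scene or an inputDir must be supplied", call. = FALSE)
    scene <- readSceneInputs(inputDir)
  }
  years <- scene$years
  config$years <- as.integer(years)
  config$noMiningYears <- as.integer(scene$config$noMiningYears)
  validateConfig(config)
  miningYears <- setdiff(years, config$noMiningYears)
  if (is.null(testYear)) testYear <- max(miningYears)
  if (!testYear %in% miningYears)
    stop("testYear must be a mining year", call. = FALSE)
  tick("inputs", s)

  # FVC inversion from the reflectance pairs through the real path
  s <- Sys.time()
  fvc <- lapply(as.character(years), function(y) {
    pair <- scene$reflectance[[y]]
    computeFVC(computeNDVI(pair$nir, pair$red), scene$endpoints)
  })
  names(fvc) <- as.character(years)
  tick("fvc", s)

  s <- Sys.time()
  stacks <- buildDriverStacks(scene$dem, scene$meteo, scene$activity,
                              scene$urban, scene$mine, config)
  tick("drivers", s)

  # noise calibration: per-year GWANN + attribution on the no-mining years
  s <- Sys.time()
  nmy <- as.character(config$noMiningYears)
  virt <- virtualContribution(stacks[nmy], fvc[nmy], config)
  noise <- fitNoise(virt$wMine, alpha = config$alpha)
  tick("noise", s)

  # tested year: train, attribute, test
  s <- Sys.time()
  ty <- as.character(testYear)
  fit <- trainGWANN(stacks[[ty]], fvc[[ty]], config)
  contrib <- computeContributions(fit$model, stacks[[ty]], config)
  pred <- predictFVC(fit$model, stacks[[ty]], clip = TRUE)
  accTest <- evaluateAccuracy(pred, fvc[[ty]], years = testYear,
                              mreFloor = config$mreFloor)
  accuracy <- aggregateAccuracy(rbind(virt$accuracy, accTest))
  tick("train_attribute", s)

  s <- Sys.time()
  wMine <- contrib@W[["mine"]]
  srmd <- significanceMask(wMine, noise)
  tick("significance", s)

  s <- Sys.time()
  mineMask <- rasterizePolygons(scene$mine, scene$dem)
  metrics <- if (any(srmd@values)) srmdMetrics(srmd, mineMask) else NULL
  tick("metrics", s)

  manifest <- list(
    seed = config$seed,
    testYear = testYear,
    years = years,
    noMiningYears = config$noMiningYears,
    nNoiseSamples = length(noise@samples),
    criticalValue = noise@criticalValue,
    srmdPixels = sum(srmd@values),
    stageSeconds = timings,
    totalSeconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(list(config = config, accuracy = accuracy, noise = noise,
                        contributions = contrib, wMine = wMine, srmd = srmd,
                        metrics = metrics, history = fit$history,
                        manifest = manifest),
                   class = "srmdRun")
  if (!is.null(outDir)) writeRunOutputs(run, scene, outDir)
  run
}

logStage <- function(stage, secs) {
  message(sprintf("[%s] stage %-16s %.2fs",
                  format(Sys.time(), "%H:%M:%S"), stage, secs))
}

#' Read pipeline inputs from a directory
#'
#' Reads the file layout written by [writeSceneBundle()] (which mirrors what a
#' real study supplies): reflectance pairs, DEM, boundaries, activity and
#' meteorology CSVs and the truth sidecar (for year bookkeeping and
#' endpoints).
#'
#' @param dir input directory.
#' @return a `sceneBundle`-like list sufficient for [runAll()].
#' @export
readSceneInputs <- function(dir) {
  need <- function(p) {
    if (!file.exists(p)) stop(sprintf("missing input file: '%s'", p),
                              call. = FALSE)
    p
  }
  meta <- yaml::read_yaml(need(file.path(dir, "truth_synthetic.yaml")))
  years <- sort(c(unlist(meta$noMiningYears), unlist(meta$miningYears)))
  dem <- readGrid(need(file.path(dir, "dem.asc")))
  refl <- lapply(as.character(years), function(y) list(
    nir = readGrid(need(file.path(dir, sprintf("nir_%s.asc", y)))),
    red = readGrid(need(file.path(dir, sprintf("red_%s.asc", y))))))
  names(refl) <- as.character(years)
  list(
    config = list(noMiningYears = unlist(meta$noMiningYears),
                  miningYears = unlist(meta$miningYears)),
    years = years, dem = dem, reflectance = refl,
    urban = readPolygonsGeoJSON(need(file.path(dir, "urban.geojson"))),
    mine = readPolygonsGeoJSON(need(file.path(dir, "mine.geojson"))),
    activity = utils::read.csv(need(file.path(dir, "activity.csv"))),
    meteo = utils::read.csv(need(file.path(dir, "meteo.csv"))),
    endpoints = fvcEndpoints(meta$ndviMin, meta$ndviMax))
}

writeRunOutputs <- function(run, scene, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeGrid(run$srmd, file.path(outDir, "srmd_mask.asc"))
  writeGrid(run$wMine, file.path(outDir, "w_mine.asc"))
  for (nm in driverNames) {
    writeGrid(run$contributions@C[[nm]],
              file.path(outDir, sprintf("C_%s.asc", nm)))
    writeGrid(run$contributions@W[[nm]],
              file.path(outDir, sprintf("W_%s.asc", nm)))
  }
  utils::write.csv(run$accuracy, file.path(outDir, "accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(v_w_mine = run$noise@samples),
                   file.path(outDir, "noise_samples.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    mean = run$noise@mean, sd = run$noise@sd,
    critical = run$noise@criticalValue, alpha = run$noise@alpha,
    n = length(run$noise@samples)),
    file.path(outDir, "noise_summary.csv"), row.names = FALSE)
  utils::write.csv(run$history, file.path(outDir, "training_log.csv"),
                   row.names = FALSE)
  if (!is.null(run$metrics)) {
    utils::write.csv(data.frame(distance_km = run$metrics$distances),
                     file.path(outDir, "disturbance_distances.csv"),
                     row.names = FALSE)
    utils::write.csv(run$metrics$stats,
                     file.path(outDir, "disturbance_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(run$metrics$directions,
                     file.path(outDir, "directional_ranges.csv"),
                     row.names = FALSE)
  }
  yaml::write_yaml(run$manifest, file.path(outDir, "manifest.yaml"))
  invisible(outDir)
}

#' @export
print.srmdRun <- function(x, ...) {
  cat("SRMD pipeline run\n")
  cat(sprintf("  tested year: %d; %d noise samples; V_%.2f = %.4g\n",
              x$manifest$testYear, x$manifest$nNoiseSamples,
              1 - x$noise@alpha, x$noise@criticalValue))
  cat(sprintf("  mean RMSE %.4f, mean MRE %.4f over %d years\n",
              attr(x$accuracy, "meanRMSE"), attr(x$accuracy, "meanMRE"),
              nrow(x$accuracy)))
  cat(sprintf("  SRMD: %d pixels\n", x$manifest$srmdPixels))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
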