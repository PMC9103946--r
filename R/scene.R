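#' Synthetic-scene generator configuration
#'
#' The generator emulates the study setting at desk scale: a ~5.4 km square
#' grid of 90 m cells in a semi-arid grassland, eleven analysed years (ten
#' without mining, one mining year), a central open-pit mine adjacent to an
#' urban area to its west, station meteorology drawn around the study area's
#' climatology (275 mm summer precipitation, 3.25 degC), and elevation falling
#' west to east between 1319 m and 939 m. FVC is generated from the normalized
#' drivers as
#' `clip01( g(X) - amplitude * exp(-D_mine_km / decay) + eps )`,
#' `eps ~ N(0, noiseSd)`, with `g` linear (optionally with a quadratic
#' topography term) so the attribution has an analytic truth.
#'
#' @param nrow,ncol grid size in cells (>= 20 each).
#' @param cellSizeM cell size in metres.
#' @param noMiningYears,miningYears integer year labels (>= 2 no-mining and
#'   >= 1 mining year).
#' @param coefficients named vector `c(intercept, pre, temp, dem, urban)` of
#'   the generative linear FVC function on the normalized drivers.
#' @param quadDem coefficient of an optional `(X_dem - 0.5)^2` term, to
#'   exercise the network's nonlinear capacity (0 = linear truth).
#' @param miningAmplitude FVC suppression at the mine boundary (mining years
#'   only). The default 0.2 is four times the default noise, a strong but
#'   plausible vegetation loss.
#' @param miningDecayKm e-folding distance of the suppression.
#' @param noiseSd SD of the additive FVC noise; 0.05 mirrors typical FVC
#'   inversion error.
#' @param coalProduction mining-year coal production (Mt); also the assumed
#'   production of the virtual factor.
#' @param endpoints `fvcEndpoints` used when synthesising reflectance (the
#'   published study endpoints 0.08 / 0.7 by default).
#' @param seed integer seed; identical seeds give identical bundles.
#' @return list of class `sceneConfig`.
#' @export
sceneConfig <- function(nrow = 60L, ncol = 60L, cellSizeM = 90,
                        noMiningYears = c(1992L, 1995:2003),
                        miningYears = 2020L,
                        coefficients = c(intercept = 0.65, pre = 0.15,
                                         temp = 0.10, dem = -0.25,
                                         urban = -0.15),
                        quadDem = 0, miningAmplitude = 0.2,
                        miningDecayKm = 1, noiseSd = 0.05,
                        coalProduction = 32,
                        endpoints = fvcEndpoints(0.08, 0.7),
                        seed = 1L) {
  cfg <- list(nrow = as.integer(nrow), ncol = as.integer(ncol),
              cellSizeM = cellSizeM,
              noMiningYears = as.integer(noMiningYears),
              miningYears = as.integer(miningYears),
              coefficients = coefficients, quadDem = quadDem,
              miningAmplitude = miningAmplitude,
              miningDecayKm = miningDecayKm, noiseSd = noiseSd,
              coalProduction = coalProduction, endpoints = endpoints,
              seed = as.integer(seed))
  if (cfg$nrow < 20L || cfg$ncol < 20L)
    stop("scene grid must be at least 20 x 20", call. = FALSE)
  if (length(cfg$noMiningYears) < 2L || length(cfg$miningYears) < 1L)
    stop("need at least two no-mining years and one mining year",
         call. = FALSE)
  if (cfg$noiseSd < 0) stop("noiseSd must be non-negative", call. = FALSE)
  if (cfg$miningDecayKm <= 0)
    stop("miningDecayKm must be positive", call. = FALSE)
  stopifnot(all(c("intercept", "pre", "temp", "dem", "urban") %in%
                  names(cfg$coefficients)))
  class(cfg) <- "sceneConfig"
  cfg
}

# smooth seeded field in [0, 1] from a few random low-frequency cosines
smoothField <- function(nr, nc, nWaves = 4L) {
  xs <- (seq_len(nc) - 0.5) / nc
  ys <- (seq_len(nr) - 0.5) / nr
  f <- matrix(0, nr, nc)
  for (i in seq_len(nWaves)) {
    fx <- stats::runif(1, 0.5, 2.5); fy <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi); a <- stats::runif(1, 0.3, 1)
    f <- f + a * outer(cos(2 * pi * fy * ys + ph[1]),
                       cos(2 * pi * fx * xs + ph[2]))
  }
  (f - min(f)) / (max(f) - min(f))
}

rectRing <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
}

#' Generate a synthetic multi-year scene with known truth
#'
#' Produces everything the pipeline consumes -- DEM, boundaries, activity and
#' meteorology series, per-year reflectance pairs, observed FVC and driver
#' stacks -- from a known generative FVC function, plus the ground truth
#' needed for parameter-recovery tests (generative coefficients, mining
#' suppression field, and the true disturbance mask: cells whose suppression
#' exceeds twice the noise SD).
#'
#' @param config a [sceneConfig()].
#' @return list of class `sceneBundle` with fields `config`, `dem`, `urban`,
#'   `mine` (polygon sets), `meteo`, `activity` (data.frames), `years`,
#'   `fvc`, `reflectance`, `stacks` (per-year named lists), `suppression`
#'   ([Grid-class]), `truth` (list incl. `trueDisturbance`
#'   [RegionMask-class] and `trueRadiusKm`), and `endpoints`.
#' @export
generateScene <- function(config = sceneConfig()) {
  stopifnot(inherits(config, "sceneConfig"))
  nr <- config$nrow; nc <- config$ncol; cs <- config$cellSizeM
  years <- sort(c(config$noMiningYears, config$miningYears))
  ny <- length(years)
  withSeed(config$seed, {
    wEast <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
    demVals <- 939 + 380 * (1 - wEast) * 0.8 +
      76 * smoothField(nr, nc)
    dem <- grid(demVals, cellSize = cs, origin = c(0, nr * cs),
                crs = "synthetic-metres")

    # central mine, urban block adjacent to its west (as in the study area)
    W <- nc * cs; H <- nr * cs
    mine <- polygonSet(rectRing(0.44 * W, 0.44 * H, 0.56 * W, 0.56 * H),
                       properties = list(name = "mine"))
    urban <- polygonSet(rectRing(0.20 * W, 0.33 * H, 0.44 * W, 0.50 * H),
                        properties = list(name = "urban"))

    meteo <- data.frame(
      year = years,
      precipitation = pmax(80, 275 + stats::rnorm(ny, 0, 50)),
      temperature = 3.25 + stats::rnorm(ny, 0, 0.8))
    activity <- data.frame(
      year = years,
      population = round(seq(140000, 190000, length.out = ny)),
      coalProduction = ifelse(years %in% config$miningYears,
                              config$coalProduction, 0))

    cfgStudy <- srmdConfig(years = years,
                           noMiningYears = config$noMiningYears)
    stacks <- buildDriverStacks(dem, meteo, activity, urban, mine, cfgStudy,
                                assumedProduction = config$coalProduction)

    dMine <- distanceToRegion(dem, mine, units = "km")
    supp <- config$miningAmplitude *
      exp(-dMine@values / config$miningDecayKm)
    a <- config$coefficients
    fvc <- list(); refl <- list()
    for (y in as.character(years)) {
      st <- stacks[[y]]
      g <- a["intercept"] +
        a["pre"] * st@factors$pre@values +
        a["temp"] * st@factors$temp@values +
        a["dem"] * st@factors$dem@values +
        a["urban"] * st@factors$urban@values +
        config$quadDem * (st@factors$dem@values - 0.5)^2
      mining <- as.integer(y) %in% config$miningYears
      f <- g - if (mining) supp else 0
      if (config$noiseSd > 0)
        f <- f + stats::rnorm(length(f), 0, config$noiseSd)
      f <- pmin(1, pmax(0, f))
      fg <- setGridValues(dem, matrix(f, nr, nc))
      fvc[[y]] <- fg
      refl[[y]] <- sceneToReflectance(fg, config$endpoints)
    }
    trueDist <- regionMask(supp > 2 * config$noiseSd, dem)
    trueRadius <- if (config$noiseSd > 0 &&
                      config$miningAmplitude > 2 * config$noiseSd)
      config$miningDecayKm *
        log(config$miningAmplitude / (2 * config$noiseSd))
    else NA_real_
  })
  structure(list(
    config = config, dem = dem, urban = urban, mine = mine,
    meteo = meteo, activity = activity, years = years,
    fvc = fvc, reflectance = refl, stacks = stacks,
    suppression = setGridValues(dem, matrix(supp, nr, nc)),
    endpoints = config$endpoints,
    truth = list(coefficients = config$coefficients,
                 quadDem = config$quadDem,
                 miningAmplitude = config$miningAmplitude,
                 miningDecayKm = config$miningDecayKm,
                 noiseSd = config$noiseSd,
                 trueDisturbance = trueDist,
                 trueRadiusKm = trueRadius,
                 seed = config$seed)),
    class = "sceneBundle")
}

#' Invert FVC to a synthetic red/NIR reflectance pair
#'
#' Maps FVC back through the pixel dichotomy model to NDVI
#' (`NDVI = ndviMin + FVC * (ndviMax - ndviMin)`) and materialises a
#' reflectance pair with constant band sum 0.4, so that running the real
#' pipeline (reflectance -> NDVI -> FVC) recovers the input FVC exactly for
#' unclipped cells.
#'
#' @param fvc a [Grid-class] of FVC in \[0, 1\].
#' @param endpoints an `fvcEndpoints`.
#' @return list with `nir` and `red` [Grid-class]s.
#' @export
sceneToReflectance <- function(fvc, endpoints) {
  stopifnot(is(fvc, "Grid"), inherits(endpoints, "fvcEndpoints"))
  v <- fvc@values
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stop("FVC must lie in [0, 1]", call. = FALSE)
  ndvi <- endpoints$ndviMin + v * (endpoints$ndviMax - endpoints$ndviMin)
  list(nir = setGridValues(fvc, 0.2 * (1 + ndvi)),
       red = setGridValues(fvc, 0.2 * (1 - ndvi)))
}

#' Write a scene bundle to disk as the pipeline's input files
#'
#' Emits exactly what a real study would provide: per-year red/NIR
#' reflectance ASCII grids, the DEM, urban/mine GeoJSON boundaries, activity
#' and meteorology CSVs, and a YAML truth sidecar (plus the true-disturbance
#' mask as a raster).
#'
#' @param bundle a `sceneBundle`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSceneBundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sceneBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGrid(bundle$dem, file.path(dir, "dem.asc"))
  for (y in as.character(bundle$years)) {
    writeGrid(bundle$reflectance[[y]]$nir,
              file.path(dir, sprintf("nir_%s.asc", y)))
    writeGrid(bundle$reflectance[[y]]$red,
              file.path(dir, sprintf("red_%s.asc", y)))
    writeGrid(bundle$fvc[[y]], file.path(dir, sprintf("fvc_%s.asc", y)))
  }
  writePolygonsGeoJSON(bundle$urban, file.path(dir, "urban.geojson"))
  writePolygonsGeoJSON(bundle$mine, file.path(dir, "mine.geojson"))
  utils::write.csv(bundle$activity, file.path(dir, "activity.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$meteo, file.path(dir, "meteo.csv"),
                   row.names = FALSE)
  tr <- bundle$truth
  yaml::write_yaml(list(
    coefficients = as.list(tr$coefficients),
    quadDem = tr$quadDem,
    miningAmplitude = tr$miningAmplitude,
    miningDecayKm = tr$miningDecayKm,
    noiseSd = tr$noiseSd,
    trueRadiusKm = tr$trueRadiusKm,
    seed = tr$seed,
    ndviMin = bundle$endpoints$ndviMin,
    ndviMax = bundle$endpoints$ndviMax,
    noMiningYears = bundle$config$noMiningYears,
    miningYears = bundle$config$miningYears),
    file.path(dir, "truth_synthetic.yaml"))
  writeGrid(tr$trueDisturbance, file.path(dir, "true_disturbance.asc"))
  invisible(dir)
}
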