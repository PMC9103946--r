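#' @import methods
NULL

#' Grid: a georeferenced raster field
#'
#' The universal raster carrier of the package. A `Grid` is a rectangular,
#' north-up field of real values: row 1 is the northernmost row, and the centre
#' of pixel (r, c) lies at `origin + (c - 0.5, -(r - 0.5)) * cellSize` in
#' projected map coordinates (metres). Missing cells are stored as `NA` and are
#' excluded from every statistic; the `nodata` slot only records the sentinel
#' used on disk.
#'
#' @slot values numeric matrix, `NA` = nodata.
#' @slot cellSize positive cell size in metres (square pixels).
#' @slot origin numeric length-2, map coordinates (x, y) of the outer top-left
#'   corner of the grid.
#' @slot nodata numeric sentinel written to / recognised in files.
#' @slot crs free-text tag for the projected CRS; inputs must share it.
#'
#' @aliases Grid
#' @exportClass Grid
setClass("Grid",
  representation(
    values = "matrix",
    cellSize = "numeric",
    origin = "numeric",
    nodata = "numeric",
    crs = "character"
  ),
  prototype(
    values = matrix(numeric(0), 0, 0),
    cellSize = 30,
    origin = c(0, 0),
    nodata = -9999,
    crs = "local-metres"
  )
)

setValidity("Grid", function(object) {
  msg <- character(0)
  if (!(is.numeric(object@values) || is.logical(object@values)))
    msg <- c(msg, "values must be a numeric (or logical) matrix")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number (metres)")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be finite map coordinates (x, y)")
  if (length(object@nodata) != 1L)
    msg <- c(msg, "nodata must be a single value")
  if (length(object@crs) != 1L)
    msg <- c(msg, "crs must be a single string")
  if (length(msg)) msg else TRUE
})

#' RegionMask: a boolean field aligned to a reference Grid
#'
#' Carries region membership (mining area, urban area, SRMD, buffers) on the
#' same lattice as its reference [Grid]. Values are logical; `NA` is not
#' allowed (membership is decidable everywhere).
#'
#' @aliases RegionMask
#' @exportClass RegionMask
setClass("RegionMask", contains = "Grid")

setValidity("RegionMask", function(object) {
  if (!is.logical(object@values))
    return("RegionMask values must be logical")
  if (anyNA(object@values))
    return("RegionMask values must not contain NA")
  TRUE
})

#' DriverStack: the five normalized driving factors for one year
#'
#' Holds the min-max normalized driving factors of FVC for a single year:
#' precipitation (`pre`), temperature (`temp`), topography (`dem`), urban
#' activity (`urban`) and mining activity (`mine`), each a [Grid] in \[0, 1\],
#' mutually aligned. For years in the no-mining period the mining factor is the
#' *virtual* factor VX_mine (an assumed production and boundary applied to a
#' year without mining), flagged by `miningIsVirtual`.
#'
#' @slot year integer study year.
#' @slot factors named list of five aligned [Grid]s
#'   (`pre`, `temp`, `dem`, `urban`, `mine`), values in \[0, 1\].
#' @slot bounds named list of per-factor `c(min, max)` used in normalization.
#' @slot miningIsVirtual logical, `TRUE` when the mining factor is the virtual
#'   one of the no-mining period.
#'
#' @aliases DriverStack
#' @exportClass DriverStack
setClass("DriverStack",
  representation(
    year = "integer",
    factors = "list",
    bounds = "list",
    miningIsVirtual = "logical"
  )
)

driverNames <- c("pre", "temp", "dem", "urban", "mine")

setValidity("DriverStack", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@factors)), sort(driverNames)))
    msg <- c(msg, sprintf("factors must be exactly {%s}",
                          paste(driverNames, collapse = ", ")))
  else {
    ok <- vapply(object@factors, is, logical(1), class2 = "Grid")
    if (!all(ok)) msg <- c(msg, "every factor must be a Grid")
    else {
      ref <- object@factors[[1]]
      for (nm in names(object@factors)) {
        g <- object@factors[[nm]]
        if (!sameGeometry(ref, g))
          msg <- c(msg, sprintf("factor '%s' is not aligned to the others", nm))
        v <- g@values
        v <- v[!is.na(v)]
        if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
          msg <- c(msg, sprintf("factor '%s' has values outside [0, 1]", nm))
      }
    }
  }
  if (length(object@year) != 1L) msg <- c(msg, "year must be a single integer")
  if (length(object@miningIsVirtual) != 1L || is.na(object@miningIsVirtual))
    msg <- c(msg, "miningIsVirtual must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' GWANNModel: a geographically weighted artificial neural network
#'
#' A feed-forward network with a 5-wide input layer (the normalized driving
#' factors), tanh activations at every layer, and one output neuron per
#' *anchor location*. During training the error of each training pixel at
#' output neuron j is weighted by a Gaussian kernel of the geographic distance
#' between the pixel and anchor j; prediction at a pixel reads the output
#' neuron of its nearest anchor, fed that pixel's own drivers.
#'
#' @slot layerSizes integer vector, `c(5, hidden..., nAnchors)`.
#' @slot weights list of weight matrices, one per connection layer
#'   (`nIn x nOut`).
#' @slot biases list of per-neuron bias vectors, one per connection layer.
#' @slot anchors `m x 2` matrix of anchor map coordinates (x, y).
#' @slot anchorCells integer vector: linear pixel index (column-major over the
#'   training grid) of each anchor.
#' @slot nearestAnchor integer vector over all pixels of the training grid:
#'   which anchor's output neuron serves each pixel.
#' @slot kernel kernel name (only `"gaussian"`).
#' @slot bandwidth kernel bandwidth in metres.
#' @slot geometry list describing the training grid (`dim`, `cellSize`,
#'   `origin`, `crs`), used to reject mismatched prediction grids.
#' @slot seed integer seed used for weight initialization.
#' @slot trained logical.
#'
#' @aliases GWANNModel
#' @exportClass GWANNModel
setClass("GWANNModel",
  representation(
    layerSizes = "integer",
    weights = "list",
    biases = "list",
    anchors = "matrix",
    anchorCells = "integer",
    nearestAnchor = "integer",
    kernel = "character",
    bandwidth = "numeric",
    geometry = "list",
    seed = "integer",
    trained = "logical"
  )
)

setValidity("GWANNModel", function(object) {
  msg <- character(0)
  ls <- object@layerSizes
  if (length(ls) < 3L) msg <- c(msg, "need at least one hidden layer")
  if (length(ls) && ls[1] != 5L)
    msg <- c(msg, "input width must be 5 (the five driving factors)")
  if (length(ls) && nrow(object@anchors) != ls[length(ls)])
    msg <- c(msg, "one output neuron per anchor location required")
  if (length(object@weights) != length(ls) - 1L)
    msg <- c(msg, "one weight matrix per connection layer required")
  if (!all(vapply(object@weights, function(w) all(is.finite(w)), logical(1))))
    msg <- c(msg, "weights must be finite")
  if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
    msg <- c(msg, "bandwidth must be positive")
  if (length(msg)) msg else TRUE
})

#' ContributionMaps: per-factor partial derivatives and contribution shares
#'
#' Result of the finite-difference attribution: per-pixel partial derivatives
#' `C[[i]]` of predicted FVC with respect to each normalized driving factor,
#' and contribution shares `W[[i]] = C_i / sum(C_k)` (signed shares; cells
#' whose denominator magnitude falls below a floor are nodata).
#'
#' @slot C named list of five [Grid]s of partial derivatives.
#' @slot W named list of five [Grid]s of contribution shares.
#' @slot year integer year attributed.
#'
#' @aliases ContributionMaps
#' @exportClass ContributionMaps
setClass("ContributionMaps",
  representation(C = "list", W = "list", year = "integer")
)

setValidity("ContributionMaps", function(object) {
  msg <- character(0)
  for (sl in c("C", "W")) {
    x <- slot(object, sl)
    if (!identical(sort(names(x)), sort(driverNames)))
      msg <- c(msg, sprintf("%s must hold exactly the five factors", sl))
  }
  if (length(msg)) msg else TRUE
})

#' NoiseModel: the empirical null of the mining contribution
#'
#' Pools the virtual mining contributions (V-W_mine) of the no-mining years
#' and summarises them: sample moments, a Gaussian curve fitted to the
#' histogram (a normality diagnostic only), and the critical value `V_(1-alpha)`
#' -- the empirical (1 - alpha) cumulative-frequency point of the pooled
#' samples, used as the one-sided significance threshold.
#'
#' @slot samples pooled V-W_mine values (NA dropped).
#' @slot mean,sd sample moments.
#' @slot gaussianFit named numeric `c(amplitude, centre, width)` of the
#'   histogram curve fit (NA if the fit failed).
#' @slot criticalValue empirical `(1 - alpha)` quantile of `samples`.
#' @slot alpha significance level.
#'
#' @aliases NoiseModel
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(
    samples = "numeric",
    mean = "numeric",
    sd = "numeric",
    gaussianFit = "numeric",
    criticalValue = "numeric",
    alpha = "numeric"
  )
)

setValidity("NoiseModel", function(object) {
  msg <- character(0)
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(object@sd) == 1L && !is.na(object@sd) && object@sd < 0)
    msg <- c(msg, "sd must be non-negative")
  if (length(msg)) msg else TRUE
})
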