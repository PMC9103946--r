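#' Initialize a GWANN
#'
#' Builds an untrained network `5 -> hidden... -> nAnchors` with tanh
#' activations at every layer (output included; reported predictions are
#' clipped to \[0, 1\]). Weights are drawn uniformly from
#' `(-1/sqrt(fanIn), 1/sqrt(fanIn))`, biases start at zero; the draw is fully
#' reproducible under `seed` and leaves the caller's RNG state untouched.
#'
#' @param hidden integer vector of hidden-layer widths (>= 1 layer).
#' @param anchors `m x 2` matrix of anchor map coordinates.
#' @param seed integer seed for the weight draw.
#' @param bandwidth Gaussian kernel bandwidth in metres.
#' @param geometry list describing the training grid (see [GWANNModel-class]);
#'   may be empty for free-standing use.
#' @param anchorCells,nearestAnchor optional pixel bookkeeping (see
#'   [GWANNModel-class]).
#' @return an untrained [GWANNModel-class].
#' @export
gwannModel <- function(hidden, anchors, seed = 1L, bandwidth = 1000,
                       geometry = list(), anchorCells = integer(0),
                       nearestAnchor = integer(0)) {
  anchors <- as.matrix(anchors)
  if (!nrow(anchors)) stop("at least one anchor location is required",
                           call. = FALSE)
  hidden <- as.integer(hidden)
  if (!length(hidden) || any(hidden < 1L))
    stop("at least one hidden layer of positive width is required",
         call. = FALSE)
  layerSizes <- c(5L, hidden, nrow(anchors))
  weights <- vector("list", length(layerSizes) - 1L)
  biases <- vector("list", length(layerSizes) - 1L)
  withSeed(seed, {
    for (l in seq_along(weights)) {
      nIn <- layerSizes[l]; nOut <- layerSizes[l + 1L]
      r <- 1 / sqrt(nIn)
      weights[[l]] <- matrix(stats::runif(nIn * nOut, -r, r), nIn, nOut)
      biases[[l]] <- numeric(nOut)
    }
  })
  new("GWANNModel", layerSizes = layerSizes, weights = weights,
      biases = biases, anchors = anchors,
      anchorCells = as.integer(anchorCells),
      nearestAnchor = as.integer(nearestAnchor),
      kernel = "gaussian", bandwidth = as.numeric(bandwidth),
      geometry = geometry, seed = as.integer(seed), trained = FALSE)
}

setMethod("show", "GWANNModel", function(object) {
  cat(sprintf("GWANNModel: layers [%s], %d anchors, gaussian bandwidth %.6g m, %s\n",
              paste(object@layerSizes, collapse = "-"),
              nrow(object@anchors), object@bandwidth,
              if (object@trained) "trained" else "untrained"))
})

#' Geographic weights between samples and anchors
#'
#' Gaussian kernel of the Euclidean distance between each training-sample
#' location and each output neuron's anchor:
#' `w = exp(-d^2 / (2 * bandwidth^2))`. The weight is 1 at distance zero,
#' decays monotonically, and is symmetric in its two location arguments.
#'
#' @param sampleLocations `n x 2` matrix of sample map coordinates.
#' @param anchors `m x 2` matrix of anchor map coordinates.
#' @param bandwidth positive bandwidth in the same length units.
#' @return an `n x m` weight matrix in (0, 1].
#' @export
geoWeights <- function(sampleLocations, anchors, bandwidth) {
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  sampleLocations <- as.matrix(sampleLocations)
  anchors <- as.matrix(anchors)
  d2 <- outer(sampleLocations[, 1], anchors[, 1], "-")^2 +
        outer(sampleLocations[, 2], anchors[, 2], "-")^2
  exp(-d2 / (2 * bandwidth^2))
}

# batch forward pass: X is n x 5; returns activations per layer
# (A[[1]] = X, A[[l+1]] = tanh(A[[l]] W_l + b_l))
forwardBatch <- function(model, X) {
  A <- vector("list", length(model@weights) + 1L)
  A[[1L]] <- X
  for (l in seq_along(model@weights)) {
    Z <- A[[l]] %*% model@weights[[l]]
    A[[l + 1L]] <- tanh(Z + rep(model@biases[[l]], each = nrow(Z)))
  }
  A
}

#' Forward pass for one sample
#'
#' Propagates a single 5-vector of normalized drivers through the network:
#' `Layer_j = sum_i w_ij p_i + bias_j`, `p_j = tanh(Layer_j)` at every hidden
#' and output neuron. Outputs lie in (-1, 1).
#'
#' @param model a [GWANNModel-class].
#' @param x numeric 5-vector of normalized drivers.
#' @return list with `outputs` (per-anchor outputs) and `activations` (per
#'   layer, for backpropagation).
#' @export
gwannForward <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != model@layerSizes[1] || any(!is.finite(x)))
    stop("input must be a finite 5-vector", call. = FALSE)
  A <- forwardBatch(model, matrix(x, 1L))
  list(outputs = drop(A[[length(A)]]), activations = A)
}

#' Geographically weighted error of one sample
#'
#' `E = 1/2 * sum_j D_j (r_j - p_j)^2`, the kernel-weighted squared error of
#' the sample across the output neurons.
#'
#' @param predictions per-output predictions `p_j`.
#' @param targets per-output targets `r_j` (for a training pixel: its observed
#'   FVC, replicated across outputs).
#' @param weights per-output geographic weights `D_j`; `NULL` means
#'   unweighted (all 1).
#' @return a single non-negative number.
#' @export
weightedError <- function(predictions, targets, weights = NULL) {
  if (length(predictions) != length(targets))
    stop("predictions and targets differ in length", call. = FALSE)
  sq <- (targets - predictions)^2
  if (!is.null(weights)) {
    if (length(weights) != length(sq))
      stop("weights and predictions differ in length", call. = FALSE)
    sq <- weights * sq
  }
  sum(sq) / 2
}

#' Error signals (deltas) by backpropagation, one sample
#'
#' Output neurons: `delta_j = phi'(Layer_j) * D_j * (p_j - r_j)`; hidden
#' neurons: `delta_j = phi'(Layer_j) * sum_k delta_k w_jk`, with
#' `phi' = 1 - tanh^2`.
#'
#' @param model a [GWANNModel-class].
#' @param cache result of [gwannForward()] for the sample.
#' @param targets per-output targets.
#' @param weights per-output geographic weights (`NULL` = unweighted).
#' @return list of per-layer delta vectors (hidden layers first, output last).
#' @export
backpropDeltas <- function(model, cache, targets, weights = NULL) {
  if (is.null(cache$activations))
    stop("forward cache is missing; run gwannForward() first", call. = FALSE)
  A <- cache$activations
  L <- length(model@weights)
  deltas <- vector("list", L)
  P <- A[[L + 1L]]
  G <- P - matrix(targets, nrow = nrow(P), ncol = ncol(P))
  if (!is.null(weights)) G <- G * rep(weights, each = nrow(P))
  deltas[[L]] <- G * (1 - P^2)
  if (L > 1L) for (l in seq(L - 1L, 1L)) {
    deltas[[l]] <- (deltas[[l + 1L]] %*% t(model@weights[[l + 1L]])) *
      (1 - A[[l + 1L]]^2)
  }
  lapply(deltas, drop)
}

#' One gradient-descent weight update
#'
#' Applies `dw_ij = -eta * delta_j * p_i` to every connection, and the same
#' rule with unit input to every bias.
#'
#' @param model a [GWANNModel-class].
#' @param deltas per-layer deltas from [backpropDeltas()].
#' @param cache the forward cache of the same sample.
#' @param eta positive learning rate.
#' @return the updated [GWANNModel-class].
#' @export
updateWeights <- function(model, deltas, cache, eta) {
  if (eta < 0) stop("eta must be non-negative", call. = FALSE)
  if (!all(vapply(deltas, function(d) all(is.finite(d)), logical(1))))
    stop("non-finite deltas", call. = FALSE)
  A <- cache$activations
  for (l in seq_along(model@weights)) {
    dl <- matrix(deltas[[l]], nrow = nrow(A[[l]]))
    model@weights[[l]] <- model@weights[[l]] - eta * crossprod(A[[l]], dl)
    model@biases[[l]] <- model@biases[[l]] - eta * colSums(dl)
  }
  model
}

#' Batch loss and gradient of the geographically weighted error
#'
#' The training objective is the sample-mean of the per-sample weighted error:
#' `E = 1/(2n) * sum_s sum_j D_sj (r_s - p_sj)^2`. `gwannGradient` returns its
#' exact analytic gradient via backpropagation; it is checked against central
#' differences in the test suite.
#'
#' @param model a [GWANNModel-class].
#' @param X `n x 5` matrix of driver samples.
#' @param r length-n vector of observed FVC targets.
#' @param D `n x m` geographic weight matrix, or `NULL` for the unweighted
#'   (standard backpropagation) objective.
#' @return `gwannLoss`: a number. `gwannGradient`: list with `weights` and
#'   `biases` gradients, shaped like the model's.
#' @export
gwannLoss <- function(model, X, r, D = NULL) {
  A <- forwardBatch(model, X)
  P <- A[[length(A)]]
  G <- (matrix(r, nrow(P), ncol(P)) - P)^2
  if (!is.null(D)) G <- D * G
  sum(G) / (2 * nrow(X))
}

#' @rdname gwannLoss
#' @export
gwannGradient <- function(model, X, r, D = NULL) {
  n <- nrow(X)
  A <- forwardBatch(model, X)
  L <- length(model@weights)
  P <- A[[L + 1L]]
  G <- P - matrix(r, nrow(P), ncol(P))
  if (!is.null(D)) G <- G * D
  delta <- G * (1 - P^2)
  gw <- vector("list", L)
  gb <- vector("list", L)
  for (l in seq(L, 1L)) {
    gw[[l]] <- crossprod(A[[l]], delta) / n
    gb[[l]] <- colSums(delta) / n
    if (l > 1L)
      delta <- (delta %*% t(model@weights[[l]])) * (1 - A[[l]]^2)
  }
  list(weights = gw, biases = gb)
}

# choose a regular anchor stride so that the anchor count stays within budget
anchorStride <- function(dims, budget) {
  k <- 1L
  while (ceiling(dims[1] / k) * ceiling(dims[2] / k) > budget) k <- k + 1L
  k
}

# pick anchor cells on a stride-k sublattice of the grid; returns linear
# (column-major) cell indices
anchorCellsForGrid <- function(dims, stride) {
  rows <- seq.int(from = as.integer(ceiling(stride / 2)), to = dims[1],
                  by = stride)
  cols <- seq.int(from = as.integer(ceiling(stride / 2)), to = dims[2],
                  by = stride)
  as.integer(outer(rows, (cols - 1L) * dims[1], "+"))
}

# assemble the n x 5 sample matrix from a DriverStack; returns X, valid cell
# indices and locations
stackSamples <- function(stack) {
  X <- vapply(driverNames, function(nm)
    as.vector(stack@factors[[nm]]@values), numeric(length(stack@factors[[1]]@values)))
  dimnames(X) <- NULL  # keep trained weights free of factor dimnames
  ok <- stats::complete.cases(X)
  list(X = X, ok = ok, ref = stack@factors[[1]])
}

#' Train a GWANN on one year (or pooled years)
#'
#' Full-batch gradient descent on the geographically weighted loss: every
#' epoch evaluates all training pixels, weights each pixel's error at output
#' neuron j by the Gaussian kernel of its distance to anchor j, and applies
#' the averaged gradient with learning rate `eta`. Training stops after
#' `maxEpochs` epochs or when the epoch-over-epoch loss change falls below
#' `tolerance`. Fully deterministic under `config$seed`.
#'
#' @param stacks a [DriverStack-class], or a list of them (pooled training
#'   when `config$trainingScope == "pooled"`; otherwise use one call per
#'   year).
#' @param fvc the observed FVC [Grid-class] (or list matching `stacks`).
#' @param config an [srmdConfig()].
#' @param weighted `FALSE` switches off the geographic weighting entirely
#'   (ordinary backpropagation; used as the unweighted reference).
#' @return list with `model` (trained [GWANNModel-class]) and `history`
#'   (data.frame of `epoch`, `error`).
#' @export
trainGWANN <- function(stacks, fvc, config = srmdConfig(), weighted = TRUE) {
  if (is(stacks, "DriverStack")) stacks <- list(stacks)
  if (is(fvc, "Grid")) fvc <- list(fvc)
  stopifnot(length(stacks) == length(fvc), length(stacks) >= 1L)
  ref <- stacks[[1]]@factors[[1]]
  for (i in seq_along(stacks)) {
    stopIfUnaligned(ref, stacks[[i]]@factors[[1]], fvc[[i]])
  }
  dims <- gridDim(ref)
  ctr <- cellCenters(ref)
  stride <- anchorStride(dims, config$anchorBudget)
  aCells <- anchorCellsForGrid(dims, stride)
  anchors <- ctr[aCells, , drop = FALSE]
  bw <- config$bandwidthM
  if (is.null(bw)) {
    ext <- extentOf(ref)
    bw <- sqrt((ext["xmax"] - ext["xmin"])^2 +
               (ext["ymax"] - ext["ymin"])^2) / 4
    bw <- unname(bw)
  }
  # nearest anchor of every pixel (ties -> first, i.e. lowest anchor index)
  d2all <- outer(ctr[, 1], anchors[, 1], "-")^2 +
           outer(ctr[, 2], anchors[, 2], "-")^2
  nearest <- max.col(-d2all, ties.method = "first")

  Xs <- list(); rs <- list(); locs <- list()
  for (i in seq_along(stacks)) {
    s <- stackSamples(stacks[[i]])
    okY <- s$ok & !is.na(as.vector(fvc[[i]]@values))
    if (!any(okY))
      stop(sprintf("year %d has no valid training pixels", stacks[[i]]@year),
           call. = FALSE)
    Xs[[i]] <- s$X[okY, , drop = FALSE]
    rs[[i]] <- as.vector(fvc[[i]]@values)[okY]
    locs[[i]] <- ctr[okY, , drop = FALSE]
  }
  X <- do.call(rbind, Xs)
  r <- do.call(c, rs)
  loc <- do.call(rbind, locs)
  D <- if (weighted) geoWeights(loc, anchors, bw) else NULL

  model <- gwannModel(config$hidden, anchors, seed = config$seed,
                      bandwidth = bw,
                      geometry = list(dim = dims, cellSize = ref@cellSize,
                                      origin = ref@origin, crs = ref@crs),
                      anchorCells = aCells, nearestAnchor = nearest)
  # start every output neuron at the target mean so the operating point is
  # not manufactured through the weights of (near-)constant inputs, which
  # would contaminate their finite-difference derivatives downstream
  L <- length(model@weights)
  model@biases[[L]] <- rep(atanh(min(0.99, max(-0.99, mean(r)))),
                           length(model@biases[[L]]))
  errs <- numeric(config$maxEpochs)
  ePrev <- Inf
  epoch <- 0L
  n <- nrow(X)
  L <- length(model@weights)
  R <- matrix(r, n, model@layerSizes[length(model@layerSizes)])
  eta <- config$eta
  while (epoch < config$maxEpochs) {
    epoch <- epoch + 1L
    # one shared forward pass yields both the epoch loss and the gradient
    A <- forwardBatch(model, X)
    P <- A[[L + 1L]]
    G <- P - R
    if (!is.null(D)) G <- G * D
    e <- sum(G * (P - R)) / (2 * n)   # = sum(D * (r - p)^2) / (2n)
    delta <- G * (1 - P^2)
    for (l in seq(L, 1L)) {
      if (l > 1L)
        deltaPrev <- (delta %*% t(model@weights[[l]])) * (1 - A[[l]]^2)
      model@weights[[l]] <- model@weights[[l]] -
        (eta / n) * crossprod(A[[l]], delta)
      model@biases[[l]] <- model@biases[[l]] - (eta / n) * colSums(delta)
      if (l > 1L) delta <- deltaPrev
    }
    errs[epoch] <- e
    if (abs(ePrev - e) < config$tolerance) break
    ePrev <- e
  }
  model@trained <- TRUE
  list(model = model,
       history = data.frame(epoch = seq_len(epoch), error = errs[seq_len(epoch)]))
}

#' Predict FVC over a grid from a trained GWANN
#'
#' Each pixel's prediction is the output neuron of its nearest anchor,
#' evaluated on the pixel's own driver vector. Raw network outputs lie in
#' (-1, 1); with `clip = TRUE` (reporting) they are clipped to \[0, 1\].
#' Attribution uses `clip = FALSE` so that finite differences see the smooth
#' surface.
#'
#' @param model a trained [GWANNModel-class].
#' @param stack a [DriverStack-class] on the training grid geometry.
#' @param clip clip predictions into \[0, 1\]?
#' @return a [Grid-class] of predicted FVC (nodata where any driver is
#'   nodata).
#' @export
predictFVC <- function(model, stack, clip = TRUE) {
  stopifnot(is(model, "GWANNModel"), is(stack, "DriverStack"))
  if (!model@trained) stop("model is not trained", call. = FALSE)
  ref <- stack@factors[[1]]
  geo <- model@geometry
  if (!all(gridDim(ref) == geo$dim) ||
      abs(ref@cellSize - geo$cellSize) > 1e-6 ||
      any(abs(ref@origin - geo$origin) > 1e-6))
    stop("prediction grid does not match the training geometry", call. = FALSE)
  s <- stackSamples(stack)
  X <- s$X[s$ok, , drop = FALSE]
  L <- length(model@weights)
  A <- X
  if (L > 1L) for (l in seq_len(L - 1L)) {
    Z <- A %*% model@weights[[l]]
    A <- tanh(sweep(Z, 2L, model@biases[[l]], "+"))
  }
  j <- model@nearestAnchor[s$ok]
  WL <- model@weights[[L]]
  out <- tanh(rowSums(A * t(WL)[j, , drop = FALSE]) + model@biases[[L]][j])
  if (clip) out <- pmin(1, pmax(0, out))
  v <- rep(NA_real_, length(s$ok))
  v[s$ok] <- out
  setGridValues(ref, matrix(v, nrow = gridDim(ref)[1]))
}

#' Accuracy of predicted FVC: RMSE and MRE
#'
#' Per year: `RMSE = sqrt(mean((pred - obs)^2))` over valid cells and
#' `MRE = mean(|pred - obs| / obs)` over cells with `obs >= mreFloor` (the
#' relative error divides by the observation). Cross-year means are arithmetic
#' means of the per-year values.
#'
#' @param predicted,observed [Grid-class]s, or lists of them (one per year).
#' @param years optional integer labels for the rows.
#' @param mreFloor exclusion floor for the MRE denominator.
#' @return data.frame with columns `year`, `rmse`, `mre`, `n`, and attributes
#'   `meanRMSE` / `meanMRE`; see [aggregateAccuracy()].
#' @export
evaluateAccuracy <- function(predicted, observed, years = NULL,
                             mreFloor = 0.01) {
  if (is(predicted, "Grid")) predicted <- list(predicted)
  if (is(observed, "Grid")) observed <- list(observed)
  stopifnot(length(predicted) == length(observed), length(predicted) >= 1L)
  if (is.null(years)) years <- seq_along(predicted)
  rows <- lapply(seq_along(predicted), function(i) {
    stopIfUnaligned(predicted[[i]], observed[[i]])
    p <- as.vector(predicted[[i]]@values)
    o <- as.vector(observed[[i]]@values)
    ok <- !is.na(p) & !is.na(o)
    if (!any(ok)) stop("no valid cells to evaluate", call. = FALSE)
    rmse <- sqrt(mean((p[ok] - o[ok])^2))
    okm <- ok & !is.na(o) & o >= mreFloor
    mre <- if (any(okm)) mean(abs((p[okm] - o[okm]) / o[okm])) else NA_real_
    data.frame(year = years[i], rmse = rmse, mre = mre, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  aggregateAccuracy(out)
}

#' @describeIn evaluateAccuracy Attach cross-year arithmetic means
#'   (`meanRMSE`, `meanMRE`) to a per-year accuracy table with columns
#'   `rmse` and `mre`.
#' @param report data.frame with columns `rmse` and `mre`.
#' @export
aggregateAccuracy <- function(report) {
  stopifnot(all(c("rmse", "mre") %in% names(report)))
  attr(report, "meanRMSE") <- mean(report$rmse)
  attr(report, "meanMRE") <- mean(report$mre, na.rm = TRUE)
  report
}

#' Save / load a GWANN checkpoint
#'
#' Checkpoints are flat JSON holding everything that defines the model: layer
#' sizes, weights and biases, anchor locations and pixel bookkeeping, kernel
#' parameters, training-grid geometry and seed. Numbers are written at full
#' precision, so a round trip reproduces predictions to double precision.
#'
#' @param model a [GWANNModel-class].
#' @param path destination (conventionally `.json`).
#' @return `writeGWANN`: `path`, invisibly. `readGWANN`: the restored
#'   [GWANNModel-class].
#' @export
writeGWANN <- function(model, path) {
  stopifnot(is(model, "GWANNModel"))
  doc <- list(
    format = "gwannSRMD-checkpoint-1",
    layerSizes = model@layerSizes,
    weights = model@weights,
    biases = model@biases,
    anchors = model@anchors,
    anchorCells = model@anchorCells,
    nearestAnchor = model@nearestAnchor,
    kernel = model@kernel,
    bandwidth = model@bandwidth,
    geometry = model@geometry,
    seed = model@seed,
    trained = model@trained)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGWANN
#' @export
readGWANN <- function(path) {
  if (!file.exists(path))
    stop(sprintf("checkpoint does not exist: '%s'", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "gwannSRMD-checkpoint-1"))
    stop(sprintf("'%s' is not a GWANN checkpoint", path), call. = FALSE)
  geo <- doc$geometry
  if (length(geo)) geo <- lapply(geo, unlist)
  new("GWANNModel",
      layerSizes = as.integer(doc$layerSizes),
      weights = lapply(doc$weights, as.matrix),
      biases = lapply(doc$biases, as.numeric),
      anchors = as.matrix(doc$anchors),
      anchorCells = as.integer(doc$anchorCells),
      nearestAnchor = as.integer(doc$nearestAnchor),
      kernel = doc$kernel,
      bandwidth = as.numeric(doc$bandwidth),
      geometry = geo,
      seed = as.integer(doc$seed),
      trained = isTRUE(doc$trained))
}
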