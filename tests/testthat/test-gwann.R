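randomAnchors <- function(m, seed = 1) {
  withr::with_seed(seed, matrix(runif(2 * m, 0, 1000), m, 2))
}

test_that("model initialization is seeded, symmetric and validated", {
  a <- randomAnchors(3)
  m1 <- gwannModel(4, a, seed = 7)
  m2 <- gwannModel(4, a, seed = 7)
  m3 <- gwannModel(4, a, seed = 8)
  expect_identical(m1@weights, m2@weights)
  expect_false(identical(m1@weights, m3@weights))
  expect_equal(m1@layerSizes, c(5L, 4L, 3L))
  # fan-in scaling of the uniform init
  expect_lte(max(abs(m1@weights[[1]])), 1 / sqrt(5))
  expect_lte(max(abs(m1@weights[[2]])), 1 / sqrt(4))
  expect_error(gwannModel(4, a[0, , drop = FALSE]), "anchor")
  expect_error(gwannModel(integer(0), a), "hidden")
})

test_that("geoWeights is a unit-peak, monotone, symmetric Gaussian kernel", {
  b <- 500
  expect_equal(geoWeights(cbind(0, 0), cbind(0, 0), b)[1, 1], 1)
  expect_equal(geoWeights(cbind(0, 0), cbind(b, 0), b)[1, 1], exp(-0.5),
               ignore_attr = TRUE)
  # two samples equidistant from one anchor get equal weights
  w <- geoWeights(rbind(c(0, 300), c(300, 0)), cbind(0, 0), b)
  expect_equal(w[1, 1], w[2, 1])
  # monotone decay along increasing distance
  d <- seq(0, 3000, by = 100)
  w2 <- geoWeights(cbind(d, 0), cbind(0, 0), b)
  expect_true(all(diff(w2[, 1]) < 0))
  expect_error(geoWeights(cbind(0, 0), cbind(0, 0), 0), "bandwidth")
})

test_that("forward pass follows the tanh composition", {
  a <- randomAnchors(3)
  m <- gwannModel(4, a, seed = 1)
  # zero network: all outputs tanh(0) = 0
  m0 <- m
  m0@weights <- lapply(m0@weights, function(w) w * 0)
  expect_equal(gwannForward(m0, rep(0.5, 5))$outputs, rep(0, 3))
  # single-path scalar network: tanh(w2 * tanh(w1 * x)) by hand
  mp <- gwannModel(1, cbind(0, 0), seed = 2)
  mp@weights[[1]] <- matrix(c(0.7, 0, 0, 0, 0), 5, 1)
  mp@weights[[2]] <- matrix(1.3, 1, 1)
  x <- c(0.4, 0, 0, 0, 0)
  expect_equal(gwannForward(mp, x)$outputs, tanh(1.3 * tanh(0.7 * 0.4)))
  # outputs bounded by the activation on random inputs
  withr::with_seed(5, for (i in 1:10) {
    out <- gwannForward(m, runif(5))$outputs
    expect_true(all(out > -1 & out < 1))
  })
  expect_error(gwannForward(m, c(1, 2, NA, 4, 5)), "finite")
})

test_that("weightedError matches the hand-worked example and its limits", {
  expect_equal(weightedError(c(0.2, 0.6), c(0.4, 0.8), c(1, 0.5)),
               0.5 * (1 * 0.04 + 0.5 * 0.04))  # = 0.03
  expect_equal(weightedError(c(0.3, 0.9), c(0.3, 0.9), c(1, 1)), 0)
  p <- c(0.1, 0.5, 0.9); r <- c(0.2, 0.4, 0.6)
  expect_equal(weightedError(p, r, rep(1, 3)), 0.5 * sum((r - p)^2))
  expect_equal(weightedError(p, r, NULL), 0.5 * sum((r - p)^2))
  expect_error(weightedError(p, r[1:2]), "length")
})

test_that("backpropDeltas: stationary point, weight nullity, formula", {
  a <- randomAnchors(2)
  m <- gwannModel(3, a, seed = 3)
  x <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  fw <- gwannForward(m, x)
  # perfect predictions -> zero output deltas
  d0 <- backpropDeltas(m, fw, targets = fw$outputs, weights = c(1, 1))
  expect_equal(d0[[2]], c(0, 0))
  expect_equal(d0[[1]], c(0, 0, 0))
  # a zero geographic weight silences that output everywhere upstream
  dA <- backpropDeltas(m, fw, targets = c(0.9, 0.1), weights = c(1, 0))
  expect_equal(dA[[2]][2], 0)
  mOnly1 <- m
  mOnly1@weights[[2]][, 2] <- 0  # removing output 2's influence changes nothing
  fw1 <- gwannForward(mOnly1, x)
  dB <- backpropDeltas(mOnly1, fw1, targets = c(0.9, 0.1), weights = c(1, 0))
  expect_equal(dA[[1]], dB[[1]])
  # output delta formula phi'(L) * D * (p - r)
  tgt <- c(0.3, 0.7); wts <- c(0.8, 0.4)
  dC <- backpropDeltas(m, fw, tgt, wts)
  expect_equal(dC[[2]], (1 - fw$outputs^2) * wts * (fw$outputs - tgt))
  expect_error(backpropDeltas(m, list(), tgt, wts), "cache")
})

test_that("updateWeights applies -eta * delta * p and descends", {
  a <- randomAnchors(2)
  m <- gwannModel(3, a, seed = 4)
  x <- runif(5)
  fw <- gwannForward(m, x)
  d <- backpropDeltas(m, fw, targets = c(0.5, 0.2), weights = c(1, 0.5))
  # eta = 0: nothing moves
  m0 <- updateWeights(m, d, fw, 0)
  expect_identical(m0@weights, m@weights)
  # hand-check one connection: w_new = w - eta * p_i * delta_j
  m1 <- updateWeights(m, d, fw, 0.1)
  pHidden <- fw$activations[[2]][1, ]
  expect_equal(m1@weights[[2]][2, 1],
               m@weights[[2]][2, 1] - 0.1 * pHidden[2] * d[[2]][1])
  expect_equal(m1@weights[[1]][3, 2],
               m@weights[[1]][3, 2] - 0.1 * x[3] * d[[1]][2])
  expect_equal(m1@biases[[2]][1], m@biases[[2]][1] - 0.1 * d[[2]][1])
  # repeated small steps strictly decrease the weighted error
  wts <- c(1, 0.5); tgt <- c(0.5, 0.2)
  errs <- numeric(25)
  mm <- m
  for (i in 1:25) {
    fwi <- gwannForward(mm, x)
    errs[i] <- weightedError(fwi$outputs, tgt, wts)
    mm <- updateWeights(mm, backpropDeltas(mm, fwi, tgt, wts), fwi, 0.05)
  }
  expect_true(all(diff(errs) < 0))
})

test_that("analytic gradients equal central differences on random 5-4-3 nets", {
  for (seed in 1:3) {
    m <- gwannModel(4, randomAnchors(3, seed), seed = seed)
    withr::with_seed(100 + seed, {
      X <- matrix(runif(5 * 6), 6, 5)
      r <- runif(6)
      D <- geoWeights(matrix(runif(12, 0, 1000), 6, 2), m@anchors, 400)
    })
    g <- gwannGradient(m, X, r, D)
    eps <- 1e-6
    for (l in 1:2) {
      idx <- rbind(c(1, 1), c(dim(m@weights[[l]])))  # corners of each matrix
      for (k in seq_len(nrow(idx))) {
        i <- idx[k, 1]; j <- idx[k, 2]
        mp <- m; mp@weights[[l]][i, j] <- mp@weights[[l]][i, j] + eps
        mn <- m; mn@weights[[l]][i, j] <- mn@weights[[l]][i, j] - eps
        num <- (gwannLoss(mp, X, r, D) - gwannLoss(mn, X, r, D)) / (2 * eps)
        expect_equal(g$weights[[l]][i, j], num, tolerance = 1e-6)
      }
    }
  }
})

test_that("training is deterministic and prediction respects geometry and clip", {
  sc <- generateScene(tinySceneConfig(seed = 2))
  cfg <- fastConfig(seed = 2)
  y <- as.character(sc$years[1])
  f1 <- trainGWANN(sc$stacks[[y]], sc$fvc[[y]], cfg)
  f2 <- trainGWANN(sc$stacks[[y]], sc$fvc[[y]], cfg)
  expect_identical(f1$model@weights, f2$model@weights)
  expect_identical(f1$history, f2$history)

  p <- predictFVC(f1$model, sc$stacks[[y]])
  expect_true(sameGeometry(p, sc$fvc[[y]]))
  expect_true(all(gridValues(p) >= 0 & gridValues(p) <= 1, na.rm = TRUE))
  pRaw <- predictFVC(f1$model, sc$stacks[[y]], clip = FALSE)
  expect_equal(gridValues(p),
               pmin(pmax(gridValues(pRaw), 0), 1))

  other <- generateScene(tinySceneConfig(seed = 3))
  big <- generateScene(sceneConfig(nrow = 30L, ncol = 30L,
                                   noMiningYears = c(1992L, 1995L, 1996L),
                                   miningYears = 2020L, seed = 3))
  expect_error(predictFVC(f1$model, big$stacks[[1]]), "geometry")
})

test_that("accuracy metrics follow their definitions", {
  g <- tinyGrid(matrix(runif(25, 0.2, 0.9), 5, 5))
  acc0 <- evaluateAccuracy(g, g)
  expect_equal(acc0$rmse, 0)
  expect_equal(acc0$mre, 0)

  p <- tinyGrid(matrix(c(0.5, 0.6, 0.7, 0.005, NA, runif(20)), 5, 5))
  o <- tinyGrid(matrix(c(0.4, 0.5, 0.9, 0.002, 0.5, runif(20)), 5, 5))
  acc <- evaluateAccuracy(p, o, mreFloor = 0.01)
  pv <- as.vector(gridValues(p)); ov <- as.vector(gridValues(o))
  ok <- !is.na(pv) & !is.na(ov)
  expect_equal(acc$rmse, sqrt(mean((pv[ok] - ov[ok])^2)))
  okm <- ok & ov >= 0.01
  expect_equal(acc$mre, mean(abs((pv[okm] - ov[okm]) / ov[okm])))
  expect_equal(acc$n, sum(ok))

  rep2 <- aggregateAccuracy(data.frame(rmse = c(0.1, 0.3), mre = c(0.2, 0.4)))
  expect_equal(attr(rep2, "meanRMSE"), 0.2)
  expect_equal(attr(rep2, "meanMRE"), 0.3)
})

test_that("a checkpoint round trip reproduces the model and its predictions", {
  sc <- generateScene(tinySceneConfig(seed = 31))
  cfg <- fastConfig(seed = 31)
  y <- as.character(sc$years[1])
  fit <- trainGWANN(sc$stacks[[y]], sc$fvc[[y]], cfg)
  tmp <- withr::local_tempfile(fileext = ".json")
  writeGWANN(fit$model, tmp)
  back <- readGWANN(tmp)
  expect_equal(back@layerSizes, fit$model@layerSizes)
  expect_equal(back@weights, fit$model@weights, tolerance = 1e-12)
  expect_equal(gridValues(predictFVC(back, sc$stacks[[y]])),
               gridValues(predictFVC(fit$model, sc$stacks[[y]])),
               tolerance = 1e-12)
  expect_error(readGWANN("nope.json"), "nope.json")
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(readGWANN(bad), "checkpoint")
})
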