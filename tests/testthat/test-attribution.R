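test_that("perturbFactor applies the relative bias to one factor only", {
  sc <- generateScene(tinySceneConfig(seed = 8))
  st <- sc$stacks[[1]]
  p <- perturbFactor(st, "dem", biasFactor = 0.001)
  x <- gridValues(st@factors$dem)
  expect_equal(gridValues(p$bias)[x != 0], (0.001 * x)[x != 0])
  # a cell at exactly 0 gets the absolute floor
  expect_equal(gridValues(p$bias)[x == 0],
               rep(1e-6, sum(x == 0)))
  expect_equal(gridValues(p$stack@factors$dem), x + gridValues(p$bias))
  # untouched factors are bit-identical
  for (nm in c("pre", "temp", "urban", "mine"))
    expect_identical(gridValues(p$stack@factors[[nm]]),
                     gridValues(st@factors[[nm]]))
  # X = 0.5 -> dX = 0.0005
  st2 <- st
  st2@factors$urban <- setGridValues(st2@factors$urban, matrix(0.5, 24, 24))
  expect_equal(gridValues(perturbFactor(st2, "urban")$bias),
               matrix(5e-4, 24, 24), ignore_attr = TRUE)
  expect_error(perturbFactor(st, "cosmic"), "cosmic")
})

test_that("contribution shares follow the signed-denominator formula", {
  ref <- tinyGrid(matrix(0, 3, 3))
  mk <- function(v) setGridValues(ref, matrix(v, 3, 3))
  C <- list(pre = mk(1), temp = mk(1), dem = mk(1), urban = mk(1),
            mine = mk(1))
  cm <- contributionShares(C)
  for (nm in names(C)) expect_equal(gridValues(cm@W[[nm]]),
                                    matrix(0.2, 3, 3), ignore_attr = TRUE)
  C2 <- list(pre = mk(2), temp = mk(1), dem = mk(1), urban = mk(0),
             mine = mk(0))
  cm2 <- contributionShares(C2)
  expect_equal(gridValues(cm2@W$pre)[1, 1], 0.5)
  expect_equal(gridValues(cm2@W$temp)[1, 1], 0.25)
  expect_equal(gridValues(cm2@W$mine)[1, 1], 0)
  # shares sum to 1 wherever defined, including mixed signs
  set.seed(13)
  C3 <- lapply(C, function(g) mk(rnorm(9)))
  cm3 <- contributionShares(C3)
  tot <- Reduce(`+`, lapply(cm3@W, gridValues))
  expect_equal(tot[!is.na(tot)], rep(1, sum(!is.na(tot))))
  # a denominator below the floor becomes nodata, not an unbounded share
  C4 <- list(pre = mk(1), temp = mk(-1), dem = mk(0.5), urban = mk(-0.5),
             mine = mk(1e-12))
  cm4 <- contributionShares(C4)
  expect_true(all(is.na(gridValues(cm4@W$mine))))
  expect_error(contributionShares(C[1:4]), "five")
})

test_that("fitNoise summarises samples and takes the empirical quantile", {
  withr::with_seed(31, {
    z <- rnorm(2e5)
    nm <- fitNoise(z, alpha = 0.05)
  })
  expect_equal(nm@mean, mean(z))
  expect_equal(nm@sd, sd(z))
  expect_equal(nm@criticalValue, quantile(z, 0.95, names = FALSE))
  expect_equal(nm@criticalValue, 1.645, tolerance = 0.02)  # known N(0,1) quantile
  # histogram Gaussian fit is a sound diagnostic on normal data
  expect_equal(unname(nm@gaussianFit["centre"]), 0, tolerance = 0.02)
  expect_equal(unname(nm@gaussianFit["width"]), 1, tolerance = 0.05)
  expect_error(fitNoise(rnorm(50)), "100")
  expect_error(fitNoise(z, alpha = 1.2), "alpha")
})

test_that("significanceMask flags strictly above the critical value", {
  withr::with_seed(17, nm <- fitNoise(rnorm(5000, 0.054, 0.017)))
  ref <- tinyGrid(matrix(0, 2, 2))
  w <- setGridValues(ref, matrix(c(0.09, nm@criticalValue,
                                   nm@criticalValue + 1e-9, NA), 2, 2))
  m <- significanceMask(w, nm)
  expect_true(gridValues(m)[1, 1])    # 0.09 > ~0.085
  expect_false(gridValues(m)[2, 1])   # exactly at the critical value: kept null
  expect_true(gridValues(m)[1, 2])
  expect_false(gridValues(m)[2, 2])   # nodata never flagged
})

test_that("type-I error of the test matches alpha on null draws", {
  withr::with_seed(23, {
    noise <- fitNoise(rnorm(5e4, 0.054, 0.017), alpha = 0.05)
    n <- 1e4
    w <- grid(matrix(rnorm(n, 0.054, 0.017), 100, 100), cellSize = 30)
    frac <- mean(gridValues(significanceMask(w, noise)))
  })
  expect_equal(frac, 0.05, tolerance = 2 * sqrt(0.05 * 0.95 / n) / 0.05)
})

test_that("virtualContribution requires virtual stacks and keeps year bookkeeping", {
  sc <- generateScene(tinySceneConfig(seed = 14))
  cfg <- fastConfig(seed = 14)
  nm <- as.character(sc$config$noMiningYears)
  out <- virtualContribution(sc$stacks[nm], sc$fvc[nm], cfg)
  expect_setequal(names(out$wMine), nm)
  expect_s4_class(out$wMine[[1]], "Grid")
  expect_equal(nrow(out$accuracy), length(nm))
  # deterministic under the same seed
  out2 <- virtualContribution(sc$stacks[nm], sc$fvc[nm], cfg)
  expect_identical(gridValues(out$wMine[[1]]), gridValues(out2$wMine[[1]]))
  # a real-mining stack is rejected
  expect_error(virtualContribution(sc$stacks["2020"], sc$fvc["2020"], cfg),
               "virtual")
})

test_that("finite-difference derivative is stable under step halving", {
  sc <- generateScene(tinySceneConfig(seed = 16, noiseSd = 0.02))
  cfg <- fastConfig(seed = 16, maxEpochs = 120L)
  y <- as.character(sc$config$miningYears[1])
  fit <- trainGWANN(sc$stacks[[y]], sc$fvc[[y]], cfg)
  c1 <- gridValues(partialDerivative(fit$model, sc$stacks[[y]], "dem", 0.001))
  c2 <- gridValues(partialDerivative(fit$model, sc$stacks[[y]], "dem", 0.0005))
  rel <- abs(c2 - c1) / pmax(abs(c1), 1e-6)
  expect_lt(stats::median(rel, na.rm = TRUE), 0.01)
})
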