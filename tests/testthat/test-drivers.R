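test_that("distanceToRegion matches the brute-force oracle exactly", {
  set.seed(3)
  for (i in 1:6) {
    nr <- sample(8:30, 1); nc <- sample(8:30, 1)
    ref <- grid(matrix(0, nr, nc), cellSize = 30, origin = c(0, nr * 30),
                crs = "t")
    m <- matrix(runif(nr * nc) < 0.08, nr, nc)
    if (!any(m)) m[sample(nr * nc, 1)] <- TRUE
    mask <- regionMask(m, ref)
    got <- gridValues(distanceToRegion(ref, mask))
    expect_equal(got, bruteDistanceKm(ref, m), tolerance = 1e-12)
  }
})

test_that("distanceToRegion: inside zero, 4-neighbour one cell, single-cell closed form", {
  ref <- grid(matrix(0, 10, 10), cellSize = 100, origin = c(0, 1000), crs = "t")
  m <- matrix(FALSE, 10, 10); m[4, 6] <- TRUE
  d <- gridValues(distanceToRegion(ref, regionMask(m, ref)))
  expect_equal(d[4, 6], 0)
  expect_equal(d[5, 6], 0.1)  # 4-neighbour: one 100 m step
  # closed form sqrt(dr^2 + dc^2) * cellsize / 1000 everywhere
  want <- outer(1:10, 1:10, function(r, c) sqrt((r - 4)^2 + (c - 6)^2) * 0.1)
  expect_equal(d, want, tolerance = 1e-12)
  expect_error(distanceToRegion(ref, regionMask(matrix(FALSE, 10, 10), ref)),
               "empty")
})

test_that("quantifyActivity is magnitude/(distance+1), linear and monotone", {
  ref <- grid(matrix(0, 1, 3), cellSize = 1000, origin = c(0, 1000), crs = "t")
  d <- setGridValues(ref, matrix(c(0, 9, 4), 1, 3))
  q <- quantifyActivity(10, d)
  expect_equal(as.vector(gridValues(q)), c(10, 1, 2))
  expect_equal(gridValues(quantifyActivity(0, d)),
               matrix(0, 1, 3), ignore_attr = TRUE)
  expect_equal(gridValues(quantifyActivity(20, d)), 2 * gridValues(q))
  expect_error(quantifyActivity(-1, d), "non-negative")
})

test_that("virtual mining factor equals activity over distance and decays along rays", {
  nr <- 20
  ref <- grid(matrix(0, nr, nr), cellSize = 90, origin = c(0, nr * 90),
              crs = "t")
  m <- matrix(FALSE, nr, nr); m[9:12, 9:12] <- TRUE
  mask <- regionMask(m, ref)
  vf <- quantifyVirtualMining(32, mask, ref)
  expect_s3_class(vf, "driverField")
  expect_true(vf$virtual)
  expect_equal(gridValues(vf$raw),
               gridValues(quantifyActivity(32, distanceToRegion(ref, mask))))
  expect_equal(gridValues(quantifyVirtualMining(64, mask, ref)$raw),
               2 * gridValues(vf$raw))
  # non-increasing along a ray walking east from the region
  ray <- gridValues(vf$raw)[10, 12:nr]
  expect_true(all(diff(ray) <= 0))
})

test_that("normalizeFactor maps min/max to 0/1 and rejects constants", {
  out <- normalizeFactor(c(2, 4, 6))
  expect_equal(out$values, c(0, 0.5, 1))
  expect_equal(out$bounds, c(2, 6))
  set.seed(9)
  x <- runif(50, -3, 7)
  nv <- normalizeFactor(x)$values
  expect_equal(nv[which.min(x)], 0)
  expect_equal(nv[which.max(x)], 1)
  # idempotent on already-normalized data with unit bounds
  expect_equal(normalizeFactor(nv, bounds = c(0, 1))$values, nv)
  expect_error(normalizeFactor(rep(3, 5), factorId = "temp"), "temp")
})

test_that("pearsonWindowSelection ranks windows by |r| with the right aggregation", {
  set.seed(11)
  ny <- 8
  meteo <- matrix(runif(ny * 12, 0, 120), ny, 12)
  winds <- list(7L, 6:8, 7:9)
  # FVC equal to the June-August accumulation -> r = 1 and top rank
  fvc <- rowSums(meteo[, 6:8])
  out <- pearsonWindowSelection(fvc, meteo, winds, "precipitation")
  expect_equal(out$r[out$window == "6-8"], 1)
  expect_equal(out$window[1], "6-8")
  # negated aggregate -> r = -1
  out2 <- pearsonWindowSelection(-fvc, meteo, winds, "precipitation")
  expect_equal(out2$r[out2$window == "6-8"], -1)
  # direct sum-formula oracle for temperature (means)
  fvc3 <- runif(ny)
  out3 <- pearsonWindowSelection(fvc3, meteo, list(7:9), "temperature")
  a <- rowMeans(meteo[, 7:9])
  rOracle <- sum((fvc3 - mean(fvc3)) * (a - mean(a))) /
    sqrt(sum((fvc3 - mean(fvc3))^2) * sum((a - mean(a))^2))
  expect_equal(out3$r, rOracle)
  # zero variance -> NA
  outZ <- pearsonWindowSelection(rep(0.5, ny), meteo, list(7L))
  expect_true(is.na(outZ$r))
  expect_error(pearsonWindowSelection(fvc[1:2], meteo[1:2, ], winds), "three")
  expect_error(pearsonWindowSelection(fvc, meteo, list(13L)), "1..12")
})

test_that("driver stacks flag virtual mining years and keep factors in [0,1]", {
  sc <- generateScene(tinySceneConfig(seed = 5))
  cfg <- srmdConfig(years = sc$years,
                    noMiningYears = sc$config$noMiningYears)
  stacks <- buildDriverStacks(sc$dem, sc$meteo, sc$activity, sc$urban,
                              sc$mine, cfg)
  expect_named(stacks, as.character(sc$years))
  for (y in as.character(sc$years)) {
    st <- stacks[[y]]
    expect_s4_class(st, "DriverStack")
    expect_equal(st@miningIsVirtual,
                 st@year %in% cfg$noMiningYears)
    for (nm in c("pre", "temp", "dem", "urban", "mine")) {
      v <- gridValues(st@factors[[nm]])
      expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
    }
  }
  # DEM factor identical across years (same input DEM)
  expect_equal(gridValues(stacks[[1]]@factors$dem),
               gridValues(stacks[[2]]@factors$dem))
  # the virtual factor equals the real one built from the assumed pair
  expect_equal(gridValues(stacks[["1992"]]@factors$mine),
               gridValues(stacks[["2020"]]@factors$mine))
})
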