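test_that("maskBoundary finds 8-connectivity boundaries with edge convention", {
  ref <- tinyGrid(matrix(0, 9, 9))
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_equal(gridValues(maskBoundary(regionMask(one, ref))), one)

  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  bnd <- gridValues(maskBoundary(regionMask(sq, ref)))
  expect_equal(sum(bnd), 16L)              # perimeter of a filled 5x5 square
  expect_false(bnd[5, 5])                  # interior excluded
  # brute-force neighbour-scan oracle
  oracle <- matrix(FALSE, 9, 9)
  for (r in 1:9) for (c in 1:9) if (sq[r, c]) {
    out <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > 9 || cc < 1 || cc > 9 || !sq[rr, cc]) out <- TRUE
    }
    oracle[r, c] <- out
  }
  expect_equal(bnd, oracle)

  allT <- matrix(TRUE, 9, 9)
  bndAll <- gridValues(maskBoundary(regionMask(allT, ref)))
  inner <- matrix(TRUE, 9, 9); inner[2:8, 2:8] <- FALSE
  expect_equal(bndAll, inner)              # grid-edge pixels only
  expect_error(maskBoundary(regionMask(matrix(FALSE, 9, 9), ref)), "empty")
})

test_that("disturbanceDistances equals the brute-force all-pairs oracle", {
  set.seed(21)
  for (i in 1:5) {
    nr <- sample(10:40, 1)
    ref <- grid(matrix(0, nr, nr), cellSize = 90, origin = c(0, nr * 90),
                crs = "t")
    mine <- matrix(FALSE, nr, nr)
    mine[sample(nr, 3), sample(nr, 3)] <- TRUE
    blob <- matrix(runif(nr * nr) < 0.2, nr, nr)
    blob <- blob | mine
    dd <- disturbanceDistances(regionMask(blob, ref), regionMask(mine, ref))
    # oracle: boundary pixels by neighbour scan, then all-pairs min distance
    bnd <- gridValues(maskBoundary(regionMask(blob, ref)))
    want <- bruteDistanceKm(ref, mine)[bnd]
    expect_equal(sort(dd$distances), sort(want), tolerance = 1e-12)
    expect_true(all(diff(unlist(dd$stats[c("q25", "median", "q75", "max")]))
                    >= 0))
  }
})

test_that("disturbance distance is 0 where the SRMD touches or equals the mine", {
  ref <- tinyGrid(matrix(0, 12, 12))
  mine <- matrix(FALSE, 12, 12); mine[5:8, 5:8] <- TRUE
  mineM <- regionMask(mine, ref)
  ddSelf <- disturbanceDistances(mineM, mineM)   # SRMD = mine region
  expect_true(all(ddSelf$distances == 0))
  srmd <- matrix(FALSE, 12, 12); srmd[5:8, 5:10] <- TRUE  # overlaps the mine
  dd <- disturbanceDistances(regionMask(srmd, ref), mineM)
  expect_equal(min(dd$distances), 0)
  expect_error(disturbanceDistances(regionMask(matrix(FALSE, 12, 12), ref),
                                    mineM), "empty")
})

test_that("bufferFraction has the right limits and is monotone in radius", {
  ref <- tinyGrid(matrix(0, 20, 20), cs = 90)
  mine <- matrix(FALSE, 20, 20); mine[9:12, 9:12] <- TRUE
  set.seed(4)
  srmd <- matrix(runif(400) < 0.3, 20, 20); srmd[10, 10] <- TRUE
  sm <- regionMask(srmd, ref); mm <- regionMask(mine, ref)
  expect_equal(bufferFraction(sm, mm, 1e6), 1)            # radius -> Inf
  expect_equal(bufferFraction(sm, mm, 0),
               sum(srmd & mine) / sum(srmd))              # radius 0
  radii <- seq(0, 2, by = 0.1)
  fr <- vapply(radii, function(r) bufferFraction(sm, mm, r), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("directional sectors partition the boundary and respect geometry", {
  nr <- 31
  ref <- grid(matrix(0, nr, nr), cellSize = 90, origin = c(0, nr * 90),
              crs = "t")
  mine <- matrix(FALSE, nr, nr); mine[15:17, 15:17] <- TRUE
  mm <- regionMask(mine, ref)

  # isotropic disk -> all sectors within one cell size of each other
  ctr <- cellCenters(ref)
  cen <- colMeans(ctr[as.vector(mine), ])
  dc <- sqrt((ctr[, 1] - cen[1])^2 + (ctr[, 2] - cen[2])^2)
  disk <- matrix(dc <= 900, nr, nr)
  dr <- directionalRanges(regionMask(disk, ref), mm, 8L)
  expect_equal(sum(dr$n), sum(gridValues(maskBoundary(regionMask(disk, ref)))))
  expect_lt(max(dr$max) - min(dr$max), 0.09 + 1e-9)

  # SRMD confined to the NE quadrant -> only north/east sectors populated
  ne <- matrix(FALSE, nr, nr); ne[3:10, 22:29] <- TRUE
  ne <- ne | mine  # keep the mine itself so distances start at 0
  drNE <- directionalRanges(regionMask(ne, ref), mm, 8L)
  az <- azimuths <- (atan2(ctr[, 1] - cen[1], ctr[, 2] - cen[2]) * 180 / pi) %% 360
  bndNE <- as.vector(gridValues(maskBoundary(regionMask(ne, ref))))
  secOracle <- sort(unique(pmin(8, floor(az[bndNE] / 45) + 1)))
  expect_setequal(dr$sector[drNE$n > 0], secOracle)

  # one sector recovers the global range
  dd <- disturbanceDistances(regionMask(ne, ref), mm)
  dr1 <- directionalRanges(regionMask(ne, ref), mm, 1L)
  expect_equal(dr1$min, min(dd$distances))
  expect_equal(dr1$max, max(dd$distances))
})

test_that("srmdMetrics bundles distances, buffer fraction and directions", {
  ref <- tinyGrid(matrix(0, 15, 15), cs = 90)
  mine <- matrix(FALSE, 15, 15); mine[7:9, 7:9] <- TRUE
  srmd <- matrix(FALSE, 15, 15); srmd[5:11, 5:11] <- TRUE
  res <- srmdMetrics(regionMask(srmd, ref), regionMask(mine, ref),
                     bufferKm = 3)
  expect_s3_class(res, "srmdResult")
  expect_equal(res$bufferFraction, 1)
  expect_equal(nrow(res$directions), 8L)
  expect_output(print(res), "disturbance distance")
})
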