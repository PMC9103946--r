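# shared fixtures: tiny grids and fast study configs used across test files

tinyGrid <- function(values, cs = 30) {
  grid(as.matrix(values), cellSize = cs, origin = c(0, nrow(as.matrix(values)) * cs),
       crs = "test-metres")
}

# desk-scale scene kept small for unit tests (not the acceptance scenes)
tinySceneConfig <- function(seed = 1L, ...) {
  sceneConfig(nrow = 24L, ncol = 24L, cellSizeM = 90,
              noMiningYears = c(1992L, 1995L, 1996L), miningYears = 2020L,
              seed = seed, ...)
}

fastConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(anchorBudget = 36L, maxEpochs = 60L, eta = 0.3, seed = seed),
    list(...))
  do.call(srmdConfig, args)
}

# brute-force oracle: min centre-to-centre distance from every cell to any
# TRUE cell of `mask` (km)
bruteDistanceKm <- function(ref, mask) {
  ctr <- cellCenters(ref)
  tgt <- ctr[as.vector(mask), , drop = FALSE]
  d <- vapply(seq_len(nrow(ctr)), function(i)
    sqrt(min((tgt[, 1] - ctr[i, 1])^2 + (tgt[, 2] - ctr[i, 2])^2)),
    numeric(1))
  matrix(d, nrow = gridDim(ref)[1]) / 1000
}
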