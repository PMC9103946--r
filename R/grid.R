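#' Construct a Grid
#'
#' @param values numeric matrix (row 1 = northernmost row); `NA` marks nodata.
#' @param cellSize cell size in metres.
#' @param origin map coordinates `c(x, y)` of the outer top-left corner.
#' @param crs free-text CRS tag; all grids of a study must share it.
#' @param nodata sentinel value used on disk; occurrences in `values` are
#'   converted to `NA`.
#' @return a [Grid-class] object.
#' @examples
#' g <- grid(matrix(1:12, 3, 4), cellSize = 30, origin = c(0, 90))
#' gridDim(g)
#' @export
grid <- function(values, cellSize = 30, origin = c(0, nrow(values) * cellSize),
                 crs = "local-metres", nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[values == nodata] <- NA_real_
  new("Grid", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin), nodata = as.numeric(nodata),
      crs = as.character(crs))
}

#' Construct a RegionMask aligned to a reference Grid
#'
#' @param values logical matrix, or anything coercible; `NA` becomes `FALSE`.
#' @param ref reference [Grid-class] supplying the georeferencing.
#' @return a [RegionMask-class].
#' @export
regionMask <- function(values, ref) {
  stopifnot(is(ref, "Grid"))
  values <- as.matrix(values)
  mode(values) <- "logical"
  values[is.na(values)] <- FALSE
  if (!all(dim(values) == dim(ref@values)))
    stop("mask shape does not match the reference grid")
  new("RegionMask", values = values, cellSize = ref@cellSize,
      origin = ref@origin, nodata = -9999, crs = ref@crs)
}

#' @describeIn grid Extract the value matrix (NA = nodata).
#' @param x a [Grid-class].
#' @export
gridValues <- function(x) {
  stopifnot(is(x, "Grid"))
  x@values
}

#' @describeIn grid Replace the value matrix, keeping the georeferencing.
#' @export
setGridValues <- function(x, values) {
  stopifnot(is(x, "Grid"))
  values <- as.matrix(values)
  if (!all(dim(values) == dim(x@values)))
    stop("replacement values have the wrong shape")
  if (is(x, "RegionMask")) mode(values) <- "logical"
  else storage.mode(values) <- "double"
  x@values <- values
  validObject(x)
  x
}

#' @describeIn grid Cell size in metres.
#' @export
cellSize <- function(x) {
  stopifnot(is(x, "Grid"))
  x@cellSize
}

#' @describeIn grid Map coordinates of the outer top-left corner.
#' @export
gridOrigin <- function(x) {
  stopifnot(is(x, "Grid"))
  x@origin
}

#' @describeIn grid Dimensions `c(nrow, ncol)`.
#' @export
gridDim <- function(x) {
  stopifnot(is(x, "Grid"))
  dim(x@values)
}

#' Cell-centre coordinates of a Grid
#'
#' Returns the map coordinates of every pixel centre, column-major (the order
#' of `as.vector(gridValues(x))`): pixel (r, c) sits at
#' `origin + (c - 0.5, -(r - 0.5)) * cellSize`.
#'
#' @param x a [Grid-class].
#' @return an `n x 2` matrix of (x, y) coordinates.
#' @export
cellCenters <- function(x) {
  stopifnot(is(x, "Grid"))
  d <- dim(x@values)
  cs <- x@cellSize
  xs <- x@origin[1] + (seq_len(d[2]) - 0.5) * cs
  ys <- x@origin[2] - (seq_len(d[1]) - 0.5) * cs
  cbind(x = rep(xs, each = d[1]), y = rep(ys, times = d[2]))
}

#' Do two grids share shape, cell size, origin and CRS?
#'
#' @param a,b [Grid-class] objects.
#' @param tol positional tolerance in metres.
#' @return `TRUE` or `FALSE`.
#' @export
sameGeometry <- function(a, b, tol = 1e-6) {
  is(a, "Grid") && is(b, "Grid") &&
    all(dim(a@values) == dim(b@values)) &&
    abs(a@cellSize - b@cellSize) <= tol &&
    all(abs(a@origin - b@origin) <= tol) &&
    identical(a@crs, b@crs)
}

#' Assert alignment of grids, with a helpful error
#' @param ... grids to compare against the first.
#' @keywords internal
stopIfUnaligned <- function(...) {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1])
    if (!sameGeometry(ref, g))
      stop("input grids are not aligned; run alignGrids() first", call. = FALSE)
  invisible(TRUE)
}

setMethod("show", "Grid", function(object) {
  d <- dim(object@values)
  v <- object@values[!is.na(object@values)]
  cat(sprintf("%s: %d x %d cells of %.6g m [%s]\n", class(object),
              d[1], d[2], object@cellSize, object@crs))
  cat(sprintf("  origin (top-left): (%.6g, %.6g)\n",
              object@origin[1], object@origin[2]))
  if (is.logical(object@values)) {
    cat(sprintf("  %d of %d cells TRUE\n", sum(object@values),
                length(object@values)))
  } else if (length(v)) {
    cat(sprintf("  values: [%.6g, %.6g], %d nodata cells\n",
                min(v), max(v), sum(is.na(object@values))))
  } else cat("  all cells nodata\n")
})

extentOf <- function(g) {
  d <- dim(g@values)
  c(xmin = g@origin[1], xmax = g@origin[1] + d[2] * g@cellSize,
    ymin = g@origin[2] - d[1] * g@cellSize, ymax = g@origin[2])
}

#' Align grids onto a common lattice
#'
#' Crops all grids to their common spatial intersection, snapped to the first
#' grid's lattice, resampling by nearest neighbour. Cell size and CRS must
#' agree. Already-aligned inputs are returned unchanged.
#'
#' @param grids list of [Grid-class] objects with overlapping extents.
#' @return list of aligned grids (same length and order as the input).
#' @export
alignGrids <- function(grids) {
  stopifnot(is.list(grids), length(grids) >= 1L)
  lapply(grids, function(g) stopifnot(is(g, "Grid")))
  ref <- grids[[1]]
  if (all(vapply(grids, sameGeometry, logical(1), a = ref)))
    return(grids)
  cs <- ref@cellSize
  for (g in grids) {
    if (abs(g@cellSize - cs) > 1e-9)
      stop("alignGrids() requires a common cell size (no rescaling)")
    if (!identical(g@crs, ref@crs))
      stop("alignGrids() requires a common CRS tag")
  }
  exts <- vapply(grids, extentOf, numeric(4))
  xmin <- max(exts["xmin", ]); xmax <- min(exts["xmax", ])
  ymin <- max(exts["ymin", ]); ymax <- min(exts["ymax", ])
  if (xmin >= xmax - 1e-9 || ymin >= ymax - 1e-9)
    stop("grids have disjoint extents; nothing to align")
  # snap the intersection inward onto the first grid's lattice
  c0 <- ceiling((xmin - ref@origin[1]) / cs - 1e-9)
  xmin <- ref@origin[1] + c0 * cs
  r0 <- ceiling((ref@origin[2] - ymax) / cs - 1e-9)
  ymax <- ref@origin[2] - r0 * cs
  nc <- floor((xmax - xmin) / cs + 1e-9)
  nr <- floor((ymax - ymin) / cs + 1e-9)
  if (nc < 1L || nr < 1L)
    stop("grid intersection is empty after snapping")
  xc <- xmin + (seq_len(nc) - 0.5) * cs
  yc <- ymax - (seq_len(nr) - 0.5) * cs
  lapply(grids, function(g) {
    d <- dim(g@values)
    ci <- round((xc - g@origin[1]) / cs + 0.5)
    ri <- round((g@origin[2] - yc) / cs + 0.5)
    out <- matrix(NA_real_, nr, nc)
    okc <- ci >= 1L & ci <= d[2]
    okr <- ri >= 1L & ri <= d[1]
    out[okr, okc] <- g@values[ri[okr], ci[okc], drop = FALSE]
    if (is(g, "RegionMask")) {
      mode(out) <- "logical"
      out[is.na(out)] <- FALSE
      new("RegionMask", values = out, cellSize = cs, origin = c(xmin, ymax),
          nodata = -9999, crs = g@crs)
    } else {
      new("Grid", values = out, cellSize = cs, origin = c(xmin, ymax),
          nodata = g@nodata, crs = g@crs)
    }
  })
}
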