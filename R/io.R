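#' Read a raster from an ESRI ASCII grid file
#'
#' Rasters are carried on disk as ESRI ASCII grids (`.asc`), a plain-text
#' single-band format with full georeferencing in the header. A sidecar
#' `<file>.prj`, when present, supplies the CRS tag; otherwise `crs` is used.
#'
#' @param path path to an `.asc` file.
#' @param crs CRS tag to attach when no `.prj` sidecar exists.
#' @return a [Grid-class].
#' @seealso [writeGrid()]
#' @export
readGrid <- function(path, crs = "local-metres") {
  if (!file.exists(path))
    stop(sprintf("raster file does not exist: '%s'", path), call. = FALSE)
  sg <- tryCatch(sp::read.asciigrid(path),
    error = function(e) stop(sprintf(
      "'%s' is not a readable georeferenced ASCII grid: %s",
      path, conditionMessage(e)), call. = FALSE))
  p <- sp::gridparameters(sg)
  if (abs(p$cellsize[1] - p$cellsize[2]) > 1e-9)
    stop(sprintf("'%s' has non-square cells; unsupported", path), call. = FALSE)
  nr <- p$cells.dim[2]; nc <- p$cells.dim[1]; cs <- p$cellsize[1]
  # sp returns values west->east, north->south
  vals <- matrix(sg@data[[1]], nrow = nr, ncol = nc, byrow = TRUE)
  origin <- c(p$cellcentre.offset[1] - cs / 2,
              p$cellcentre.offset[2] - cs / 2 + nr * cs)
  prj <- paste0(path, ".prj")
  if (file.exists(prj)) crs <- readLines(prj, n = 1L, warn = FALSE)
  new("Grid", values = vals, cellSize = cs, origin = origin,
      nodata = -9999, crs = crs)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' `NA` cells are written as the grid's nodata sentinel; the CRS tag goes to a
#' `<file>.prj` sidecar. Round-tripping preserves integer values exactly and
#' floating values to better than 1e-7.
#'
#' @param x a [Grid-class] (a [RegionMask-class] is written as 0/1).
#' @param path destination `.asc` path.
#' @return `path`, invisibly.
#' @export
writeGrid <- function(x, path) {
  stopifnot(is(x, "Grid"))
  v <- x@values
  if (is.logical(v)) v <- v * 1.0
  d <- dim(v)
  ext <- extentOf(x)
  gt <- sp::GridTopology(
    cellcentre.offset = c(ext["xmin"] + x@cellSize / 2,
                          ext["ymin"] + x@cellSize / 2),
    cellsize = rep(x@cellSize, 2), cells.dim = c(d[2], d[1]))
  sg <- sp::SpatialGridDataFrame(sp::SpatialGrid(gt),
                                 data.frame(z = as.vector(t(v))))
  sp::write.asciigrid(sg, path, na.value = x@nodata)
  writeLines(x@crs, paste0(path, ".prj"))
  invisible(path)
}

#' Read boundary polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection, a single Feature, or a bare (Multi)Polygon
#' geometry, in the grids' projected coordinates. Returns a polygon set: a
#' list of features, each holding its rings (closed `n x 2` coordinate
#' matrices; first ring exterior, further rings holes under the even-odd rule)
#' and its properties.
#'
#' @param path path to a GeoJSON file.
#' @return an object of class `srmdPolygonSet`.
#' @export
readPolygonsGeoJSON <- function(path) {
  if (!file.exists(path))
    stop(sprintf("GeoJSON file does not exist: '%s'", path), call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- switch(js$type %||% "",
    FeatureCollection = js$features,
    Feature = list(js),
    Polygon = ,
    MultiPolygon = list(list(type = "Feature", geometry = js,
                             properties = list())),
    stop(sprintf("'%s' is not a GeoJSON polygon document", path),
         call. = FALSE))
  ringMat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    colnames(m) <- c("x", "y")
    m
  }
  features <- lapply(feats, function(f) {
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ringMat),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, ringMat)), recursive = FALSE),
      stop("only Polygon/MultiPolygon geometries are supported"))
    list(rings = rings, properties = f$properties %||% list())
  })
  structure(list(features = features), class = "srmdPolygonSet")
}

#' Build a polygon set in code
#'
#' @param ... one or more closed rings, each an `n x 2` matrix of projected
#'   (x, y) coordinates. All rings form one feature (even-odd rule).
#' @param properties optional list of feature properties.
#' @return an `srmdPolygonSet`.
#' @export
polygonSet <- function(..., properties = list()) {
  rings <- lapply(list(...), function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, nrow(r) >= 3)
    colnames(r) <- c("x", "y")
    r
  })
  structure(list(features = list(list(rings = rings,
                                      properties = properties))),
            class = "srmdPolygonSet")
}

#' Write a polygon set to GeoJSON
#'
#' @param polys an `srmdPolygonSet`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writePolygonsGeoJSON <- function(polys, path) {
  stopifnot(inherits(polys, "srmdPolygonSet"))
  feats <- lapply(polys$features, function(f) {
    coords <- lapply(f$rings, function(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    list(type = "Feature",
         properties = if (length(f$properties)) f$properties else
           structure(list(), names = character(0)),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  doc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize polygons onto a reference grid
#'
#' Marks every cell whose centre falls inside the polygon set (even-odd rule
#' across rings; centres on a ring edge count as inside).
#'
#' @param polys an `srmdPolygonSet`, or an already-aligned [RegionMask-class]
#'   (returned unchanged).
#' @param ref reference [Grid-class].
#' @return a [RegionMask-class] aligned to `ref`.
#' @export
rasterizePolygons <- function(polys, ref) {
  stopifnot(is(ref, "Grid"))
  if (is(polys, "RegionMask")) {
    if (!sameGeometry(polys, ref))
      stop("mask is not aligned to the reference grid")
    return(polys)
  }
  stopifnot(inherits(polys, "srmdPolygonSet"))
  ctr <- cellCenters(ref)
  inside <- rep(FALSE, nrow(ctr))
  for (f in polys$features) {
    parity <- rep(0L, nrow(ctr))
    onEdge <- rep(FALSE, nrow(ctr))
    for (r in f$rings) {
      pip <- sp::point.in.polygon(ctr[, 1], ctr[, 2], r[, 1], r[, 2])
      parity <- parity + as.integer(pip == 1L)
      onEdge <- onEdge | pip >= 2L
    }
    inside <- inside | (parity %% 2L == 1L) | onEdge
  }
  regionMask(matrix(inside, nrow = gridDim(ref)[1]), ref)
}
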