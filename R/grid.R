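#' Regular longitude/latitude grid definition
#'
#' `GridDef` describes a regular lon/lat raster grid with square cells:
#' the number of rows and columns, the west/south origin and the cell
#' size in decimal degrees. Row 1 is the northernmost row (the usual
#' raster scan order), column 1 the westernmost column.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot west,south numeric coordinates (degrees) of the outer south-west
#'   corner.
#' @slot cellSize numeric cell edge length in degrees (cells are square
#'   in degree space).
#'
#' @param nRows,nCols grid dimensions.
#' @param west,south south-west corner, degrees.
#' @param cellSize cell size in degrees; defaults to 2.5 arc-minutes
#'   (`2.5/60`), the resolution of standard bioclimatic layers.
#' @param x a `GridDef`.
#'
#' @return `GridDef()` returns a validated `GridDef` object. `nRows()`,
#'   `nCols()` and `cellSize()` return the corresponding slots;
#'   `gridExtent()` returns `c(west, south, east, north)`.
#'
#' @examples
#' g <- GridDef(60, 90, west = 95, south = 30)
#' gridExtent(g)
#' @export GridDef
#' @exportClass GridDef
#' @aliases GridDef nRows nCols cellSize gridExtent
setClass("GridDef", representation(
  nRows = "integer", nCols = "integer",
  west = "numeric", south = "numeric", cellSize = "numeric"
))

setValidity("GridDef", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a positive integer")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a positive integer")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a positive number")
  if (length(msg)) msg else TRUE
})

GridDef <- function(nRows, nCols, west, south, cellSize = 2.5 / 60) {
  new("GridDef", nRows = as.integer(nRows), nCols = as.integer(nCols),
      west = as.numeric(west), south = as.numeric(south),
      cellSize = as.numeric(cellSize))
}

#' @rdname GridDef-class
setMethod("nRows", "GridDef", function(x) x@nRows)
#' @rdname GridDef-class
setMethod("nCols", "GridDef", function(x) x@nCols)
#' @rdname GridDef-class
setMethod("cellSize", "GridDef", function(x) x@cellSize)

#' @rdname GridDef-class
setMethod("gridExtent", "GridDef", function(x) {
  c(west = x@west, south = x@south,
    east = x@west + x@nCols * x@cellSize,
    north = x@south + x@nRows * x@cellSize)
})

setMethod("show", "GridDef", function(object) {
  e <- gridExtent(object)
  cat(sprintf("GridDef: %d rows x %d cols @ %.6g deg\n",
              object@nRows, object@nCols, object@cellSize))
  cat(sprintf("  extent: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              e["west"], e["east"], e["south"], e["north"]))
})

#' Cell-center coordinates
#'
#' Longitude/latitude of cell centers. `cellCenterLon`/`cellCenterLat`
#' are vectorized over column/row indices (1-based, row 1 = north).
#' `cellCenters` returns the full center grid as a data.frame in
#' row-major scan order.
#'
#' @param grid a [GridDef-class].
#' @param row,col 1-based indices.
#' @return numeric degrees; `cellCenters` a data.frame with `row`,
#'   `col`, `lon`, `lat`.
#' @export
cellCenterLon <- function(grid, col) grid@west + (col - 0.5) * grid@cellSize

#' @rdname cellCenterLon
#' @export
cellCenterLat <- function(grid, row) {
  north <- grid@south + grid@nRows * grid@cellSize
  north - (row - 0.5) * grid@cellSize
}

#' @rdname cellCenterLon
#' @export
cellCenters <- function(grid) {
  idx <- expand.grid(col = seq_len(grid@nCols), row = seq_len(grid@nRows))
  data.frame(row = idx$row, col = idx$col,
             lon = cellCenterLon(grid, idx$col),
             lat = cellCenterLat(grid, idx$row))
}

#' Spherical cell area
#'
#' Area in km^2 of the cells of a given grid row on the authalic sphere:
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`. Constant within a
#' row (all cells of a row share the latitude band).
#'
#' @param grid a [GridDef-class].
#' @param row 1-based row index (vectorized).
#' @return numeric km^2.
#' @examples
#' g <- GridDef(180, 360, -180, -90, 1)
#' cellAreaKm2(g, 90)  # 1x1 degree cell touching the equator from north
#' @export
cellAreaKm2 <- function(grid, row) {
  north <- grid@south + grid@nRows * grid@cellSize
  top <- (north - (row - 1) * grid@cellSize) * pi / 180
  bottom <- (north - row * grid@cellSize) * pi / 180
  EARTH_RADIUS_KM^2 * (grid@cellSize * pi / 180) * (sin(top) - sin(bottom))
}

#' Per-cell area matrix
#'
#' @param grid a [GridDef-class].
#' @return matrix (nRows x nCols) of cell areas in km^2.
#' @export
cellAreaMatrix <- function(grid) {
  matrix(rep(cellAreaKm2(grid, seq_len(grid@nRows)), grid@nCols),
         nrow = grid@nRows)
}

# Row/col of the cell containing (lon, lat); floor convention, points on
# the extreme east/south boundary clamped into the last cell. Returns
# NA for points outside the extent.
lonLatToCell <- function(grid, lon, lat) {
  e <- gridExtent(grid)
  inside <- lon >= e["west"] & lon <= e["east"] &
    lat >= e["south"] & lat <= e["north"]
  col <- floor((lon - e["west"]) / grid@cellSize) + 1
  row <- floor((e["north"] - lat) / grid@cellSize) + 1
  col <- pmin(pmax(col, 1), grid@nCols)
  row <- pmin(pmax(row, 1), grid@nRows)
  col[!inside] <- NA_integer_
  row[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

sameGrid <- function(a, b, tol = 1e-9) {
  a@nRows == b@nRows && a@nCols == b@nCols &&
    abs(a@west - b@west) < tol && abs(a@south - b@south) < tol &&
    abs(a@cellSize - b@cellSize) < tol
}
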