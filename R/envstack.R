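#' Stack of environmental raster layers on a shared grid
#'
#' `EnvStack` holds named 2-D layers (matrices, row 1 = north) that share
#' one [GridDef-class] plus a logical validity mask (`TRUE` = valid cell,
#' e.g. land). Masked-out cells carry `NA` in every layer.
#'
#' @slot grid the shared [GridDef-class].
#' @slot layers named list of numeric matrices.
#' @slot mask logical matrix, `TRUE` where cells are valid.
#'
#' @param grid a [GridDef-class].
#' @param layers named list of matrices with dimensions
#'   `nRows(grid) x nCols(grid)`.
#' @param mask optional logical matrix; defaults to all-`TRUE`.
#' @param x an `EnvStack`.
#' @param name layer name.
#'
#' @return `EnvStack()` a validated object; `layerNames()` the layer
#'   names; `getLayer()` one matrix; `validMask()` the mask;
#'   `gridDef()` the grid.
#' @export EnvStack
#' @exportClass EnvStack
#' @aliases EnvStack gridDef layerNames getLayer validMask
setClass("EnvStack", representation(
  grid = "GridDef", layers = "list", mask = "matrix"
))

setValidity("EnvStack", function(object) {
  msg <- character()
  nr <- object@grid@nRows; nc <- object@grid@nCols
  if (length(object@layers) == 0L)
    msg <- c(msg, "at least one layer required")
  nms <- names(object@layers)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms))
    msg <- c(msg, "layers must have unique non-empty names")
  for (nm in nms) {
    l <- object@layers[[nm]]
    if (!is.matrix(l) || nrow(l) != nr || ncol(l) != nc)
      msg <- c(msg, sprintf("layer '%s' does not match the grid dimensions", nm))
  }
  if (!is.logical(object@mask) || nrow(object@mask) != nr ||
      ncol(object@mask) != nc)
    msg <- c(msg, "mask must be a logical nRows x nCols matrix")
  if (length(msg)) msg else TRUE
})

EnvStack <- function(grid, layers, mask = NULL) {
  if (is.null(mask))
    mask <- matrix(TRUE, grid@nRows, grid@nCols)
  layers <- lapply(layers, function(l) {
    l[!mask] <- NA_real_
    l
  })
  new("EnvStack", grid = grid, layers = layers, mask = mask)
}

#' @rdname EnvStack-class
setMethod("gridDef", "EnvStack", function(x) x@grid)
#' @rdname EnvStack-class
setMethod("layerNames", "EnvStack", function(x) names(x@layers))
#' @rdname EnvStack-class
setMethod("getLayer", "EnvStack", function(x, name) {
  if (!name %in% names(x@layers))
    stop("no layer named '", name, "'")
  x@layers[[name]]
})
#' @rdname EnvStack-class
setMethod("validMask", "EnvStack", function(x) x@mask)

setMethod("show", "EnvStack", function(object) {
  cat(sprintf("EnvStack: %d layer(s) on a %d x %d grid (%d valid cells)\n",
              length(object@layers), object@grid@nRows, object@grid@nCols,
              sum(object@mask)))
  cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
})

#' Subset or extend an EnvStack
#'
#' `subsetLayers` keeps the named layers; `addLayers` appends new ones
#' (masked like the rest).
#'
#' @param stack an [EnvStack-class].
#' @param names layer names to keep.
#' @param layers named list of matrices to add.
#' @return an [EnvStack-class].
#' @export
subsetLayers <- function(stack, names) {
  miss <- setdiff(names, layerNames(stack))
  if (length(miss))
    stop("layers not present: ", paste(miss, collapse = ", "))
  EnvStack(stack@grid, stack@layers[names], stack@mask)
}

#' @rdname subsetLayers
#' @export
addLayers <- function(stack, layers) {
  EnvStack(stack@grid, c(stack@layers, layers), stack@mask)
}

#' Extract layer values at occurrence cells or at all valid cells
#'
#' Returns the per-cell predictor table used for model fitting and
#' screening: one row per requested cell, one column per layer.
#'
#' @param stack an [EnvStack-class].
#' @param cells optional data.frame with `row`, `col` (e.g. from
#'   [assignCells()]); when `NULL`, all valid cells in row-major scan
#'   order are used.
#' @return matrix of layer values (columns named by layer); attribute
#'   `"cells"` holds the row/col index table.
#' @export
extractValues <- function(stack, cells = NULL) {
  if (is.null(cells)) {
    idx <- which(t(stack@mask), arr.ind = FALSE)  # row-major order
    cc <- cellCenters(stack@grid)
    cells <- cc[idx, c("row", "col")]
  }
  lin <- cbind(cells$row, cells$col)
  out <- vapply(stack@layers, function(l) l[lin], numeric(nrow(cells)))
  out <- matrix(out, nrow = nrow(cells),
                dimnames = list(NULL, names(stack@layers)))
  attr(out, "cells") <- cells
  out
}
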