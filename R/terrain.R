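#' Derive slope and aspect from an elevation layer
#'
#' Horn's 3x3 finite-difference method on the lon/lat grid. Cell sizes
#' are converted to metres per row: `dx = cellSize * 111195 * cos(lat)`,
#' `dy = cellSize * 111195`. Edge cells use replicated-edge padding.
#' Slope is returned in degrees (>= 0); aspect in degrees clockwise from
#' north in `[0, 360)`, pointing downhill, with flat cells (zero
#' gradient) assigned the sentinel `-1`. Masked cells stay `NA`.
#'
#' @param elevation numeric matrix (row 1 = north), or an
#'   [EnvStack-class] containing a layer named `"elevation"`.
#' @param grid a [GridDef-class] (taken from the stack if one is given).
#' @return list with matrices `slope` and `aspect`.
#' @export
deriveTerrain <- function(elevation, grid = NULL) {
  if (is(elevation, "EnvStack")) {
    grid <- gridDef(elevation)
    elevation <- getLayer(elevation, "elevation")
  }
  stopifnot(is.matrix(elevation), !is.null(grid))
  nr <- nrow(elevation); nc <- ncol(elevation)
  mask <- is.na(elevation)
  z <- elevation
  if (any(mask)) {
    # fill no-data with the layer mean so padding stays finite; masked
    # cells are re-blanked below
    z[mask] <- mean(z, na.rm = TRUE)
  }
  # replicated-edge pad
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  sh <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  zNW <- sh(0, 0); zN <- sh(0, 1); zNE <- sh(0, 2)
  zW  <- sh(1, 0);                 zE  <- sh(1, 2)
  zSW <- sh(2, 0); zS <- sh(2, 1); zSE <- sh(2, 2)
  dyM <- grid@cellSize * METERS_PER_DEGREE
  latRow <- cellCenterLat(grid, seq_len(nr))
  dxM <- dyM * cos(latRow * pi / 180)
  gx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * dxM)  # east
  gy <- ((zNW + 2 * zN + zNE) - (zSW + 2 * zS + zSE)) / (8 * dyM)  # north
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  flat <- gx == 0 & gy == 0
  aspect[flat] <- -1
  slope[mask] <- NA_real_
  aspect[mask] <- NA_real_
  list(slope = slope, aspect = aspect)
}

#' Add derived terrain layers to a stack
#'
#' Convenience wrapper: derives slope/aspect from the stack's
#' `elevation` layer and appends them.
#'
#' @param stack an [EnvStack-class] with an `elevation` layer.
#' @return the stack with `slope` and `aspect` layers added.
#' @export
addTerrain <- function(stack) {
  tr <- deriveTerrain(stack)
  addLayers(stack, tr)
}
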