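#' Set of species occurrence records
#'
#' Ordered point records (id, species, lon/lat in WGS84 decimal degrees)
#' plus a flag recording whether the set has been spatially thinned and,
#' if so, on which grid.
#'
#' @slot records data.frame with columns `id`, `species`, `lon`, `lat`.
#' @slot thinned logical.
#' @slot grid list holding the thinning [GridDef-class] (empty if none).
#'
#' @param id record identifiers (unique).
#' @param lon,lat coordinates in decimal degrees.
#' @param species species label, recycled.
#' @param x an `OccurrenceSet`.
#'
#' @return `OccurrenceSet()` a validated object; `occRecords()` the
#'   records data.frame; `isThinned()` the flag.
#' @export OccurrenceSet
#' @exportClass OccurrenceSet
#' @aliases OccurrenceSet occRecords isThinned
setClass("OccurrenceSet", representation(
  records = "data.frame", thinned = "logical", grid = "list"
))

setValidity("OccurrenceSet", function(object) {
  d <- object@records
  msg <- character()
  need <- c("id", "species", "lon", "lat")
  if (!all(need %in% names(d)))
    return("records must have columns id, species, lon, lat")
  if (anyDuplicated(d$id)) msg <- c(msg, "record ids must be unique")
  if (nrow(d) && (any(d$lon < -180 | d$lon > 180, na.rm = TRUE) ||
                  any(d$lat < -90 | d$lat > 90, na.rm = TRUE)))
    msg <- c(msg, "coordinates outside [-180,180] x [-90,90]")
  if (length(msg)) msg else TRUE
})

OccurrenceSet <- function(id, lon, lat, species = "unknown") {
  d <- data.frame(id = as.character(id), species = rep_len(species, length(id)),
                  lon = as.numeric(lon), lat = as.numeric(lat),
                  stringsAsFactors = FALSE)
  new("OccurrenceSet", records = d, thinned = FALSE, grid = list())
}

#' @rdname OccurrenceSet-class
setMethod("occRecords", "OccurrenceSet", function(x) x@records)
#' @rdname OccurrenceSet-class
setMethod("isThinned", "OccurrenceSet", function(x) x@thinned)

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d record(s)%s\n", nrow(object@records),
              if (object@thinned) " (thinned)" else ""))
  if (nrow(object@records))
    print(utils::head(object@records, 4))
})

setMethod("length", "OccurrenceSet", function(x) nrow(x@records))

#' Assign occurrence records to grid cells
#'
#' Each record is mapped to the cell containing it by the floor
#' convention: `row = floor((north - lat)/cellSize)`,
#' `col = floor((lon - west)/cellSize)` (1-based in the result), so a
#' point on an interior shared edge belongs to the cell to its
#' south/east; points on the outer east/south boundary are clamped into
#' the last cell. Records outside the grid extent are flagged, not
#' dropped.
#'
#' @param occ an [OccurrenceSet-class].
#' @param grid a [GridDef-class].
#' @return data.frame with `id`, `row`, `col`, `inside`; rejected
#'   (outside-extent) records have `NA` row/col and `inside = FALSE`.
#' @export
assignCells <- function(occ, grid) {
  d <- occRecords(occ)
  cl <- lonLatToCell(grid, d$lon, d$lat)
  data.frame(id = d$id, row = cl$row, col = cl$col, inside = cl$inside,
             stringsAsFactors = FALSE)
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Within every occupied grid cell the record whose great-circle
#' (haversine) distance to the cell center is smallest is retained; all
#' other records in the cell are discarded. Distance ties are broken by
#' the smallest record id. Records outside the grid extent, and — when
#' `stack` is supplied — records in cells where any predictor layer is
#' masked/no-data (incomplete habitat information), are excluded before
#' thinning and reported in the `rejected` attribute. The result is
#' ordered by row-major cell scan order.
#'
#' @param occ an [OccurrenceSet-class] (not yet thinned on this grid).
#' @param grid a [GridDef-class].
#' @param stack optional [EnvStack-class] used to require complete
#'   habitat information (a valid cell in every layer).
#' @return a thinned [OccurrenceSet-class]; attributes `nBefore`,
#'   `nAfter` and `rejected` (data.frame of excluded records with a
#'   `reason`) summarize the operation.
#' @export
thinOccurrences <- function(occ, grid, stack = NULL) {
  if (isThinned(occ))
    stop("occurrence set is already thinned")
  d <- occRecords(occ)
  asg <- assignCells(occ, grid)
  rejected <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  out <- cbind(d, asg[c("row", "col", "inside")])
  if (any(!out$inside)) {
    rejected <- rbind(rejected, data.frame(id = out$id[!out$inside],
                                           reason = "outside grid extent"))
    out <- out[out$inside, , drop = FALSE]
  }
  if (!is.null(stack)) {
    if (!sameGrid(gridDef(stack), grid))
      stop("stack grid does not match the thinning grid")
    ok <- validMask(stack)[cbind(out$row, out$col)]
    if (any(!ok)) {
      rejected <- rbind(rejected, data.frame(id = out$id[!ok],
                                             reason = "incomplete habitat information"))
      out <- out[ok, , drop = FALSE]
    }
  }
  if (nrow(out)) {
    out$dist <- haversineKm(out$lon, out$lat,
                            cellCenterLon(grid, out$col),
                            cellCenterLat(grid, out$row))
    # per-cell argmin of distance, ties -> smallest id; then scan order
    out <- out[order(out$row, out$col, out$dist, out$id), , drop = FALSE]
    keep <- !duplicated(out[c("row", "col")])
    dropped <- out[!keep, , drop = FALSE]
    if (nrow(dropped))
      rejected <- rbind(rejected, data.frame(id = dropped$id,
                                             reason = "duplicate cell"))
    out <- out[keep, , drop = FALSE]
  }
  res <- new("OccurrenceSet",
             records = data.frame(id = out$id, species = out$species,
                                  lon = out$lon, lat = out$lat,
                                  stringsAsFactors = FALSE),
             thinned = TRUE, grid = list(grid))
  attr(res, "nBefore") <- nrow(d)
  attr(res, "nAfter") <- nrow(out)
  attr(res, "rejected") <- rejected
  res
}
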