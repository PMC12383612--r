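#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed
#' by rows of values, northernmost row first — the layout probability
#' surfaces are conventionally exchanged in.
#'
#' @param layer numeric matrix (row 1 = north).
#' @param grid a [GridDef-class].
#' @param file path.
#' @param noData sentinel written for `NA` cells.
#' @return `readEsriAscii` returns a list with elements `grid`
#'   (a [GridDef-class]) and `values` (matrix with `NA` for no-data).
#' @export
writeEsriAscii <- function(layer, grid, file, noData = -9999) {
  stopifnot(is.matrix(layer), nrow(layer) == grid@nRows,
            ncol(layer) == grid@nCols)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid@nCols),
    sprintf("nrows %d", grid@nRows),
    sprintf("xllcorner %.10g", grid@west),
    sprintf("yllcorner %.10g", grid@south),
    sprintf("cellsize %.10g", grid@cellSize),
    sprintf("NODATA_value %.10g", noData)
  ), con)
  vals <- layer
  vals[is.na(vals)] <- noData
  write.table(format(vals, trim = TRUE, digits = 10, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeEsriAscii
#' @export
readEsriAscii <- function(file) {
  hdr <- readLines(file, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  nc <- as.integer(val["ncols"]); nr <- as.integer(val["nrows"])
  vals <- scan(file, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(val["nodata_value"]))
    m[m == val["nodata_value"]] <- NA_real_
  list(grid = GridDef(nr, nc, val["xllcorner"], val["yllcorner"],
                      val["cellsize"]),
       values = m)
}

#' Write an EnvStack as one ESRI ASCII grid per layer
#'
#' @param stack an [EnvStack-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeStackAscii <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(layerNames(stack), function(nm) {
    f <- file.path(dir, paste0(nm, ".asc"))
    writeEsriAscii(getLayer(stack, nm), gridDef(stack), f)
    f
  }, character(1))
  invisible(paths)
}

#' Read a directory of ESRI ASCII grids into an EnvStack
#'
#' All `.asc` files in `dir` are read; they must share one grid. Cells
#' that are no-data in any layer are masked out.
#'
#' @param dir directory of `.asc` files.
#' @return an [EnvStack-class].
#' @export
readStackAscii <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc files in ", dir)
  parsed <- lapply(files, readEsriAscii)
  grid <- parsed[[1]]$grid
  for (p in parsed[-1])
    if (!sameGrid(grid, p$grid)) stop("layers in ", dir, " disagree on the grid")
  layers <- lapply(parsed, `[[`, "values")
  names(layers) <- sub("\\.asc$", "", basename(files))
  mask <- Reduce(`&`, lapply(layers, function(l) !is.na(l)))
  EnvStack(grid, layers, mask)
}

#' Occurrence CSV input/output
#'
#' The on-disk occurrence format is a CSV with columns
#' `id,species,longitude,latitude` (WGS84 decimal degrees).
#'
#' @param occ an [OccurrenceSet-class].
#' @param file path.
#' @return `readOccurrenceCsv` returns an [OccurrenceSet-class].
#' @export
writeOccurrenceCsv <- function(occ, file) {
  d <- occRecords(occ)
  write.csv(data.frame(id = d$id, species = d$species,
                       longitude = d$lon, latitude = d$lat),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeOccurrenceCsv
#' @export
readOccurrenceCsv <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "longitude", "latitude")
  if (!all(need %in% names(d)))
    stop("occurrence CSV must have columns id, longitude, latitude")
  OccurrenceSet(id = d$id,
                lon = d$longitude, lat = d$latitude,
                species = if ("species" %in% names(d)) d$species else "unknown")
}

#' Serialize a fitted model as a JSON lambdas file
#'
#' Writes feature names, coefficients, penalties, the per-variable
#' scaling/clamp ranges and model metadata (RM, feature classes, knots,
#' log Z, entropy, sample sizes) to JSON; `readModelJson` restores a
#' fully functional [MaxEntModel-class].
#'
#' @param model a [MaxEntModel-class].
#' @param file path.
#' @return `readModelJson` returns the restored model.
#' @export
writeModelJson <- function(model, file) {
  obj <- list(
    spec = model@spec,
    features = data.frame(name = model@featureNames,
                          lambda = unname(model@lambda),
                          beta = unname(model@betas),
                          stringsAsFactors = FALSE),
    featureVars = model@featureVars,
    rm = model@rm, scaling = model@scaling,
    logZ = model@logZ, entropy = model@entropy,
    bgMeans = as.list(model@bgMeans),
    nPresence = model@nPresence, nBackground = model@nBackground,
    creditByVar = as.list(model@creditByVar),
    objective = model@objective, converged = model@converged,
    iterations = model@iterations)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(file) {
  o <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("MaxEntModel",
      spec = list(classes = o$spec$classes,
                  variableNames = o$spec$variableNames,
                  hingeKnots = as.integer(o$spec$hingeKnots),
                  thresholdKnots = as.integer(o$spec$thresholdKnots)),
      featureNames = o$features$name,
      lambda = stats::setNames(o$features$lambda, o$features$name),
      betas = stats::setNames(o$features$beta, o$features$name),
      featureVars = if (is.list(o$featureVars)) o$featureVars
                    else as.list(o$featureVars),
      rm = o$rm, scaling = as.data.frame(o$scaling),
      logZ = o$logZ, entropy = o$entropy,
      bgMeans = unlist(o$bgMeans),
      nPresence = as.integer(o$nPresence),
      nBackground = as.integer(o$nBackground),
      creditByVar = unlist(o$creditByVar),
      objective = o$objective, converged = o$converged,
      iterations = as.integer(o$iterations))
}

#' Write centroids and track segments as GeoJSON
#'
#' Centroids become Point features; consecutive centroids of each
#' scenario become a LineString.
#'
#' @param track data.frame from [buildTrack()] (or a centroid table with
#'   `lon`, `lat`, `period`, `scenario`).
#' @param centroids data.frame of centroids with `lon`, `lat`, `period`,
#'   `scenario`.
#' @param file path.
#' @return invisibly, the path.
#' @export
writeTrackGeoJSON <- function(centroids, file) {
  pts <- lapply(seq_len(nrow(centroids)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(centroids$lon[i], centroids$lat[i])),
         properties = list(period = centroids$period[i],
                           scenario = centroids$scenario[i]))
  })
  lines <- lapply(split(centroids, centroids$scenario), function(d) {
    if (nrow(d) < 2) return(NULL)
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(d)), function(i)
                           c(d$lon[i], d$lat[i]))),
         properties = list(scenario = d$scenario[1]))
  })
  lines <- Filter(Negate(is.null), lines)
  fc <- list(type = "FeatureCollection", features = c(pts, unname(lines)))
  jsonlite::write_json(fc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
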