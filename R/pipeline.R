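#' Default pipeline configuration
#'
#' The reference configuration for the fully synthetic end-to-end run:
#' a 60 x 90 grid at 2.5 arc-minutes with 8 autocorrelated predictor
#' layers (one carrying a north-south temperature gradient so warming
#' scenarios shift the suitable band poleward), a linear Gibbs truth,
#' ~150 raw occurrences, the standard 8 RM x 9 FC tuning grids, 10
#' replicate 75/25 runs, the 0.1/0.3/0.5 classification thresholds and
#' the inclusive 0.1 binary threshold. Every field can be overridden by
#' the caller (smaller grids/knots for quick runs).
#'
#' @param seed master seed.
#' @return nested configuration list (see [runPipeline()]).
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    outDir = NULL,
    simulate = list(
      nRows = 60, nCols = 90, west = 100, south = 30, cellSize = 2.5 / 60,
      layers = c("bio3", "bio11", "bio13", "bio15", "bio19",
                 "elevation", "slope", "aspect"),
      ranges = list(c(22, 51), c(-16, 16), c(50, 316), c(50, 149),
                    c(2, 201), c(1, 4178), c(0, 3.1), c(0, 360)),
      corrLength = 6,
      latGradient = c(bio11 = -6),   # degC per degree northward
      truth = list(coefficients = c(bio11 = 5, bio13 = 3, elevation = -4),
                   featureForm = "linear"),
      nDraws = 50, clusterSd = 0.005, perCluster = 3,
      periods = c("2050s", "2070s", "2090s"),
      scenarioShifts = list(  # additive warming on bio11 per period
        "SSP1-2.6" = c(1.0, 1.3, 1.5),
        "SSP3-7.0" = c(1.5, 2.5, 3.5),
        "SSP5-8.5" = c(2.0, 3.3, 4.5)),
      shiftLayer = "bio11"),
    screening = list(threshold = 0.75, fc = "LQH", rm = 1,
                     nBackground = 10000, hingeKnots = 10),
    tuning = list(fcGrid = c("L", "H", "LQ", "LQH", "LQHP", "LQHPT",
                             "QHP", "QHPT", "HPT"),
                  rmGrid = seq(0.5, 4, by = 0.5),
                  k = 5, hingeKnots = 10, thresholdKnots = 10,
                  nBackground = 10000),
    model = list(nRep = 10, split = 0.75, nBackground = 10000,
                 hingeKnots = 10, thresholdKnots = 10,
                 fc = NULL, rm = NULL),   # NULL: take the tuned best
    classification = list(breaks = c(0.1, 0.3, 0.5), binaryThreshold = 0.1),
    track = list(yearsBetween = 20)
  )
}

stageSeed <- function(master, stage) {
  (as.integer(master) * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
}

# Keys replaced wholesale rather than merged element-wise (their
# elements form one coherent setting, e.g. the scenario set).
atomicConfigKeys <- c("scenarioShifts", "ranges", "latGradient", "truth")

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])) && !nm %in% atomicConfigKeys)
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

simulateScenarioStacks <- function(cfg, seed) {
  s <- cfg$simulate
  grid <- GridDef(s$nRows, s$nCols, s$west, s$south, s$cellSize)
  stack <- generateEnvStack(grid, s$layers, corrLength = s$corrLength,
                            seed = stageSeed(seed, "simulate"),
                            ranges = s$ranges)
  for (nm in names(s$latGradient)) {
    lat <- cellCenterLat(grid, seq_len(grid@nRows))
    adj <- s$latGradient[[nm]] * (lat - mean(lat))
    stack@layers[[nm]] <- stack@layers[[nm]] + adj
  }
  truth <- makeTruth(stack, s$truth$coefficients, s$truth$featureForm)
  occ <- sampleOccurrences(truth, n = s$nDraws, clusterSd = s$clusterSd,
                           perCluster = s$perCluster,
                           seed = stageSeed(seed, "occurrences"))
  scen <- list()
  for (sc in names(s$scenarioShifts)) {
    for (pi in seq_along(s$periods)) {
      st2 <- stack
      st2@layers[[s$shiftLayer]] <- st2@layers[[s$shiftLayer]] +
        s$scenarioShifts[[sc]][pi]
      scen[[paste(s$periods[pi], sc, sep = "-")]] <-
        list(stack = st2, period = s$periods[pi], scenario = sc)
    }
  }
  list(grid = grid, stack = stack, truth = truth, occ = occ,
       scenarios = scen)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> thin -> screen -> tune -> fit (replicated)
#' -> project -> classify -> change -> centroid from one configuration
#' (a nested list as produced by [defaultPipelineConfig()], a YAML file
#' path, or a partial list merged over the defaults). Each stage draws
#' its seed deterministically from the master seed, so identical
#' configurations give identical outputs. When `config$outDir` is set,
#' summary tables (tuning, change, class areas, centroids), the
#' suitability layers (ESRI ASCII), a GeoJSON track file, the thinned
#' occurrences, a run log and a metadata JSON are written there.
#'
#' @param config configuration list (partial lists are merged over
#'   [defaultPipelineConfig()]) or path to a YAML file of the same
#'   structure.
#' @param seed optional master-seed override.
#' @return list of class `PipelineResult`: `config`, `occThinned`,
#'   `screening`, `tuning`, `runs` (the replicate-run object),
#'   `currentLayer`, `projections` (named suitability layers),
#'   `classAreas`, `changes` (per scenario-period `ChangeSummary`),
#'   `changeTable` (Table-3-schema data.frame), `centroids`, `tracks`,
#'   `log` (character vector of stage messages).
#' @export
runPipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  sim <- withStage("simulate", simulateScenarioStacks(cfg, cfg$seed))
  note("simulate: %d layers on %dx%d grid; %d raw occurrences; %d scenario stacks",
       length(layerNames(sim$stack)), nRows(sim$grid), nCols(sim$grid),
       length(sim$occ), length(sim$scenarios))

  occThin <- withStage("thin",
    thinOccurrences(sim$occ, sim$grid, stack = sim$stack))
  note("thin: %d -> %d records", attr(occThin, "nBefore"),
       attr(occThin, "nAfter"))

  scr <- withStage("screen", screenPredictors(
    sim$stack, occThin, threshold = cfg$screening$threshold,
    nBackground = cfg$screening$nBackground,
    seed = stageSeed(cfg$seed, "screen"),
    fc = cfg$screening$fc, rm = cfg$screening$rm,
    hingeKnots = cfg$screening$hingeKnots))
  note("screen: retained %d/%d predictors (%s)", length(scr$retained),
       length(layerNames(sim$stack)), paste(scr$retained, collapse = ","))

  screenStack <- subsetLayers(sim$stack, scr$retained)
  bgCells <- sampleBackground(screenStack, cfg$tuning$nBackground,
                              seed = stageSeed(cfg$seed, "background"))
  bgVals <- extractValues(screenStack, bgCells)
  asg <- assignCells(occThin, sim$grid)
  presVals <- extractValues(screenStack, asg[c("row", "col")])

  tun <- withStage("tune", tuneMaxent(
    presVals, bgVals, fcGrid = cfg$tuning$fcGrid, rmGrid = cfg$tuning$rmGrid,
    partition = makePartition(nrow(presVals), "random_kfold",
                              k = min(cfg$tuning$k, nrow(presVals)),
                              seed = stageSeed(cfg$seed, "tune")),
    hingeKnots = cfg$tuning$hingeKnots,
    thresholdKnots = cfg$tuning$thresholdKnots))
  note("tune: best FC=%s RM=%.2g (Delta.AICc=0)", tun$best$fc, tun$best$rm)

  fc <- if (is.null(cfg$model$fc)) tun$best$fc else cfg$model$fc
  rmv <- if (is.null(cfg$model$rm)) tun$best$rm else cfg$model$rm
  runs <- withStage("fit", replicateRuns(
    screenStack, occThin, fc = fc, rm = rmv, nRep = cfg$model$nRep,
    split = cfg$model$split, seed = stageSeed(cfg$seed, "fit"),
    nBackground = cfg$model$nBackground,
    hingeKnots = cfg$model$hingeKnots,
    thresholdKnots = cfg$model$thresholdKnots))
  note("fit: %d replicates, train AUC %.3f +/- %.3f (%s)",
       cfg$model$nRep, runs$aucTrainMean,
       if (is.na(runs$aucTrainSd)) 0 else runs$aucTrainSd,
       runs$accuracyClass)

  projections <- withStage("project", {
    out <- list()
    for (nm in names(sim$scenarios)) {
      st <- subsetLayers(sim$scenarios[[nm]]$stack, scr$retained)
      ls <- lapply(runs$models, function(mdl)
        predictMaxent(mdl, st, type = "logistic", clamp = TRUE))
      out[[nm]] <- Reduce(`+`, ls) / length(ls)
    }
    out
  })
  note("project: %d scenario layers", length(projections))

  brk <- cfg$classification$breaks
  thrB <- cfg$classification$binaryThreshold
  allLayers <- c(list(current = runs$meanLayer), projections)
  areasTab <- withStage("classify", do.call(rbind, lapply(
    names(allLayers), function(nm) {
      cl <- classifySuitability(allLayers[[nm]], breaks = brk)
      d <- classAreas(cl, sim$grid)
      d$layer <- nm
      d
    })))

  curBin <- binarizeSuitability(runs$meanLayer, thrB)
  changes <- withStage("change", lapply(projections, function(l)
    habitatChange(curBin, binarizeSuitability(l, thrB), sim$grid)))
  changeTable <- do.call(rbind, lapply(names(changes), function(nm) {
    ch <- changes[[nm]]
    parts <- strsplit(nm, "-")[[1]]
    data.frame(period = parts[1],
               scenario = paste(parts[-1], collapse = "-"),
               retainedKm2 = ch$retainedKm2, lostKm2 = ch$lostKm2,
               gainedKm2 = ch$gainedKm2,
               retentionRate = ch$rates[["retention"]],
               lossRate = ch$rates[["loss"]],
               gainRate = ch$rates[["gain"]],
               stringsAsFactors = FALSE)
  }))
  note("change: %d scenario comparisons", nrow(changeTable))

  centroids <- withStage("centroid", do.call(rbind, lapply(
    names(allLayers), function(nm) {
      ct <- weightedCentroid(allLayers[[nm]], sim$grid, threshold = thrB)
      parts <- strsplit(nm, "-")[[1]]
      data.frame(period = parts[1],
                 scenario = if (length(parts) > 1)
                   paste(parts[-1], collapse = "-") else "current",
                 lon = ct[["lon"]], lat = ct[["lat"]],
                 stringsAsFactors = FALSE)
    })))
  scenNames <- unique(centroids$scenario[centroids$scenario != "current"])
  tracks <- lapply(scenNames, function(sc) {
    d <- rbind(centroids[centroids$scenario == "current", ],
               centroids[centroids$scenario == sc, ])
    d$scenario <- sc
    buildTrack(d, yearsBetween = cfg$track$yearsBetween)
  })
  names(tracks) <- scenNames
  note("centroid: %d tracks", length(tracks))

  res <- structure(list(
    config = cfg, grid = sim$grid, stack = sim$stack, truth = sim$truth,
    occRaw = sim$occ, occThinned = occThin, screening = scr,
    tuning = tun, runs = runs, currentLayer = runs$meanLayer,
    projections = projections, classAreas = areasTab, changes = changes,
    changeTable = changeTable, centroids = centroids, tracks = tracks,
    log = logLines), class = "PipelineResult")

  if (!is.null(cfg$outDir)) writePipelineOutputs(res, cfg$outDir)
  res
}

writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) write.csv(d, file.path(outDir, f), row.names = FALSE)
  w(res$tuning$results, "tuning.csv")
  w(res$changeTable, "change_summary.csv")
  write.csv(res$screening$correlation, file.path(outDir, "correlation.csv"))
  w(data.frame(variable = names(res$screening$contributions),
               contribution = as.numeric(res$screening$contributions),
               retained = names(res$screening$contributions) %in%
                 res$screening$retained), "screening_report.csv")
  w(res$classAreas, "class_areas.csv")
  w(res$centroids, "centroids.csv")
  writeOccurrenceCsv(res$occThinned, file.path(outDir, "occurrences_thinned.csv"))
  writeEsriAscii(res$currentLayer, res$grid,
                 file.path(outDir, "suitability_current.asc"))
  for (nm in names(res$projections))
    writeEsriAscii(res$projections[[nm]], res$grid,
                   file.path(outDir, paste0("suitability_", nm, ".asc")))
  writeTrackGeoJSON(res$centroids, file.path(outDir, "centroid_tracks.geojson"))
  writeLines(res$log, file.path(outDir, "run.log"))
  meta <- res$config
  meta$simulate$ranges <- lapply(meta$simulate$ranges, as.numeric)
  jsonlite::write_json(meta, file.path(outDir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
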