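## pipeline: end-to-end replica orchestration with fixed seeds and a
## reproducibility manifest.

#' Run the multi-replica ABF landscape pipeline
#'
#' Runs `nReplicas` independent ABF simulations on a preset (or supplied)
#' potential -- half started in each end basin, replica `i` seeded with
#' `baseSeed + i - 1` -- then merges the replica grids by pooling,
#' integrates the mean-force field, detects basins and extracts the
#' minimum free-energy path and barrier between the two deepest basins.
#' With `outDir` set, writes per-replica grids, the merged grid, the
#' landscape and path TSVs, a basin summary JSON and a manifest recording
#' every parameter and seed; reruns with the same configuration produce
#' byte-identical numeric outputs.
#'
#' @param potential an [AnalyticPotential-class] or a preset name for
#'   [potentialPreset()].
#' @param nReplicas number of independent ABF runs (half per start basin).
#' @param stepsPerReplica Langevin steps per replica.
#' @param baseSeed integer; replica seeds are `baseSeed + 0:(n-1)`.
#' @param params an [ABFParams-class].
#' @param lp a [LangevinParams-class] template (its seed and initial
#'   position are overridden per replica).
#' @param startPoints 2 x d matrix of the two start basins; defaults to
#'   the preset's first and last well.
#' @param minDepth basin-depth threshold for [findBasins()].
#' @param outDir optional output directory.
#' @return list with `grids`, `merged`, `landscape`, `basins`, `path`,
#'   `barrier`, `manifest`.
#' @export
runLandscapePipeline <- function(potential = "state_e", nReplicas = 14,
                                 stepsPerReplica = 2e5, baseSeed = 1L,
                                 params = abfParams(),
                                 lp = langevinParams(),
                                 startPoints = NULL, minDepth = 2,
                                 outDir = NULL) {
  presetName <- NA_character_
  if (is.character(potential)) {
    presetName <- potential
    potential <- potentialPreset(potential)
  }
  if (is.null(startPoints)) {
    wells <- attr(potential, "wells")
    if (is.null(wells))
      stop("startPoints must be given for a non-preset potential")
    startPoints <- wells[c(1, nrow(wells)), , drop = FALSE]
  }
  startPoints <- as.matrix(startPoints)

  grids <- vector("list", nReplicas)
  for (i in seq_len(nReplicas)) {
    lpi <- lp
    lpi@seed <- as.integer(baseSeed + i - 1L)
    lpi@initialPosition <-
      as.numeric(startPoints[(i - 1L) %% nrow(startPoints) + 1L, ])
    grids[[i]] <- runABF(potential, params, lpi, stepsPerReplica,
                         bias = TRUE, record = FALSE)$grid
  }
  merged <- mergeRuns(grids)
  landscape <- integrateGradient(merged)
  basins <- findBasins(landscape, minDepth = minDepth)
  path <- NULL
  barrier <- NA_real_
  if (length(basins) >= 2) {
    path <- tryCatch(minFreeEnergyPath(landscape, basins[[1]], basins[[2]]),
                     error = function(e) NULL)
    if (!is.null(path)) barrier <- barrierHeight(path)
  }

  manifest <- list(
    preset = presetName,
    n_replicas = nReplicas,
    steps_per_replica = stepsPerReplica,
    base_seed = as.integer(baseSeed),
    replica_seeds = as.integer(baseSeed + seq_len(nReplicas) - 1L),
    start_points = startPoints,
    timestep = lp@timestep, friction = lp@friction,
    temperature = lp@temperature,
    bin_width = params@binWidth, domain = params@domain,
    n_full = params@nFull, boundary_k = params@boundaryK,
    min_depth = minDepth,
    package_version = as.character(utils::packageVersion("conforma")))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nReplicas))
      writeBinGrid(grids[[i]], file.path(outDir,
                                         sprintf("run%02d.abf.tsv", i)))
    writeBinGrid(merged, file.path(outDir, "merged.abf.tsv"))
    writeLandscape(landscape, file.path(outDir, "landscape.tsv"),
                   matrixFile = file.path(outDir, "landscape_matrix.tsv"))
    writeBasinSummary(basins, landscape, file.path(outDir, "basins.json"))
    if (!is.null(path))
      writePath(path, landscape, file.path(outDir, "mfep.tsv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(grids = grids, merged = merged, landscape = landscape,
       basins = basins, path = path, barrier = barrier,
       manifest = manifest)
}
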