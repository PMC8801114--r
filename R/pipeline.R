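#' @include genealogyTree.R dimReduction.R syntheticData.R
NULL

#' Assemble a pipeline configuration
#'
#' A validated bag of options driving [runPipeline()].  Input is either a
#' synthetic-panel specification (`specs`) or an incidence CSV
#' (`inputPath`); exactly one must be given.
#'
#' @param specs list of [DiseaseSpec-class] (synthetic input).
#' @param inputPath path to an incidence CSV (real input).
#' @param seed master seed; mandatory, fixes simulation and UMAP.
#' @param outdir output directory (created if needed).
#' @param ageGrid common age grid for the harmonized matrix.
#' @param truncate apply the age-80 truncation rule.
#' @param truncateAge,minPointsAfter truncation parameters.
#' @param gateThreshold linearity-gate r-squared threshold in [0, 1.01]
#'   (values above 1 force every stratum to fail the gate).
#' @param jitter per-study bin-edge jitter in years for synthetic panels.
#' @param counterpartRule apply the registry counterpart-exclusion rule.
#' @param embedLevel embed `"dataset"` profiles (one per study) or
#'   `"stratum"` averages.
#' @param nNeighbors,minDist UMAP parameters.
#' @param sharedBinWidth bin width (years) of the shared-age-range count.
#' @param sexMode `"pooled"` or `"split"` tree rendering.
#' @param useMidpoints age-range bounds from midpoints instead of edges.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(specs = defaultPanelSpecs(), inputPath = NULL,
                           seed = 1L, outdir = tempfile("ndsteps_run_"),
                           ageGrid = 30:79, truncate = TRUE,
                           truncateAge = 80, minPointsAfter = 4L,
                           gateThreshold = 0.8, jitter = 2,
                           counterpartRule = TRUE,
                           embedLevel = c("dataset", "stratum"),
                           nNeighbors = 5, minDist = 0.3,
                           sharedBinWidth = 2,
                           sexMode = c("pooled", "split"),
                           useMidpoints = FALSE) {
  embedLevel <- match.arg(embedLevel)
  sexMode <- match.arg(sexMode)
  if (is.null(specs) == is.null(inputPath))
    stop("provide exactly one of 'specs' or 'inputPath'")
  if (is.null(seed) || is.na(seed))
    stop("'seed' is mandatory")
  if (gateThreshold < 0 || gateThreshold > 1.01)
    stop("'gateThreshold' must lie in [0, 1.01]")
  if (sharedBinWidth <= 0) stop("'sharedBinWidth' must be > 0")
  cfg <- list(specs = specs, inputPath = inputPath, seed = as.integer(seed),
              outdir = outdir, ageGrid = ageGrid, truncate = truncate,
              truncateAge = truncateAge,
              minPointsAfter = as.integer(minPointsAfter),
              gateThreshold = gateThreshold, jitter = jitter,
              counterpartRule = counterpartRule, embedLevel = embedLevel,
              nNeighbors = nNeighbors, minDist = minDist,
              sharedBinWidth = sharedBinWidth, sexMode = sexMode,
              useMidpoints = useMidpoints)
  class(cfg) <- "PipelineConfig"
  cfg
}

.configHash <- function(config) {
  plain <- config
  plain$specs <- lapply(plain$specs, function(s)
    list(s@diseaseCode, s@sex, s@nTrue, s@backgroundRiskU, s@ageMin,
         s@ageMax, s@binWidth, s@noiseSigma, s@nStudies, s@model,
         s@peakAge, s@peakShape))
  plain$outdir <- NULL   # hash identifies the analysis, not its location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(plain), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

# CSV with a provenance comment naming the config hash; read back with
# read.csv(..., comment.char = "#").
.writeTable <- function(df, path, hash, rowNames = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = rowNames)
  invisible(path)
}

.stage <- function(name, stratum = NULL, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "'",
         if (!is.null(stratum)) paste0(" (stratum ", stratum, ")") else "",
         " failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full incidence-to-tree pipeline
#'
#' Executes ingest (or simulation) -> registry filter -> multistep fits ->
#' harmonized incidence matrix -> PCA/UMAP embeddings -> age-range
#' analysis -> genealogy tree, writing each artifact to the configured
#' output directory: `fits.csv`, `incidence_matrix.csv` (with coverage
#' sidecar), `pca.csv`, `umap.csv`, `age_ranges.csv`, `tree.json` and
#' `manifest.json`, plus PDF figures.  Every table carries the config
#' hash; reruns with the same configuration are byte-identical.
#'
#' @param config a [pipelineConfig()] object.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the computed objects and the artifact
#'   paths (`$paths`).
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(seed = 1L, outdir = tempfile())
#' res <- runPipeline(cfg, quiet = TRUE)
#' names(res$paths)
#' }
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  say <- function(...) if (!quiet) message("[ndsteps] ", ...)
  path <- function(f) file.path(config$outdir, f)

  panel <- .stage("ingest", expr = {
    if (!is.null(config$specs)) {
      say("simulating panel (", length(config$specs), " specs, seed ",
          config$seed, ")")
      generatePanel(config$specs, seed = config$seed, jitter = config$jitter)
    } else {
      say("reading ", config$inputPath)
      readIncidenceTable(config$inputPath)
    }
  })
  panel <- .stage("registry_filter", expr =
    filterRegistry(panel, counterpartRule = config$counterpartRule,
                   verbose = !quiet))

  truncAge <- if (config$truncate) config$truncateAge else Inf
  fits <- .stage("fit", expr =
    fitPanel(panel, truncateAge = truncAge,
             minPointsAfter = config$minPointsAfter,
             gateThreshold = config$gateThreshold))
  .writeTable(fitTable(fits), path("fits.csv"), hash)

  im <- .stage("matrix", expr =
    buildIncidenceMatrix(panel, ageGrid = config$ageGrid))
  .writeTable(as.data.frame(incidence(im)), path("incidence_matrix.csv"),
              hash, rowNames = TRUE)
  jsonlite::write_json(
    list(config_hash = hash, age = ageGrid(im),
         coverage = apply(coverage(im), 1L, as.integer, simplify = FALSE)),
    path("incidence_matrix.coverage.json"), auto_unbox = TRUE, digits = NA)

  profiles <- .stage("embed", expr = {
    prof <- if (config$embedLevel == "dataset")
      studyProfiles(panel, ageGrid = config$ageGrid)
    else incidence(im)
    completeColumns(prof)
  })
  pca <- .stage("embed", expr = pcaEmbed(profiles))
  .writeTable(data.frame(label = pca@labels, embeddingCoords(pca)[, 1:2],
                         check.names = FALSE), path("pca.csv"), hash)
  um <- .stage("embed", expr =
    umapEmbed(profiles, nNeighbors = config$nNeighbors,
              minDist = config$minDist, seed = config$seed))
  .writeTable(data.frame(label = um@labels, embeddingCoords(um),
                         check.names = FALSE), path("umap.csv"), hash)
  grDevices::pdf(path("embeddings.pdf"), width = 8, height = 4.5)
  graphics::par(mfrow = c(1, 2))
  plot(pca); plot(um)
  grDevices::dev.off()

  summaries <- .stage("ranges", expr =
    ageRangeSummaries(panel, fits, truncateAge = truncAge,
                      minPointsAfter = config$minPointsAfter,
                      useMidpoints = config$useMidpoints))
  stepsRange <- if (sum(summaries$passesLinearity) >= 3L)
    .stage("ranges", expr = fitStepsVsRange(summaries)) else NULL
  shared <- .stage("ranges", expr =
    sharedAgeBins(summaries, binWidth = config$sharedBinWidth))
  .writeTable(summaries, path("age_ranges.csv"), hash)
  .writeTable(shared$bins, path("shared_age_bins.csv"), hash)

  gated <- summaries[summaries$passesLinearity, , drop = FALSE]
  tree <- .stage("tree", expr = {
    if (nrow(gated) < 2L) {
      say("no allocatable diseases: fewer than 2 strata pass the ",
          "linearity gate")
      empty <- data.frame(stratum = character(0), nSteps = integer(0),
                          commonSteps = integer(0),
                          specificSteps = integer(0))
      buildTree(empty, summaries, sexMode = config$sexMode)
    } else {
      sm <- buildSharingMatrix(
        data.frame(stratum = gated$stratum, nSteps = gated$nSteps))
      buildTree(allocateSteps(sm), summaries, sexMode = config$sexMode)
    }
  })
  writeTreeJSON(tree, path("tree.json"))
  grDevices::pdf(path("tree.pdf"), width = 7, height = 7)
  plot(tree)
  grDevices::dev.off()

  manifest <- list(
    config_hash = hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("ndsteps")),
    n_datasets = length(panel),
    n_strata = length(fits),
    gate_threshold = config$gateThreshold,
    gated_strata = sum(summaries$passesLinearity),
    steps_vs_range = stepsRange,
    shared_interval = shared$sharedInterval,
    artifacts = c("fits.csv", "incidence_matrix.csv", "pca.csv", "umap.csv",
                  "age_ranges.csv", "tree.json", "manifest.json"))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(config$specs))
    writePanelManifest(config$specs, config$seed, path("panel_manifest.json"))

  invisible(list(
    panel = panel, fits = fits, incidenceMatrix = im, pca = pca, umap = um,
    summaries = summaries, stepsVsRange = stepsRange, sharedBins = shared,
    tree = tree, configHash = hash,
    paths = stats::setNames(
      file.path(config$outdir, manifest$artifacts), manifest$artifacts)))
}
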