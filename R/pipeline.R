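#' Deterministic configuration hash
#'
#' MD5 of the serialized object (version-stable serialization), used to
#' stamp run manifests.
#'
#' @param x any R object.
#' @return character(1) hex digest.
#' @export
configHash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
}

#' Assemble a full pipeline configuration
#'
#' Stage parameters for the whole analysis with defaults at the standard
#' protocol values: asinh cofactor 5, state cutoffs +/-1.2, entropy over
#' 1,000 cells x 10 iterations, 50 um graph pruning, 1,000 permutations at
#' alpha 0.01 with a >= 3-patient consistency filter, k = 12 neighborhoods,
#' and the strict > 3 patients / > 5% dominant-SC filter. All stage
#' randomness derives from the single global seed.
#'
#' @param seed global seed; every stage seed is derived from it.
#' @param transform a [transformSpec()].
#' @param gating_rules a gating rule table.
#' @param state_thresholds a [stateThresholds()].
#' @param entropy an [entropySpec()].
#' @param max_dist graph pruning distance (um).
#' @param interaction an [interactionSpec()].
#' @param k number of cellular neighborhoods.
#' @param kmeans_n_init k-means restarts.
#' @param sc an [scSpec()].
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L,
                           transform = transformSpec(),
                           gating_rules = defaultGatingRules(),
                           state_thresholds = stateThresholds(),
                           entropy = entropySpec(seed = seed + 1L),
                           max_dist = 50,
                           interaction = interactionSpec(seed = seed + 2L),
                           k = 12L,
                           kmeans_n_init = 10L,
                           sc = scSpec()) {
    stopifnot(max_dist > 0, k >= 1)
    structure(list(seed = as.integer(seed), transform = transform,
                   gating_rules = gating_rules,
                   state_thresholds = state_thresholds, entropy = entropy,
                   max_dist = max_dist, interaction = interaction,
                   k = as.integer(k), kmeans_n_init = as.integer(kmeans_n_init),
                   sc = sc),
              class = "PipelineConfig")
}

.validateConfig <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    if (config$interaction$alpha <= 0 || config$interaction$alpha >= 1)
        stop("validation error: alpha must lie in (0, 1)")
    if (config$transform$cofactor <= 0)
        stop("validation error: cofactor must be positive")
    invisible(TRUE)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes phenotype -> graph -> diversity/interactions -> neighborhoods ->
#' spatial contexts on a cell table, in order, aborting with the failing
#' stage's name on error. Returns all stage outputs plus a run manifest
#' (config hash, seed, package version, timestamps) that is reproducible for
#' identical config + input.
#'
#' @param table a [CellTable-class] with raw intensities (e.g. from
#'   [generateCohort()] or [readCellTable()]).
#' @param config a [pipelineConfig()].
#' @param skip_phenotyping use planted `true_type` labels instead of running
#'   the gating stage (for generator-only studies without markers).
#' @return list: table (annotated), graphs, entropy, entropy_tests,
#'   interactions, aggregated_calls, cn_model, cn_summary, spatial_contexts,
#'   dominant_scs, networks, network_comparison, manifest.
#' @export
runPipeline <- function(table, config = pipelineConfig(),
                        skip_phenotyping = FALSE) {
    .validateConfig(config)
    t0 <- Sys.time()

    if (!skip_phenotyping) {
        table <- .stage("phenotype", {
            tb <- transformIntensities(table, config$transform)
            tb <- zScoreIntensities(tb, config$transform$batch_key)
            tb <- excludeBroadlyHigh(tb, config$transform)
            tb <- assignTypes(tb, config$gating_rules)
            callStates(tb, config$state_thresholds)
        })
        type_column <- "cell_type"
    } else type_column <- "true_type"

    graphs <- .stage("graph", buildSpatialGraph(table, config$max_dist))

    entropy <- .stage("diversity",
                      subsampledEntropy(table, config$entropy,
                                        type_column = type_column))
    entropy_tests <- .stage("diversity", {
        list(cohort = compareEntropy(entropy, "cohort"),
             patient = tryCatch(compareEntropy(entropy, "patient"),
                                error = function(e) conditionMessage(e)))
    })

    interactions <- .stage("interactions",
                           testInteractions(table, graphs,
                                            config$interaction,
                                            type_column = type_column))
    aggregated <- .stage("interactions",
                         aggregateCalls(interactions$patient,
                                        config$interaction))

    cd <- as.data.frame(colData(table))
    labels <- stats::setNames(as.character(cd[[type_column]]), cd$cell_id)
    cn_model <- .stage("neighborhoods", {
        vec <- neighborComposition(graphs, labels)
        fitNeighborhoods(vec, k = config$k, seed = config$seed + 3L,
                         n_init = config$kmeans_n_init)
    })
    table <- addCNLabels(table, cn_model)
    cn_summary <- .stage("neighborhoods", cnPrevalence(cn_model, table,
                                                       type_column))

    scres <- .stage("contexts", detectSpatialContexts(table, graphs,
                                                      config$sc))
    dominant <- .stage("contexts", filterDominantSCs(scres, config$sc))
    counts <- base::table(colData(table)$cn)
    networks <- .stage("contexts", {
        suppressWarnings(list(
            primary = buildCNNetwork(dominant, "primary", counts),
            recurrent = buildCNNetwork(dominant, "recurrent", counts)))
    })
    comparison <- .stage("contexts",
                         compareNetworks(networks$primary,
                                         networks$recurrent,
                                         defaultCNAnnotation()))

    manifest <- list(
        package_version = as.character(utils::packageVersion("spatialTME")),
        seed = config$seed,
        config_hash = configHash(config),
        input_hash = configHash(list(assay = rawIntensities(table),
                                     cells = as.data.frame(colData(
                                         table))[.REQUIRED_CELL_COLS])),
        started = format(t0, usetz = TRUE),
        finished = format(Sys.time(), usetz = TRUE))

    list(table = table, graphs = graphs, entropy = entropy,
         entropy_tests = entropy_tests, interactions = interactions,
         aggregated_calls = aggregated, cn_model = cn_model,
         cn_summary = cn_summary, spatial_contexts = scres,
         dominant_scs = dominant, networks = networks,
         network_comparison = comparison, manifest = manifest)
}
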