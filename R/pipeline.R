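#' Default pipeline configuration
#'
#' Returns the default configuration list for \code{\link{runPipeline}},
#' which callers override field by field (or via a YAML file with the same
#' structure). \code{cohort} holds either \code{simulate} (arguments to
#' \code{\link{cohortConfig}}) or \code{files} (paths to per-layer
#' matrices, a clinical table, and optional prior lists / probe map).
#'
#' @param seed Master seed; every random stage derives its own stream from
#'   it.
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(simulate = list()),
    prep = list(topFrac = 0.25, maxBadFrac = 0.05),
    grid = list(distances = c("euclidean", "manhattan"),
                linkages = c("ward_d", "average"),
                kRange = 2:11, minClusterSize = 10L),
    eval = list(B = 500L, searchB = 100L, iters = 500L, folds = 5L,
                taus = c(730, 1095, 1825)),
    models = list(includeCoc = TRUE, ablation = FALSE),
    outdir = "survcoc_out")
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(defaultPipelineConfig(), config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Assemble cohort inputs: list(layers, clinical, survival, digests, log)
.loadCohortInputs <- function(cfg) {
  ch <- cfg$cohort
  if (!is.null(ch$simulate)) {
    args <- ch$simulate
    if (is.null(args$seed)) args$seed <- deriveSeed(cfg$seed, "cohort")
    coh <- generateCohort(do.call(cohortConfig, args))
    return(list(layers = coh@layers, clinical = coh@clinical,
                survival = coh@survival, digests = NULL,
                log = sprintf("simulated cohort: n=%d",
                              length(coh@survival@time)),
                cohort = coh))
  }
  fl <- ch$files
  stopifnot(!is.null(fl$clinical))
  cl <- readClinicalTable(fl$clinical)
  layers <- list()
  scaleOf <- c(expression = "fpkm", methylation = "beta", mirna = "rpm")
  for (nm in intersect(names(scaleOf), names(fl))) {
    layers[[nm]] <- readOmicsMatrix(fl[[nm]], layer = nm,
                                    scale = scaleOf[[nm]],
                                    transposed = isTRUE(fl$transposed))
  }
  if (!length(layers)) stop("no omics layer files configured")
  if (!is.null(fl$probe_map) && !is.null(layers$methylation)) {
    map <- readProbeGeneMap(fl$probe_map)
    layers$methylation <- aggregateProbesToGenes(layers$methylation, map)
  }
  # sample alignment: identifier intersection, deterministic sorted order
  ids <- sort(Reduce(intersect, c(list(as.character(cl$clinical$sample_id)),
                                  lapply(layers, sampleIDs))))
  nDropped <- length(cl$survival@time) - length(ids)
  if (!length(ids)) stop("no samples shared by clinical and omics inputs")
  keep <- match(ids, cl$survival@sampleIDs)
  surv <- SurvData(cl$survival@time[keep], cl$survival@event[keep], ids)
  clin <- cl$clinical[match(ids, cl$clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  for (nm in names(layers)) {
    l <- layers[[nm]]
    l@values <- l@values[match(ids, rownames(l@values)), , drop = FALSE]
    layers[[nm]] <- l
  }
  paths <- unlist(fl[vapply(fl, is.character, TRUE)])
  list(layers = layers, clinical = clin, survival = surv,
       digests = as.list(tools::md5sum(paths[file.exists(paths)])),
       log = sprintf("intersected samples: kept %d, dropped %d",
                     length(ids), nDropped))
}

.prepLayer <- function(x, prep, prior = NULL) {
  x <- filterLowQuality(x, maxBadFrac = prep$maxBadFrac)
  x <- selectFeatures(x, topFrac = prep$topFrac, prior = prior)
  imputeMedian(x)
}

#' Run the full integration pipeline
#'
#' Executes omics preparation (quality filter, top-CV + prior feature
#' selection, median imputation), the per-layer prognosis-driven
#' cluster-parameter searches in both regimes (with clinical companions,
#' and label-only), the cluster-of-clusters integration, evaluation of the
#' requested covariate-combination models, the model comparison against the
#' full model CGMm, and (optionally) the leave-one-covariate-out ablation.
#' All outputs are written to \code{outdir} as delimited text plus a JSON
#' run manifest; re-running with the same configuration and master seed
#' reproduces the tables byte-identically.
#'
#' @param config Configuration list or YAML path; see
#'   \code{\link{defaultPipelineConfig}}.
#' @return Invisibly, a list with the cohort bundle, search results, model
#'   evaluations, comparison table and manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  cfg <- .loadConfig(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list(); warningsLog <- character()
  stageTime <- function(nm) {
    t1 <- proc.time()[["elapsed"]]
    timings[[nm]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  inputs <- .loadCohortInputs(cfg)
  stageTime("load")

  priors <- list()
  pl <- cfg$cohort$files$priors
  if (!is.null(pl))
    for (nm in names(pl)) priors[[nm]] <- readPriorList(pl[[nm]])
  prepped <- list()
  for (nm in names(inputs$layers))
    prepped[[nm]] <- .prepLayer(inputs$layers[[nm]], cfg$prep, priors[[nm]])
  stageTime("prep")

  grid <- do.call(clusterGridSpec, cfg$grid)
  evalCfg <- do.call(evalConfig,
                     c(cfg$eval, list(seed = deriveSeed(cfg$seed, "eval"))))
  clinDesign <- encodeCovariates(inputs$clinical)
  ageBreaks <- attr(clinDesign@values, "ageBreaks")

  letterOf <- c(expression = "G", methylation = "M", mirna = "m")
  searches <- list()
  labelsCompanion <- list(); labelsAlone <- list()
  for (nm in names(prepped)) {
    lt <- letterOf[[nm]]
    searches[[paste0(nm, "_companion")]] <-
      clusterGridSearch(prepped[[nm]], inputs$survival,
                        companions = clinDesign, grid = grid,
                        evalCfg = evalCfg, labelPrefix = lt)
    labelsCompanion[[lt]] <- winningLabels(searches[[paste0(nm, "_companion")]])
    searches[[paste0(nm, "_alone")]] <-
      clusterGridSearch(prepped[[nm]], inputs$survival, companions = NULL,
                        grid = grid, evalCfg = evalCfg, labelPrefix = lt)
    labelsAlone[[lt]] <- winningLabels(searches[[paste0(nm, "_alone")]])
    nInfeas <- sum(!candidateTable(searches[[paste0(nm, "_companion")]])$feasible)
    if (nInfeas)
      warningsLog <- c(warningsLog,
                       sprintf("%s: %d infeasible candidates", nm, nInfeas))
  }
  cocSearch <- NULL
  if (isTRUE(cfg$models$includeCoc) && length(labelsCompanion) == 3) {
    cocSearch <- clusterOfClusters(labelsCompanion, inputs$survival,
                                   companions = clinDesign, grid = grid,
                                   evalCfg = evalCfg)
    searches[["coc"]] <- cocSearch
  }
  stageTime("cluster_search")

  bundle <- list(clinical = inputs$clinical, survival = inputs$survival,
                 labelsCompanion = labelsCompanion,
                 labelsAlone = labelsAlone,
                 labelsCoC = if (!is.null(cocSearch))
                   winningLabels(cocSearch) else NULL,
                 ageBreaks = ageBreaks)

  specs <- enumerateModels(includeCoc = isTRUE(cfg$models$includeCoc) &&
                             !is.null(bundle$labelsCoC))
  evals <- list()
  for (sp in specs) {
    evals[[modelCode(sp)]] <- evaluateModel(sp, bundle, evalCfg)
    bsRe <- evals[[modelCode(sp)]]@bootstrap@nRedrawn
    if (bsRe) warningsLog <- c(warningsLog,
                               sprintf("%s: %d bootstrap replicates redrawn",
                                       modelCode(sp), bsRe))
  }
  stageTime("evaluate")

  comparison <- compareModels(evals)
  abl <- NULL
  if (isTRUE(cfg$models$ablation)) {
    abl <- ablation(bundle, evalCfg, fullEval = evals[["CGMm"]])
    stageTime("ablation")
  }

  # ---- outputs ----
  out <- cfg$outdir
  for (nm in names(searches))
    writeCandidateTable(searches[[nm]], file.path(out,
                                                  paste0("candidates_", nm, ".tsv")))
  for (lt in names(labelsCompanion))
    writeClusterLabels(labelsCompanion[[lt]],
                       file.path(out, paste0("labels_", lt, "_companion.tsv")))
  if (!is.null(bundle$labelsCoC))
    writeClusterLabels(bundle$labelsCoC, file.path(out, "labels_coc.tsv"))
  if ("CGMm" %in% names(evals)) {
    tb <- coefTable(evals[["CGMm"]]@fit)
    tb[-1] <- lapply(tb[-1], signif, 6)
    utils::write.table(tb, file.path(out, "coefficients_CGMm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeModelEvaluations(evals, file.path(out, "model_evaluations.json"))
  compOut <- comparison
  compOut[] <- lapply(compOut, function(x) if (is.numeric(x)) signif(x, 8)
                      else x)
  utils::write.table(compOut, file.path(out, "comparison.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  if (!is.null(abl)) {
    ablOut <- abl
    ablOut[] <- lapply(ablOut, function(x) if (is.numeric(x)) signif(x, 8)
                       else x)
    utils::write.table(ablOut, file.path(out, "ablation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  stageTime("write")

  manifest <- list(
    package_version = as.character(utils::packageVersion("SurvCoC")),
    master_seed = cfg$seed,
    config = cfg,
    input_digests = inputs$digests,
    log = inputs$log,
    timings_sec = timings,
    warnings = warningsLog)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(bundle = bundle, searches = searches, evals = evals,
                 comparison = comparison, ablation = abl,
                 manifest = manifest, outdir = out,
                 cohort = inputs$cohort))
}

#' Serialise model evaluations to JSON
#'
#' Stores, per model, the apparent and bias-corrected Harrell's C with its
#' full per-replicate distribution, the per-iteration cross-validated
#' Uno's C values per horizon, the global PH-test p-value, the three
#' global-test p-values and the seeds -- enough to re-run the paired model
#' comparison from the file alone.
#'
#' @param evals Named list of \linkS4class{ModelEvaluation}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeModelEvaluations <- function(evals, path) {
  out <- lapply(evals, function(ev) {
    list(code = modelCode(ev),
         apparent_c = ev@bootstrap@apparent,
         corrected_c = ev@bootstrap@mean,
         corrected_ci95 = ev@bootstrap@ci95,
         bootstrap_values = ev@bootstrap@values,
         bootstrap_seed = ev@bootstrap@seed,
         cv_taus = ev@cv@taus,
         cv_means = ev@cv@means,
         cv_values = apply(ev@cv@values, 2, identity, simplify = FALSE),
         cv_seed = ev@cv@seed,
         ph_global_p = ev@ph@table$p[nrow(ev@ph@table)],
         p_lrt = ev@tests$lrt$p, p_score = ev@tests$score$p,
         p_wald = ev@tests$wald$p,
         n_covariates = length(ev@fit@beta))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
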