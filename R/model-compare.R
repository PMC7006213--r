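#' Enumerate the covariate-combination models
#'
#' The standard comparison set: the full integration model CGMm, the three
#' two-layer models, the three one-layer models, clinical alone, the three
#' omics-alone models, and (optionally) clinical plus the
#' cluster-of-clusters covariate, CA -- 12 models in all.
#'
#' @param includeCoc Include the CA model (default TRUE).
#' @return List of \linkS4class{ModelSpec}.
#' @export
#' @examples
#' vapply(enumerateModels(), modelCode, "")
enumerateModels <- function(includeCoc = TRUE) {
  codes <- c("CGMm", "CGM", "CGm", "CMm", "CG", "CM", "Cm", "C",
             "G", "M", "m")
  if (includeCoc) codes <- c(codes, "CA")
  lapply(codes, function(cd) new("ModelSpec", code = cd))
}

# Build the CoxDesign for a model code from a cohort bundle.
# bundle: list(clinical, survival, labelsCompanion = list(G=, M=, m=),
#              labelsAlone = list(G=, M=, m=), labelsCoC, ageBreaks)
.modelDesign <- function(spec, bundle) {
  code <- strsplit(spec@code, "")[[1]]
  withClinical <- "C" %in% code
  clusters <- list()
  for (letter in intersect(code, c("G", "M", "m"))) {
    src <- if (withClinical) bundle$labelsCompanion else bundle$labelsAlone
    if (is.null(src[[letter]]))
      stop(sprintf("model %s needs cluster labels for layer %s", spec@code,
                   letter))
    clusters[[letter]] <- src[[letter]]
  }
  if ("A" %in% code) {
    if (is.null(bundle$labelsCoC))
      stop("model ", spec@code, " needs cluster-of-clusters labels")
    clusters[["A"]] <- bundle$labelsCoC
  }
  if (withClinical) {
    encodeCovariates(bundle$clinical, clusters = clusters,
                     ageBreaks = bundle$ageBreaks)
  } else {
    if (!length(clusters)) stop("empty model")
    des <- NULL
    for (nm in names(clusters))
      des <- clusterDesign(clusters[[nm]], companions = des, prefix = nm)
    des
  }
}

#' Evaluate one covariate-combination model
#'
#' Builds the model's design, fits the Cox model, and computes the
#' bias-corrected Harrell's C (bootstrap), the cross-validated Uno's C at
#' the configured horizons, the proportional-hazards test and the three
#' global tests. The bootstrap and cross-validation seeds are derived only
#' from the master seed (not the model code), so evaluations of different
#' models on the same cohort consume identical resample and fold indices
#' and their per-iteration values are paired.
#'
#' @param spec A \linkS4class{ModelSpec} or model-code string.
#' @param bundle Cohort bundle: a list with elements \code{clinical},
#'   \code{survival}, \code{labelsCompanion} (named list of
#'   \linkS4class{ClusterLabels} for G/M/m selected alongside clinical
#'   companions), \code{labelsAlone} (selected without companions),
#'   \code{labelsCoC}, and optional \code{ageBreaks}.
#' @param evalCfg An \code{\link{evalConfig}}.
#' @return A \linkS4class{ModelEvaluation}.
#' @export
evaluateModel <- function(spec, bundle, evalCfg = evalConfig()) {
  if (is.character(spec)) spec <- new("ModelSpec", code = spec)
  des <- .modelDesign(spec, bundle)
  surv <- bundle$survival
  fit <- fitCox(des, surv)
  if (!fit@converged)
    stop(sprintf("model %s: Cox fit failed (%s)", spec@code, fit@message))
  bs <- tryCatch(
    optimismCorrectedC(des, surv, B = evalCfg$B,
                       seed = deriveSeed(evalCfg$seed, "bootstrap")),
    error = function(e) stop(sprintf("model %s: %s", spec@code,
                                     conditionMessage(e))))
  cv <- tryCatch(
    cvUnoC(des, surv, taus = evalCfg$taus, folds = evalCfg$folds,
           iters = evalCfg$iters, seed = deriveSeed(evalCfg$seed, "cv")),
    error = function(e) stop(sprintf("model %s: %s", spec@code,
                                     conditionMessage(e))))
  ph <- phTest(fit, des, surv)
  tests <- modelTests(fit)
  new("ModelEvaluation", spec = spec, design = des, fit = fit,
      bootstrap = bs, cv = cv, ph = ph, tests = tests)
}

#' Compare evaluated models on their paired C-index distributions
#'
#' For each requested (a, b) pair reports the difference in mean C for the
#' bias-corrected bootstrap distribution and each cross-validation horizon,
#' the two-sided paired Wilcoxon signed-rank p-value on the per-iteration
#' value pairs (Pratt's zero handling), the percentile 95\% interval of the
#' paired differences, and -- when model b's covariates are a subset of
#' model a's -- the nested likelihood-ratio p-value. All evaluations must
#' share seeds and sample set so the distributions are paired.
#'
#' @param evals List of \linkS4class{ModelEvaluation}; names default to the
#'   model codes.
#' @param pairs Two-column character matrix of model codes (a, b); by
#'   default the first model is compared against every other.
#' @return data.frame of class \code{"ComparisonTable"}.
#' @export
compareModels <- function(evals, pairs = NULL) {
  codes <- vapply(evals, modelCode, "")
  names(evals) <- codes
  if (is.null(pairs))
    pairs <- cbind(codes[1], codes[-1])
  stopifnot(ncol(pairs) == 2)
  taus <- evals[[1]]@cv@taus
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- evals[[pairs[r, 1]]]; b <- evals[[pairs[r, 2]]]
    if (a@bootstrap@seed != b@bootstrap@seed || a@cv@seed != b@cv@seed)
      stop("evaluations are not paired: seeds differ")
    if (length(a@bootstrap@values) != length(b@bootstrap@values) ||
        nrow(a@cv@values) != nrow(b@cv@values))
      stop("evaluations are not paired: iteration counts differ")
    row <- list(model_a = pairs[r, 1], model_b = pairs[r, 2])
    dBoot <- a@bootstrap@values - b@bootstrap@values
    row$delta_boot <- mean(dBoot)
    qb <- stats::quantile(dBoot, c(0.025, 0.975))
    row$delta_boot_lo <- unname(qb[1]); row$delta_boot_hi <- unname(qb[2])
    row$p_wilcox_boot <- pairedSignedRank(a@bootstrap@values,
                                          b@bootstrap@values)$p
    for (j in seq_along(taus)) {
      dj <- a@cv@values[, j] - b@cv@values[, j]
      qt <- stats::quantile(dj, c(0.025, 0.975))
      tag <- sprintf("cv%g", taus[j])
      row[[paste0("delta_", tag)]] <- mean(dj)
      row[[paste0("delta_", tag, "_lo")]] <- unname(qt[1])
      row[[paste0("delta_", tag, "_hi")]] <- unname(qt[2])
      row[[paste0("p_wilcox_", tag)]] <-
        pairedSignedRank(a@cv@values[, j], b@cv@values[, j])$p
    }
    # nesting judged on design columns; df from the fitted ranks, so that
    # aliased (collinear) columns do not inflate the test
    nested <- all(colnames(b@design@values) %in% colnames(a@design@values))
    row$p_lrt <- if (nested) .lrtNestedRank(a@fit, b@fit)$p else NA_real_
    rows[[r]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "zero_handling") <- "pratt"
  class(out) <- c("ComparisonTable", class(out))
  out
}

#' Leave-one-covariate-out ablation of the full model
#'
#' Starting from the full integration model (clinical decomposed into
#' T / N / M-stage / Age blocks plus the three omics cluster blocks), each
#' of the seven blocks is removed in turn, the reduced model is
#' re-evaluated on the same seeds, and compared with the full model. The
#' report always has seven rows.
#'
#' @param bundle Cohort bundle as in \code{\link{evaluateModel}}.
#' @param evalCfg An \code{\link{evalConfig}}.
#' @param fullEval Optional precomputed \linkS4class{ModelEvaluation} of
#'   CGMm (avoids refitting).
#' @return data.frame of class \code{"AblationReport"}: one row per removed
#'   block with the C-index drops and p-values.
#' @export
ablation <- function(bundle, evalCfg = evalConfig(), fullEval = NULL) {
  if (is.null(fullEval))
    fullEval <- evaluateModel("CGMm", bundle, evalCfg)
  stopifnot(modelCode(fullEval) == "CGMm")
  des <- fullEval@design
  dropBlocks <- list("T_stage", "N_stage", "M_stage", "Age", "G", "M", "m")
  labels <- c("Without T stage", "Without N stage", "Without M stage",
              "Without Age", "Without Gene", "Without Methylation",
              "Without miRNA")
  stopifnot(all(unlist(dropBlocks) %in% names(des@blocks)))
  surv <- bundle$survival
  rows <- list()
  taus <- fullEval@cv@taus
  for (i in seq_along(labels)) {
    red <- dropDesignBlocks(des, dropBlocks[[i]])
    fit <- fitCox(red, surv)
    if (!fit@converged)
      stop(labels[i], ": reduced fit failed (", fit@message, ")")
    bs <- optimismCorrectedC(red, surv, B = evalCfg$B,
                             seed = deriveSeed(evalCfg$seed, "bootstrap"))
    cv <- cvUnoC(red, surv, taus = taus, folds = evalCfg$folds,
                 iters = evalCfg$iters, seed = deriveSeed(evalCfg$seed, "cv"))
    row <- list(removed = labels[i])
    row$delta_boot <- fullEval@bootstrap@mean - bs@mean
    row$p_wilcox_boot <- pairedSignedRank(fullEval@bootstrap@values,
                                          bs@values)$p
    for (j in seq_along(taus)) {
      tag <- sprintf("cv%g", taus[j])
      row[[paste0("delta_", tag)]] <- fullEval@cv@means[j] - cv@means[j]
      row[[paste0("p_wilcox_", tag)]] <-
        pairedSignedRank(fullEval@cv@values[, j], cv@values[, j])$p
    }
    row$p_lrt <- .lrtNestedRank(fullEval@fit, fit)$p
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("AblationReport", class(out))
  out
}
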