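#' @useDynLib SurvCoC, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' OmicsMatrix: one omics layer as a samples-by-features matrix
#'
#' Container for a single omics layer. Rows are samples, columns are
#' features; \code{NA} entries are allowed. The \code{layer} tag records the
#' biological layer and \code{scale} the measurement scale (FPKM-like
#' expression, beta-value methylation in \eqn{[0,1]}, RPM-like miRNA, or the
#' binary patient-by-cluster indicator matrix used by the cluster-of-clusters
#' step).
#'
#' @slot values Numeric matrix (samples x features) with dimnames.
#' @slot layer One of \code{"expression"}, \code{"methylation"},
#'   \code{"mirna"}, \code{"cluster_binary"}.
#' @slot scale One of \code{"fpkm"}, \code{"beta"}, \code{"rpm"},
#'   \code{"binary"}.
#' @export
setClass("OmicsMatrix",
  representation(values = "matrix", layer = "character", scale = "character"))

.omics_layers <- c("expression", "methylation", "mirna", "cluster_binary")
.omics_scales <- c("fpkm", "beta", "rpm", "binary")

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry sample (row) and feature (column) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate feature ids")
  }
  if (length(object@layer) != 1L || !object@layer %in% .omics_layers)
    msg <- c(msg, "invalid layer tag")
  if (length(object@scale) != 1L || !object@scale %in% .omics_scales)
    msg <- c(msg, "invalid scale tag")
  if (identical(object@scale, "beta")) {
    vv <- v[!is.na(v)]
    if (length(vv) && (min(vv) < 0 || max(vv) > 1))
      msg <- c(msg, "beta-scale values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values Numeric samples-by-features matrix with dimnames.
#' @param layer,scale Layer and measurement-scale tags (see
#'   \linkS4class{OmicsMatrix}).
#' @return An \linkS4class{OmicsMatrix}.
#' @export
#' @examples
#' m <- matrix(rexp(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' OmicsMatrix(m, layer = "expression", scale = "fpkm")
OmicsMatrix <- function(values, layer, scale) {
  new("OmicsMatrix", values = values, layer = layer, scale = scale)
}

#' SurvData: right-censored follow-up
#'
#' Per-sample follow-up time in days and event indicator (1 = death
#' observed, 0 = censored).
#'
#' @slot time Non-negative numeric vector (days).
#' @slot event Integer 0/1 vector.
#' @slot sampleIDs Character sample identifiers.
#' @export
setClass("SurvData",
  representation(time = "numeric", event = "integer", sampleIDs = "character"))

setValidity("SurvData", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@event) != n || length(object@sampleIDs) != n)
    msg <- c(msg, "time, event and sampleIDs must have equal length")
  if (any(!is.finite(object@time)) || any(object@time < 0))
    msg <- c(msg, "times must be finite and non-negative")
  if (!all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event must be 0/1")
  if (anyDuplicated(object@sampleIDs)) msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct a SurvData object
#'
#' @param time Follow-up times in days.
#' @param event Event indicators (1 = death, 0 = censored).
#' @param sampleIDs Sample identifiers; defaults to names of \code{time} or
#'   \code{"S1"..}.
#' @return A \linkS4class{SurvData}.
#' @export
SurvData <- function(time, event, sampleIDs = NULL) {
  if (is.null(sampleIDs))
    sampleIDs <- if (!is.null(names(time))) names(time)
                 else paste0("S", seq_along(time))
  new("SurvData", time = as.numeric(time), event = as.integer(event),
      sampleIDs = as.character(sampleIDs))
}

#' ClusterLabels: a patient partition from one clustering candidate
#'
#' @slot labels Integer vector in \code{1..k}, one per sample, numbered by
#'   first appearance.
#' @slot k Integer number of clusters.
#' @slot params Named list recording the generating parameters
#'   (\code{metric}, \code{linkage}, \code{k}), empty for externally
#'   supplied partitions.
#' @slot sampleIDs Character sample identifiers (source-matrix order).
#' @export
setClass("ClusterLabels",
  representation(labels = "integer", k = "integer", params = "list",
                 sampleIDs = "character"))

setValidity("ClusterLabels", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@sampleIDs))
    msg <- c(msg, "labels and sampleIDs length mismatch")
  k <- object@k
  if (length(k) != 1L || k < 1L) msg <- c(msg, "invalid k")
  else if (!setequal(unique(object@labels), seq_len(k)))
    msg <- c(msg, "labels must occupy every value in 1..k")
  if (length(msg)) msg else TRUE
})

#' MergeTree: agglomerative merge history
#'
#' Encodes \code{n - 1} merges in \code{\link[stats]{hclust}} convention:
#' negative entries of \code{merge} are leaves, positive entries earlier
#' merge steps.
#'
#' @slot nLeaves Integer leaf count.
#' @slot merge Integer (n-1) x 2 matrix.
#' @slot height Numeric merge heights (may be non-monotone for median or
#'   centroid linkage).
#' @slot labels Character leaf labels.
#' @slot linkage Linkage name used.
#' @export
setClass("MergeTree",
  representation(nLeaves = "integer", merge = "matrix", height = "numeric",
                 labels = "character", linkage = "character"))

setValidity("MergeTree", function(object) {
  n <- object@nLeaves
  msg <- character()
  if (nrow(object@merge) != max(n - 1L, 0L) || ncol(object@merge) != 2L)
    msg <- c(msg, "merge must be (nLeaves-1) x 2")
  if (length(object@height) != max(n - 1L, 0L))
    msg <- c(msg, "height length mismatch")
  lv <- -object@merge[object@merge < 0]
  if (n > 1L && !setequal(lv, seq_len(n)))
    msg <- c(msg, "every leaf must appear exactly once")
  if (length(msg)) msg else TRUE
})

#' ClusterSearchResult: the clustering-parameter grid with its winner
#'
#' @slot candidates data.frame with one row per (metric, linkage, k)
#'   candidate: columns \code{metric}, \code{linkage}, \code{k},
#'   \code{feasible}, \code{score}, \code{reason}.
#' @slot labelSets List of \linkS4class{ClusterLabels}, one per candidate.
#' @slot winner Integer row index of the winning candidate.
#' @slot scoreType Character description of the selection score.
#' @export
setClass("ClusterSearchResult",
  representation(candidates = "data.frame", labelSets = "list",
                 winner = "integer", scoreType = "character"))

setValidity("ClusterSearchResult", function(object) {
  msg <- character()
  cd <- object@candidates
  if (length(object@labelSets) != nrow(cd))
    msg <- c(msg, "one label set per candidate required")
  w <- object@winner
  if (length(w) != 1L || w < 1L || w > nrow(cd)) msg <- c(msg, "bad winner")
  else {
    if (!isTRUE(cd$feasible[w])) msg <- c(msg, "winner must be feasible")
    sc <- cd$score[cd$feasible]
    if (length(sc) && any(sc > cd$score[w] + 1e-12))
      msg <- c(msg, "winner score must be maximal among feasible candidates")
  }
  if (length(msg)) msg else TRUE
})

#' CoxDesign: dummy-coded covariate matrix for Cox fitting
#'
#' Treatment-coded design with the reference levels used in colon-cancer
#' staging models: T1, N0, M0, the youngest age bin, and cluster 1 of every
#' cluster-label covariate.
#'
#' @slot values Numeric samples x covariates matrix.
#' @slot referenceLevels Named character vector, baseline level per factor.
#' @slot blocks Named list mapping covariate blocks (e.g. \code{"T"},
#'   \code{"Age"}, \code{"G"}) to column names, used by the ablation study.
#' @slot sampleIDs Character sample ids (row order).
#' @export
setClass("CoxDesign",
  representation(values = "matrix", referenceLevels = "character",
                 blocks = "list", sampleIDs = "character"))

setValidity("CoxDesign", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@sampleIDs))
    msg <- c(msg, "row/sampleIDs mismatch")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "design columns must be named")
  if (length(msg)) msg else TRUE
})

#' CoxPHFit: a fitted Cox proportional-hazards model
#'
#' Result of the Newton--Raphson maximisation of the Efron partial
#' likelihood. Hazard ratios and their normal-approximation 95\% confidence
#' intervals are \code{exp(beta +/- 1.96 se)}.
#'
#' @slot beta Named coefficient vector.
#' @slot se Standard errors from the inverse observed information.
#' @slot vcov Variance-covariance matrix.
#' @slot loglikNull,loglikFull Log partial likelihood at beta = 0 and at the
#'   maximum.
#' @slot score0,info0 Score vector and information at beta = 0 (for the
#'   global score test).
#' @slot nEvents,n Event and sample counts.
#' @slot converged Logical convergence flag.
#' @slot iterations Newton iterations used.
#' @slot logLikTrace Per-iteration log partial likelihood.
#' @slot linearPredictor Linear predictor on the training samples
#'   (original row order).
#' @slot message Diagnostic message when not converged.
#' @export
setClass("CoxPHFit",
  representation(beta = "numeric", se = "numeric", vcov = "matrix",
                 loglikNull = "numeric", loglikFull = "numeric",
                 score0 = "numeric", info0 = "matrix",
                 nEvents = "integer", n = "integer",
                 converged = "logical", iterations = "integer",
                 logLikTrace = "numeric", linearPredictor = "numeric",
                 message = "character"))

#' ConcordanceResult: a single concordance index
#'
#' @slot c Concordance in \eqn{[0,1]}.
#' @slot nPairs Number of usable (weighted, for the IPCW variant) pairs.
#' @slot variant \code{"harrell"} or \code{"uno"}.
#' @slot tau Truncation horizon in days (Uno variant only, else NULL).
#' @export
setClass("ConcordanceResult",
  representation(c = "numeric", nPairs = "numeric", variant = "character",
                 tau = "numericOrNULL"))

setValidity("ConcordanceResult", function(object) {
  if (object@c < 0 || object@c > 1) "concordance must lie in [0,1]" else TRUE
})

#' BootstrapCResult: bias-corrected Harrell's C distribution
#'
#' Per-replicate optimism-subtracted values
#' \eqn{C_{app} - (C_{boot} - C_{orig})}; their mean equals the classical
#' optimism-corrected estimate.
#'
#' @slot apparent Apparent (training-data) Harrell's C.
#' @slot values Per-replicate bias-corrected values.
#' @slot mean Mean bias-corrected C.
#' @slot ci95 2.5/97.5 percentile interval of \code{values}.
#' @slot seed Seed used.
#' @slot nRedrawn Number of failed-and-redrawn replicates.
#' @export
setClass("BootstrapCResult",
  representation(apparent = "numeric", values = "numeric", mean = "numeric",
                 ci95 = "numeric", seed = "integer", nRedrawn = "integer"))

#' CVConcordance: cross-validated Uno's C distributions
#'
#' One pooled out-of-fold Uno's C per iteration and horizon.
#'
#' @slot taus Horizons in days.
#' @slot values Iterations x horizons matrix of Uno's C values.
#' @slot means Column means.
#' @slot folds,seed Fold count and seed used.
#' @slot nRedrawn Iterations redrawn after a failed fold fit.
#' @export
setClass("CVConcordance",
  representation(taus = "numeric", values = "matrix", means = "numeric",
                 folds = "integer", seed = "integer", nRedrawn = "integer"))

#' PHTestResult: proportional-hazards assumption test
#'
#' Grambsch--Therneau score test on scaled Schoenfeld residuals against the
#' Kaplan--Meier-transformed time scale; per-covariate and global
#' chi-square statistics.
#'
#' @slot table data.frame with rows per covariate plus GLOBAL: columns
#'   \code{chisq}, \code{df}, \code{p}.
#' @export
setClass("PHTestResult", representation(table = "data.frame"))

#' ModelSpec: a covariate-combination code
#'
#' Codes follow the field's shorthand: \code{C} clinical, \code{G} gene
#' expression clusters, \code{M} DNA methylation clusters, \code{m} miRNA
#' clusters, \code{A} the integrated cluster-of-clusters covariate.
#'
#' @slot code Character code, e.g. \code{"CGMm"} or \code{"CA"}.
#' @export
setClass("ModelSpec", representation(code = "character"))

setValidity("ModelSpec", function(object) {
  code <- object@code
  if (length(code) != 1L || nchar(code) < 1L) return("empty code")
  ch <- strsplit(code, "")[[1]]
  if (!all(ch %in% c("C", "G", "M", "m", "A"))) return("invalid code letter")
  if (anyDuplicated(ch)) return("duplicate code letter")
  if ("A" %in% ch && any(c("G", "M", "m") %in% ch))
    return("A is mutually exclusive with G/M/m")
  TRUE
})

#' ModelEvaluation: the full evaluation bundle for one model
#'
#' @slot spec \linkS4class{ModelSpec}.
#' @slot design \linkS4class{CoxDesign} used.
#' @slot fit \linkS4class{CoxPHFit}.
#' @slot bootstrap \linkS4class{BootstrapCResult}.
#' @slot cv \linkS4class{CVConcordance}.
#' @slot ph \linkS4class{PHTestResult}.
#' @slot tests Named list with the likelihood-ratio, score and Wald global
#'   test statistics and p-values.
#' @export
setClass("ModelEvaluation",
  representation(spec = "ModelSpec", design = "CoxDesign", fit = "CoxPHFit",
                 bootstrap = "BootstrapCResult", cv = "CVConcordance",
                 ph = "PHTestResult", tests = "list"))

#' SyntheticCohort: a simulated multi-omics survival cohort
#'
#' @slot layers Named list of three \linkS4class{OmicsMatrix} objects
#'   (\code{expression}, \code{methylation}, \code{mirna}).
#' @slot clinical data.frame with columns \code{sample_id}, \code{t_stage},
#'   \code{n_stage}, \code{m_stage}, \code{age_years}.
#' @slot survival \linkS4class{SurvData}.
#' @slot trueSubtype Integer latent subtype per sample.
#' @slot trueLinearPredictor Generating log-hazard per sample.
#' @slot config The generating configuration (list).
#' @export
setClass("SyntheticCohort",
  representation(layers = "list", clinical = "data.frame",
                 survival = "SurvData", trueSubtype = "integer",
                 trueLinearPredictor = "numeric", config = "list"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- object@survival@sampleIDs
  for (nm in names(object@layers)) {
    if (!identical(rownames(object@layers[[nm]]@values), ids))
      msg <- c(msg, sprintf("layer '%s' sample order differs from survival", nm))
  }
  if (!identical(as.character(object@clinical$sample_id), ids))
    msg <- c(msg, "clinical sample order differs from survival")
  if (length(object@trueSubtype) != length(ids) ||
      length(object@trueLinearPredictor) != length(ids))
    msg <- c(msg, "truth vectors must match sample count")
  if (length(msg)) msg else TRUE
})
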