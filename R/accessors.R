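#' @name accessors
#' @title Accessors for SurvCoC classes
#' @description Accessor generics and methods; user code should use these
#'   rather than reaching into slots.
#' @param object An object of the documented class.
#' @param x An object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("omicsValues", function(object) standardGeneric("omicsValues"))
#' @rdname accessors
#' @export
setGeneric("omicsLayer", function(object) standardGeneric("omicsLayer"))
#' @rdname accessors
#' @export
setGeneric("omicsScale", function(object) standardGeneric("omicsScale"))
#' @rdname accessors
#' @export
setGeneric("survTime", function(object) standardGeneric("survTime"))
#' @rdname accessors
#' @export
setGeneric("survEvent", function(object) standardGeneric("survEvent"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(object) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("clusterParams", function(object) standardGeneric("clusterParams"))
#' @rdname accessors
#' @export
setGeneric("winningLabels", function(object) standardGeneric("winningLabels"))
#' @rdname accessors
#' @export
setGeneric("winningParams", function(object) standardGeneric("winningParams"))
#' @rdname accessors
#' @export
setGeneric("candidateTable", function(object) standardGeneric("candidateTable"))
#' @rdname accessors
#' @export
setGeneric("coefTable", function(object) standardGeneric("coefTable"))
#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setGeneric("designBlocks", function(object) standardGeneric("designBlocks"))
#' @rdname accessors
#' @export
setGeneric("cIndex", function(object) standardGeneric("cIndex"))
#' @rdname accessors
#' @export
setGeneric("modelCode", function(object) standardGeneric("modelCode"))
#' @rdname accessors
#' @export
setGeneric("cohortLayers", function(object) standardGeneric("cohortLayers"))
#' @rdname accessors
#' @export
setGeneric("cohortClinical", function(object) standardGeneric("cohortClinical"))
#' @rdname accessors
#' @export
setGeneric("cohortSurvival", function(object) standardGeneric("cohortSurvival"))
#' @rdname accessors
#' @export
setGeneric("trueSubtype", function(object) standardGeneric("trueSubtype"))
#' @rdname accessors
#' @export
setGeneric("trueLinearPredictor", function(object) standardGeneric("trueLinearPredictor"))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "OmicsMatrix", function(object) rownames(object@values))
#' @rdname accessors
#' @export
setMethod("featureIDs", "OmicsMatrix", function(object) colnames(object@values))
#' @rdname accessors
#' @export
setMethod("omicsValues", "OmicsMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("omicsLayer", "OmicsMatrix", function(object) object@layer)
#' @rdname accessors
#' @export
setMethod("omicsScale", "OmicsMatrix", function(object) object@scale)
#' @rdname accessors
#' @export
setMethod("dim", "OmicsMatrix", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "SurvData", function(object) object@sampleIDs)
#' @rdname accessors
#' @export
setMethod("survTime", "SurvData", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("survEvent", "SurvData", function(object) object@event)
#' @rdname accessors
#' @export
setMethod("length", "SurvData", function(x) length(x@time))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "ClusterLabels", function(object) object@sampleIDs)
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "ClusterLabels", function(object) {
  stats::setNames(object@labels, object@sampleIDs)
})
#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterLabels", function(object) object@k)
#' @rdname accessors
#' @export
setMethod("clusterParams", "ClusterLabels", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("candidateTable", "ClusterSearchResult",
          function(object) object@candidates)
#' @rdname accessors
#' @export
setMethod("winningLabels", "ClusterSearchResult",
          function(object) object@labelSets[[object@winner]])
#' @rdname accessors
#' @export
setMethod("winningParams", "ClusterSearchResult", function(object) {
  cd <- object@candidates[object@winner, , drop = FALSE]
  list(metric = cd$metric, linkage = cd$linkage, k = cd$k, score = cd$score)
})

#' @rdname accessors
#' @export
setMethod("designMatrix", "CoxDesign", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("designBlocks", "CoxDesign", function(object) object@blocks)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "CoxDesign", function(object) object@sampleIDs)

#' @rdname accessors
#' @export
setMethod("coef", "CoxPHFit", function(object) object@beta)
#' @rdname accessors
#' @export
setMethod("vcov", "CoxPHFit", function(object) object@vcov)
#' @rdname accessors
#' @export
setMethod("logLik", "CoxPHFit", function(object) object@loglikFull)

#' Coefficient table of a Cox fit
#'
#' @param object A \linkS4class{CoxPHFit}.
#' @return data.frame with columns covariate, beta, se, hr, ci_low, ci_high,
#'   p (Wald, two-sided).
#' @rdname accessors
#' @export
setMethod("coefTable", "CoxPHFit", function(object) {
  b <- object@beta; s <- object@se
  z <- b / s
  data.frame(covariate = names(b), beta = unname(b), se = unname(s),
             hr = exp(unname(b)),
             ci_low = exp(unname(b) - 1.96 * unname(s)),
             ci_high = exp(unname(b) + 1.96 * unname(s)),
             p = 2 * stats::pnorm(-abs(unname(z))),
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("cIndex", "ConcordanceResult", function(object) object@c)
#' @rdname accessors
#' @export
setMethod("cIndex", "BootstrapCResult", function(object) object@mean)
#' @rdname accessors
#' @export
setMethod("cIndex", "CVConcordance", function(object) object@means)

#' @rdname accessors
#' @export
setMethod("modelCode", "ModelSpec", function(object) object@code)
#' @rdname accessors
#' @export
setMethod("modelCode", "ModelEvaluation", function(object) object@spec@code)

#' @rdname accessors
#' @export
setMethod("cohortLayers", "SyntheticCohort", function(object) object@layers)
#' @rdname accessors
#' @export
setMethod("cohortClinical", "SyntheticCohort", function(object) object@clinical)
#' @rdname accessors
#' @export
setMethod("cohortSurvival", "SyntheticCohort", function(object) object@survival)
#' @rdname accessors
#' @export
setMethod("trueSubtype", "SyntheticCohort", function(object) object@trueSubtype)
#' @rdname accessors
#' @export
setMethod("trueLinearPredictor", "SyntheticCohort",
          function(object) object@trueLinearPredictor)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "SyntheticCohort",
          function(object) object@survival@sampleIDs)
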