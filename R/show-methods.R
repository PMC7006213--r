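#' @name show-methods
#' @title Show methods
#' @description Compact console summaries for SurvCoC objects.
#' @param object Object to display.
#' @keywords internal
NULL

setMethod("show", "OmicsMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("OmicsMatrix: %d samples x %d features [layer=%s, scale=%s]\n",
              d[1], d[2], object@layer, object@scale))
  nna <- sum(is.na(object@values))
  if (nna) cat(sprintf("  %d NA entries (%.2f%%)\n", nna,
                       100 * nna / prod(d)))
})

setMethod("show", "SurvData", function(object) {
  cat(sprintf("SurvData: %d samples, %d events (%.1f%% censored)\n",
              length(object@time), sum(object@event),
              100 * mean(object@event == 0L)))
})

setMethod("show", "ClusterLabels", function(object) {
  p <- object@params
  ptxt <- if (length(p)) sprintf(" [%s/%s/k=%s]", p$metric, p$linkage, p$k)
          else ""
  cat(sprintf("ClusterLabels: %d samples in %d clusters%s; sizes: %s\n",
              length(object@labels), object@k, ptxt,
              paste(tabulate(object@labels, object@k), collapse = ", ")))
})

setMethod("show", "MergeTree", function(object) {
  cat(sprintf("MergeTree: %d leaves, linkage=%s\n", object@nLeaves,
              object@linkage))
})

setMethod("show", "ClusterSearchResult", function(object) {
  cd <- object@candidates
  cat(sprintf("ClusterSearchResult: %d candidates (%d feasible), score=%s\n",
              nrow(cd), sum(cd$feasible), object@scoreType))
  w <- cd[object@winner, ]
  cat(sprintf("  winner: %s / %s / k=%d (score %.4f)\n",
              w$metric, w$linkage, w$k, w$score))
})

setMethod("show", "CoxDesign", function(object) {
  cat(sprintf("CoxDesign: %d samples x %d covariates; blocks: %s\n",
              nrow(object@values), ncol(object@values),
              paste(names(object@blocks), collapse = ", ")))
})

setMethod("show", "CoxPHFit", function(object) {
  cat(sprintf("CoxPHFit: %d covariates, n=%d, events=%d, %s in %d iterations\n",
              length(object@beta), object@n, object@nEvents,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
  cat(sprintf("  log-lik: null %.3f -> full %.3f\n", object@loglikNull,
              object@loglikFull))
  if (length(object@beta)) {
    tb <- coefTable(object)
    print(utils::head(tb, 10), row.names = FALSE, digits = 4)
    if (nrow(tb) > 10) cat(sprintf("  ... %d more rows\n", nrow(tb) - 10))
  }
})

setMethod("show", "ConcordanceResult", function(object) {
  tau <- if (is.null(object@tau)) "" else sprintf(", tau=%g days", object@tau)
  cat(sprintf("ConcordanceResult [%s%s]: C = %.4f (%g usable pairs)\n",
              object@variant, tau, object@c, object@nPairs))
})

setMethod("show", "BootstrapCResult", function(object) {
  cat(sprintf(paste0("BootstrapCResult: apparent C %.4f, bias-corrected ",
                     "%.4f [%.4f, %.4f], B=%d (%d redrawn)\n"),
              object@apparent, object@mean, object@ci95[1], object@ci95[2],
              length(object@values), object@nRedrawn))
})

setMethod("show", "CVConcordance", function(object) {
  cat(sprintf("CVConcordance: %d iterations x %d-fold\n",
              nrow(object@values), object@folds))
  for (j in seq_along(object@taus))
    cat(sprintf("  tau %5g days: mean C = %.4f\n", object@taus[j],
                object@means[j]))
})

setMethod("show", "PHTestResult", function(object) {
  cat("Proportional-hazards test (scaled Schoenfeld residuals):\n")
  print(object@table, digits = 4)
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s\n", object@code))
})

setMethod("show", "ModelEvaluation", function(object) {
  cat(sprintf("ModelEvaluation [%s]\n", object@spec@code))
  cat(sprintf("  bias-corrected Harrell's C: %.4f\n", object@bootstrap@mean))
  for (j in seq_along(object@cv@taus))
    cat(sprintf("  CV Uno's C at %g days: %.4f\n", object@cv@taus[j],
                object@cv@means[j]))
  g <- object@ph@table
  cat(sprintf("  global PH test p: %.4g\n", g$p[nrow(g)]))
})

setMethod("show", "SyntheticCohort", function(object) {
  n <- length(object@survival@time)
  cat(sprintf("SyntheticCohort: %d samples, %d events, %d latent subtypes\n",
              n, sum(object@survival@event),
              length(unique(object@trueSubtype))))
  for (nm in names(object@layers))
    cat(sprintf("  %-12s %d features\n", nm, ncol(object@layers[[nm]]@values)))
})
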