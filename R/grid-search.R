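#' Specify the clustering-parameter grid
#'
#' The full grid crosses the seven distance metrics, the eight linkages and
#' cluster numbers 2--11, with the constraint that every cluster must hold
#' at least \code{minClusterSize} (default 10) patients.
#'
#' @param distances Subset of the seven metrics.
#' @param linkages Subset of the eight linkages.
#' @param kRange Integer vector of cluster numbers (default 2:11).
#' @param minClusterSize Minimal cluster size (default 10).
#' @param minkowskiP Minkowski exponent.
#' @param standardize Z-score features before distances.
#' @return List of class \code{"ClusterGridSpec"}.
#' @export
clusterGridSpec <- function(distances = .distance_metrics,
                            linkages = .linkage_names,
                            kRange = 2:11, minClusterSize = 10L,
                            minkowskiP = 3, standardize = FALSE) {
  distances <- match.arg(distances, .distance_metrics, several.ok = TRUE)
  linkages <- match.arg(linkages, .linkage_names, several.ok = TRUE)
  stopifnot(all(kRange >= 2), minClusterSize >= 1)
  structure(list(distances = distances, linkages = linkages,
                 kRange = as.integer(kRange),
                 minClusterSize = as.integer(minClusterSize),
                 minkowskiP = minkowskiP, standardize = isTRUE(standardize)),
            class = "ClusterGridSpec")
}

#' Evaluation settings for candidate scoring and model evaluation
#'
#' @param B Bootstrap replicates for the final optimism-corrected C.
#' @param searchB Replicates used when scoring grid candidates (cheaper).
#' @param iters Cross-validation iterations.
#' @param folds Cross-validation folds.
#' @param taus Uno horizons in days.
#' @param seed Master seed; all sub-seeds are derived from it.
#' @return List of class \code{"EvalConfig"}.
#' @export
evalConfig <- function(B = 500L, searchB = 100L, iters = 500L, folds = 5L,
                       taus = c(730, 1095, 1825), seed = 1L) {
  structure(list(B = as.integer(B), searchB = as.integer(searchB),
                 iters = as.integer(iters), folds = as.integer(folds),
                 taus = taus, seed = as.integer(seed)),
            class = "EvalConfig")
}

#' Prognosis-driven grid search over clustering parameters
#'
#' For every (metric, linkage, k) candidate the patients are clustered, the
#' candidate is marked infeasible when any cluster holds fewer than
#' \code{minClusterSize} patients or the Cox fit on the dummy-coded cluster
#' label (plus any companion covariates) fails, and feasible candidates are
#' scored by the bias-corrected Harrell's C of that model
#' (\code{\link{optimismCorrectedC}} with \code{searchB} replicates). The
#' winner is the feasible candidate with maximal score; ties go to fewer
#' clusters, then grid order. Each candidate's bootstrap seed is derived
#' from the master seed and the candidate's own parameters, so the winner
#' does not depend on evaluation order.
#'
#' @param x An \linkS4class{OmicsMatrix} or numeric matrix (samples x
#'   features, NA-free).
#' @param survival A \linkS4class{SurvData} in the same sample order.
#' @param companions Optional \linkS4class{CoxDesign} of companion
#'   covariates (e.g. the clinical design) included in the scoring model;
#'   NULL reproduces the literal single-covariate selection.
#' @param grid A \code{\link{clusterGridSpec}}.
#' @param evalCfg An \code{\link{evalConfig}}; \code{searchB} and
#'   \code{seed} are used here.
#' @param labelPrefix Column prefix for the cluster dummy columns.
#' @return A \linkS4class{ClusterSearchResult}.
#' @export
clusterGridSearch <- function(x, survival, companions = NULL,
                              grid = clusterGridSpec(),
                              evalCfg = evalConfig(),
                              labelPrefix = "Omics") {
  v <- if (is(x, "OmicsMatrix")) x@values else as.matrix(x)
  stopifnot(is(survival, "SurvData"),
            identical(nrow(v), length(survival@time)))
  if (!is.null(rownames(v)) &&
      !identical(rownames(v), survival@sampleIDs))
    stop("matrix and survival sample orders differ")

  rows <- list(); labelSets <- list(); idx <- 0L
  for (metric in grid$distances) {
    d <- pairwiseDistance(v, metric, minkowskiP = grid$minkowskiP,
                          standardize = grid$standardize)
    for (linkage in grid$linkages) {
      tree <- hierarchicalCluster(d, linkage)
      for (k in grid$kRange) {
        idx <- idx + 1L
        lab <- cutTreeK(tree, k, params = list(metric = metric,
                                               linkage = linkage, k = k))
        lab@sampleIDs <- survival@sampleIDs
        labelSets[[idx]] <- lab
        sizes <- tabulate(lab@labels, k)
        if (min(sizes) < grid$minClusterSize) {
          rows[[idx]] <- data.frame(metric = metric, linkage = linkage,
                                    k = k, feasible = FALSE, score = NA_real_,
                                    reason = sprintf("cluster of size %d < %d",
                                                     min(sizes),
                                                     grid$minClusterSize))
          next
        }
        des <- clusterDesign(lab, companions = companions,
                             prefix = labelPrefix)
        score <- tryCatch({
          bs <- optimismCorrectedC(
            des, survival, B = evalCfg$searchB,
            seed = deriveSeed(evalCfg$seed,
                              paste("cand", metric, linkage, k, sep = "_")))
          bs@mean
        }, error = function(e) NA_real_)
        if (is.na(score)) {
          rows[[idx]] <- data.frame(metric = metric, linkage = linkage,
                                    k = k, feasible = FALSE,
                                    score = NA_real_,
                                    reason = "Cox fit failed")
        } else {
          rows[[idx]] <- data.frame(metric = metric, linkage = linkage,
                                    k = k, feasible = TRUE, score = score,
                                    reason = "")
        }
      }
    }
  }
  cand <- do.call(rbind, rows)
  if (!any(cand$feasible)) stop("no feasible candidate")
  feas <- which(cand$feasible)
  best <- feas[order(-cand$score[feas], cand$k[feas], feas)][1]
  new("ClusterSearchResult", candidates = cand, labelSets = labelSets,
      winner = as.integer(best),
      scoreType = sprintf("bias-corrected Harrell's C (B=%d)%s",
                          evalCfg$searchB,
                          if (is.null(companions)) ", label-only model"
                          else ", with companion covariates"))
}

#' Binary patient-by-cluster indicator matrix
#'
#' One column per (label set, cluster) pair; the entry is 1 iff the patient
#' carries that cluster label. Every row sums to the number of label sets.
#'
#' @param labelSets Named list of \linkS4class{ClusterLabels} sharing one
#'   sample order; names prefix the columns.
#' @return An \linkS4class{OmicsMatrix} with \code{layer = "cluster_binary"},
#'   \code{scale = "binary"}.
#' @export
oneHotClusterMatrix <- function(labelSets) {
  stopifnot(length(labelSets) >= 1)
  if (is.null(names(labelSets)))
    names(labelSets) <- paste0("set", seq_along(labelSets))
  ids <- labelSets[[1]]@sampleIDs
  for (ls in labelSets)
    if (!identical(ls@sampleIDs, ids))
      stop("label sets differ in sample order")
  cols <- list()
  for (nm in names(labelSets)) {
    ls <- labelSets[[nm]]
    for (j in seq_len(ls@k))
      cols[[sprintf("%s_cluster%d", nm, j)]] <- as.numeric(ls@labels == j)
  }
  v <- do.call(cbind, cols)
  rownames(v) <- ids
  OmicsMatrix(v, layer = "cluster_binary", scale = "binary")
}

#' Cluster-of-clusters integration
#'
#' Runs the prognosis-driven grid search on the binary patient-by-cluster
#' matrix assembled from the per-layer winning label sets; the winner's
#' labels constitute the integrated-omics covariate.
#'
#' @inheritParams clusterGridSearch
#' @param labelSets Named list of per-layer \linkS4class{ClusterLabels}.
#' @return A \linkS4class{ClusterSearchResult}.
#' @export
clusterOfClusters <- function(labelSets, survival, companions = NULL,
                              grid = clusterGridSpec(),
                              evalCfg = evalConfig()) {
  oneHot <- oneHotClusterMatrix(labelSets)
  clusterGridSearch(oneHot, survival, companions = companions, grid = grid,
                    evalCfg = evalCfg, labelPrefix = "A")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Equal-length label vectors.
#' @return Numeric scalar.
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  # degenerate partitions (all-singleton or single-cluster on both sides):
  # identical partitions score 1, anything else 0
  if (mx == expected) return(as.numeric(sij == mx))
  (sij - expected) / (mx - expected)
}
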