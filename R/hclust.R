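#' Agglomerative hierarchical clustering via Lance--Williams updates
#'
#' Builds the merge tree for any of the eight conventional linkages:
#' ward_d (Ward on the supplied distances as-is), ward_d2 (Ward on squared
#' distances, heights square-rooted back), single, complete, average
#' (UPGMA), mcquitty (WPGMA), median (WPGMC) and centroid (UPGMC); the last
#' two operate on squared-euclidean semantics and may produce height
#' inversions, which are tolerated because \code{\link{cutTreeK}} cuts by
#' merge count, not height. Ties in the minimal inter-cluster distance are
#' broken by the lexicographically smallest pair of cluster indices in
#' creation order (leaves first, in input order, then merge steps), making
#' the procedure fully deterministic.
#'
#' @param d A \code{\link[stats]{dist}} or symmetric distance matrix.
#' @param linkage One of \code{"ward_d"}, \code{"ward_d2"}, \code{"single"},
#'   \code{"complete"}, \code{"average"}, \code{"mcquitty"},
#'   \code{"median"}, \code{"centroid"}.
#' @return A \linkS4class{MergeTree}.
#' @export
#' @examples
#' d <- dist(c(a = 0, b = 1, c = 10))
#' tr <- hierarchicalCluster(d, "single")
#' tr@height  # 1, 9
hierarchicalCluster <- function(d, linkage = "average") {
  linkage <- match.arg(linkage, .linkage_names)
  D <- as.matrix(d)
  n <- nrow(D)
  stopifnot(n >= 1, isTRUE(all.equal(D, t(D))), all(diag(D) == 0))
  labs <- rownames(D)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  squared <- linkage %in% c("ward_d2", "median", "centroid")
  if (squared) D <- D^2
  if (n == 1L)
    return(new("MergeTree", nLeaves = 1L,
               merge = matrix(integer(), 0, 2), height = numeric(),
               labels = labs, linkage = linkage))

  code <- -seq_len(n)       # hclust codes of active clusters
  size <- rep(1L, n)
  active <- seq_len(n)      # columns of D currently in play, creation order
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(D) <- Inf

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    Da <- D[active, active, drop = FALSE]
    Da[lower.tri(Da, diag = TRUE)] <- Inf
    minval <- min(Da)
    ties <- which(Da == minval, arr.ind = TRUE)
    # lexicographically smallest (row, col) in creation order
    pick <- ties[order(ties[, 1], ties[, 2])[1], ]
    a <- pick[1]; b <- pick[2]          # positions within `active`, a < b
    ia <- active[a]; ib <- active[b]
    na <- size[ia]; nb <- size[ib]
    dab <- D[ia, ib]

    merge[step, ] <- sort(c(code[ia], code[ib]))
    height[step] <- if (squared) sqrt(max(dab, 0)) else dab

    others <- active[-c(a, b)]
    if (length(others)) {
      dak <- D[ia, others]; dbk <- D[ib, others]
      nk <- size[others]
      dnew <- switch(linkage,
        single   = pmin(dak, dbk),
        complete = pmax(dak, dbk),
        average  = (na * dak + nb * dbk) / (na + nb),
        mcquitty = (dak + dbk) / 2,
        ward_d   = ,
        ward_d2  = ((na + nk) * dak + (nb + nk) * dbk - nk * dab) /
                     (na + nb + nk),
        centroid = (na * dak + nb * dbk) / (na + nb) -
                     na * nb * dab / (na + nb)^2,
        median   = dak / 2 + dbk / 2 - dab / 4)
      # reuse slot ia for the merged cluster, drop ib
      D[ia, others] <- dnew
      D[others, ia] <- dnew
    }
    size[ia] <- na + nb
    code[ia] <- step
    # the merged cluster is the youngest: append it to the creation order
    active <- c(active[-c(a, b)], ia)
  }
  new("MergeTree", nLeaves = as.integer(n), merge = merge, height = height,
      labels = labs, linkage = linkage)
}

#' Cut a merge tree into k clusters
#'
#' Returns the partition present after \code{nLeaves - k} merges,
#' renumbered \code{1..k} by order of first sample appearance. Cutting by
#' merge count keeps the partitions nested in k and tolerates height
#' inversions of median/centroid linkage.
#'
#' @param tree A \linkS4class{MergeTree}.
#' @param k Number of clusters, \code{1 <= k <= nLeaves}.
#' @param params Optional list of generating parameters to record on the
#'   result.
#' @return A \linkS4class{ClusterLabels}.
#' @export
cutTreeK <- function(tree, k, params = list()) {
  stopifnot(is(tree, "MergeTree"))
  n <- tree@nLeaves
  if (k < 1 || k > n) stop("k must lie in [1, nLeaves]")
  grp <- -seq_len(n)                     # cluster code per sample
  nm <- n - k
  if (nm > 0) {
    members <- vector("list", nm)
    for (s in seq_len(nm)) {
      kids <- tree@merge[s, ]
      idx <- unlist(lapply(kids, function(cd) {
        if (cd < 0) -cd else members[[cd]]
      }))
      members[[s]] <- idx
      grp[idx] <- s
    }
  }
  labels <- match(grp, unique(grp))
  new("ClusterLabels", labels = as.integer(labels), k = as.integer(k),
      params = params, sampleIDs = tree@labels)
}
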