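.distance_metrics <- c("euclidean", "maximum", "manhattan", "canberra",
                       "binary", "minkowski", "correlation")
.linkage_names <- c("ward_d", "ward_d2", "single", "complete", "average",
                    "mcquitty", "median", "centroid")

#' Pairwise sample distances
#'
#' Computes the symmetric sample-by-sample distance matrix under one of the
#' seven supported metrics: euclidean, maximum, manhattan, canberra
#' (zero/zero terms contribute 0), binary (fraction of discordant positions
#' among positions where at least one value is nonzero), minkowski with
#' exponent \code{minkowskiP}, and correlation (1 - Pearson r). Euclidean,
#' maximum, manhattan, binary and minkowski are delegated to
#' \code{\link[stats]{dist}}, whose definitions match exactly; canberra is
#' computed in-package, with \eqn{|x| + |y|} in the denominator and 0/0
#' terms contributing zero (\code{stats::dist} instead rescales the sum
#' for omitted terms).
#'
#' @param x An \linkS4class{OmicsMatrix} or numeric samples-by-features
#'   matrix with no NA entries (impute or filter upstream).
#' @param metric Metric name.
#' @param minkowskiP Minkowski exponent (> 0); default 3 so the metric is
#'   distinct from euclidean.
#' @param standardize If TRUE features are z-scored before the distance
#'   computation (zero-variance features are left centred only).
#' @return A \code{\link[stats]{dist}} object.
#' @export
#' @examples
#' m <- matrix(c(0, 3, 4, 0, 0, 0), 2, 3, byrow = TRUE,
#'             dimnames = list(c("a", "b"), NULL))
#' as.matrix(pairwiseDistance(m, "canberra"))["a", "b"]  # 2
pairwiseDistance <- function(x, metric = "euclidean", minkowskiP = 3,
                             standardize = FALSE) {
  metric <- match.arg(metric, .distance_metrics)
  v <- if (is(x, "OmicsMatrix")) x@values else as.matrix(x)
  if (anyNA(v)) stop("distance computation requires NA-free input; ",
                     "impute or filter upstream")
  if (standardize) {
    sds <- apply(v, 2, stats::sd)
    v <- scale(v, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  if (metric == "correlation") {
    rsd <- apply(v, 1, stats::sd)
    if (any(rsd == 0))
      stop("correlation distance undefined for zero-variance sample(s): ",
           paste(rownames(v)[rsd == 0], collapse = ", "))
    d <- 1 - stats::cor(t(v))
    return(stats::as.dist(d))
  }
  if (metric == "canberra") {
    # sum |x-y| / (|x| + |y|) with 0/0 terms contributing 0 -- note this is
    # not stats::dist's canberra, which rescales for omitted terms and uses
    # |x + y| in the denominator
    n <- nrow(v)
    D <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
    for (i in seq_len(max(n - 1L, 0L))) {
      rest <- v[(i + 1):n, , drop = FALSE]
      num <- abs(sweep(rest, 2, v[i, ]))
      den <- abs(rest) + matrix(abs(v[i, ]), nrow(rest), ncol(v),
                                byrow = TRUE)
      term <- num / den
      term[den == 0] <- 0
      D[i, (i + 1):n] <- rowSums(term)
    }
    return(stats::as.dist(t(D)))
  }
  if (metric == "minkowski") {
    stopifnot(minkowskiP > 0)
    return(stats::dist(v, method = "minkowski", p = minkowskiP))
  }
  stats::dist(v, method = metric)
}
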