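#' Remove low-quality features
#'
#' Drops every feature whose count of bad entries exceeds
#' \code{maxBadFrac} of the samples, keeping the boundary case (a feature
#' with exactly 5\% bad values survives the default filter). For beta-scale
#' methylation data only NA counts as bad -- a beta value of exactly 0 is a
#' valid measurement -- while for all other scales both NA and exact 0
#' count.
#'
#' @param x An \linkS4class{OmicsMatrix}.
#' @param maxBadFrac Maximal tolerated bad fraction (default 0.05).
#' @return The filtered \linkS4class{OmicsMatrix} (pure column selection;
#'   surviving values and the sample order are untouched).
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2, 3, 4, 5), 3, 2,
#'             dimnames = list(paste0("s", 1:3), c("a", "b")))
#' filterLowQuality(OmicsMatrix(m, "expression", "fpkm"), maxBadFrac = 0.2)
filterLowQuality <- function(x, maxBadFrac = 0.05) {
  stopifnot(is(x, "OmicsMatrix"), nrow(x@values) > 0, ncol(x@values) > 0)
  v <- x@values
  bad <- is.na(v)
  if (!identical(x@scale, "beta")) bad <- bad | (!is.na(v) & v == 0)
  frac <- colSums(bad) / nrow(v)
  keep <- frac <= maxBadFrac
  if (!any(keep)) stop("no features survive the quality filter")
  out <- x
  out@values <- v[, keep, drop = FALSE]
  out
}

#' Per-feature coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) over the non-NA entries of
#' each feature divided by their mean. Features with zero mean get NA and
#' are ranked last by \code{\link{selectFeatures}}.
#'
#' @param x An \linkS4class{OmicsMatrix}; every feature needs at least two
#'   non-NA values.
#' @return Named numeric vector of CVs.
#' @export
featureCV <- function(x) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- x@values
  nOK <- colSums(!is.na(v))
  if (any(nOK < 2))
    stop("features with fewer than 2 non-NA values: ",
         paste(colnames(v)[nOK < 2], collapse = ", "))
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2, stats::sd, na.rm = TRUE)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu)
  stats::setNames(cv, colnames(v))
}

#' Select features by variability and prior knowledge
#'
#' Keeps the union of (a) the features ranked in the top
#' \code{ceiling(topFrac * n_features)} by coefficient of variation, ties
#' broken lexicographically by feature id, and (b) prior-knowledge features
#' present in the matrix. Original column order is preserved.
#'
#' @param x A quality-filtered \linkS4class{OmicsMatrix}.
#' @param topFrac Fraction of features kept by CV rank (default 0.25).
#' @param prior Character vector of prior feature ids (optional).
#' @return The reduced \linkS4class{OmicsMatrix}.
#' @export
selectFeatures <- function(x, topFrac = 0.25, prior = NULL) {
  stopifnot(is(x, "OmicsMatrix"), topFrac > 0, topFrac <= 1)
  feats <- colnames(x@values)
  cv <- featureCV(x)
  nKeep <- ceiling(topFrac * length(feats))
  ord <- order(-ifelse(is.na(cv), -Inf, cv), feats)  # NA CV ranks last
  top <- feats[ord][seq_len(nKeep)]
  prior <- unique(as.character(prior))
  missing <- setdiff(prior, feats)
  if (length(missing))
    warning(sprintf("%d prior feature(s) absent from the matrix: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")))
  keep <- feats %in% union(top, intersect(prior, feats))
  out <- x
  out@values <- x@values[, keep, drop = FALSE]
  out
}

#' Aggregate methylation probes to gene-level beta values
#'
#' Probes on excluded chromosomes (X and Y by default) are dropped first,
#' then probes with more than \code{maxNAFrac} NA values; the gene-level
#' beta value of a sample is the arithmetic mean of its non-NA beta values
#' over the gene's remaining probes. Genes left without probes are absent
#' from the output. Probes not covered by the map are dropped with a
#' warning.
#'
#' @param x A beta-scale \linkS4class{OmicsMatrix} of probes.
#' @param map data.frame with columns \code{probe}, \code{gene},
#'   \code{chromosome}; each probe maps to one (gene, chromosome) pair.
#' @param excludedChrom Chromosomes whose probes are removed.
#' @param maxNAFrac Maximal tolerated NA fraction per probe.
#' @return A gene-level beta \linkS4class{OmicsMatrix}; genes appear in
#'   order of their first surviving probe.
#' @export
aggregateProbesToGenes <- function(x, map, excludedChrom = c("X", "Y"),
                                   maxNAFrac = 0.05) {
  stopifnot(is(x, "OmicsMatrix"), identical(x@scale, "beta"),
            all(c("probe", "gene", "chromosome") %in% names(map)))
  if (anyDuplicated(map$probe))
    stop("each probe must map to at most one (gene, chromosome) pair")
  probes <- colnames(x@values)
  covered <- intersect(probes, map$probe)
  if (!length(covered)) stop("the probe-gene map covers none of the probes")
  if (length(covered) < length(probes))
    warning(sprintf("%d unmapped probe(s) dropped",
                    length(probes) - length(covered)))
  rownames(map) <- map$probe
  chrom <- map[covered, "chromosome"]
  covered <- covered[!chrom %in% excludedChrom]
  naFrac <- colSums(is.na(x@values[, covered, drop = FALSE])) / nrow(x@values)
  covered <- covered[naFrac <= maxNAFrac]
  if (!length(covered))
    stop("no probes survive the chromosome and NA filters")
  genes <- map[covered, "gene"]
  ug <- unique(genes)
  v <- x@values[, covered, drop = FALSE]
  out <- matrix(NA_real_, nrow(v), length(ug),
                dimnames = list(rownames(v), ug))
  for (g in ug) {
    sub <- v[, genes == g, drop = FALSE]
    out[, g] <- rowMeans(sub, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  OmicsMatrix(out, layer = "methylation", scale = "beta")
}

#' Impute remaining NA entries by the per-feature median
#'
#' Distance computation requires complete data; after the 5\% quality
#' filter at most a twentieth of any feature is missing, and those entries
#' are replaced by the feature's median over observed samples.
#'
#' @param x An \linkS4class{OmicsMatrix}.
#' @return The completed \linkS4class{OmicsMatrix}.
#' @export
imputeMedian <- function(x) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- x@values
  nas <- which(colSums(is.na(v)) > 0)
  for (j in nas) {
    med <- stats::median(v[, j], na.rm = TRUE)
    v[is.na(v[, j]), j] <- med
  }
  out <- x
  out@values <- v
  out
}
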