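#' Read and write delimited omics matrices
#'
#' Matrices are stored as tab-delimited text with samples as rows, a
#' leading \code{sample_id} column and a header row of feature
#' identifiers. \code{NA} is written as the literal string \code{NA};
#' numbers carry 10 significant digits so a write/read round trip is
#' lossless at working precision. Transposed files (features as rows) are
#' supported through \code{transposed = TRUE}.
#'
#' @param x An \linkS4class{OmicsMatrix}.
#' @param path File path.
#' @param layer,scale Tags for the matrix being read.
#' @param transposed If TRUE the file stores features as rows.
#' @param sep Field separator.
#' @return \code{readOmicsMatrix} returns an \linkS4class{OmicsMatrix};
#'   \code{writeOmicsMatrix} returns \code{path} invisibly.
#' @export
writeOmicsMatrix <- function(x, path, sep = "\t") {
  stopifnot(is(x, "OmicsMatrix"))
  v <- x@values
  out <- data.frame(sample_id = rownames(v),
                    signif(v, 10),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeOmicsMatrix
#' @export
readOmicsMatrix <- function(path, layer, scale, transposed = FALSE,
                            sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  ids <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  mode(v) <- "numeric"
  rownames(v) <- ids
  if (transposed) v <- t(v)
  OmicsMatrix(v, layer = layer, scale = scale)
}

#' Read a prior-knowledge feature list
#'
#' One identifier per line; blank lines and duplicates are dropped.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
readPriorList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Read a probe-to-gene map
#'
#' Three-column delimited text: probe, gene, chromosome.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return data.frame with columns \code{probe}, \code{gene},
#'   \code{chromosome}.
#' @export
readProbeGeneMap <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "gene", "chromosome") %in% names(df)))
  df
}

#' Read a clinical table with survival columns
#'
#' Expects columns \code{sample_id, t_stage, n_stage, m_stage, age_years,
#' time_days, event}; stage levels outside the supported closed sets
#' (e.g. Tis, N1c, Mx) must be excluded upstream.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return List with elements \code{clinical} (data.frame) and
#'   \code{survival} (\linkS4class{SurvData}).
#' @export
readClinicalTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "t_stage", "n_stage", "m_stage", "age_years",
            "time_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (f in c("t", "n", "m")) {
    col <- paste0(f, "_stage")
    bad <- setdiff(unique(df[[col]]), .stage_levels[[f]])
    if (length(bad))
      stop(sprintf("unsupported %s levels: %s", col,
                   paste(bad, collapse = ", ")))
    df[[col]] <- factor(df[[col]], levels = .stage_levels[[f]])
  }
  surv <- SurvData(df$time_days, df$event, df$sample_id)
  list(clinical = df[, c("sample_id", "t_stage", "n_stage", "m_stage",
                         "age_years")],
       survival = surv)
}

#' Write cluster labels as a two-column file
#'
#' @param labels A \linkS4class{ClusterLabels}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
writeClusterLabels <- function(labels, path) {
  stopifnot(is(labels, "ClusterLabels"))
  utils::write.table(
    data.frame(sample_id = labels@sampleIDs, label = labels@labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a candidate table of a cluster-parameter search
#'
#' @param result A \linkS4class{ClusterSearchResult}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
writeCandidateTable <- function(result, path) {
  stopifnot(is(result, "ClusterSearchResult"))
  cd <- result@candidates
  cd$winner <- seq_len(nrow(cd)) == result@winner
  cd$score <- ifelse(is.na(cd$score), NA, signif(cd$score, 10))
  utils::write.table(cd, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
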