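#' Treatment-code clinical covariates and cluster labels
#'
#' Builds the dummy-coded design used throughout the package: T stage
#' against reference T1, N stage against N0, M stage against M0, age binned
#' into four quartile-based left-closed right-open intervals (reference:
#' youngest bin), and each supplied cluster-label covariate against its
#' cluster 1. With the five T, five N and two M levels plus four age bins a
#' clinical-only design has 4 + 4 + 1 + 3 = 12 columns.
#'
#' @param clinical data.frame with columns \code{t_stage}, \code{n_stage},
#'   \code{m_stage} (factors or characters over the supported closed level
#'   sets) and \code{age_years}.
#' @param clusters Named list of \linkS4class{ClusterLabels}; the names
#'   (e.g. \code{"G"}, \code{"M"}, \code{"m"}, \code{"A"}) prefix the
#'   design columns, and each list entry contributes \code{k - 1} columns.
#' @param ageBreaks Optional numeric cutpoints for the age bins; by default
#'   the empirical quartiles of \code{age_years}.
#' @return A \linkS4class{CoxDesign}. An error is raised when any
#'   non-reference level has zero samples, since its column would be
#'   identically zero.
#' @export
encodeCovariates <- function(clinical, clusters = list(), ageBreaks = NULL) {
  n <- nrow(clinical)
  ids <- if (!is.null(clinical$sample_id)) as.character(clinical$sample_id)
         else as.character(seq_len(n))
  cols <- list(); blocks <- list(); refs <- c()

  addFactor <- function(x, levels, block, colNames) {
    x <- factor(as.character(x), levels = levels)
    if (anyNA(x)) stop(sprintf("unsupported level in block %s", block))
    cnt <- table(x)
    if (any(cnt == 0))
      stop(sprintf("level(s) %s of block %s have zero samples; the design %s",
                   paste(names(cnt)[cnt == 0], collapse = ", "), block,
                   "column would be all-zero"))
    for (j in seq_along(levels)[-1]) {
      cols[[colNames[j - 1]]] <<- as.numeric(x == levels[j])
    }
    blocks[[block]] <<- colNames
    refs[block] <<- levels[1]
  }

  addFactor(clinical$t_stage, .stage_levels$t, "T_stage", .stage_levels$t[-1])
  addFactor(clinical$n_stage, .stage_levels$n, "N_stage", .stage_levels$n[-1])
  addFactor(clinical$m_stage, .stage_levels$m, "M_stage", .stage_levels$m[-1])

  age <- clinical$age_years
  if (is.null(ageBreaks))
    ageBreaks <- unname(stats::quantile(age, probs = seq(0, 1, 0.25)))
  if (length(ageBreaks) != 5) stop("ageBreaks must give 4 bins (5 cutpoints)")
  bin <- cut(age, breaks = ageBreaks, right = FALSE, include.lowest = TRUE)
  # make the top cutpoint inclusive
  bin[age >= ageBreaks[5]] <- levels(bin)[4]
  binNames <- sprintf("Age[%g,%g)", ageBreaks[1:4], ageBreaks[2:5])
  binNames[4] <- sprintf("Age[%g,%g]", ageBreaks[4], ageBreaks[5])
  levels(bin) <- binNames
  addFactor(bin, binNames, "Age", binNames[-1])

  for (nm in names(clusters)) {
    lab <- clusters[[nm]]
    stopifnot(is(lab, "ClusterLabels"))
    if (!identical(lab@sampleIDs, ids))
      stop(sprintf("cluster labels '%s' are not in the design sample order",
                   nm))
    k <- lab@k
    lv <- paste0("Cluster", seq_len(k))
    addFactor(paste0("Cluster", lab@labels), lv, nm,
              paste0(nm, ".", lv[-1]))
  }

  v <- do.call(cbind, cols)
  colnames(v) <- names(cols)
  rownames(v) <- ids
  des <- new("CoxDesign", values = v, referenceLevels = refs,
             blocks = blocks, sampleIDs = ids)
  attr(des@values, "ageBreaks") <- ageBreaks
  des
}

#' Dummy-code a single cluster-label covariate
#'
#' Convenience wrapper used by the grid search when scoring a label-only
#' model: returns the \code{k - 1} treatment-coded columns (cluster 1 as
#' reference) as a \linkS4class{CoxDesign}, optionally appended to
#' companion covariates.
#'
#' @param labels A \linkS4class{ClusterLabels}.
#' @param companions Optional \linkS4class{CoxDesign} with the same sample
#'   order.
#' @param prefix Column prefix.
#' @return A \linkS4class{CoxDesign}.
#' @export
clusterDesign <- function(labels, companions = NULL, prefix = "Omics") {
  stopifnot(is(labels, "ClusterLabels"))
  k <- labels@k
  v <- matrix(0, length(labels@labels), max(k - 1L, 0L))
  if (k > 1L) {
    for (j in 2:k) v[, j - 1] <- as.numeric(labels@labels == j)
    colnames(v) <- paste0(prefix, ".Cluster", 2:k)
  } else colnames(v) <- character()
  rownames(v) <- labels@sampleIDs
  blocks <- stats::setNames(list(colnames(v)), prefix)
  if (!is.null(companions)) {
    stopifnot(is(companions, "CoxDesign"))
    if (!identical(companions@sampleIDs, labels@sampleIDs))
      stop("companion design and labels differ in sample order")
    v <- cbind(companions@values, v)
    blocks <- c(companions@blocks, blocks)
  }
  new("CoxDesign", values = v,
      referenceLevels = c(if (!is.null(companions))
        companions@referenceLevels, stats::setNames("Cluster1", prefix)),
      blocks = blocks, sampleIDs = labels@sampleIDs)
}

#' Restrict a design to a subset of columns
#'
#' @param design A \linkS4class{CoxDesign}.
#' @param dropBlocks Character vector of block names to remove.
#' @return A \linkS4class{CoxDesign}.
#' @export
dropDesignBlocks <- function(design, dropBlocks) {
  stopifnot(is(design, "CoxDesign"))
  keepB <- setdiff(names(design@blocks), dropBlocks)
  cols <- unlist(design@blocks[keepB], use.names = FALSE)
  new("CoxDesign", values = design@values[, cols, drop = FALSE],
      referenceLevels = design@referenceLevels[
        names(design@referenceLevels) %in% keepB],
      blocks = design@blocks[keepB], sampleIDs = design@sampleIDs)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Efron-tie-corrected Cox partial likelihood by
#' Newton--Raphson with step-halving, declaring convergence when the log
#' partial likelihood changes by less than \code{tol} (default 1e-9) or
#' after \code{maxIter} iterations. Standard errors come from the inverse
#' observed information. Degenerate designs (constant columns, singular
#' information, runaway coefficients) yield \code{converged = FALSE} with a
#' diagnostic message instead of an error, so callers such as the
#' cluster-parameter grid search can treat them as infeasible candidates.
#' Linearly dependent covariates -- which arise when two omics layers
#' recover the same patient partition -- are aliased: the dependent columns
#' are dropped (pivoted QR) and named in the fit's \code{message}.
#'
#' @param design A \linkS4class{CoxDesign} or plain numeric design matrix
#'   with column names.
#' @param survival A \linkS4class{SurvData} with at least one event.
#' @param tol Convergence tolerance on the log partial likelihood.
#' @param maxIter Maximal Newton iterations.
#' @return A \linkS4class{CoxPHFit}.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
#' sv <- SurvData(rexp(100, exp(0.5 * x[, 1])), rep(1L, 100))
#' fitCox(x, sv)
fitCox <- function(design, survival, tol = 1e-9, maxIter = 50L) {
  X <- if (is(design, "CoxDesign")) design@values else as.matrix(design)
  stopifnot(is(survival, "SurvData"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n != length(survival@time))
    stop("design and survival differ in sample count")
  if (sum(survival@event) < 1L) stop("at least one event is required")

  p <- ncol(X)
  bad <- function(msg, ll0 = NA_real_) {
    new("CoxPHFit", beta = stats::setNames(rep(NA_real_, p), colnames(X)),
        se = rep(NA_real_, p), vcov = matrix(NA_real_, p, p),
        loglikNull = ll0, loglikFull = NA_real_,
        score0 = rep(NA_real_, p), info0 = matrix(NA_real_, p, p),
        nEvents = sum(survival@event), n = as.integer(n),
        converged = FALSE, iterations = 0L, logLikTrace = numeric(),
        linearPredictor = rep(NA_real_, n), message = msg)
  }
  if (p == 0L) return(bad("empty design"))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    return(bad(paste("constant column(s):",
                     paste(colnames(X)[sds == 0], collapse = ", "))))
  # linearly dependent columns (e.g. two layers recovering the same
  # partition) are aliased and dropped, as lm/coxph treat collinearity
  dropped <- character()
  qx <- qr(sweep(X, 2, colMeans(X)))
  if (qx$rank < p) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
    p <- ncol(X)
  }

  ord <- order(survival@time)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)[ord, , drop = FALSE]
  tt <- survival@time[ord]
  ev <- survival@event[ord]

  beta <- rep(0, p)
  st <- .cox_efron_stats(Xc, tt, ev, beta)
  ll0 <- st$loglik
  score0 <- as.numeric(st$score)
  info0 <- st$info
  ll <- ll0
  trace <- ll
  iter <- 0L
  converged <- FALSE
  msg <- ""
  ridgeSolve <- function(A, b = NULL) {
    # plain solve, falling back to a tiny ridge for near-singular
    # information (heavily overlapping indicator columns in resamples)
    out <- tryCatch(if (is.null(b)) solve(A) else solve(A, b),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
    eps <- 1e-8 * mean(diag(A)) + 1e-12
    tryCatch(if (is.null(b)) solve(A + diag(eps, nrow(A)))
             else solve(A + diag(eps, nrow(A)), b),
             error = function(e) NULL)
  }
  repeat {
    iter <- iter + 1L
    step <- ridgeSolve(st$info, st$score)
    if (is.null(step)) { msg <- "singular information"; break }
    stepSize <- 1
    repeat {
      cand <- beta + stepSize * as.numeric(step)
      stC <- .cox_efron_stats(Xc, tt, ev, cand)
      if (is.finite(stC$loglik) && stC$loglik >= ll - 1e-12) break
      stepSize <- stepSize / 2
      if (stepSize < 1e-10) break
    }
    if (!is.finite(stC$loglik) || stC$loglik < ll - 1e-12) {
      msg <- "step-halving failed"; break
    }
    beta <- cand
    delta <- stC$loglik - ll
    ll <- stC$loglik
    st <- stC
    trace <- c(trace, ll)
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxIter) { msg <- "iteration limit reached"; break }
  }
  # monotone likelihood (e.g. a covariate level without events) plateaus
  # with large finite coefficients; like coxph, the fit is reported as
  # converged once the log-likelihood is stationary, with a note
  if (converged && max(abs(beta)) > 15)
    msg <- "coefficient(s) may be unbounded (monotone likelihood)"

  V <- ridgeSolve(st$info)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) <= 0)) {
    converged <- FALSE
    if (msg == "") msg <- "singular information at the optimum"
    V <- matrix(NA_real_, p, p)
  }
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  lp <- as.numeric(X %*% beta)
  if (length(dropped))
    msg <- paste0(msg, if (nzchar(msg)) "; ",
                  "aliased column(s) dropped: ",
                  paste(dropped, collapse = ", "))
  new("CoxPHFit", beta = beta,
      se = stats::setNames(sqrt(diag(V)), colnames(X)), vcov = V,
      loglikNull = ll0, loglikFull = ll,
      score0 = stats::setNames(score0, colnames(X)), info0 = info0,
      nEvents = sum(ev), n = as.integer(n),
      converged = converged, iterations = iter, logLikTrace = trace,
      linearPredictor = lp, message = msg)
}

#' Linear predictor of a Cox fit on (new) data
#'
#' @param fit A \linkS4class{CoxPHFit}.
#' @param design A \linkS4class{CoxDesign} or matrix with the fit's columns.
#' @return Numeric linear predictor.
#' @export
coxLinearPredictor <- function(fit, design) {
  X <- if (is(design, "CoxDesign")) design@values else as.matrix(design)
  if (!all(names(fit@beta) %in% colnames(X)))
    stop("design lacks fitted covariate columns")
  as.numeric(X[, names(fit@beta), drop = FALSE] %*% fit@beta)
}
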