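#' Proportional-hazards assumption test
#'
#' Score test for time-varying coefficients on Schoenfeld residuals against
#' the Kaplan--Meier-transformed time scale \eqn{g(t) = 1 - \hat S_{KM}(t)}.
#' With Schoenfeld residuals \eqn{s_k} and Efron-averaged risk-set variance
#' matrices \eqn{V_k} at the event times, and \eqn{g_k} centred at the mean
#' over events, the global statistic is
#' \deqn{T = u' \left(\textstyle\sum_k g_k^2 V_k -
#'   \left(\sum_k g_k V_k\right)\left(\sum_k V_k\right)^{-1}
#'   \left(\sum_k g_k V_k\right)\right)^{-1} u, \qquad
#'   u = \sum_k g_k s_k,}
#' chi-square with p degrees of freedom under proportional hazards (the
#' score test of adding \eqn{x\,g(t)} interactions); per-covariate
#' statistics use the corresponding diagonal element. A p-value above 0.05
#' indicates no evidence of a time-varying coefficient.
#'
#' @param fit A converged \linkS4class{CoxPHFit}.
#' @param design The design the fit was computed on.
#' @param survival The matching \linkS4class{SurvData}.
#' @return A \linkS4class{PHTestResult}.
#' @export
phTest <- function(fit, design, survival) {
  stopifnot(is(fit, "CoxPHFit"), fit@converged, is(survival, "SurvData"))
  if (sum(survival@event) == 0L) stop("no events")
  X <- if (is(design, "CoxDesign")) design@values else as.matrix(design)
  if (!is.null(names(fit@beta)) && !is.null(colnames(X)))
    X <- X[, names(fit@beta), drop = FALSE]  # respect aliased-column drops
  p <- ncol(X)
  ord <- order(survival@time)
  Xo <- sweep(X, 2, colMeans(X))[ord, , drop = FALSE]
  tt <- survival@time[ord]
  ev <- survival@event[ord]
  sch <- .cox_schoenfeld(Xo, tt, ev, unname(fit@beta))
  S <- sch$residuals
  d <- nrow(S)
  km <- kmEstimate(survival@time, survival@event)
  g <- 1 - kmEval(km, sch$time)
  g <- g - mean(g)
  A <- matrix(0, p, p); B <- matrix(0, p, p); C <- matrix(0, p, p)
  for (k in seq_len(d)) {
    Vk <- sch$vmat[, , k, drop = TRUE]
    if (p == 1L) Vk <- matrix(Vk, 1, 1)
    A <- A + Vk
    B <- B + g[k] * Vk
    C <- C + g[k]^2 * Vk
  }
  W <- C - B %*% tryCatch(solve(A, B), error = function(e)
    stop("singular information in PH test"))
  u <- as.numeric(crossprod(g, S))           # sum_k g_k s_k, length p
  Winv <- tryCatch(solve(W), error = function(e)
    stop("singular variance in PH test"))
  global <- as.numeric(t(u) %*% Winv %*% u)
  perCov <- u^2 / diag(W)
  tab <- data.frame(
    covariate = c(colnames(X), "GLOBAL"),
    chisq = c(perCov, global),
    df = c(rep(1L, p), p),
    p = c(stats::pchisq(perCov, 1, lower.tail = FALSE),
          stats::pchisq(global, p, lower.tail = FALSE)),
    stringsAsFactors = FALSE)
  new("PHTestResult", table = tab)
}

#' Global likelihood-ratio, score and Wald tests of a Cox fit
#'
#' All three test the full coefficient vector against zero on
#' \code{length(beta)} degrees of freedom: LRT
#' \eqn{2(\ell_{full} - \ell_0)}, the score test
#' \eqn{U_0' I_0^{-1} U_0} evaluated at \eqn{\beta = 0} (equal to the
#' log-rank statistic for a single binary covariate), and the Wald test
#' \eqn{\hat\beta' \hat\Sigma^{-1} \hat\beta}.
#'
#' @param fit A converged \linkS4class{CoxPHFit}.
#' @return Named list with elements \code{lrt}, \code{score}, \code{wald},
#'   each a list \code{(statistic, df, p)}.
#' @export
modelTests <- function(fit) {
  stopifnot(is(fit, "CoxPHFit"), fit@converged)
  p <- length(fit@beta)
  lrt <- max(0, 2 * (fit@loglikFull - fit@loglikNull))
  score <- as.numeric(t(fit@score0) %*% solve(fit@info0) %*% fit@score0)
  wald <- as.numeric(t(fit@beta) %*% solve(fit@vcov) %*% fit@beta)
  mk <- function(s) list(statistic = s, df = p,
                         p = stats::pchisq(s, p, lower.tail = FALSE))
  list(lrt = mk(lrt), score = mk(score), wald = mk(wald))
}

#' Likelihood-ratio test between nested Cox models
#'
#' The reduced model's covariates must be a subset of the full model's
#' (checked by column name) and both must be fitted on the same samples.
#' The statistic \eqn{2(\ell_{full} - \ell_{reduced})}, floored at zero,
#' is compared to a chi-square with df = the column-count difference.
#'
#' @param full,reduced Converged \linkS4class{CoxPHFit} objects.
#' @return List \code{(statistic, df, p)}.
#' @export
lrtNested <- function(full, reduced) {
  stopifnot(is(full, "CoxPHFit"), is(reduced, "CoxPHFit"),
            full@converged, reduced@converged)
  if (!all(names(reduced@beta) %in% names(full@beta)))
    stop("models are not nested: reduced covariates must be a subset")
  if (full@n != reduced@n)
    stop("models are not fitted on the same samples")
  df <- length(full@beta) - length(reduced@beta)
  stat <- max(0, 2 * (full@loglikFull - reduced@loglikFull))
  list(statistic = stat, df = df,
       p = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

# Nested LRT judged on fitted ranks: used when designs are nested by
# construction but aliasing may have dropped different columns in the two
# fits (e.g. perfectly collinear omics layers).
.lrtNestedRank <- function(full, reduced) {
  df <- length(full@beta) - length(reduced@beta)
  stat <- max(0, 2 * (full@loglikFull - reduced@loglikFull))
  list(statistic = stat, df = df,
       p = if (df <= 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Paired Wilcoxon signed-rank test with Pratt's zero handling
#'
#' Two-sided test of a location shift between paired distributions. Zero
#' differences are included when ranking absolute differences and dropped
#' from the statistic afterwards (Pratt's method). For 25 or fewer nonzero,
#' untied differences the exact signed-rank distribution is used; otherwise
#' the normal approximation with continuity correction and the standard
#' zero/tie variance corrections. With no nonzero differences the p-value
#' is 1.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @return List \code{(statistic, p, nNonzero, method)} where
#'   \code{statistic} is the positive-rank sum \eqn{W^+}.
#' @export
#' @examples
#' pairedSignedRank(c(0.1, 0.2, 0.3), c(0.3, 0.1, 0.2))$statistic
pairedSignedRank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n <- length(d)
  n0 <- sum(d == 0)
  if (n0 == n)
    return(list(statistic = 0, p = 1, nNonzero = 0L, method = "degenerate"))
  r <- rank(abs(d))                      # zeros participate in ranking
  wPlus <- sum(r[d > 0])
  nz <- d != 0
  hasTies <- anyDuplicated(abs(d[nz])) > 0
  if (n0 == 0 && !hasTies && n <= 25) {
    # exact: W+ over n untied pairs
    wMinus <- sum(r[d < 0])
    w <- min(wPlus, wMinus)
    pv <- min(1, 2 * stats::psignrank(w, n))
    return(list(statistic = wPlus, p = pv, nNonzero = as.integer(n),
                method = "exact"))
  }
  # Pratt normal approximation: E and Var of W+ with zero and tie corrections
  mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  tiesTab <- table(r[nz])
  tieCorr <- sum(tiesTab^3 - tiesTab) / 48
  v <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    tieCorr
  z <- (wPlus - mu - sign(wPlus - mu) * 0.5) / sqrt(v)
  pv <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = wPlus, p = pv, nNonzero = as.integer(sum(nz)),
       method = "normal-pratt")
}
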