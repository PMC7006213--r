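#' Bootstrap optimism-corrected Harrell's C
#'
#' Apparent C is Harrell's C of the full-data fit's linear predictor. Each
#' replicate resamples patients with replacement, refits, and computes the
#' model's C on the bootstrap sample (\eqn{C_{boot}}) and on the original
#' data (\eqn{C_{orig}}); the replicate's bias-corrected value is
#' \eqn{C_{app} - (C_{boot} - C_{orig})} and the reported estimate is the
#' mean over replicates -- identical to the classical optimism-corrected
#' estimate \eqn{C_{app} - \overline{optimism}}. Replicates whose fit
#' fails (e.g. a resample drops a rare covariate level) are redrawn and
#' counted; more than \code{0.2 B} failures abort.
#'
#' @param design A \linkS4class{CoxDesign} or design matrix.
#' @param survival A \linkS4class{SurvData}.
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @return A \linkS4class{BootstrapCResult}.
#' @export
optimismCorrectedC <- function(design, survival, B = 500L, seed = 1L) {
  X <- if (is(design, "CoxDesign")) design@values else as.matrix(design)
  full <- fitCox(X, survival)
  if (!full@converged)
    stop("full-data Cox fit failed: ", full@message)
  apparent <- harrellC(full@linearPredictor, survival)@c
  n <- nrow(X)
  vals <- numeric(B)
  nRedrawn <- 0L
  withSeed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        bs <- SurvData(survival@time[idx], survival@event[idx],
                       paste0("b", seq_len(n)))
        fb <- fitCox(X[idx, , drop = FALSE], bs)
        if (fb@converged) break
        nRedrawn <- nRedrawn + 1L
        if (nRedrawn > 0.2 * B)
          stop("more than 20% of bootstrap replicates failed to fit")
      }
      cBoot <- harrellC(fb@linearPredictor, bs)@c
      cOrig <- harrellC(as.numeric(X[, names(fb@beta), drop = FALSE] %*%
                                     fb@beta), survival)@c
      vals[b] <- apparent - (cBoot - cOrig)
    }
  })
  new("BootstrapCResult", apparent = apparent, values = vals,
      mean = mean(vals),
      ci95 = unname(stats::quantile(vals, c(0.025, 0.975))),
      seed = as.integer(seed), nRedrawn = nRedrawn)
}

# event-stratified fold assignment: events and censored samples are dealt
# into folds separately so every fold retains events
.stratifiedFolds <- function(event, folds) {
  n <- length(event)
  f <- integer(n)
  for (grp in list(which(event == 1L), which(event == 0L))) {
    if (!length(grp)) next
    f[sample(grp)] <- rep_len(seq_len(folds), length(grp))
  }
  f
}

#' Cross-validated Uno's C distributions
#'
#' Repeats an event-stratified k-fold split; within each iteration every
#' fold is predicted by a model fitted on the remaining folds, the
#' out-of-fold linear predictors are pooled, and one Uno's C per horizon
#' is computed from the pooled predictor. By default the censoring
#' distribution for the IPCW weights is estimated once on the full sample
#' so all folds share one weight function (\code{perFoldG = TRUE} switches
#' to per-training-fold estimates). Iterations with a failed fold fit are
#' redrawn and counted.
#'
#' @param design A \linkS4class{CoxDesign} or design matrix.
#' @param survival A \linkS4class{SurvData}.
#' @param taus Horizons in days (default 2/3/5 years).
#' @param folds Number of folds (default 5).
#' @param iters Number of iterations (default 500).
#' @param seed Integer seed.
#' @param perFoldG Estimate the censoring KM per training fold.
#' @return A \linkS4class{CVConcordance}.
#' @export
cvUnoC <- function(design, survival, taus = c(730, 1095, 1825), folds = 5L,
                   iters = 500L, seed = 1L, perFoldG = FALSE) {
  X <- if (is(design, "CoxDesign")) design@values else as.matrix(design)
  n <- nrow(X)
  stopifnot(length(survival@time) == n, sum(survival@event) >= folds)
  vals <- matrix(NA_real_, iters, length(taus))
  nRedrawn <- 0L
  withSeed(seed, {
    for (it in seq_len(iters)) {
      repeat {
        f <- .stratifiedFolds(survival@event, folds)
        lp <- rep(NA_real_, n)
        perFold <- matrix(NA_real_, folds, length(taus))
        ok <- TRUE
        for (k in seq_len(folds)) {
          tr <- f != k
          trSurv <- SurvData(survival@time[tr], survival@event[tr],
                             paste0("t", which(tr)))
          fit <- fitCox(X[tr, , drop = FALSE], trSurv)
          if (!fit@converged) { ok <- FALSE; break }
          lp[!tr] <- as.numeric(X[!tr, names(fit@beta), drop = FALSE] %*%
                                  fit@beta)
          if (perFoldG) {
            teSurv <- SurvData(survival@time[!tr], survival@event[!tr],
                               paste0("e", which(!tr)))
            for (j in seq_along(taus))
              perFold[k, j] <- unoC(trSurv, lp[!tr], teSurv, taus[j])@c
          }
        }
        if (ok) break
        nRedrawn <- nRedrawn + 1L
        if (nRedrawn > 0.5 * iters)
          stop("too many cross-validation iterations failed to fit")
      }
      if (perFoldG) {
        vals[it, ] <- colMeans(perFold)
      } else {
        for (j in seq_along(taus))
          vals[it, j] <- unoC(survival, lp, survival, taus[j])@c
      }
    }
  })
  new("CVConcordance", taus = taus, values = vals, means = colMeans(vals),
      folds = as.integer(folds), seed = as.integer(seed),
      nRedrawn = nRedrawn)
}
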