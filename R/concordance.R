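#' Kaplan--Meier estimate of a survivor function
#'
#' Minimal product-limit estimator used for the censoring distribution in
#' the IPCW concordance and for the time transform of the
#' proportional-hazards test.
#'
#' @param time,event Follow-up times and 0/1 indicators of the event whose
#'   survivor function is estimated (pass \code{1 - event} for the
#'   censoring distribution).
#' @return List with sorted unique event \code{times} and the survivor
#'   value \code{surv} immediately after each.
#' @keywords internal
kmEstimate <- function(time, event) {
  ord <- order(time)
  tt <- time[ord]; ee <- event[ord]
  ut <- unique(tt[ee == 1])
  n <- length(tt)
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    atRisk <- sum(tt >= ut[i])
    d <- sum(tt == ut[i] & ee == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  list(times = ut, surv = surv)
}

#' Evaluate a KM survivor function
#'
#' @param km Result of \code{\link{kmEstimate}}.
#' @param t Evaluation times.
#' @param left If TRUE return the left limit \eqn{S(t-)}.
#' @return Numeric survivor values.
#' @keywords internal
kmEval <- function(km, t, left = FALSE) {
  if (!length(km$times)) return(rep(1, length(t)))
  idx <- if (left) findInterval(t, km$times, left.open = TRUE)
         else findInterval(t, km$times)
  c(1, km$surv)[idx + 1L]
}

#' Harrell's concordance index
#'
#' Usable pairs are ordered pairs (i, j) where i has an observed event at
#' \eqn{t_i} and j's observed time strictly exceeds \eqn{t_i}; pairs of
#' tied event times are unusable. A pair is concordant when the risk of the
#' earlier failure is higher; tied risks earn half credit. With all risks
#' equal the index is 0.5 by this convention.
#'
#' @param risk Numeric risk score per sample (higher = worse prognosis).
#' @param survival A \linkS4class{SurvData}.
#' @return A \linkS4class{ConcordanceResult}.
#' @export
#' @examples
#' sv <- SurvData(c(1, 2, 3, 4), c(1L, 1L, 1L, 1L))
#' cIndex(harrellC(c(2, 1, 4, 3), sv))  # 1/3
harrellC <- function(risk, survival) {
  stopifnot(is(survival, "SurvData"), all(is.finite(risk)),
            length(risk) == length(survival@time))
  tt <- survival@time; ev <- survival@event
  credit <- 0; usable <- 0
  for (i in which(ev == 1L)) {
    later <- tt > tt[i]
    m <- sum(later)
    if (!m) next
    usable <- usable + m
    credit <- credit + sum(risk[i] > risk[later]) +
      0.5 * sum(risk[i] == risk[later])
  }
  if (usable == 0) stop("no usable pairs for Harrell's C")
  new("ConcordanceResult", c = credit / usable, nPairs = usable,
      variant = "harrell", tau = NULL)
}

#' Uno's IPCW concordance index truncated at a horizon
#'
#' Inverse-probability-of-censoring-weighted concordance:
#' \deqn{\hat C_\tau = \frac{\sum_{i,j} \delta_i \hat G(t_i-)^{-2}
#'   1\{t_i < t_j, t_i < \tau\}(1\{\eta_i > \eta_j\} +
#'   0.5\,1\{\eta_i = \eta_j\})}{\sum_{i,j} \delta_i \hat G(t_i-)^{-2}
#'   1\{t_i < t_j, t_i < \tau\}}}
#' where \eqn{\hat G} is the Kaplan--Meier estimate of the censoring
#' survivor function from \code{trainSurvival}, evaluated just before
#' \eqn{t_i}. Under zero censoring and \eqn{\tau \ge \max t} all weights
#' are equal and the index coincides with Harrell's C.
#'
#' @param trainSurvival \linkS4class{SurvData} supplying the censoring
#'   distribution.
#' @param testRisk Risk scores on the evaluation samples.
#' @param testSurvival \linkS4class{SurvData} for the evaluation samples.
#' @param tau Truncation horizon in days (> 0); the conventional horizons
#'   are 2/3/5 years = 730/1095/1825 days.
#' @return A \linkS4class{ConcordanceResult} (\code{nPairs} is the number
#'   of contributing pairs, unweighted).
#' @export
unoC <- function(trainSurvival, testRisk, testSurvival, tau) {
  stopifnot(is(trainSurvival, "SurvData"), is(testSurvival, "SurvData"),
            tau > 0, length(testRisk) == length(testSurvival@time))
  G <- kmEstimate(trainSurvival@time, 1L - trainSurvival@event)
  tt <- testSurvival@time; ev <- testSurvival@event
  num <- 0; den <- 0; npairs <- 0
  for (i in which(ev == 1L & tt < tau)) {
    later <- tt > tt[i]
    m <- sum(later)
    if (!m) next
    g <- kmEval(G, tt[i], left = TRUE)
    if (g <= 0)
      stop(sprintf(paste0("censoring survivor function is 0 before t=%g; ",
                          "tau=%g exceeds the censoring support"), tt[i], tau))
    w <- 1 / g^2
    npairs <- npairs + m
    den <- den + w * m
    num <- num + w * (sum(testRisk[i] > testRisk[later]) +
                        0.5 * sum(testRisk[i] == testRisk[later]))
  }
  if (den == 0) stop("no usable pairs for Uno's C")
  new("ConcordanceResult", c = num / den, nPairs = npairs,
      variant = "uno", tau = tau)
}
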