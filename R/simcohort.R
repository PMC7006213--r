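#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates every knob of the generator. Defaults emulate a
#' TCGA-style colon-adenocarcinoma cohort: 344 patients, ~79\% censoring,
#' three latent prognostic subtypes expressed in all three omics layers,
#' and clinical stage frequencies at realistic proportions (T3 dominant,
#' rare T4b, ~15\% M1).
#'
#' @param nSamples Number of patients.
#' @param nFeatures Named integer vector: features per layer
#'   (\code{expression}, \code{methylation}, \code{mirna}).
#' @param nSubtypes Number of latent subtypes K.
#' @param subtypeProps Length-K probability vector (sums to 1).
#' @param subtypeLogHR Length-K log hazard ratios; first entry must be 0
#'   (reference subtype).
#' @param clinicalLogHR List with per-level log-HR vectors \code{t} (length
#'   5, ref T1), \code{n} (length 5, ref N0), \code{m} (length 2, ref M0)
#'   and a scalar \code{age} slope per decade of centred age.
#' @param nInformative Named integer vector: subtype-separated features per
#'   layer; NULL (the default) uses (40, 40, 20) capped at the layer's
#'   feature count.
#' @param effectSize Named numeric vector: mean shift (in within-subtype
#'   standard-deviation units) of the informative features per layer.
#' @param baseline List \code{(family, scale, shape)}; family
#'   \code{"exponential"} (rate = \code{scale} per day) or
#'   \code{"weibull"}.
#' @param censorRate Target censoring fraction in \eqn{[0,1)}.
#' @param missingRate Fraction of entries replaced by NA in each layer.
#' @param sharedSubtypes If TRUE (default) one latent subtype drives every
#'   layer; if FALSE each layer receives an independent subtype while the
#'   hazard still follows the primary one.
#' @param clinicalFreqs List of category frequencies for t/n/m stages.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return A validated list of class \code{"CohortConfig"}.
#' @export
#' @examples
#' cfg <- cohortConfig(nSamples = 100, seed = 1)
#' cfg$censorRate
cohortConfig <- function(nSamples = 344L,
                         nFeatures = c(expression = 200L, methylation = 200L,
                                       mirna = 60L),
                         nSubtypes = 3L,
                         subtypeProps = c(0.40, 0.35, 0.25),
                         subtypeLogHR = c(0, 0.7, 1.4),
                         clinicalLogHR = list(
                           t = c(0, 0.1, 0.3, 0.5, 0.7),
                           n = c(0, 0.25, 0.35, 1.0, 1.0),
                           m = c(0, 1.6),
                           age = 0.35),
                         nInformative = NULL,
                         effectSize = c(expression = 2, methylation = 2,
                                        mirna = 2),
                         baseline = list(family = "exponential",
                                         scale = 4e-5, shape = 1),
                         censorRate = 0.794,
                         missingRate = 0,
                         sharedSubtypes = TRUE,
                         clinicalFreqs = list(
                           t = c(T1 = 10, T2 = 62, T3 = 254, T4a = 12,
                                 T4b = 6),
                           n = c(N0 = 211, N1a = 35, N1b = 40, N2a = 32,
                                 N2b = 26),
                           m = c(M0 = 292, M1 = 52)),
                         seed = 1L) {
  layers <- c("expression", "methylation", "mirna")
  nFeatures <- as.integer(nFeatures[layers])
  names(nFeatures) <- layers
  if (is.null(nInformative))
    nInformative <- pmin(c(expression = 40L, methylation = 40L,
                           mirna = 20L), nFeatures)
  nInformative <- as.integer(nInformative[layers])
  effectSize <- as.numeric(effectSize[layers])
  names(nFeatures) <- names(nInformative) <- names(effectSize) <- layers
  stopifnot(nSamples >= 4, all(nFeatures > 0),
            nSubtypes >= 1, length(subtypeProps) == nSubtypes,
            length(subtypeLogHR) == nSubtypes)
  if (abs(sum(subtypeProps) - 1) > 1e-8)
    stop("subtypeProps must sum to 1")
  if (subtypeLogHR[1] != 0)
    stop("subtypeLogHR[1] is the reference subtype and must be 0")
  if (any(nInformative > nFeatures))
    stop("nInformative must not exceed nFeatures")
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must lie in [0, 1)")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (nSamples * min(subtypeProps) < 2)
    stop("expected minimum subtype size below 2; decrease nSubtypes or ",
         "rebalance subtypeProps")
  if (!baseline$family %in% c("exponential", "weibull"))
    stop("baseline family must be 'exponential' or 'weibull'")
  stopifnot(length(clinicalLogHR$t) == 5, length(clinicalLogHR$n) == 5,
            length(clinicalLogHR$m) == 2, length(clinicalLogHR$age) == 1)
  structure(list(nSamples = as.integer(nSamples), nFeatures = nFeatures,
                 nSubtypes = as.integer(nSubtypes),
                 subtypeProps = subtypeProps, subtypeLogHR = subtypeLogHR,
                 clinicalLogHR = clinicalLogHR, nInformative = nInformative,
                 effectSize = effectSize, baseline = baseline,
                 censorRate = censorRate, missingRate = missingRate,
                 sharedSubtypes = isTRUE(sharedSubtypes),
                 clinicalFreqs = clinicalFreqs, seed = as.integer(seed)),
            class = "CohortConfig")
}

.stage_levels <- list(
  t = c("T1", "T2", "T3", "T4a", "T4b"),
  n = c("N0", "N1a", "N1b", "N2a", "N2b"),
  m = c("M0", "M1"))

# Draw a categorical clinical covariate and guarantee >= 2 samples per level
# (rare levels are topped up from the most common one) so treatment-coded
# designs are never rank-deficient.
.sample_stage <- function(n, freqs, levels) {
  freqs <- freqs[levels]
  x <- sample(levels, n, replace = TRUE, prob = freqs / sum(freqs))
  for (lv in levels) {
    need <- 2L - sum(x == lv)
    if (need > 0) {
      donor <- names(which.max(table(x)))
      idx <- which(x == donor)[seq_len(need)]
      x[idx] <- lv
    }
  }
  factor(x, levels = levels)
}

# Expected censoring fraction when censoring ~ U(0, cmax) and the event time
# has per-sample hazard rate[i] (exponential) or Weibull(shape, per-sample
# scale). Used by the bisection calibration.
.expected_censor_frac <- function(cmax, config, lp) {
  fam <- config$baseline$family
  if (fam == "exponential") {
    r <- config$baseline$scale * exp(lp)
    mean((1 - exp(-r * cmax)) / (r * cmax))
  } else {
    shape <- config$baseline$shape
    lam <- config$baseline$scale
    # S(t) = exp(-lam * t^shape * e^lp); average survivor over U(0, cmax)
    grid <- seq(0, cmax, length.out = 201L)[-1]
    mean(vapply(lp, function(l) {
      mean(exp(-lam * grid^shape * exp(l)))
    }, numeric(1)))
  }
}

.calibrate_cmax <- function(config, lp) {
  target <- config$censorRate
  lo <- 1; hi <- 1
  while (.expected_censor_frac(hi, config, lp) > target && hi < 1e8) hi <- hi * 2
  while (.expected_censor_frac(lo, config, lp) < target && lo > 1e-8) lo <- lo / 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (.expected_censor_frac(mid, config, lp) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# per-feature subtype mean-shift pattern: each informative feature gets a
# random permutation of K equally spaced standardized offsets spanning
# [-effectSize/2 * (K-1) ... ] so adjacent subtypes differ by effectSize.
.subtype_shifts <- function(K, effectSize) {
  base <- (seq_len(K) - (K + 1) / 2) * effectSize
  sample(base)
}

#' Generate a synthetic multi-omics survival cohort
#'
#' Draws latent subtypes, TNM/age clinical covariates, three omics layers
#' with subtype-separated informative features, and right-censored survival
#' times from a proportional-hazards model whose log-hazard is the sum of
#' the clinical effects and the subtype effect. Censoring times are uniform
#' on \eqn{(0, c_{max})} with \eqn{c_{max}} calibrated by bisection so the
#' expected censoring fraction equals \code{censorRate}.
#'
#' Expression and miRNA layers are generated on the log scale (normal per
#' subtype, unit within-subtype sd) and exponentiated, giving skewed
#' non-negative FPKM/RPM-like values; methylation features are drawn from
#' Beta distributions whose means are subtype-shifted on the scale of the
#' feature's Beta standard deviation, so \code{effectSize} is comparable
#' across layers.
#'
#' @param config A \code{\link{cohortConfig}}.
#' @return A \linkS4class{SyntheticCohort}.
#' @export
#' @examples
#' coh <- generateCohort(cohortConfig(nSamples = 60, seed = 7))
#' coh
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  withSeed(config$seed, {
    n <- config$nSamples
    K <- config$nSubtypes
    ids <- sprintf("S%04d", seq_len(n))

    z <- sample.int(K, n, replace = TRUE, prob = config$subtypeProps)
    # top up empty subtypes (expected size >= 2 was enforced by the config)
    for (k in seq_len(K)) {
      need <- 2L - sum(z == k)
      if (need > 0) z[which(z == names(which.max(table(z))))[seq_len(need)]] <- k
    }

    clin <- data.frame(
      sample_id = ids,
      t_stage = .sample_stage(n, config$clinicalFreqs$t, .stage_levels$t),
      n_stage = .sample_stage(n, config$clinicalFreqs$n, .stage_levels$n),
      m_stage = .sample_stage(n, config$clinicalFreqs$m, .stage_levels$m),
      age_years = pmin(90, pmax(31, round(stats::rnorm(n, 66, 12)))),
      stringsAsFactors = FALSE)

    lhr <- config$clinicalLogHR
    lp <- lhr$t[as.integer(clin$t_stage)] +
      lhr$n[as.integer(clin$n_stage)] +
      lhr$m[as.integer(clin$m_stage)] +
      lhr$age * (clin$age_years - 66) / 10 +
      config$subtypeLogHR[z]

    # event times under the configured baseline
    E <- stats::rexp(n)
    fam <- config$baseline$family
    tev <- if (fam == "exponential") {
      E / (config$baseline$scale * exp(lp))
    } else {
      (E / (config$baseline$scale * exp(lp)))^(1 / config$baseline$shape)
    }
    if (config$censorRate > 0) {
      cmax <- .calibrate_cmax(config, lp)
      cens <- stats::runif(n, 0, cmax)
      time <- pmin(tev, cens)
      event <- as.integer(tev <= cens)
    } else {
      time <- tev
      event <- rep(1L, n)
    }
    surv <- SurvData(time = time, event = event, sampleIDs = ids)

    layerSubtype <- function() {
      if (config$sharedSubtypes) z
      else sample.int(K, n, replace = TRUE, prob = config$subtypeProps)
    }

    genContinuous <- function(lname, scaleTag) {
      p <- config$nFeatures[[lname]]
      pi <- config$nInformative[[lname]]
      es <- config$effectSize[[lname]]
      zz <- layerSubtype()
      mu <- stats::runif(p, 1, 4)            # log-scale baselines
      x <- matrix(stats::rnorm(n * p), n, p)
      x <- sweep(x, 2, mu, "+")
      if (pi > 0 && es != 0) {
        info <- seq_len(pi)                  # informative block first
        for (f in info) {
          sh <- .subtype_shifts(K, es)
          x[, f] <- x[, f] + sh[zz]
        }
      }
      vals <- exp(x)
      dimnames(vals) <- list(ids, sprintf("%s_f%04d", lname, seq_len(p)))
      OmicsMatrix(vals, layer = lname, scale = scaleTag)
    }

    genMethylation <- function() {
      p <- config$nFeatures[["methylation"]]
      pi <- config$nInformative[["methylation"]]
      es <- config$effectSize[["methylation"]]
      zz <- layerSubtype()
      phi <- 30
      m0 <- stats::runif(p, 0.2, 0.8)
      vals <- matrix(0, n, p)
      for (f in seq_len(p)) {
        mf <- rep(m0[f], n)
        if (f <= pi && es != 0) {
          sdf <- sqrt(m0[f] * (1 - m0[f]) / (1 + phi))
          sh <- .subtype_shifts(K, es) * sdf
          mf <- pmin(0.95, pmax(0.05, m0[f] + sh[zz]))
        }
        vals[, f] <- stats::rbeta(n, mf * phi, (1 - mf) * phi)
      }
      # rbeta can return exact 0/1 at the double-precision boundary; nudge
      vals[vals <= 0] <- .Machine$double.eps
      vals[vals >= 1] <- 1 - 1e-12
      dimnames(vals) <- list(ids, sprintf("methylation_f%04d", seq_len(p)))
      OmicsMatrix(vals, layer = "methylation", scale = "beta")
    }

    layers <- list(expression = genContinuous("expression", "fpkm"),
                   methylation = genMethylation(),
                   mirna = genContinuous("mirna", "rpm"))

    if (config$missingRate > 0) {
      for (nm in names(layers)) {
        layers[[nm]] <- injectMissingness(
          layers[[nm]], config$missingRate, badValue = "na",
          seed = deriveSeed(config$seed, paste0("missing_", nm)))
      }
    }

    new("SyntheticCohort", layers = layers, clinical = clin, survival = surv,
        trueSubtype = as.integer(z), trueLinearPredictor = as.numeric(lp),
        config = unclass(config))
  })
}

#' Replace a fixed fraction of matrix entries by NA or zero
#'
#' Exactly \code{round(missingRate * n_entries)} entries, chosen uniformly
#' at random under \code{seed}, are replaced. The linear indices of the
#' replaced entries are recorded in the \code{"missing_idx"} attribute of
#' the returned values for test inspection.
#'
#' @param x An \linkS4class{OmicsMatrix}.
#' @param missingRate Fraction in \eqn{[0,1)}.
#' @param badValue \code{"na"} or \code{"zero"}.
#' @param seed Integer seed.
#' @return An \linkS4class{OmicsMatrix} with entries replaced.
#' @export
injectMissingness <- function(x, missingRate, badValue = c("na", "zero"),
                              seed = 1L) {
  stopifnot(is(x, "OmicsMatrix"), missingRate >= 0, missingRate < 1)
  badValue <- match.arg(badValue)
  v <- x@values
  nrep <- round(missingRate * length(v))
  if (nrep == 0) return(x)
  idx <- withSeed(seed, sample.int(length(v), nrep))
  v[idx] <- if (badValue == "na") NA_real_ else 0
  attr(v, "missing_idx") <- sort(idx)
  out <- x
  out@values <- v
  validObject(out)
  out
}

#' Write a synthetic cohort to delimited files
#'
#' Writes one tab-delimited matrix per layer (samples as rows, feature
#' header), a clinical table with columns \code{sample_id, t_stage, n_stage,
#' m_stage, age_years, time_days, event}, and a JSON truth file holding the
#' latent subtype, the generating linear predictor and the seed.
#'
#' @param cohort A \linkS4class{SyntheticCohort}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in names(cohort@layers)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    writeOmicsMatrix(cohort@layers[[nm]], p)
    paths[nm] <- p
  }
  clin <- cohort@clinical
  clin$time_days <- cohort@survival@time
  clin$event <- cohort@survival@event
  p <- file.path(dir, "clinical.tsv")
  utils::write.table(clin, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["clinical"] <- p
  truth <- list(seed = cohort@config$seed,
                true_subtype = cohort@trueSubtype,
                true_linear_predictor = cohort@trueLinearPredictor,
                subtype_log_hr = cohort@config$subtypeLogHR,
                clinical_log_hr = cohort@config$clinicalLogHR)
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- p
  invisible(paths)
}
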