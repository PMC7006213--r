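test_that("covariate encoding produces the expected treatment-coded layout", {
  clin <- makeClinical(60)
  des <- encodeCovariates(clin)
  expect_equal(ncol(designMatrix(des)), 12)  # 4 + 4 + 1 + 3
  expect_true(all(designMatrix(des) %in% c(0, 1)))
  # adding cluster labels with k = (4, 10, 4) gives 27 columns
  labs <- list(G = makeLabels(rep_len(1:4, 60), 4),
               M = makeLabels(rep_len(1:10, 60), 10),
               m = makeLabels(rep_len(1:4, 60), 4))
  des2 <- encodeCovariates(clin, clusters = labs)
  expect_equal(ncol(designMatrix(des2)), 27)  # 12 + 3 + 9 + 3
  expect_setequal(names(designBlocks(des2)),
                  c("T_stage", "N_stage", "M_stage", "Age", "G", "M", "m"))
  # a sample at every reference level has an all-zero row
  ref <- clin
  ref$t_stage[1] <- "T1"; ref$n_stage[1] <- "N0"; ref$m_stage[1] <- "M0"
  ref$age_years[1] <- min(ref$age_years)
  d3 <- encodeCovariates(ref)
  expect_true(all(designMatrix(d3)[1, ] == 0))
  # an empty non-reference level is an error, not a silent all-zero column
  bad <- clin
  bad$m_stage <- "M0"
  expect_error(encodeCovariates(bad), "zero samples")
})

test_that("Cox fitting matches an established implementation", {
  skip_if_not_installed("survival")
  withSeed(2, {
    for (trial in 1:3) {
      n <- 250
      x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
      tt <- ceiling(rexp(n, 0.002 * exp(0.7 * x[, 1] - 0.3 * x[, 3])))
      cc <- ceiling(runif(n, 1, 1200))
      sv <- SurvData(pmin(tt, cc), as.integer(tt <= cc))
      f1 <- fitCox(x, sv)
      f2 <- survival::coxph(survival::Surv(survTime(sv), survEvent(sv)) ~ x,
                            ties = "efron")
      expect_true(f1@converged)
      expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-6)
      expect_equal(unname(f1@se), unname(sqrt(diag(vcov(f2)))),
                   tolerance = 1e-6)
      expect_equal(f1@loglikFull, f2$loglik[2], tolerance = 1e-8)
      expect_equal(f1@loglikNull, f2$loglik[1], tolerance = 1e-8)
    }
  })
})

test_that("the partial likelihood never decreases along the Newton path", {
  withSeed(6, {
    n <- 150
    x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
    tt <- rexp(n, 0.01 * exp(1.2 * x[, 1]))
    sv <- SurvData(tt, rep(1L, n))
    f <- fitCox(x, sv)
    expect_true(all(diff(f@logLikTrace) >= -1e-10))
    expect_gte(f@loglikFull, f@loglikNull)
  })
})

test_that("null and degenerate designs are handled as specified", {
  withSeed(3, {
    n <- 120
    g <- rep(0:1, each = n / 2)
    tt <- rexp(n, 0.01)  # no group effect
    sv <- SurvData(tt, rep(1L, n))
    f <- fitCox(cbind(grp = g), sv)
    expect_lt(abs(coef(f)[["grp"]]), 2 * f@se[["grp"]])
    # constant column: infeasible, not an error
    fc <- fitCox(cbind(flat = rep(1, n)), sv)
    expect_false(fc@converged)
    expect_match(fc@message, "constant")
    expect_error(fitCox(cbind(x = rnorm(5)), SurvData(1:5, rep(0L, 5))),
                 "at least one event")
  })
})

test_that("a single-covariate fit recovers the generating coefficient", {
  est <- vapply(1:3, function(s) {
    withSeed(100 + s, {
      n <- 2000
      x <- cbind(z = rnorm(n))
      tt <- rexp(n, 1e-3 * exp(0.7 * x[, "z"]))
      cc <- runif(n, 0, 2500)
      sv <- SurvData(pmin(tt, cc), as.integer(tt <= cc))
      coef(fitCox(x, sv))[["z"]]
    })
  }, numeric(1))
  expect_true(all(abs(est - 0.7) <= 0.1))
})

test_that("the score test at beta = 0 equals the log-rank statistic", {
  withSeed(10, {
    for (trial in 1:3) {
      n <- 120
      g <- rbinom(n, 1, 0.5)
      tt <- rexp(n, 0.01 * exp(0.5 * g))
      cc <- runif(n, 0, 200)
      time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
      f <- fitCox(cbind(grp = g), SurvData(time, ev))
      sc <- modelTests(f)$score
      expect_equal(sc$statistic, oracleLogrank(time, ev, g),
                   tolerance = 1e-8)
    }
  })
})

test_that("global tests agree with the survival package summary", {
  skip_if_not_installed("survival")
  withSeed(12, {
    n <- 200
    x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    tt <- rexp(n, 0.01 * exp(0.5 * x[, 1]))
    cc <- runif(n, 0, 250)
    sv <- SurvData(pmin(tt, cc), as.integer(tt <= cc))
    f1 <- fitCox(x, sv)
    s2 <- summary(survival::coxph(
      survival::Surv(survTime(sv), survEvent(sv)) ~ x, ties = "efron"))
    mt <- modelTests(f1)
    expect_equal(mt$lrt$statistic, unname(s2$logtest["test"]),
                 tolerance = 1e-6)
    expect_equal(mt$score$statistic, unname(s2$sctest["test"]),
                 tolerance = 1e-6)
    expect_equal(mt$wald$statistic, unname(s2$waldtest["test"]),
                 tolerance = 1e-3)
    expect_gte(mt$lrt$statistic, 0)
  })
})

test_that("hazard ratios and intervals are consistent with the coefficients", {
  withSeed(30, {
    n <- 150
    x <- cbind(z = rnorm(n))
    sv <- SurvData(rexp(n, 0.01 * exp(0.4 * x[, "z"])), rep(1L, n))
    tb <- coefTable(fitCox(x, sv))
    expect_equal(tb$hr, exp(tb$beta))
    expect_equal(tb$ci_low, exp(tb$beta - 1.96 * tb$se))
    expect_equal(tb$ci_high, exp(tb$beta + 1.96 * tb$se))
  })
})

test_that("nested LRT behaves at its boundaries and detects real effects", {
  withSeed(40, {
    n <- 400
    x <- cbind(a = rnorm(n), b = rnorm(n))
    sv <- SurvData(rexp(n, 0.01 * exp(1.0 * x[, "a"])), rep(1L, n))
    full <- fitCox(x, sv)
    redA <- fitCox(x[, "b", drop = FALSE], sv)   # misses the true effect
    expect_lt(lrtNested(full, redA)$p, 0.001)
    expect_equal(lrtNested(full, full)$p, 1)
    other <- fitCox(cbind(c = rnorm(n)), sv)
    expect_error(lrtNested(full, other), "nested")
  })
})
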