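test_that("cohort generation is a pure function of the config", {
  cfg <- cohortConfig(nSamples = 80, nFeatures = c(expression = 30,
                                                   methylation = 30,
                                                   mirna = 10), seed = 11)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(omicsValues(cohortLayers(a)$expression),
                   omicsValues(cohortLayers(b)$expression))
  expect_identical(survTime(cohortSurvival(a)), survTime(cohortSurvival(b)))
  expect_identical(trueSubtype(a), trueSubtype(b))
  # and a different seed changes the draw
  c2 <- generateCohort(cohortConfig(nSamples = 80,
                                    nFeatures = cfg$nFeatures, seed = 12))
  expect_false(identical(survTime(cohortSurvival(a)),
                         survTime(cohortSurvival(c2))))
})

test_that("config validation rejects degenerate settings", {
  expect_error(cohortConfig(nSamples = 20, nSubtypes = 3,
                            subtypeProps = c(0.9, 0.05, 0.05),
                            subtypeLogHR = c(0, 0, 0)),
               "minimum subtype size")
  expect_error(cohortConfig(censorRate = 1), "censorRate")
  expect_error(cohortConfig(missingRate = -0.1), "missingRate")
  expect_error(cohortConfig(subtypeProps = c(0.5, 0.4),
                            subtypeLogHR = c(0, 1), nSubtypes = 2),
               "sum to 1")
  expect_error(cohortConfig(subtypeLogHR = c(0.5, 0, 0)), "reference")
})

test_that("cohort components share sample order and measurement scales", {
  coh <- generateCohort(cohortConfig(nSamples = 60, seed = 3))
  ids <- sampleIDs(coh)
  for (l in cohortLayers(coh)) expect_identical(sampleIDs(l), ids)
  expect_identical(as.character(cohortClinical(coh)$sample_id), ids)
  meth <- omicsValues(cohortLayers(coh)$methylation)
  expect_true(all(meth > 0 & meth < 1))
  expect_true(all(omicsValues(cohortLayers(coh)$expression) >= 0))
  expect_true(all(trueSubtype(coh) %in% 1:3))
})

test_that("null configurations behave as expected", {
  # no effects at all: constant linear predictor, C = 0.5 by all-ties rule
  cfg <- cohortConfig(nSamples = 100,
                      subtypeLogHR = c(0, 0, 0),
                      clinicalLogHR = list(t = rep(0, 5), n = rep(0, 5),
                                           m = c(0, 0), age = 0),
                      seed = 5)
  coh <- generateCohort(cfg)
  expect_equal(var(trueLinearPredictor(coh)), 0)
  expect_equal(cIndex(harrellC(trueLinearPredictor(coh),
                               cohortSurvival(coh))), 0.5)
})

test_that("zero effect size leaves layers uninformative about subtype", {
  aris <- vapply(1:3, function(s) {
    coh <- generateCohort(cohortConfig(
      nSamples = 120, effectSize = c(expression = 0, methylation = 0,
                                     mirna = 0),
      nFeatures = c(expression = 60, methylation = 60, mirna = 20),
      seed = s))
    x <- cohortLayers(coh)$expression
    lab <- cutTreeK(hierarchicalCluster(pairwiseDistance(x, "manhattan"),
                                        "ward_d"), 3)
    adjustedRand(lab@labels, trueSubtype(coh))
  }, numeric(1))
  expect_lt(mean(abs(aris)), 0.1)
})

test_that("survival generation matches the configured model", {
  # censoring fraction lands near the target; worse subtypes fail earlier
  fracs <- c(); gap <- c()
  for (s in 1:20) {
    coh <- generateCohort(cohortConfig(
      nSamples = 400, subtypeLogHR = c(0, 0.7, 1.4), censorRate = 0.6,
      nFeatures = c(expression = 20, methylation = 20, mirna = 10),
      seed = s))
    ev <- survEvent(cohortSurvival(coh))
    tt <- survTime(cohortSurvival(coh))
    z <- trueSubtype(coh)
    fracs <- c(fracs, mean(ev == 0))
    gap <- c(gap, mean(tt[z == 1 & ev == 1]) - mean(tt[z == 3 & ev == 1]))
  }
  expect_true(all(fracs >= 0.5 & fracs <= 0.7))
  expect_lt(abs(mean(fracs) - 0.6), 0.05)
  expect_gt(mean(gap), 0)  # subtype 3 (highest hazard) fails earlier
})

test_that("true linear predictor is concordant with survival", {
  cs <- vapply(1:3, function(s) {
    coh <- generateCohort(cohortConfig(
      nSamples = 1000,
      nFeatures = c(expression = 10, methylation = 10, mirna = 5),
      seed = s))
    cIndex(harrellC(trueLinearPredictor(coh), cohortSurvival(coh)))
  }, numeric(1))
  expect_true(all(cs > 0.5))
})

test_that("stronger planted effects do not degrade cluster recovery", {
  es <- c(0, 0.8, 2)
  meanARI <- vapply(es, function(e) {
    mean(vapply(1:10, function(s) {
      coh <- generateCohort(cohortConfig(
        nSamples = 150,
        nFeatures = c(expression = 60, methylation = 20, mirna = 10),
        nInformative = c(expression = 20, methylation = 5, mirna = 3),
        effectSize = c(expression = e, methylation = e, mirna = e),
        seed = s))
      lab <- cutTreeK(hierarchicalCluster(
        pairwiseDistance(cohortLayers(coh)$expression, "manhattan"),
        "ward_d"), 3)
      adjustedRand(lab@labels, trueSubtype(coh))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanARI) > -0.02))
  expect_gt(meanARI[3], 0.9)
})

test_that("missingness injection replaces the exact count reproducibly", {
  m <- matrix(runif(100), 10, 10,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:10)))
  x <- OmicsMatrix(m, "expression", "fpkm")
  expect_identical(injectMissingness(x, 0, seed = 1), x)
  a <- injectMissingness(x, 0.1, seed = 7)
  expect_equal(sum(is.na(omicsValues(a))), 10)
  b <- injectMissingness(x, 0.1, seed = 7)
  expect_identical(omicsValues(a), omicsValues(b))
  z <- injectMissingness(x, 0.13, badValue = "zero", seed = 2)
  expect_equal(sum(omicsValues(z) == 0), round(0.13 * 100))
  idx <- attr(omicsValues(a), "missing_idx")
  expect_true(all(is.na(omicsValues(a)[idx])))
})

test_that("cohort writer produces aligned files and a truth record", {
  dir <- tempfile("cohort")
  coh <- generateCohort(cohortConfig(
    nSamples = 40, nFeatures = c(expression = 10, methylation = 10,
                                 mirna = 5), seed = 2))
  paths <- writeCohort(coh, dir)
  expect_true(all(file.exists(paths)))
  clin <- read.delim(paths[["clinical"]])
  expect_equal(nrow(clin), 40)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$true_subtype, trueSubtype(coh))
  back <- readOmicsMatrix(paths[["expression"]], "expression", "fpkm")
  expect_equal(omicsValues(back), omicsValues(cohortLayers(coh)$expression),
               tolerance = 1e-8)
})
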