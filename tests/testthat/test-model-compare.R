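# compact evaluation settings and a bundle with planted omics signal
smallBundle <- function(seed = 1, n = 160, omicsSignal = TRUE) {
  coh <- generateCohort(cohortConfig(
    nSamples = n,
    nFeatures = c(expression = 40, methylation = 40, mirna = 15),
    nInformative = c(expression = 15, methylation = 15, mirna = 6),
    effectSize = if (omicsSignal) c(expression = 2.5, methylation = 2.5,
                                    mirna = 2.5)
                 else c(expression = 0, methylation = 0, mirna = 0),
    subtypeLogHR = if (omicsSignal) c(0, 0.8, 1.6) else c(0, 0, 0),
    censorRate = 0.4, seed = seed))
  sv <- cohortSurvival(coh)
  clin <- cohortClinical(coh)
  grid <- clusterGridSpec("manhattan", "ward_d", kRange = 2:4,
                          minClusterSize = 10L)
  cfg <- evalConfig(B = 30, searchB = 15, iters = 10, folds = 5,
                    taus = unname(stats::quantile(survTime(sv), c(0.5, 0.75))),
                    seed = seed)
  clinDesign <- encodeCovariates(clin)
  lab <- list(); labAlone <- list()
  for (nm in c("expression", "methylation", "mirna")) {
    lt <- c(expression = "G", methylation = "M", mirna = "m")[[nm]]
    x <- imputeMedian(cohortLayers(coh)[[nm]])
    lab[[lt]] <- winningLabels(clusterGridSearch(
      x, sv, companions = clinDesign, grid = grid, evalCfg = cfg,
      labelPrefix = lt))
    labAlone[[lt]] <- lab[[lt]]
  }
  coc <- clusterOfClusters(lab, sv, companions = clinDesign, grid = grid,
                           evalCfg = cfg)
  list(bundle = list(clinical = clin, survival = sv,
                     labelsCompanion = lab, labelsAlone = labAlone,
                     labelsCoC = winningLabels(coc)),
       cfg = cfg, coh = coh)
}

test_that("the model enumeration yields the standard covariate combinations", {
  specs <- enumerateModels()
  codes <- vapply(specs, modelCode, "")
  expect_length(codes, 12)
  expect_setequal(codes, c("CGMm", "CGM", "CGm", "CMm", "CG", "CM", "Cm",
                           "C", "G", "M", "m", "CA"))
  expect_length(enumerateModels(includeCoc = FALSE), 11)
  expect_error(new("ModelSpec", code = "GA"), "mutually exclusive")
  expect_error(new("ModelSpec", code = "Cx"), "invalid")
})

bb <- smallBundle(seed = 3)

test_that("model evaluation is deterministic and internally consistent", {
  e1 <- evaluateModel("CG", bb$bundle, bb$cfg)
  e2 <- evaluateModel("CG", bb$bundle, bb$cfg)
  expect_identical(e1@bootstrap@values, e2@bootstrap@values)
  expect_identical(e1@cv@values, e2@cv@values)
  expect_equal(modelCode(e1), "CG")
  expect_true(e1@fit@converged)
  expect_true(all(e1@cv@values >= 0 & e1@cv@values <= 1))
  # C and G blocks both present in the design
  expect_true(all(c("T_stage", "G") %in% names(designBlocks(e1@design))))
})

test_that("paired comparisons report zero difference against self and antisymmetry", {
  eC <- evaluateModel("C", bb$bundle, bb$cfg)
  eCG <- evaluateModel("CG", bb$bundle, bb$cfg)
  self <- compareModels(list(eC, eC))
  expect_equal(self$delta_boot, 0)
  expect_equal(self$p_wilcox_boot, 1)
  ab <- compareModels(list(eCG, eC))
  ba <- compareModels(list(eC, eCG))
  expect_equal(ab$delta_boot, -ba$delta_boot)
  cvCols <- setdiff(grep("^delta_cv", names(ab), value = TRUE),
                    grep("_lo$|_hi$", names(ab), value = TRUE))
  for (cn in cvCols) expect_equal(ab[[cn]], -ba[[cn]])
  # C is nested in CG: the LRT column is populated
  expect_false(is.na(ab$p_lrt))
  # unpaired evaluations are rejected
  other <- evaluateModel("C", bb$bundle,
                         evalConfig(B = 30, searchB = 15, iters = 10,
                                    folds = 5, taus = bb$cfg$taus,
                                    seed = 999))
  expect_error(compareModels(list(eCG, other)), "not paired")
})

test_that("constant shifts between paired distributions are detected", {
  eC <- evaluateModel("C", bb$bundle, bb$cfg)
  shifted <- eC
  shifted@spec <- new("ModelSpec", code = "G")  # placeholder code
  shifted@bootstrap@values <- eC@bootstrap@values + 0.02
  withSeed(1, {
    # 500 paired values differing by a constant: p is essentially zero
    x <- runif(500)
    p <- pairedSignedRank(x + 0.02, x)$p
  })
  expect_lt(p, 1e-10)
})

test_that("the ablation report covers exactly the seven covariate blocks", {
  full <- evaluateModel("CGMm", bb$bundle, bb$cfg)
  rep7 <- ablation(bb$bundle, bb$cfg, fullEval = full)
  expect_equal(nrow(rep7), 7)
  expect_setequal(rep7$removed,
                  c("Without T stage", "Without N stage", "Without M stage",
                    "Without Age", "Without Gene", "Without Methylation",
                    "Without miRNA"))
  expect_true(all(is.finite(rep7$p_lrt)))
  expect_true(all(rep7$p_lrt >= 0 & rep7$p_lrt <= 1))
})

test_that("removing a block with no generating effect barely moves the index", {
  # cohort where T stage carries no effect but N/M do
  coh <- generateCohort(cohortConfig(
    nSamples = 300,
    nFeatures = c(expression = 20, methylation = 20, mirna = 10),
    effectSize = c(expression = 0, methylation = 0, mirna = 0),
    subtypeLogHR = c(0, 0, 0),
    clinicalLogHR = list(t = rep(0, 5), n = c(0, 0.3, 0.4, 1.0, 1.0),
                         m = c(0, 1.5), age = 0.4),
    censorRate = 0.4, seed = 21))
  sv <- cohortSurvival(coh)
  des <- encodeCovariates(cohortClinical(coh))
  full <- fitCox(des, sv)
  noT <- fitCox(dropDesignBlocks(des, "T_stage"), sv)
  cFull <- cIndex(harrellC(full@linearPredictor, sv))
  cNoT <- cIndex(harrellC(noT@linearPredictor, sv))
  expect_lt(abs(cFull - cNoT), 0.02)
  # and the nested LRT sees no signal in the T block
  expect_gt(lrtNested(full, noT)$p, 0.01)
})

test_that("omics layers that share the prognostic subtype add discrimination", {
  eC <- evaluateModel("C", bb$bundle, bb$cfg)
  eFull <- evaluateModel("CGMm", bb$bundle, bb$cfg)
  expect_gt(eFull@bootstrap@mean, eC@bootstrap@mean)
})
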