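# small planted-structure cohort shared by several blocks
plantedCohort <- function(n = 200, seed = 1) {
  generateCohort(cohortConfig(
    nSamples = n, nSubtypes = 2, subtypeProps = c(0.5, 0.5),
    subtypeLogHR = c(0, 1.5),
    clinicalLogHR = list(t = rep(0, 5), n = rep(0, 5), m = c(0, 0), age = 0),
    nFeatures = c(expression = 60, methylation = 20, mirna = 10),
    nInformative = c(expression = 25, methylation = 5, mirna = 3),
    effectSize = c(expression = 2.5, methylation = 2, mirna = 2),
    censorRate = 0.3, seed = seed))
}

test_that("the grid search recovers planted prognostic structure", {
  coh <- plantedCohort(200, seed = 31)
  grid <- clusterGridSpec("manhattan", "ward_d", kRange = 2:4)
  res <- clusterGridSearch(cohortLayers(coh)$expression,
                           cohortSurvival(coh), grid = grid,
                           evalCfg = evalConfig(searchB = 40, seed = 1))
  wp <- winningParams(res)
  expect_equal(wp$k, 2)
  expect_gte(adjustedRand(winningLabels(res)@labels, trueSubtype(coh)), 0.9)
  expect_s4_class(winningLabels(res), "ClusterLabels")
  # the winner's score is maximal among feasible candidates
  cd <- candidateTable(res)
  expect_true(all(cd$score[cd$feasible] <= wp$score + 1e-12))
})

test_that("candidates violating the minimum cluster size are infeasible", {
  coh <- plantedCohort(60, seed = 5)
  # at n = 60 a 7-cluster cut must leave some cluster below 10 patients
  grid <- clusterGridSpec("euclidean", "ward_d", kRange = 7L,
                          minClusterSize = 10L)
  expect_error(clusterGridSearch(cohortLayers(coh)$expression,
                                 cohortSurvival(coh), grid = grid,
                                 evalCfg = evalConfig(searchB = 10, seed = 1)),
               "no feasible candidate")
  # the balanced two-cluster cut of the same cohort is scored normally
  grid2 <- clusterGridSpec("euclidean", "ward_d", kRange = 2L,
                           minClusterSize = 10L)
  res <- clusterGridSearch(cohortLayers(coh)$expression,
                           cohortSurvival(coh), grid = grid2,
                           evalCfg = evalConfig(searchB = 10, seed = 1))
  expect_true(any(candidateTable(res)$feasible))
})

test_that("the full default grid enumerates every parameter combination", {
  # 7 distances x 8 linkages x k in 2..11 = 560 candidates
  coh <- plantedCohort(40, seed = 7)
  grid <- clusterGridSpec(kRange = 2:11, minClusterSize = 10L)
  res <- tryCatch(
    clusterGridSearch(cohortLayers(coh)$expression, cohortSurvival(coh),
                      grid = grid, evalCfg = evalConfig(searchB = 5, seed = 1)),
    error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "no feasible|zero-variance")
  } else {
    expect_equal(nrow(candidateTable(res)), 560)
  }
})

test_that("the winner does not depend on candidate evaluation order", {
  coh <- plantedCohort(120, seed = 9)
  x <- cohortLayers(coh)$expression
  sv <- cohortSurvival(coh)
  g1 <- clusterGridSpec(c("euclidean", "manhattan"), c("ward_d", "average"),
                        kRange = 2:4)
  g2 <- clusterGridSpec(c("manhattan", "euclidean"), c("average", "ward_d"),
                        kRange = 4:2)
  cfg <- evalConfig(searchB = 20, seed = 3)
  w1 <- winningParams(clusterGridSearch(x, sv, grid = g1, evalCfg = cfg))
  w2 <- winningParams(clusterGridSearch(x, sv, grid = g2, evalCfg = cfg))
  expect_equal(w1[c("metric", "linkage", "k")],
               w2[c("metric", "linkage", "k")])
})

test_that("one-hot coding lays out clusters as binary indicator columns", {
  l1 <- makeLabels(c(1, 2, 1), 2)
  l2 <- makeLabels(c(1, 2, 3), 3)
  oh <- oneHotClusterMatrix(list(A = l1, B = l2))
  v <- omicsValues(oh)
  expect_equal(ncol(v), 5)
  expect_true(all(rowSums(v) == 2))
  expect_equal(unname(v[, "A_cluster1"]), c(1, 0, 1))
  expect_equal(unname(v[, "A_cluster2"]), c(0, 1, 0))
  expect_equal(omicsLayer(oh), "cluster_binary")
  # the layout used in colon-cancer integration: k = (4, 10, 4) -> 18 columns
  n <- 60
  ids <- sprintf("S%03d", 1:n)
  big <- oneHotClusterMatrix(list(G = makeLabels(rep_len(1:4, n), 4, ids),
                                  M = makeLabels(rep_len(1:10, n), 10, ids),
                                  m = makeLabels(rep_len(1:4, n), 4, ids)))
  expect_equal(ncol(omicsValues(big)), 18)
  expect_true(all(rowSums(omicsValues(big)) == 3))
  # mismatched sample order is rejected
  l3 <- makeLabels(c(1, 2), 2, ids = c("a", "b"))
  expect_error(oneHotClusterMatrix(list(l1, l3)), "sample order")
})

test_that("cluster-of-clusters reproduces a shared partition exactly", {
  withSeed(22, {
    n <- 60
    ids <- sprintf("S%03d", seq_len(n))
    part <- rep_len(1:3, n)
    sets <- list(G = makeLabels(part, 3, ids), M = makeLabels(part, 3, ids),
                 m = makeLabels(part, 3, ids))
    sv <- SurvData(rexp(n, 0.01), rep(1L, n), ids)
    res <- clusterOfClusters(sets, sv,
                             grid = clusterGridSpec("manhattan", "average",
                                                    kRange = 3L),
                             evalCfg = evalConfig(searchB = 10, seed = 4))
    expect_equal(adjustedRand(winningLabels(res)@labels, part), 1)
  })
})

test_that("label sets without survival signal score near chance", {
  withSeed(25, {
    n <- 120
    ids <- sprintf("S%03d", seq_len(n))
    sets <- list(G = makeLabels(sample(rep_len(1:3, n)), 3, ids),
                 M = makeLabels(sample(rep_len(1:2, n)), 2, ids),
                 m = makeLabels(sample(rep_len(1:3, n)), 3, ids))
    sv <- SurvData(rexp(n, 0.01), rep(1L, n), ids)
    res <- clusterOfClusters(sets, sv,
                             grid = clusterGridSpec("manhattan", "average",
                                                    kRange = 2:3),
                             evalCfg = evalConfig(searchB = 60, seed = 6))
    expect_lt(abs(winningParams(res)$score - 0.5), 0.08)
  })
})

test_that("the adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  withSeed(12, {
    for (trial in 1:20) {
      a <- sample(1:3, 30, replace = TRUE)
      b <- sample(1:4, 30, replace = TRUE)
      expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b))
    }
    expect_equal(adjustedRand(1:10, rep(1:5, 2)),
                 mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
  })
})
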