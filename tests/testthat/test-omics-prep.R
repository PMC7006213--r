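om <- function(v, layer = "expression", scale = "fpkm") {
  if (is.null(rownames(v))) rownames(v) <- paste0("s", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("f", seq_len(ncol(v)))
  OmicsMatrix(v, layer, scale)
}

test_that("quality filter removes features strictly above the bad-value cut", {
  # 20 samples; 5% bad is kept ("more than 5%" is removed)
  v <- cbind(a = c(NA, rexp(19) + 1),           # 1/20 = 5% -> kept
             b = c(0, 0, rexp(18) + 1),          # 10% zeros -> removed
             c = rexp(20) + 1)
  x <- om(v)
  kept <- featureIDs(filterLowQuality(x))
  expect_identical(kept, c("a", "c"))

  # derived case: bad fractions 0, 0.05, 0.10, 0.50 on 10x4 with cut 0.05
  v2 <- matrix(1, 10, 4)
  v2[1, 2] <- NA                       # 10% -> removed at default? no: 0.10
  v2[1:5, 4] <- 0
  colnames(v2) <- c("w", "x", "y", "z")
  v2[1, 3] <- NA; v2[2, 3] <- 0        # 0.20
  rownames(v2) <- paste0("s", 1:10)
  out <- filterLowQuality(OmicsMatrix(v2, "expression", "fpkm"),
                          maxBadFrac = 0.10)
  expect_identical(featureIDs(out), c("w", "x"))

  # beta scale: zeros are valid measurements, only NA counts
  vb <- cbind(p = c(0, 0, runif(8)), q = c(NA, NA, runif(8)))
  rownames(vb) <- paste0("s", 1:10)
  outb <- filterLowQuality(OmicsMatrix(vb, "methylation", "beta"),
                           maxBadFrac = 0.1)
  expect_identical(featureIDs(outb), "p")

  expect_error(filterLowQuality(om(matrix(0, 5, 2))), "no features")
})

test_that("coefficient of variation follows the sample-sd definition", {
  v <- cbind(const = c(2, 2, 2), lin = c(1, 2, 3), na = c(1, NA, 3))
  x <- om(v)
  cv <- featureCV(x)
  expect_equal(unname(cv["const"]), 0)
  expect_equal(unname(cv["lin"]), 0.5)
  expect_equal(unname(cv["na"]), sqrt(2) / 2)
  # zero-mean feature reported NA
  v2 <- cbind(zm = c(-1, 0, 1), ok = c(1, 2, 3))
  expect_true(is.na(featureCV(om(v2))["zm"]))
  expect_error(featureCV(om(cbind(bad = c(1, NA, NA), ok = 1:3))),
               "fewer than 2")
})

test_that("feature selection unions the top-CV block with the prior list", {
  withSeed(1, {
    # 100 features with CV exactly 0.01 * rank via mean-1, sd scaled
    n <- 12
    v <- sapply(1:100, function(r) 100 + scale(rnorm(n))[, 1] * 0.01 * r * 100)
    colnames(v) <- sprintf("f%03d", 1:100)
    rownames(v) <- paste0("s", 1:n)
    x <- om(v)
    sel <- selectFeatures(x, 0.25, prior = "f001")  # lowest-CV feature
    expect_equal(ncol(omicsValues(sel)), 26)
    expect_true("f001" %in% featureIDs(sel))
    # top-25% block = the 25 highest CVs
    expect_true(all(sprintf("f%03d", 76:100) %in% featureIDs(sel)))
  })
  # counting example: 8 features, top 25% = 2, prior adds 1 more
  v <- sapply(1:8, function(r) c(1, 1 + r * 0.1, 1 + 2 * r * 0.1, 1, 1))
  colnames(v) <- paste0("g", 1:8); rownames(v) <- paste0("s", 1:5)
  sel <- selectFeatures(om(v), 0.25, prior = "g1")
  expect_equal(ncol(omicsValues(sel)), 3)
  # identity when everything is kept
  expect_identical(featureIDs(selectFeatures(om(v), 1)), colnames(v))
  expect_warning(selectFeatures(om(v), 0.25, prior = "absent"), "absent")
})

test_that("feature selection is monotone in the prior and order-preserving", {
  withSeed(4, {
    v <- matrix(rexp(20 * 30) + 0.5, 20, 30)
    colnames(v) <- sprintf("f%02d", 1:30); rownames(v) <- paste0("s", 1:20)
    x <- om(v)
    s0 <- featureIDs(selectFeatures(x, 0.2))
    s1 <- featureIDs(selectFeatures(x, 0.2, prior = c("f01", "f02", "f03")))
    expect_true(all(s0 %in% s1))
    # output preserves original column order and values untouched
    expect_identical(s1, intersect(colnames(v), s1))
    expect_identical(omicsValues(selectFeatures(x, 0.2))[, s0],
                     v[, s0])
  })
})

test_that("probe aggregation averages non-NA betas and drops X/Y probes", {
  v <- cbind(p1 = c(0.2, 0.3), p2 = c(0.4, 0.5), p3 = c(0.6, 0.1),
             px = c(0.9, 0.9), p4 = c(0.5, NA))
  rownames(v) <- c("s1", "s2")
  x <- OmicsMatrix(v, "methylation", "beta")
  map <- data.frame(probe = c("p1", "p2", "p3", "px", "p4"),
                    gene = c("gA", "gA", "gA", "gX", "gB"),
                    chromosome = c("1", "1", "2", "X", "3"))
  out <- aggregateProbesToGenes(x, map, maxNAFrac = 0.5)
  expect_equal(unname(omicsValues(out)["s1", "gA"]), mean(c(0.2, 0.4, 0.6)))
  expect_false("gX" %in% featureIDs(out))      # only probe on chr X
  expect_equal(unname(omicsValues(out)["s2", "gB"]), NA_real_)
  # NA-heavy probe excluded before averaging under the default 5% cut
  out2 <- aggregateProbesToGenes(x, map, maxNAFrac = 0.05)
  expect_false("gB" %in% featureIDs(out2))
  # per-sample gene value lies within the contributing probes' range
  withSeed(9, {
    vv <- matrix(runif(20 * 6), 20, 6,
                 dimnames = list(paste0("s", 1:20), paste0("q", 1:6)))
    mp <- data.frame(probe = paste0("q", 1:6),
                     gene = rep(c("g1", "g2", "g3"), c(2, 1, 3)),
                     chromosome = "5")
    agg <- aggregateProbesToGenes(OmicsMatrix(vv, "methylation", "beta"), mp)
    for (g in c("g1", "g2", "g3")) {
      pr <- mp$probe[mp$gene == g]
      expect_true(all(omicsValues(agg)[, g] >=
                        apply(vv[, pr, drop = FALSE], 1, min) - 1e-12))
      expect_true(all(omicsValues(agg)[, g] <=
                        apply(vv[, pr, drop = FALSE], 1, max) + 1e-12))
      expect_equal(omicsValues(agg)[, g],
                   rowMeans(vv[, pr, drop = FALSE]))
    }
  })
  expect_error(aggregateProbesToGenes(x, data.frame(probe = "nope",
                                                    gene = "g",
                                                    chromosome = "1")),
               "covers none")
})

test_that("median imputation completes a matrix without touching observed values", {
  v <- cbind(a = c(1, NA, 3, 5), b = c(2, 2, 2, 2))
  rownames(v) <- paste0("s", 1:4)
  out <- imputeMedian(om(v))
  expect_equal(unname(omicsValues(out)[2, "a"]), 3)
  expect_equal(omicsValues(out)[-2, "a"], v[-2, "a"])
})
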