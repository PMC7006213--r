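# Independent oracles, deliberately coded from the definitions rather than
# sharing any machinery with the package implementation.

# Harrell's C by exhaustive pair enumeration: ordered pairs (i, j) with i an
# event and t_j strictly later are usable; concordant if risk_i > risk_j,
# half credit for ties.
oracleHarrell <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# product-limit survivor function as a step-function closure (left limit)
oracleKMleft <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    s <- s * (1 - sum(time == ut[i] & event == 1) / sum(time >= ut[i]))
    surv[i] <- s
  }
  function(t) {
    # S(t-): product over event times strictly before t
    if (!length(ut)) return(1)
    k <- sum(ut < t)
    if (k == 0) 1 else surv[k]
  }
}

# Uno's IPCW C by brute-force double loop with KM censoring weights
oracleUno <- function(trainTime, trainEvent, risk, time, event, tau) {
  G <- oracleKMleft(trainTime, 1 - trainEvent)
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      w <- 1 / G(time[i])^2
      den <- den + w
      if (risk[i] > risk[j]) num <- num + w
      else if (risk[i] == risk[j]) num <- num + w / 2
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# two-group log-rank chi-square, direct risk-table computation
oracleLogrank <- function(time, event, group) {
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Naive O(n^3) Lance-Williams agglomerator, coefficient-table formulation.
# Clusters are kept in creation order (leaves in input order, merged
# clusters appended); ties in the minimal distance go to the
# lexicographically smallest (older, older) pair. Returns the partition
# (labels renumbered by first appearance) for every k.
oracleAgglomerate <- function(D, linkage) {
  D <- as.matrix(D)
  n <- nrow(D)
  squared <- linkage %in% c("ward_d2", "median", "centroid")
  if (squared) D <- D^2
  clusters <- lapply(seq_len(n), function(i) i)  # member lists
  cd <- D                                         # current cluster distances
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL; bestVal <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (cd[i, j] < bestVal) { bestVal <- cd[i, j]; best <- c(i, j) }
    }
    a <- best[1]; b <- best[2]
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    dab <- cd[a, b]
    newd <- numeric(m)
    for (k in seq_len(m)) {
      if (k == a || k == b) next
      nk <- length(clusters[[k]])
      co <- switch(linkage,
        single   = c(0.5, 0.5, 0, -0.5),
        complete = c(0.5, 0.5, 0, 0.5),
        average  = c(na / (na + nb), nb / (na + nb), 0, 0),
        mcquitty = c(0.5, 0.5, 0, 0),
        ward_d   = ,
        ward_d2  = c((na + nk), (nb + nk), -nk, 0) / (na + nb + nk),
        centroid = c(na / (na + nb), nb / (na + nb),
                     -na * nb / (na + nb)^2, 0),
        median   = c(0.5, 0.5, -0.25, 0))
      newd[k] <- co[1] * cd[a, k] + co[2] * cd[b, k] + co[3] * dab +
        co[4] * abs(cd[a, k] - cd[b, k])
    }
    merged <- c(clusters[[a]], clusters[[b]])
    keep <- setdiff(seq_len(m), c(a, b))
    clusters <- c(clusters[keep], list(merged))
    cd <- rbind(cbind(cd[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- match(lab, unique(lab))
  }
  partitions
}

# small random survival instance (ties in times and risks allowed)
randomSurvInstance <- function(n, tieProb = 0.3) {
  time <- sample.int(max(3, n %/% 2 + 2), n, replace = TRUE)
  event <- rbinom(n, 1, 0.7)
  risk <- if (runif(1) < tieProb) sample.int(3, n, replace = TRUE)
          else rnorm(n)
  list(time = as.numeric(time), event = as.integer(event),
       risk = as.numeric(risk))
}

# quick clinical table for design tests
makeClinical <- function(n, seed = 1) {
  withSeed(seed, {
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      t_stage = sample(rep(c("T1", "T2", "T3", "T4a", "T4b"), length.out = n)),
      n_stage = sample(rep(c("N0", "N1a", "N1b", "N2a", "N2b"), length.out = n)),
      m_stage = sample(rep(c("M0", "M1"), length.out = n)),
      age_years = sample(31:90, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

makeLabels <- function(labels, k, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(labels))
  new("ClusterLabels", labels = as.integer(labels), k = as.integer(k),
      params = list(), sampleIDs = ids)
}
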