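test_that("reference-tree ranks are uniform for an exact Kingman sampler", {
  set.seed(601)
  trs <- kingmanExactTreeSet(n = 100, L = 100, s = 5)
  ranks <- referenceTreeRanks(trs)
  expect_true(all(ranks >= 1 & ranks <= 101))
  rv <- ruvVerdict(ranks, bins = 10, reps = 1000)
  expect_true(verdict(rv))
  # all posterior samples identical to the truth: pure tie-randomised ranks
  set.seed(602)
  truths <- lapply(1:40, function(i) simulateCoalescent(5, 1))
  idSamples <- lapply(truths, function(t) lapply(1:30, function(j) t))
  trsId <- treeReplicateSet(truths, idSamples, simulateCoalescent(5, 1))
  rId <- referenceTreeRanks(trsId)
  expect_true(all(rId >= 1 & rId <= 31))
  expect_gte(length(unique(rId)), 10L)  # tie randomisation spreads the ranks
  # a biased sampler (caterpillar-leaning) fails RUV
  set.seed(603)
  cat5 <- parseNewick("((((t1:1,t2:1):1,t3:2):1,t4:3):1,t5:4);")
  biased <- lapply(1:100, function(i) lapply(1:60, function(j) {
    if (runif(1) < 0.7) cat5 else simulateCoalescent(5, 1)
  }))
  truthsB <- lapply(1:100, function(i) simulateCoalescent(5, 1))
  trsB <- treeReplicateSet(truthsB, biased, simulateCoalescent(5, 1))
  expect_false(verdict(ruvVerdict(referenceTreeRanks(trsB), bins = 10,
                                  reps = 1000)))
})

test_that("tree coverage via RF distances hits the binomial band", {
  set.seed(604)
  trs <- kingmanExactTreeSet(n = 100, L = 100, s = 5)
  cr <- treeCoverage(trs, alpha = 0.95)
  expect_gte(coveredCount(cr), 90L)
  expect_lte(coveredCount(cr), 100L)
  # constant metric: interval (c, c); covered iff d0 = c
  constMetric <- function(a, b) 3
  crC <- treeCoverage(trs, metric = constMetric, alpha = 0.95)
  expect_equal(coveredCount(crC), 100L)
  # shifted sampler: posterior distances systematically off -> undercoverage
  shiftMetric <- function(a, b) rfDistance(a, b)
  set.seed(605)
  truths <- lapply(1:50, function(i) simulateCoalescent(5, 1))
  refs <- lapply(1:50, function(i) simulateCoalescent(5, 1))
  # posterior "samples" are copies of the reference: distances collapse to 0
  samples <- lapply(1:50, function(i) lapply(1:30, function(j) refs[[i]]))
  trsS <- treeReplicateSet(truths, samples, refs)
  crS <- treeCoverage(trsS)
  expect_lt(coveredCount(crS), binomialCentralInterval(50, 0.95)[["lower"]])
})

test_that("scalar functionals bridge tree replicates into the calibrators", {
  set.seed(606)
  trs <- kingmanExactTreeSet(n = 100, L = 400, s = 5)
  rs <- functionalReplicates(trs, rootHeight, "root_height")
  cr <- coverageCount(rs, 0.95)
  expect_true(coveredCount(cr) >= 90 && coveredCount(cr) <= 100)
  expect_error(functionalReplicates(trs, tipCount, "tip_count"),
               "zero-variance")
  # biased sampler fails RUV on tree length
  set.seed(607)
  truths <- lapply(1:60, function(i) simulateCoalescent(5, 1))
  stretch <- lapply(truths, function(t) lapply(1:50, function(j) {
    s <- simulateCoalescent(5, 1); s$edge.length <- s$edge.length * 2; s
  }))
  trsB <- treeReplicateSet(truths, stretch, simulateCoalescent(5, 1))
  rsB <- functionalReplicates(trsB, treeLength, "tree_length")
  expect_false(verdict(ruvVerdict(sbcRanks(rsB), bins = 10, reps = 1000)))
})

test_that("the shared-clade Poisson law gives its limiting constants", {
  law <- sharedCladeLaw(300, 100)       # cherries = s/3
  expect_equal(law$rate, 1 / 6)
  expect_equal(law$asymptoticRate, 1 / 6)
  expect_equal(round(100 * law$pNoShared), 85)
  expect_equal(sharedCladeLaw(100, 25)$rate, 0.125)
  expect_error(sharedCladeLaw(3, 1))
  # empirical: independent Yule tree pairs share no clades at ~exp(-c/2s)
  set.seed(608)
  s <- 150; nPairs <- 800
  noShare <- pExpect <- numeric(nPairs)
  for (i in seq_len(nPairs)) {
    a <- simulateYuleNtips(1, s); b <- simulateYuleNtips(1, s)
    shared <- 2 * (s - 2) - rfDistance(a, b)   # |intersection| * 2
    noShare[i] <- shared == 0
    pExpect[i] <- exp(-sharedCladeLaw(s, cherryCount(a))$rate)
  }
  se <- sd(noShare) / sqrt(nPairs)
  # the Poisson law is asymptotic in s: allow a 1-point finite-s deviation
  expect_lt(abs(mean(noShare) - mean(pExpect)), 3 * se + 0.01)
})

test_that("clade supports average correctly and sum to s - 2", {
  set.seed(609)
  tr <- simulateCoalescent(5, 1)
  sup1 <- cladeSupport(lapply(1:20, function(i) tr))
  expect_true(all(sup1 == 1))
  expect_equal(sum(sup1), 5 - 2)
  a <- parseNewick("((t1:1,t2:1):1,(t3:1,t4:1):1);")
  b <- parseNewick("((t1:1,t3:1):1,(t2:1,t4:1):1);")
  sup2 <- cladeSupport(rep(list(a, b), 10))
  expect_true(all(sup2 == 0.5))
  expect_equal(sum(sup2), 4 - 2)
  samples <- lapply(1:50, function(i) simulateCoalescent(6, 1))
  expect_equal(sum(cladeSupport(samples)), 6 - 2)
  bad <- c(samples[1], list(simulateCoalescent(5, 1)))
  expect_error(cladeSupport(bad), "mixed|taxon")
  # prior support of a named clade matches brute-force history enumeration
  enumCladeProb <- function(s, k) {
    # P(a fixed k-subset forms a clade) by recursion over coalescent merges
    recurse <- function(groups) {
      # groups: vector of labels, "in" tips of the target set, "out" others
      n <- length(groups)
      if (sum(groups == "in") == 1L) return(1)  # target collapsed to one
      tot <- choose(n, 2)
      p <- 0
      idx <- seq_len(n)
      for (i in idx) for (j in idx[idx > i]) {
        gi <- groups[i]; gj <- groups[j]
        if (gi == "in" && gj == "in") {
          g2 <- groups[-j]
          p <- p + recurse(g2) / tot
        } else if (gi == "out" && gj == "out") {
          p <- p + recurse(groups[-j]) / tot
        }
        # an in-out merge kills the clade: contributes 0
      }
      p
    }
    recurse(c(rep("in", k), rep("out", s - k)))
  }
  pAB <- enumCladeProb(4, 2)
  set.seed(610)
  draws <- lapply(1:4000, function(i) simulateCoalescent(4, 1))
  sup <- cladeSupport(draws)
  taxa <- sort(draws[[1]]$tip.label)
  key <- paste(sort(match(c("t1", "t2"), taxa)), collapse = ",")
  obs <- if (key %in% names(sup)) as.numeric(sup[key]) else 0
  expect_lt(abs(obs - pAB), 3 * sqrt(pAB * (1 - pAB) / 4000))
})

test_that("clade-support calibration passes exact samplers, fails biased ones", {
  set.seed(611)
  trs <- kingmanExactTreeSet(n = 60, L = 80, s = 5)
  cc <- cladeCalibration(trs)
  expect_true(verdict(cc))
  expect_equal(sum(cc@bins$nClades), nrow(cc@table))
  # every sample equals the truth: one bin at support 1 with true fraction 1
  set.seed(612)
  truths <- lapply(1:20, function(i) simulateCoalescent(5, 1))
  idSamples <- lapply(truths, function(t) lapply(1:25, function(j) t))
  ccId <- cladeCalibration(treeReplicateSet(truths, idSamples, truths[[1]]))
  top <- ccId@bins[ccId@bins$nClades > 0, ]
  expect_equal(nrow(top), 1L)
  expect_equal(top$mid, 0.95)
  expect_equal(top$fracTrue, 1)
  # sampler whose trees never share a clade with the truth: verdict fail
  set.seed(613)
  disjoint <- lapply(truths, function(t) lapply(1:25, function(j) {
    repeat {
      cand <- simulateCoalescent(5, 1)
      if (rfDistance(cand, t) == 2 * (5 - 2)) return(cand)
    }
  }))
  ccD <- cladeCalibration(treeReplicateSet(truths, disjoint, truths[[1]]))
  expect_false(verdict(ccD))
  # unequal tip counts are refused
  mixed <- treeReplicateSet(
    list(simulateCoalescent(5, 1), simulateCoalescent(6, 1)),
    list(lapply(1:25, function(j) simulateCoalescent(5, 1)),
         lapply(1:25, function(j) simulateCoalescent(6, 1))),
    simulateCoalescent(5, 1), taxa = paste0("t", 1:6))
  expect_error(cladeCalibration(mixed), "same size")
})

test_that("relabeling all trees of a replicate consistently leaves ranks alone", {
  set.seed(614)
  trs <- kingmanExactTreeSet(n = 30, L = 40, s = 5, shared = FALSE)
  relabel <- function(t, perm) {
    t$tip.label <- perm[t$tip.label]; t
  }
  perm <- setNames(paste0("t", c(3, 5, 1, 2, 4)), paste0("t", 1:5))
  trs2 <- treeReplicateSet(
    lapply(trs@truths, relabel, perm = perm),
    lapply(trs@samples, function(ss) lapply(ss, relabel, perm = perm)),
    lapply(trs@references, relabel, perm = perm))
  set.seed(777); r1 <- referenceTreeRanks(trs)
  set.seed(777); r2 <- referenceTreeRanks(trs2)
  expect_equal(r1, r2)
})
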