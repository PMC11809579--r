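test_that("log-normal sampling matches its analytic moments", {
  set.seed(201)
  x <- sampleLogNormal(1e5, logNormalParams(-3.25, 0.2))
  expect_equal(median(x), exp(-3.25), tolerance = 0.01)
  y <- sampleLogNormal(1e5, logNormalParams(-2.5, 0.5))
  expect_equal(mean(y), exp(-2.5 + 0.5^2 / 2), tolerance = 0.02)
  z <- sampleLogNormal(100, logNormalParams(-1, 1e-12))
  expect_equal(z, rep(exp(-1), 100), tolerance = 1e-9)
  expect_error(logNormalParams(0, -1))
})

test_that("Yule root-height expectation follows the harmonic formula", {
  expect_equal(yuleRootHeightExpectation(1, 2), 0.5)
  expect_equal(yuleRootHeightExpectation(1, 4), 1 / 2 + 1 / 3 + 1 / 4)
  expect_equal(yuleRootHeightExpectation(2, 2), 0.25)
  expect_error(yuleRootHeightExpectation(1, 1), "s >= 2")
})

test_that("tip-conditioned Yule simulator hits the expected root heights", {
  set.seed(202)
  grid <- expand.grid(lambda = c(0.5, 1), s = c(2, 3, 6))
  for (i in seq_len(nrow(grid))) {
    lam <- grid$lambda[i]; s <- grid$s[i]
    h <- replicate(4000, rootHeight(simulateYuleNtips(lam, s)))
    se <- sd(h) / sqrt(length(h))
    expect_lt(abs(mean(h) - yuleRootHeightExpectation(lam, s)), 3.5 * se)
    expect_true(all(replicate(5, tipCount(simulateYuleNtips(lam, s)) == s)))
  }
})

test_that("origin-conditioned Yule tip counts follow the geometric law", {
  set.seed(203)
  lam <- 0.3; tau <- 4
  N <- replicate(2e4, tipCount(simulateYuleOrigin(lam, tau)))
  expect_equal(mean(N), exp(lam * tau), tolerance = 0.03)
  p <- exp(-lam * tau)
  obs <- table(factor(pmin(N, 30), levels = 1:30))
  probs <- c(stats::dgeom(0:28, p), 1 - stats::pgeom(28, p))
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
  # tau -> 0: a single surviving lineage
  expect_true(all(replicate(10, tipCount(simulateYuleOrigin(1, 1e-9))) == 1))
  # origin age is carried on the tree
  t1 <- simulateYuleOrigin(1, 2)
  if (tipCount(t1) >= 2) expect_equal(originAge(t1), 2, tolerance = 1e-9)
})

test_that("Kingman simulator matches coalescent expectations", {
  set.seed(204)
  h2 <- replicate(5000, rootHeight(simulateCoalescent(2, 1)))
  expect_lt(abs(mean(h2) - 1), 3.5 * sd(h2) / sqrt(5000))
  h5 <- replicate(5000, rootHeight(simulateCoalescent(5, 1)))
  expect_lt(abs(mean(h5) - 2 * (1 - 1 / 5)), 3.5 * sd(h5) / sqrt(5000))
  tr <- simulateCoalescent(7, 1)
  expect_equal(tipCount(tr), 7L)
  expect_equal(tr$Nnode, 6L)
  expect_silent(validateTimeTree(tr))
})

test_that("phylogenetic BM has the shared-path covariance structure", {
  set.seed(205)
  t2 <- parseNewick("(A:1.5,B:1.5);")
  X <- t(replicate(2e4, simulatePhyloBM(t2, r = 0.8, y0 = 1)))
  expect_equal(var(X[, "A"]), 0.8 * 1.5, tolerance = 0.05)
  expect_lt(abs(cov(X[, "A"], X[, "B"])), 0.03)
  expect_equal(mean(X[, "A"]), 1, tolerance = 0.03)

  t3 <- parseNewick("((A:1,B:1):1,C:2);")
  Y <- t(replicate(2e4, simulatePhyloBM(t3, r = 1, y0 = 0)))
  expect_equal(unname(cov(Y)[c("A", "B", "C"), c("A", "B", "C")]),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3), tolerance = 0.08)

  flat <- simulatePhyloBM(t3, r = 1e-12, y0 = 0.7)
  expect_equal(unname(flat), rep(0.7, 3), tolerance = 1e-4)
})

test_that("simulated BM traits have the pruning log-density of their tree", {
  set.seed(206)
  for (rep in 1:5) {
    tr <- simulateCoalescent(5, 1)
    x <- simulatePhyloBM(tr, 0.5, 0.2)
    C <- ape::vcv(tr)[names(x), names(x)]
    dense <- -5 / 2 * log(2 * pi) -
      0.5 * as.numeric(determinant(0.5 * C)$modulus) -
      0.5 * drop(t(x - 0.2) %*% solve(0.5 * C) %*% (x - 0.2))
    expect_equal(phyloBMLogDensity(x, tr, 0.5, 0.2), dense, tolerance = 1e-8)
  }
})

test_that("rejection sampling counts attempts and matches the geometric law", {
  set.seed(207)
  always <- rejectionSample(function() 1, function(x) TRUE)
  expect_equal(always$attempts, 1L)
  expect_error(rejectionSample(function() 1, function(x) FALSE,
                               maxAttempts = 100L), "predicate")
  lam <- 0.3; tau <- 4
  p <- exp(-lam * tau)
  accProb <- stats::pgeom(19, p) - stats::pgeom(3, p)  # tip count in [5, 20]
  att <- replicate(1500, rejectionSample(
    function() simulateYuleOrigin(lam, tau), tipCountWindow(5, 20))$attempts)
  se <- sd(att) / sqrt(length(att))
  expect_lt(abs(mean(att) - 1 / accProb), 3.5 * se)
})

test_that("simulators are reproducible from a seed", {
  set.seed(99); a <- writeNewick(simulateYuleNtips(0.5, 8))
  set.seed(99); b <- writeNewick(simulateYuleNtips(0.5, 8))
  expect_identical(a, b)
  set.seed(98); c1 <- writeNewick(simulateCoalescent(6, 2))
  set.seed(98); c2 <- writeNewick(simulateCoalescent(6, 2))
  expect_identical(c1, c2)
})

test_that("moment check covers a correct target and flags a wrong one", {
  set.seed(208)
  # constant statistic with tiny jitter: every interval covers
  mc0 <- momentCheck(function() 1 + rnorm(1, 0, 1e-15), identity, 1,
                     batches = 20, batchSize = 50)
  expect_equal(mc0$fraction, 1)
  # correct Yule target: covered fraction near the level
  mc1 <- momentCheck(function() simulateYuleNtips(1, 3), rootHeight,
                     yuleRootHeightExpectation(1, 3),
                     batches = 60, batchSize = 200)
  expect_gte(mc1$covered, qbinom(0.005, 60, 0.95))
  # doubled target: far below the bounds
  mc2 <- momentCheck(function() simulateYuleNtips(1, 3), rootHeight,
                     2 * yuleRootHeightExpectation(1, 3),
                     batches = 60, batchSize = 200)
  expect_lt(mc2$fraction, 0.5)
  # degenerate batches are excluded with a warning
  expect_warning(momentCheck(function() 1, identity, 1,
                             batches = 5, batchSize = 10), "zero-variance")
})

test_that("replicate sets are written as plain-text artifacts", {
  set.seed(209)
  dir <- file.path(tempdir(), "repset-test")
  trees <- lapply(1:3, function(i) simulateCoalescent(4, 1))
  traits <- lapply(trees, simulatePhyloBM, r = 1, y0 = 0)
  params <- data.frame(replicate = 1:3, lambda = 0.1, r = 1,
                       tau = NA, y0 = 0)
  writeReplicateSet(dir, trees, traits, params,
                    manifest = list(seed = 209, model = "test"))
  expect_true(file.exists(file.path(dir, "rep002.nwk")))
  expect_true(file.exists(file.path(dir, "rep002_traits.tsv")))
  back <- parseNewick(readLines(file.path(dir, "rep001.nwk")))
  expect_equal(rfDistance(back, trees[[1]]), 0)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 209)
  unlink(dir, recursive = TRUE)
})
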