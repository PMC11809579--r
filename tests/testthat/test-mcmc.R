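test_that("scale proposal satisfies detailed balance and targets correctly", {
  set.seed(401)
  p <- scaleProposal(2, tuning = 0.999999)
  expect_equal(p$x, 2, tolerance = 1e-4)
  expect_equal(p$logHR, 0, tolerance = 1e-4)
  # forward density times exp(logHR) equals the reverse density on a grid
  tun <- 0.6
  cnorm <- 1 / (1 / tun - tun)
  for (x in c(0.5, 1, 3)) for (u in c(0.7, 1.2, 1.5)) {
    xp <- x * u
    qf <- cnorm / x          # density of x' given x
    qr <- cnorm / xp         # density of x given x'
    expect_equal(qf * exp(-log(u)), qr, tolerance = 1e-12)
  }
  # MH with this kernel alone reproduces a closed-form log-normal target
  set.seed(402)
  x <- 0.05
  lp <- function(z) logNormalLogDensity(z, logNormalParams(-3.25, 0.2))
  cur <- lp(x)
  keep <- numeric(2000)
  for (i in 1:20000) {
    pr <- scaleProposal(x, 0.75)
    new <- lp(pr$x)
    if (log(runif(1)) < new - cur + pr$logHR) { x <- pr$x; cur <- new }
    if (i %% 10 == 0) keep[i / 10] <- x
  }
  thin <- keep[seq(1, 2000, by = 4)]
  expect_gt(ks.test(thin, plnorm, -3.25, 0.2)$p.value, 0.01)
})

test_that("tree proposals keep trees valid and sample the coalescent prior", {
  set.seed(403)
  tr <- simulateCoalescent(6, 1)
  cur <- tr
  for (i in 1:400) {
    mv <- switch(1 + i %% 3,
                 nodeSlideProposal(cur),
                 narrowExchangeProposal(cur),
                 treeScaleProposal(cur))
    if (!is.null(mv)) {
      expect_silent(validateTimeTree(mv$tree))
      cur <- mv$tree
    }
  }
  expect_setequal(cur$tip.label, tr$tip.label)

  # 2-tip tree: node slide falls through to a root move
  t2 <- parseNewick("(A:1,B:1);")
  mv2 <- nodeSlideProposal(t2)
  if (!is.null(mv2)) expect_true(rootHeight(mv2$tree) != 1)

  # MH prior sampling matches coalescent expectations (s = 5, Ne = 1)
  set.seed(404)
  out <- mhRun(makeCoalescentModel(5, 1), 30000, 10)
  h <- burninThin(out$trace$root_height, 0.1, 300)
  expect_lt(abs(mean(h) - 1.6), 0.12)  # ~3 effective-sample SEs

  # RF-to-fixed-tree distribution matches direct simulation
  set.seed(405)
  ref <- simulateCoalescent(5, 1)
  direct <- replicate(3000, rfDistance(ref, simulateCoalescent(5, 1)))
  tt <- burninThin(out, 0.1, 500)
  mh <- vapply(tt$trees, function(s) rfDistance(ref, parseNewick(s)),
               numeric(1))
  pDirect <- table(factor(direct, levels = c(0, 2, 4, 6))) / length(direct)
  gof <- suppressWarnings(
    chisq.test(table(factor(mh, levels = c(0, 2, 4, 6))), p = pDirect))
  expect_gt(gof$p.value, 0.01)
})

test_that("narrow exchange reaches all 3-tip topologies uniformly", {
  set.seed(406)
  out <- mhRun(makeCoalescentModel(3, 1), 30000, 10)
  tt <- burninThin(out, 0.1, 1000)
  tops <- vapply(tt$trees, function(s) {
    p <- parseNewick(s)
    cs <- cladeSet(p)
    paste(cs, collapse = "")
  }, "")
  freq <- table(tops) / length(tops)
  expect_length(freq, 3L)
  expect_true(all(abs(freq - 1 / 3) < 0.06))
})

test_that("the MH engine reproduces conjugate posteriors and guards caches", {
  set.seed(407)
  y <- 1.2
  out <- mhRun(makeNormalNormalModel(y), 20000, 10)
  th <- burninThin(out$trace$theta, 0.1, 500)
  post <- normalNormalPosterior(y)
  expect_lt(abs(mean(th) - post$mean), 3 * post$sd / sqrt(200))
  expect_equal(sd(th), post$sd, tolerance = 0.15)
  expect_equal(nrow(out$trace), 2001L)
  expect_true(all(diff(out$trace$Sample) == 10))

  # no-data Yule-BM chain recovers both priors
  set.seed(408)
  prior <- mhRun(makeYuleBMModel(traits = NULL, s = 8, tau = 60), 20000, 10)
  lam <- burninThin(prior$trace$lambda, 0.1, 300)
  expect_gt(ks.test(lam, plnorm, -3.25, 0.2)$p.value, 0.01)
  r <- burninThin(prior$trace$r, 0.1, 300)
  expect_gt(suppressWarnings(ks.test(r, plnorm, -2.5, 0.5)$p.value), 0.01)

  # zero-weight topology moves: topology never changes
  set.seed(409)
  tr <- simulateYuleNtips(0.1, 5)
  tr$tip.label <- paste0("t", 1:5)
  x <- simulatePhyloBM(tr, 0.2, 0)
  fixed <- makeYuleBMModel(traits = x, s = 5, tau = originAge(tr) + 1,
                           weights = c(3, 3, 2, 0, 0), logTrees = TRUE,
                           initTree = tr)
  outf <- mhRun(fixed, 2000, 20)
  rf <- vapply(outf$trees, function(s) rfDistance(parseNewick(s), tr),
               numeric(1))
  expect_true(all(rf == 0))

  # a -Inf initial density aborts before iterating
  badModel <- makeNormalNormalModel(1)
  badModel$init <- function() list(theta = 0, lp = -Inf)
  expect_error(mhRun(badModel, 100), "non-finite")
})

test_that("fixed-tree BM-rate posterior matches 1-D quadrature", {
  set.seed(410)
  tr <- parseNewick("(t1:3,t2:3);")
  y <- simulatePhyloBM(tr, 0.2, 0)
  m <- makeYuleBMModel(traits = y, s = 2, tau = 10,
                       weights = c(3, 3, 0, 0, 0), initTree = tr)
  out <- mhRun(m, 40000, 10)
  rs <- burninThin(out$trace$r, 0.1, 500)
  post <- function(r) exp(logNormalLogDensity(r, logNormalParams(-2.5, 0.5)) +
                            phyloBMLogDensity(y, tr, r, 0))
  Z <- integrate(Vectorize(post), 0, Inf)$value
  cdf <- Vectorize(function(q) integrate(Vectorize(post), 0, q)$value / Z)
  expect_gt(ks.test(rs, cdf)$p.value, 0.01)
})

test_that("ESS tracks the information content of a chain", {
  set.seed(411)
  hit <- 0L
  for (i in 1:40) {
    e <- ess(rnorm(5000))
    if (e / 5000 > 0.8 && e / 5000 < 1.2) hit <- hit + 1L
  }
  expect_gte(hit, 36L)  # iid draws: ESS ~ N in the vast majority of runs
  # AR(1), rho = 0.5: ESS ~ N (1-rho)/(1+rho) = N/3
  x <- as.numeric(arima.sim(list(ar = 0.5), 40000))
  expect_equal(ess(x) / 40000, 1 / 3, tolerance = 0.2)
  expect_error(ess(rep(1, 100)), "constant")
  expect_error(ess(rnorm(5)), "at least 10")
  # cross-check against an independent estimator
  if (requireNamespace("coda", quietly = TRUE)) {
    y <- as.numeric(arima.sim(list(ar = 0.3), 20000))
    expect_equal(ess(y), unname(coda::effectiveSize(y)), tolerance = 0.15)
  }
})

test_that("burn-in and thinning keep L equidistant post-burn-in rows", {
  idx <- burninThinIndices(10000, 0.1, 200)
  expect_length(idx, 200L)
  expect_equal(idx[1], 1001)
  expect_equal(idx[200], 10000)
  expect_true(all(diff(idx) >= 1))
  expect_equal(burninThinIndices(100, 0, 100), 1:100)  # identity
  expect_equal(burninThinIndices(100, 0.1, 1), 100)    # L = 1: last row
  expect_error(burninThinIndices(100, 0.5, 60), "ESS")
  v <- burninThin(1:100, 0.1, 10)
  expect_equal(v[1], 11)
  expect_equal(v[10], 100)
})

test_that("trace logs round-trip through the BEAST-like TSV dialect", {
  set.seed(412)
  out <- mhRun(makeCoalescentModel(4, 1), 500, 10)
  path <- file.path(tempdir(), "trace-test.tsv")
  writeTraceLog(out, path)
  back <- readTraceLog(path, sub("\\.tsv$", ".trees", path))
  expect_equal(back$trace$root_height, out$trace$root_height,
               tolerance = 1e-6)
  expect_length(back$trees, length(out$trees))
  expect_equal(rfDistance(parseNewick(back$trees[5]),
                          parseNewick(out$trees[5])), 0)
  unlink(c(path, sub("\\.tsv$", ".trees", path)))
})
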