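#' Log-normal prior parameters
#'
#' Hyperparameters of a log-normal distribution on a positive rate: `meanlog`
#' is the mean of the log, `sdlog` (> 0) its standard deviation. The default
#' priors of the hierarchical demonstration model are
#' `logNormalParams(-3.25, 0.2)` for the birth rate and
#' `logNormalParams(-2.5, 0.5)` for the trait evolutionary rate.
#'
#' @param meanlog mean of the log.
#' @param sdlog standard deviation of the log, positive.
#' @return a named numeric vector of class `"logNormalParams"`.
#' @export
logNormalParams <- function(meanlog, sdlog) {
  stopifnot(is.finite(meanlog), is.finite(sdlog), sdlog > 0)
  structure(c(meanlog = meanlog, sdlog = sdlog), class = "logNormalParams")
}

#' Draw from a log-normal prior
#'
#' @param n number of draws.
#' @param params a [logNormalParams()] object.
#' @return positive draws with `log(x) ~ Normal(meanlog, sdlog^2)`.
#' @export
sampleLogNormal <- function(n, params) {
  stats::rlnorm(n, params[["meanlog"]], params[["sdlog"]])
}

#' Expected root height of a Yule tree with s tips
#'
#' For a pure-birth process with per-lineage birth rate `lambda`, the expected
#' root age of a tree with `s` tips is `sum_{i=2..s} 1 / (i lambda)`.
#'
#' @param lambda birth rate (> 0).
#' @param s tip count (>= 2).
#' @return expected root height.
#' @export
yuleRootHeightExpectation <- function(lambda, s) {
  stopifnot(lambda > 0)
  if (s < 2) stop("the root height expectation needs s >= 2")
  sum(1 / ((2:s) * lambda))
}

# -- internal simulators on the tt representation ------------------------------

# forward pure birth from one lineage, stopped on reaching s tips; the tree is
# cut right before the (s+1)-lineage event so that time spent with k lineages
# is Exp(k lambda) for every k = 1..s, giving E[root height] = sum 1/(i lambda)
.simYuleNtipsTT <- function(lambda, s) {
  if (s == 1L) return(tt_single(origin = stats::rexp(1, lambda)))
  w <- stats::rexp(s, rate = (1:s) * lambda)   # waits while k = 1..s lineages
  tsplit <- cumsum(w[seq_len(s - 1L)])         # forward times of the s-1 splits
  tend <- tsplit[s - 1L] + w[s]
  .assembleBirthTree(s, tsplit, tend, origin = tend)
}

# forward pure birth from one lineage over a fixed origin age tau; random N
.simYuleOriginTT <- function(lambda, tau) {
  tsplit <- numeric(0)
  t <- stats::rexp(1, lambda)
  k <- 1L
  while (t <= tau) {
    tsplit <- c(tsplit, t)
    k <- k + 1L
    t <- t + stats::rexp(1, k * lambda)
  }
  if (k == 1L) return(tt_single(origin = tau))
  .assembleBirthTree(k, tsplit, tau, origin = tau)
}

# origin-conditioned pure birth rejected until exactly s tips survive at the
# present; attempts abort as soon as the lineage count overshoots (pure birth
# never loses lineages), so each costs O(s). NULL if maxAttempts exhausted.
.simYuleOriginCondTT <- function(lambda, tau, s, maxAttempts = 10000L) {
  for (a in seq_len(maxAttempts)) {
    tsplit <- numeric(s)
    t <- stats::rexp(1, lambda)
    k <- 1L
    while (t <= tau && k <= s) {
      tsplit[k] <- t
      k <- k + 1L
      t <- t + stats::rexp(1, k * lambda)
    }
    if (k == s) {
      if (s == 1L) return(tt_single(origin = tau))
      return(.assembleBirthTree(s, tsplit[seq_len(s - 1L)], tau, origin = tau))
    }
  }
  NULL
}

# build a tt from forward split times of a birth process: at the j-th split a
# uniformly chosen active lineage splits; tip labels assigned uniformly
.assembleBirthTree <- function(s, tsplit, tend, origin = NA_real_) {
  nn <- 2L * s - 1L
  parent <- integer(nn)
  height <- numeric(nn)
  height[(s + 1L):nn] <- tend - tsplit
  act <- integer(s)          # parent id of each active lineage
  act[1L] <- 0L
  nact <- 1L
  for (j in seq_len(s - 1L)) {
    u <- if (nact == 1L) 1L else sample.int(nact, 1L)
    z <- s + j
    parent[z] <- act[u]
    act[u] <- z
    nact <- nact + 1L
    act[nact] <- z
  }
  lab <- sample.int(s)       # uniform random assignment of tips to lineages
  parent[lab] <- act
  kid1 <- integer(nn); kid2 <- integer(nn)
  for (v in seq_len(nn)) {
    p <- parent[v]
    if (p > 0L) {
      if (kid1[p] == 0L) kid1[p] <- v else kid2[p] <- v
    }
  }
  tt_new(s, parent, kid1, kid2, height,
         labels = paste0("t", seq_len(s)), origin = origin, root = s + 1L)
}

# standard Kingman coalescent: k lineages coalesce after Exp(k(k-1)/(2 Ne))
.simCoalescentTT <- function(s, Ne) {
  nn <- 2L * s - 1L
  parent <- integer(nn); kid1 <- integer(nn); kid2 <- integer(nn)
  height <- numeric(nn)
  act <- seq_len(s)
  t <- 0
  z <- s
  for (k in s:2) {
    t <- t + stats::rexp(1, k * (k - 1) / (2 * Ne))
    z <- z + 1L
    pr <- sample.int(k, 2L)
    a <- act[pr[1L]]; b <- act[pr[2L]]
    parent[a] <- z; parent[b] <- z
    kid1[z] <- a; kid2[z] <- b
    height[z] <- t
    act[pr[1L]] <- z
    act[pr[2L]] <- act[k]
    act <- act[seq_len(k - 1L)]
  }
  tt_new(s, parent, kid1, kid2, height,
         labels = paste0("t", seq_len(s)), origin = NA_real_, root = nn)
}

# recursive BM from the root state down; returns tip values in node order 1..s
.simBMTT <- function(tt, r, y0) {
  nn <- 2L * tt$ntip - 1L
  x <- numeric(nn)
  x[tt$root] <- y0
  ord <- rev(tt_postorder(tt))   # parents before children
  h <- tt$height
  for (z in ord) {
    c1 <- tt$kid1[z]; c2 <- tt$kid2[z]
    x[c1] <- x[z] + stats::rnorm(1, 0, sqrt(r * (h[z] - h[c1])))
    x[c2] <- x[z] + stats::rnorm(1, 0, sqrt(r * (h[z] - h[c2])))
  }
  x[seq_len(tt$ntip)]
}

# -- public simulators ---------------------------------------------------------

#' Simulate a Yule (pure-birth) tree conditioned on its tip count
#'
#' Forward simulation from one lineage: while `k` lineages are alive the next
#' split arrives after an `Exp(k lambda)` wait and a uniformly chosen lineage
#' splits; the process is stopped on reaching `s` tips (immediately before the
#' next split would occur), so the expected root height equals
#' [yuleRootHeightExpectation()]. Tip labels `t1..ts` are assigned uniformly at
#' random. The generated stem is kept as the tree's origin age.
#'
#' @param lambda birth rate (> 0).
#' @param s number of tips (>= 2; `s = 1` returns a stem-only tree).
#' @return a `phylo` time tree with `s` tips.
#' @export
simulateYuleNtips <- function(lambda, s) {
  stopifnot(lambda > 0, s >= 1)
  tt_to_phylo(.simYuleNtipsTT(lambda, as.integer(s)))
}

#' Simulate a Yule tree conditioned on its origin age
#'
#' Forward pure-birth from a single lineage starting `tau` time units before the
#' present; the number of surviving tips `N` is random with the geometric law
#' `P(N = k) = exp(-lambda tau) (1 - exp(-lambda tau))^(k-1)`.
#'
#' @param lambda birth rate (> 0).
#' @param tau origin age (> 0).
#' @return a `phylo` time tree with origin age `tau` (root edge).
#' @export
simulateYuleOrigin <- function(lambda, tau) {
  stopifnot(lambda > 0, tau > 0)
  tt_to_phylo(.simYuleOriginTT(lambda, tau))
}

#' Simulate a Kingman coalescent tree
#'
#' With `k` active lineages the next coalescence arrives after an
#' `Exp(k (k-1) / (2 Ne))` wait and a uniformly chosen pair merges. The result
#' is an ultrametric tree without a stem.
#'
#' @param s number of tips (>= 2).
#' @param Ne effective population size (> 0).
#' @return a `phylo` time tree.
#' @export
simulateCoalescent <- function(s, Ne = 1) {
  stopifnot(s >= 2, Ne > 0)
  tt_to_phylo(.simCoalescentTT(as.integer(s), Ne))
}

#' Simulate continuous traits under phylogenetic Brownian motion
#'
#' One trait value per tip, simulated recursively from the root state `y0`:
#' each child state is Normal(parent state, `r` times the branch length).
#' Equivalently the tip vector is multivariate normal with mean `y0` and
#' covariance `r C`, `C` being the shared root-to-MRCA path-length matrix.
#' Trait evolution starts at the root (crown); a stem edge carries none.
#'
#' @param phy an ultrametric `phylo` tree.
#' @param r evolutionary rate (variance per unit time, > 0).
#' @param y0 root (ancestral) state.
#' @return named numeric vector of tip trait values.
#' @export
simulatePhyloBM <- function(phy, r, y0 = 0) {
  stopifnot(r > 0)
  tt <- tt_from_phylo(phy)
  if (tt$ntip == 1L) return(stats::setNames(y0, tt$labels))
  stats::setNames(.simBMTT(tt, r, y0), tt$labels)
}

#' Rejection-sample a simulator through a predicate
#'
#' Repeatedly draws from `simulate` until `predicate` returns `TRUE`, recording
#' the number of attempts. Rejection filters of this kind (e.g. tip-count
#' windows) change the effective prior of the draws and are the deliberate
#' misspecification device of the scenario presets.
#'
#' @param simulate zero-argument function returning a draw.
#' @param predicate function of a draw returning `TRUE` to accept.
#' @param maxAttempts abort after this many failures.
#' @return list with elements `draw` and `attempts`.
#' @export
rejectionSample <- function(simulate, predicate, maxAttempts = 10000L) {
  stopifnot(maxAttempts >= 1)
  for (i in seq_len(maxAttempts)) {
    x <- simulate()
    if (isTRUE(predicate(x))) return(list(draw = x, attempts = i))
  }
  stop("rejection sampling exhausted ", maxAttempts,
       " attempts without satisfying the predicate")
}

#' Tip-count window predicate
#'
#' @param lo,hi inclusive tip-count bounds.
#' @return a predicate on `phylo` trees for [rejectionSample()].
#' @export
tipCountWindow <- function(lo, hi) {
  force(lo); force(hi)
  function(phy) {
    n <- tipCount(phy)
    n >= lo && n <= hi
  }
}

#' Confidence-interval moment check for a simulator
#'
#' The simulator-validation protocol: draw `batches` independent batches of
#' `batchSize` simulations, compute the batch statistic mean and its
#' `level`-confidence interval (mean +/- z * SE), and report how often the
#' theoretical value is covered. For a correct simulator the covered-batch
#' count is Binomial(`batches`, `level`), so it should fall within
#' [binomialCentralInterval()] bounds.
#'
#' @param simulate zero-argument function returning one simulated object.
#' @param statistic function mapping a simulated object to a scalar.
#' @param theoretical the theoretical value of the statistic's expectation.
#' @param batches number of batches (>= 2).
#' @param batchSize simulations per batch (>= 2).
#' @param level confidence level in (0, 1).
#' @return list with `fraction` covered, integer `covered` count, logical
#'   vector `hits`, per-batch `lower`/`upper`, and indices of `degenerate`
#'   (zero-variance, excluded) batches.
#' @export
momentCheck <- function(simulate, statistic, theoretical,
                        batches = 100L, batchSize = 400L, level = 0.95) {
  stopifnot(batches >= 2, batchSize >= 2, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lower <- upper <- numeric(batches)
  hits <- logical(batches)
  degenerate <- integer(0)
  for (b in seq_len(batches)) {
    vals <- vapply(seq_len(batchSize), function(j) statistic(simulate()),
                   numeric(1))
    m <- mean(vals)
    se <- stats::sd(vals) / sqrt(batchSize)
    if (se == 0) {
      degenerate <- c(degenerate, b)
      lower[b] <- upper[b] <- m
      hits[b] <- NA
      next
    }
    lower[b] <- m - z * se
    upper[b] <- m + z * se
    hits[b] <- theoretical >= lower[b] && theoretical <= upper[b]
  }
  if (length(degenerate))
    warning(length(degenerate),
            " zero-variance batch(es) excluded from the moment check")
  ok <- !is.na(hits)
  list(fraction = mean(hits[ok]), covered = sum(hits[ok]), hits = hits,
       lower = lower, upper = upper, degenerate = degenerate,
       batches = sum(ok), level = level)
}

#' Write a replicate set to disk
#'
#' Materialises the simulation stage of the validation pipeline as plain-text
#' artifacts: one Newick file and one trait TSV (`taxon`, `value`) per
#' replicate, a `parameters.tsv` with the generating values, and a
#' `manifest.json` with seeds and settings.
#'
#' @param dir output directory (created if missing).
#' @param trees list of `phylo` trees.
#' @param traits list of named trait vectors (or `NULL`).
#' @param params data.frame of generating parameters, one row per replicate.
#' @param manifest named list stored as JSON.
#' @return `dir`, invisibly.
#' @export
writeReplicateSet <- function(dir, trees, traits = NULL, params, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(trees)
  for (i in seq_len(n)) {
    writeLines(writeNewick(trees[[i]]),
               file.path(dir, sprintf("rep%03d.nwk", i)))
    if (!is.null(traits)) {
      df <- data.frame(taxon = names(traits[[i]]), value = unname(traits[[i]]))
      utils::write.table(df, file.path(dir, sprintf("rep%03d_traits.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(params, file.path(dir, "parameters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
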