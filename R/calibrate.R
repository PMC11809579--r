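#' Highest-posterior-density interval from samples
#'
#' The shortest interval containing at least `alpha` of the draws: over all
#' windows of `m = ceiling(alpha * L)` consecutive sorted samples, the one of
#' minimal width (ties broken towards the lowest start index).
#'
#' @param samples numeric draws (>= 20).
#' @param alpha credibility level in (0, 1).
#' @return named numeric `c(lower, upper)`.
#' @export
hpdInterval <- function(samples, alpha = 0.95) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  L <- length(samples)
  if (L < 20L) stop("HPD estimation needs at least 20 samples")
  xs <- sort(samples)
  m <- ceiling(alpha * L)
  k <- L - m + 1L                      # number of candidate windows
  widths <- xs[m:L] - xs[seq_len(k)]
  i <- which.min(widths)               # which.min takes the lowest index on ties
  c(lower = xs[i], upper = xs[i + m - 1L])
}

#' Central binomial acceptance interval for coverage counts
#'
#' Under a correct implementation the number of replicates whose
#' `alpha`-credibility interval covers the truth is Binomial(`n`, `alpha`);
#' this returns the central `level` interquantile bounds on that count. For
#' `n = 100, alpha = 0.95` the bounds are `(90, 99)`.
#'
#' @param n number of replicates.
#' @param alpha credibility level of the intervals.
#' @param level central interval mass (default 0.95).
#' @return integer `c(lower, upper)`.
#' @export
binomialCentralInterval <- function(n, alpha, level = 0.95) {
  stopifnot(n >= 1, alpha > 0, alpha < 1, level > 0, level < 1)
  c(lower = stats::qbinom((1 - level) / 2, n, alpha),
    upper = stats::qbinom(1 - (1 - level) / 2, n, alpha))
}

#' Coverage validation of a replicate set
#'
#' Computes each replicate's HPD interval at level `alpha`, counts how many
#' contain their generating value (closed-interval membership, so boundary hits
#' count), and attaches the [binomialCentralInterval()] acceptance band.
#'
#' @param rs a [replicateSet()].
#' @param alpha credibility level.
#' @param level acceptance-band mass.
#' @return a [CoverageReport-class].
#' @export
coverageCount <- function(rs, alpha = 0.95, level = 0.95) {
  n <- nReplicates(rs)
  if (n < 2L) stop("coverage needs at least 2 replicates")
  ints <- t(apply(rs@draws, 1L, hpdInterval, alpha = alpha))
  covered <- rs@truths >= ints[, 1L] & rs@truths <= ints[, 2L]
  b <- binomialCentralInterval(n, alpha, level)
  new("CoverageReport", parameter = rs@parameter, covered = covered,
      intervals = ints, alpha = alpha,
      lower = as.integer(b[["lower"]]), upper = as.integer(b[["upper"]]),
      level = level)
}

#' SBC rank of a true value among posterior draws
#'
#' `rank = 1 + #draws strictly below the truth`, with ties among equal values
#' broken by a uniform draw over the tied positions (so exact ties — pervasive
#' for discrete functionals such as RF distances — still yield uniform ranks
#' under correctness). Ranks live on `1..L+1`.
#'
#' @param truth the generating value.
#' @param draws its `L` posterior draws.
#' @return integer rank, with attribute `"tied"` flagging tie-broken ranks.
#' @export
sbcRank <- function(truth, draws) {
  less <- sum(draws < truth)
  ties <- sum(draws == truth)
  r <- 1L + less + (if (ties > 0L) sample.int(ties + 1L, 1L) - 1L else 0L)
  attr(r, "tied") <- ties > 0L
  r
}

#' SBC ranks for a whole replicate set
#'
#' @param rs a [replicateSet()].
#' @return integer ranks with attribute `"L"`.
#' @export
sbcRanks <- function(rs) {
  r <- vapply(seq_len(nReplicates(rs)),
              function(i) as.integer(sbcRank(rs@truths[i], rs@draws[i, ])),
              integer(1))
  attr(r, "L") <- ncol(rs@draws)
  r
}

#' Rank histogram with binomial band
#'
#' Normalised ranks `r / (L + 1)` are binned into `bins` equal-width bins on
#' (0, 1]; each bin count is Binomial(`n`, `1/bins`) under uniformity, and the
#' band is its central 95% interval. Warns when bins are empty (bins too
#' narrow, or L too low, per the practical guidelines).
#'
#' @param ranks integer ranks.
#' @param L posterior draws per replicate.
#' @param bins number of bins (>= 2, and at most `n`).
#' @return list with `counts`, `bandLower`, `bandUpper`, `expected`, `breaks`.
#' @export
rankHistogram <- function(ranks, L = attr(ranks, "L"), bins = 20L) {
  n <- length(ranks)
  if (bins < 2L) stop("need at least 2 bins")
  if (n < bins) stop("fewer ranks than bins")
  u <- ranks / (L + 1)
  idx <- pmin(bins, ceiling(u * bins))       # (0,1] bins, right-closed
  counts <- tabulate(idx, nbins = bins)
  if (any(counts == 0L))
    warning("empty rank-histogram bin(s): bins may be too narrow or L too low")
  band <- stats::qbinom(c(0.025, 0.975), n, 1 / bins)
  list(counts = counts,
       bandLower = band[1L], bandUpper = band[2L],
       expected = n / bins,
       breaks = seq(0, 1, length.out = bins + 1L))
}

#' ECDF of normalised ranks with a Monte-Carlo simultaneous band
#'
#' Evaluates the rank ECDF on the grid `j / (L + 1)` and builds a simultaneous
#' `bandLevel` confidence band by Monte-Carlo: uniform rank sets of size `n`
#' are simulated and the per-point pointwise binomial envelope is widened
#' (search over the pointwise level) until the simultaneous coverage reaches
#' `bandLevel`. Verdict: the observed ECDF stays within the band everywhere.
#'
#' @param ranks integer ranks (n >= 20).
#' @param L posterior draws per replicate.
#' @param bandLevel simultaneous coverage of the band.
#' @param reps Monte-Carlo replicates (>= 100).
#' @param gridMax maximal number of grid points.
#' @return list with `grid`, `ecdf`, `bandLower`, `bandUpper`, `pass`.
#' @export
ecdfBand <- function(ranks, L = attr(ranks, "L"), bandLevel = 0.95,
                     reps = 5000L, gridMax = 100L) {
  n <- length(ranks)
  if (n < 20L) stop("ECDF band needs n >= 20 ranks")
  if (reps < 100L) stop("need >= 100 Monte-Carlo replicates for the band")
  pts <- if (L + 1L <= gridMax) seq_len(L) else
    unique(round(seq(1L, L, length.out = gridMax)))
  p <- pts / (L + 1)                 # P(rank <= pts[j]) under uniformity
  obs <- vapply(pts, function(j) sum(ranks <= j), integer(1)) / n
  sim <- matrix(0L, reps, length(pts))
  for (b in seq_len(reps)) {
    rb <- sample.int(L + 1L, n, replace = TRUE)
    sim[b, ] <- cumsum(tabulate(rb, nbins = L + 1L))[pts]
  }
  # search the pointwise binomial level whose envelope is simultaneous
  cover <- function(gamma) {
    lo <- stats::qbinom((1 - gamma) / 2, n, p)
    hi <- stats::qbinom(1 - (1 - gamma) / 2, n, p)
    inside <- sweep(sim, 2L, lo, ">=") & sweep(sim, 2L, hi, "<=")
    mean(rowSums(inside) == length(pts))
  }
  lo <- bandLevel; hi <- 1 - 1e-9
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (cover(mid) >= bandLevel) hi <- mid else lo <- mid
  }
  gamma <- hi
  bandLo <- stats::qbinom((1 - gamma) / 2, n, p) / n
  bandHi <- stats::qbinom(1 - (1 - gamma) / 2, n, p) / n
  list(grid = p, ecdf = obs, bandLower = bandLo, bandUpper = bandHi,
       pass = all(obs >= bandLo & obs <= bandHi), gamma = gamma)
}

#' Rank-uniformity verdict with failure-pattern tag
#'
#' Combines a chi-square goodness-of-fit test of the rank histogram against
#' uniformity (rejecting at `gofLevel`) with the [ecdfBand()] verdict. The
#' pattern tag summarises which thirds of the histogram exceed their bands:
#' a central hump flags overdispersed estimates, horns underdispersion or rank
#' autocorrelation, and left/right shifts over- and underestimation.
#'
#' @param ranks integer ranks.
#' @param L posterior draws per replicate.
#' @param bins histogram bins.
#' @param gofLevel chi-square rejection level (default 0.01).
#' @param reps Monte-Carlo replicates for the ECDF band.
#' @return a [RuvReport-class].
#' @export
ruvVerdict <- function(ranks, L = attr(ranks, "L"), bins = 20L,
                       gofLevel = 0.01, reps = 2000L) {
  rh <- suppressWarnings(rankHistogram(ranks, L, bins))
  chi <- suppressWarnings(
    stats::chisq.test(rh$counts, p = rep(1 / bins, bins)))
  eb <- ecdfBand(ranks, L, reps = reps)
  pass <- chi$p.value > gofLevel && eb$pass
  pattern <- if (pass) "uniform" else
    .rankPattern(rh$counts, rh$bandLower, rh$bandUpper, eb)
  new("RuvReport", ranks = as.integer(ranks), L = as.integer(L),
      bins = as.integer(bins), counts = as.numeric(rh$counts),
      bandLower = as.numeric(rh$bandLower), bandUpper = as.numeric(rh$bandUpper),
      chisqP = chi$p.value, ecdfPass = eb$pass,
      pattern = pattern, pass = pass)
}

# classify the deviation by which thirds of the bins sit above their band;
# when the histogram bands are silent (they are far less sensitive than the
# simultaneous ECDF band), fall back to the direction of the ECDF violation
.rankPattern <- function(counts, lo, hi, eb = NULL) {
  bins <- length(counts)
  third <- cut(seq_len(bins), 3L, labels = c("left", "mid", "right"))
  above <- tapply(counts > hi, third, sum)
  below <- tapply(counts < lo, third, sum)
  excessLeft <- above[["left"]]; excessMid <- above[["mid"]]
  excessRight <- above[["right"]]
  if (excessMid > 0L && excessLeft == 0L && excessRight == 0L)
    return("central-hump")
  if (excessLeft > 0L && excessRight > 0L && excessMid == 0L)
    return("horns")
  if (excessLeft > excessRight || below[["right"]] > 0L)
    return("left-shift")
  if (excessRight > excessLeft || below[["left"]] > 0L)
    return("right-shift")
  if (!is.null(eb) && !eb$pass) {
    under <- any(eb$ecdf < eb$bandLower)  # ranks larger than uniformity allows
    over <- any(eb$ecdf > eb$bandUpper)
    if (under && !over) return("right-shift")
    if (over && !under) return("left-shift")
    mid <- eb$grid > 1 / 3 & eb$grid < 2 / 3
    if (any((eb$ecdf > eb$bandUpper)[mid])) return("central-hump")
    return("horns")
  }
  "uniform"
}
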