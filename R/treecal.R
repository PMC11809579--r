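#' Reference-tree distance ranks for tree-space RUV
#'
#' The tree-space rank device: each replicate's true tree and its posterior
#' tree samples are mapped to the real line by their distance to a reference
#' tree drawn from the prior (per replicate, or one shared across replicates),
#' and the true tree's distance is SBC-ranked among the samples' distances.
#' Rank-uniformity validation then proceeds exactly as for scalar parameters.
#' Ties are pervasive for discrete metrics on few taxa; [sbcRank()]'s
#' randomized tie-breaking handles them.
#'
#' @param trs a [treeReplicateSet()].
#' @param metric tree distance, default [rfDistance()].
#' @return integer ranks with attribute `"L"`, ready for [ruvVerdict()].
#' @export
referenceTreeRanks <- function(trs, metric = rfDistance) {
  d <- .referenceDistances(trs, metric)
  r <- vapply(seq_along(d$d0),
              function(i) as.integer(sbcRank(d$d0[i], d$dj[i, ])),
              integer(1))
  attr(r, "L") <- ncol(d$dj)
  r
}

.referenceDistances <- function(trs, metric) {
  n <- length(trs@truths)
  L <- length(trs@samples[[1L]])
  shared <- length(trs@references) == 1L
  d0 <- numeric(n)
  dj <- matrix(0, n, L)
  for (i in seq_len(n)) {
    ref <- trs@references[[if (shared) 1L else i]]
    if (!identical(sort(ref$tip.label), trs@taxa) ||
        !identical(sort(trs@truths[[i]]$tip.label), trs@taxa))
      stop("taxon set mismatch in replicate ", i)
    d0[i] <- metric(ref, trs@truths[[i]])
    dj[i, ] <- vapply(trs@samples[[i]], function(s) metric(ref, s), numeric(1))
  }
  list(d0 = d0, dj = dj)
}

#' Coverage of a tree topology through reference distances
#'
#' Per replicate, the HPD interval of the posterior samples' distances to the
#' reference tree is checked against the true tree's distance, feeding the
#' standard [coverageCount()] machinery.
#'
#' Discrete metrics (RF on few taxa takes a handful of values) make closed
#' intervals conservative: boundary atoms are always covered and the coverage
#' law inflates above `alpha`. With `tieBreak = "jitter"` (the default) all
#' distances are perturbed by a vanishing uniform jitter — the interval analogue
#' of [sbcRank()]'s mandatory randomized tie-breaking — which restores the exact
#' binomial coverage law while leaving continuous metrics untouched.
#'
#' @param trs a [treeReplicateSet()].
#' @param metric tree distance, default [rfDistance()].
#' @param alpha credibility level.
#' @param tieBreak `"jitter"` or `"none"`.
#' @return a [CoverageReport-class].
#' @export
treeCoverage <- function(trs, metric = rfDistance, alpha = 0.95,
                         tieBreak = c("jitter", "none")) {
  tieBreak <- match.arg(tieBreak)
  d <- .referenceDistances(trs, metric)
  if (tieBreak == "jitter") {
    pooled <- sort(unique(c(d$d0, as.vector(d$dj))))
    gap <- if (length(pooled) > 1L) min(diff(pooled)) else 0
    if (gap > 0) {
      eps <- gap / 1e3
      d$d0 <- d$d0 + stats::runif(length(d$d0), 0, eps)
      d$dj <- d$dj + stats::runif(length(d$dj), 0, eps)
    }
  }
  coverageCount(replicateSet("rf_to_reference", d$d0, d$dj), alpha)
}

#' Scalar-functional bridge from tree replicates
#'
#' Maps the true trees and posterior tree samples through a scalar functional
#' (e.g. root height for root-age coverage/RUV), producing a [replicateSet()]
#' on which all scalar calibration operations apply unchanged.
#'
#' @param trs a [treeReplicateSet()].
#' @param functional a function `phylo -> numeric`, e.g. [rootHeight()].
#' @param name parameter label.
#' @return a [replicateSet()].
#' @export
functionalReplicates <- function(trs, functional = rootHeight,
                                 name = "functional") {
  truths <- vapply(trs@truths, functional, numeric(1))
  draws <- t(vapply(trs@samples,
                    function(ss) vapply(ss, functional, numeric(1)),
                    numeric(length(trs@samples[[1L]]))))
  if (stats::var(c(truths, draws)) == 0)
    stop("zero-variance functional: '", name,
         "' is constant across all trees (e.g. tip count under a fixed-size model)")
  replicateSet(name, truths, draws)
}

#' Poisson law of shared clades between independent trees
#'
#' Two independent random trees on many (`s`) taxa share a number of nontrivial
#' clades that is approximately Poisson with rate `cherries / (2 s)`. For Yule
#' trees the cherry count asymptotes to `s / 3`, giving the limiting rate 1/6
#' and a `exp(-1/6) ~ 85%` chance of sharing no clades at all — the reason RF
#' distances to a random reference tree degenerate for large trees.
#'
#' @param s tip count (>= 4).
#' @param cherries cherry count of the focal tree (1 .. s/2).
#' @return list with the `rate`, the Yule `asymptoticRate` (1/6), and
#'   `pNoShared = exp(-rate)`.
#' @export
sharedCladeLaw <- function(s, cherries) {
  stopifnot(s >= 4, cherries >= 1, cherries <= s / 2)
  rate <- cherries / (2 * s)
  list(rate = rate, pNoShared = exp(-rate), asymptoticRate = 1 / 6)
}

#' Posterior clade support from tree samples
#'
#' Fraction of posterior samples containing each observed nontrivial clade.
#' Every sample of a binary rooted `s`-tip tree contributes `s - 2` nontrivial
#' clades, so supports sum to exactly `s - 2`.
#'
#' @param samples list of `phylo` posterior tree samples.
#' @param taxa common taxon ordering.
#' @return named numeric vector: clade key (see [cladeSet()]) -> support.
#' @export
cladeSupport <- function(samples, taxa = sort(samples[[1L]]$tip.label)) {
  L <- length(samples)
  keys <- unlist(lapply(samples, function(s) {
    if (!identical(sort(s$tip.label), taxa))
      stop("mixed taxon sets among tree samples")
    cladeSet(s, taxa = taxa)
  }))
  table(keys) / L
}

#' Clade-support coverage calibration
#'
#' The topology-coverage procedure: across replicates, true clades (those in
#' the generating tree) should appear among sampled clades in proportion to
#' their posterior support — 10% of all clades with support 0.1 should be true,
#' 20% of those with support 0.2, and so on. Supports are pooled over
#' replicates, binned (left-open, right-closed, width `binWidth`), and each
#' bin's true fraction is tested against its midpoint with an exact binomial
#' test, Bonferroni-corrected across bins. Requires all replicates to share one
#' tip count.
#'
#' @param trs a [treeReplicateSet()]; all trees must have equal tip counts.
#' @param binWidth support bin width (must divide 1).
#' @param level familywise rejection level before correction.
#' @return a [CladeCalibration-class].
#' @export
cladeCalibration <- function(trs, binWidth = 0.1, level = 0.05) {
  sizes <- vapply(trs@truths, tipCount, integer(1))
  if (length(unique(sizes)) != 1L)
    stop("clade-support calibration requires that the tree model only ",
         "generates trees of the same size")
  if (abs(1 / binWidth - round(1 / binWidth)) > 1e-9)
    stop("binWidth must divide 1")
  n <- length(trs@truths)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    sup <- cladeSupport(trs@samples[[i]], taxa = trs@taxa)
    trueClades <- cladeSet(trs@truths[[i]], taxa = trs@taxa)
    recs[[i]] <- data.frame(replicate = i, clade = names(sup),
                            support = as.numeric(sup),
                            isTrue = names(sup) %in% trueClades)
  }
  tab <- do.call(rbind, recs)
  nbins <- round(1 / binWidth)
  bin <- pmin(nbins, ceiling(tab$support / binWidth))
  mids <- (seq_len(nbins) - 0.5) * binWidth
  rows <- lapply(seq_len(nbins), function(b) {
    inb <- bin == b
    m <- sum(inb)
    if (m == 0L)
      return(data.frame(bin = b, mid = mids[b], nClades = 0L,
                        meanSupport = NA_real_, fracTrue = NA_real_,
                        p = NA_real_))
    k <- sum(tab$isTrue[inb])
    # the law is P(true | support) = support; within a bin the expected true
    # fraction is therefore the mean support of its clades (supports are far
    # from uniform within bins — they pile up near 0 — so the bin midpoint
    # would be a miscalibrated target)
    target <- mean(tab$support[inb])
    data.frame(bin = b, mid = mids[b], nClades = m, meanSupport = target,
               fracTrue = k / m,
               p = stats::binom.test(k, m, target)$p.value)
  })
  bins <- do.call(rbind, rows)
  tested <- !is.na(bins$p)
  bins$pAdjusted <- NA_real_
  bins$pAdjusted[tested] <- pmin(1, bins$p[tested] * sum(tested))  # Bonferroni
  pass <- all(bins$pAdjusted[tested] > level)
  new("CladeCalibration", table = tab, bins = bins, pass = pass)
}
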