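# Metropolis-Hastings proposal kernels. Each internal kernel acts on the tt
# representation and returns list(tt = , logHR = ) or NULL when the move is
# ineligible/invalid (counted as an MH rejection). Public wrappers operate on
# phylo objects.

#' Multiplicative scale proposal for a positive scalar
#'
#' Proposes `x' = u x` with `u ~ Uniform[tuning, 1/tuning]`. The Hastings
#' correction for this kernel is `log q(x'->x) - log q(x->x') = -log u`
#' (forward density `c/x`, reverse `c/x'`), which keeps detailed balance.
#'
#' @param x current value (> 0).
#' @param tuning lower bound of the multiplier, in (0, 1).
#' @return list with `x` (proposed value) and `logHR`.
#' @export
scaleProposal <- function(x, tuning = 0.75) {
  stopifnot(x > 0, tuning > 0, tuning < 1)
  u <- stats::runif(1, tuning, 1 / tuning)
  list(x = x * u, logHR = -log(u))
}

# slide one uniformly chosen non-root internal node's height within
# (max child height, parent height); symmetric, logHR = 0.
# 2-tip trees have no eligible node: fall through to a root-scale move.
.ttNodeSlide <- function(tt, tuning = 0.75) {
  int <- tt_internal_nodes(tt)
  elig <- int[int != tt$root]
  if (length(elig) == 0L) return(.ttRootMove(tt, tuning))
  z <- if (length(elig) == 1L) elig else elig[sample.int(length(elig), 1L)]
  lo <- max(tt$height[tt$kid1[z]], tt$height[tt$kid2[z]])
  hi <- tt$height[tt$parent[z]]
  tt$height[z] <- stats::runif(1, lo, hi)
  list(tt = tt, logHR = 0)
}

# root move: uniform redraw below the origin when one exists, otherwise a
# multiplicative scale on the root height (invalid proposals rejected).
.ttRootMove <- function(tt, tuning = 0.75) {
  root <- tt$root
  lo <- max(tt$height[tt$kid1[root]], tt$height[tt$kid2[root]])
  if (!is.na(tt$origin)) {
    tt$height[root] <- stats::runif(1, lo, tt$origin)
    return(list(tt = tt, logHR = 0))
  }
  u <- stats::runif(1, tuning, 1 / tuning)
  hnew <- tt$height[root] * u
  if (hnew <= lo) return(NULL)
  tt$height[root] <- hnew
  list(tt = tt, logHR = -log(u))
}

# narrow exchange: swap the uncle with a nephew where heights permit.
# Eligible moves are pairs (A, C): A an internal non-root node older than its
# sibling B, C one of A's children; after the swap B hangs from A and C from
# A's parent. Forward/reverse selection is uniform over eligible pairs, so
# logHR = log(n_fwd) - log(n_rev).
.ttNarrowExchange <- function(tt) {
  if (tt$ntip < 3L) return(NULL)
  h <- tt$height
  int <- tt_internal_nodes(tt)
  cand <- int[int != tt$root]
  sib <- function(z) {
    p <- tt$parent[z]
    if (tt$kid1[p] == z) tt$kid2[p] else tt$kid1[p]
  }
  eligA <- cand[vapply(cand, function(z) h[z] > h[sib(z)], NA)]
  nFwd <- 2L * length(eligA)
  if (nFwd == 0L) return(NULL)
  k <- sample.int(nFwd, 1L)
  A <- eligA[(k + 1L) %/% 2L]
  C <- if (k %% 2L == 1L) tt$kid1[A] else tt$kid2[A]
  P <- tt$parent[A]
  B <- sib(A)
  # swap B and C
  if (tt$kid1[P] == B) tt$kid1[P] <- C else tt$kid2[P] <- C
  if (tt$kid1[A] == C) tt$kid1[A] <- B else tt$kid2[A] <- B
  tt$parent[B] <- A
  tt$parent[C] <- P
  eligA2 <- cand[vapply(cand, function(z) {
    p <- tt$parent[z]
    s2 <- if (tt$kid1[p] == z) tt$kid2[p] else tt$kid1[p]
    h[z] > h[s2]
  }, NA)]
  nRev <- 2L * length(eligA2)
  list(tt = tt, logHR = log(nFwd) - log(nRev))
}

# scale all internal node heights by u ~ Uniform[tuning, 1/tuning]; the origin
# age stays fixed and proposals pushing the root above it are rejected.
# Green's-formula HR for scaling m coordinates: (m - 2) log u.
.ttTreeScale <- function(tt, tuning = 0.75) {
  int <- tt_internal_nodes(tt)
  if (length(int) == 0L) return(NULL)
  u <- stats::runif(1, tuning, 1 / tuning)
  hnew <- tt$height
  hnew[int] <- hnew[int] * u
  if (!is.na(tt$origin) && hnew[tt$root] > tt$origin) return(NULL)
  tt$height <- hnew
  list(tt = tt, logHR = (length(int) - 2) * log(u))
}

.wrapTreeProposal <- function(fun, phy, ...) {
  res <- fun(tt_from_phylo(phy), ...)
  if (is.null(res)) return(NULL)
  list(tree = tt_to_phylo(res$tt), logHR = res$logHR)
}

#' Time-tree proposal kernels
#'
#' `nodeSlideProposal()` redraws a uniformly chosen non-root internal node age
#' uniformly between its oldest child and its parent (topology unchanged,
#' `logHR = 0`); on a 2-tip tree it falls through to a root move.
#' `narrowExchangeProposal()` swaps an uncle with a nephew where node ages
#' permit, choosing uniformly among eligible pairs (the Hastings ratio is the
#' log-ratio of eligible-pair counts before and after). `treeScaleProposal()`
#' rescales all internal node ages by a common factor, leaving any origin age
#' fixed. Each returns `NULL` when no valid move exists (an MH rejection).
#'
#' @param phy a `phylo` time tree.
#' @param tuning scale-move tuning in (0, 1).
#' @return list with the proposed `tree` and `logHR`, or `NULL`.
#' @export
nodeSlideProposal <- function(phy, tuning = 0.75)
  .wrapTreeProposal(.ttNodeSlide, phy, tuning)

#' @rdname nodeSlideProposal
#' @export
narrowExchangeProposal <- function(phy) .wrapTreeProposal(.ttNarrowExchange, phy)

#' @rdname nodeSlideProposal
#' @export
treeScaleProposal <- function(phy, tuning = 0.75)
  .wrapTreeProposal(.ttTreeScale, phy, tuning)
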