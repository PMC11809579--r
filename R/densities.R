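#' Log-normal log-density
#'
#' Exact log pdf of the log-normal prior; returns `-Inf` for non-positive `x`.
#'
#' @param x evaluation point(s).
#' @param params a [logNormalParams()] object.
#' @return log-density value(s).
#' @export
logNormalLogDensity <- function(x, params) {
  out <- rep(-Inf, length(x))
  ok <- x > 0
  out[ok] <- stats::dlnorm(x[ok], params[["meanlog"]], params[["sdlog"]],
                           log = TRUE)
  out
}

#' Yule (pure-birth) tree log-density
#'
#' Log-density of a labeled, origin-conditioned pure-birth history:
#' `(s - 1) log(lambda) - lambda * T`, where `T` is the total lineage time from
#' the origin to the present (the stem plus all branch lengths), which for an
#' ultrametric tree equals the origin age plus the sum of internal node ages.
#' Constant label-combinatorial factors are dropped (they cancel in MCMC).
#'
#' @param phy a `phylo` time tree.
#' @param lambda birth rate (> 0).
#' @param tau origin age; defaults to the tree's own origin (root edge).
#' @return log-density.
#' @export
yuleLogDensity <- function(phy, lambda, tau = originAge(phy)) {
  stopifnot(lambda > 0)
  if (is.na(tau)) stop("Yule density needs an origin age (root edge or tau)")
  tt <- tt_from_phylo(phy)
  tt_yule_logdens(tt, lambda, tau)
}

#' Kingman coalescent tree log-density
#'
#' Sum over inter-coalescent intervals of `-k(k-1)/(2 Ne) * dt` plus
#' `(s - 1) log(1 / Ne)`.
#'
#' @param phy an ultrametric `phylo` tree.
#' @param Ne effective population size (> 0).
#' @return log-density.
#' @export
coalescentLogDensity <- function(phy, Ne = 1) {
  tt_coalescent_logdens(tt_from_phylo(phy), Ne)
}

#' Phylogenetic Brownian motion log-density
#'
#' Multivariate normal log pdf of tip traits with mean `y0` and covariance
#' `r C` (`C` = shared root-to-MRCA path lengths), evaluated by Felsenstein
#' pruning in O(s) without forming `C`.
#'
#' @param traits named numeric vector of tip values (names = tip labels).
#' @param phy a `phylo` time tree.
#' @param r evolutionary rate (> 0).
#' @param y0 known root state.
#' @return log-density.
#' @export
phyloBMLogDensity <- function(traits, phy, r, y0 = 0) {
  stopifnot(r > 0)
  tt <- tt_from_phylo(phy)
  x <- traits[tt$labels]
  if (anyNA(x)) stop("traits must be named by the tree's tip labels")
  ss <- tt_bm_suffstat(tt, as.numeric(x), y0)
  tt_bm_logdens(ss, r, tt$ntip)
}
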