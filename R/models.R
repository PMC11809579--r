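# Model constructors for the MH engine (see mcmc.R for the contract).

#' Hierarchical Yule + phylogenetic BM model
#'
#' The demonstration model: birth rate `lambda` and trait rate `r` carry
#' log-normal priors, the time tree `phi` a Yule prior conditioned on a known
#' origin age `tau`, and the tip traits a phylogenetic-BM likelihood with known
#' root state `y0`. The posterior is sampled over `(lambda, r, phi)` with the
#' tip count fixed by the data. With `traits = NULL` the data term is dropped
#' and the chain samples the prior ("sampling from the prior").
#'
#' The posterior factorises as prior(lambda) + prior(r) + Yule(phi | lambda,
#' tau) + BM(y | phi, r); scalar moves update their factors in O(1) (the BM
#' term depends on `r` only through `-s/2 log r - Q/(2r)` for cached pruning
#' statistics), tree moves re-run the O(s) pruning.
#'
#' Scalars start at their prior medians. The tree starts at a fresh prior-like
#' draw (a Yule simulation conditioned on the observed tip count, rescaled
#' below `tau` if needed) — never at the data-generating truth, which would
#' mask initialisation-sensitive bugs.
#'
#' @param traits named tip trait vector, or `NULL` for a no-data run.
#' @param s tip count (required when `traits` is `NULL`).
#' @param tau known origin age.
#' @param y0 known root trait value.
#' @param lambdaPrior,rPrior [logNormalParams()] priors used in inference.
#' @param tuning scale-move tuning in (0, 1).
#' @param weights kernel weights: lambda scale, r scale, node slide, narrow
#'   exchange, root/tree scale.
#' @param logTrees store Newick tree samples in the trace.
#' @param initTree optional `phylo` starting tree (e.g. for fixed-topology
#'   checks with zero tree-move weights); must match `s` and fit under `tau`.
#' @return a model list for [mhRun()].
#' @export
makeYuleBMModel <- function(traits = NULL, s = length(traits), tau, y0 = 0,
                            lambdaPrior = logNormalParams(-3.25, 0.2),
                            rPrior = logNormalParams(-2.5, 0.5),
                            tuning = 0.75,
                            weights = c(lambda = 3, r = 3, slide = 2,
                                        exchange = 1, rootTree = 1),
                            logTrees = FALSE, initTree = NULL) {
  stopifnot(s >= 2, tau > 0)
  hasData <- !is.null(traits)
  labels <- paste0("t", seq_len(s))
  x <- NULL      # trait values in the chain tree's tip-node order (set at init)
  if (hasData && anyNA(as.numeric(traits[labels])))
    stop("traits must be named t1..t", s)

  lpLambda <- function(l) logNormalLogDensity(l, lambdaPrior)
  lpR <- function(r) logNormalLogDensity(r, rPrior)
  bmTerm <- function(ss, r) if (hasData) tt_bm_logdens(ss, r, s) else 0
  suff <- function(tt) if (hasData) tt_bm_suffstat(tt, x, y0) else NULL
  yuleTerm <- function(lambda, sumH) (s - 1) * log(lambda) - lambda * (tau + sumH)

  assemble <- function(lambda, r, tt) {
    sumH <- tt_sum_internal_heights(tt)
    ss <- suff(tt)
    list(lambda = lambda, r = r, tt = tt, sumH = sumH, ss = ss,
         lp = lpLambda(lambda) + lpR(r) + yuleTerm(lambda, sumH) +
           bmTerm(ss, r))
  }

  init <- function() {
    lambda0 <- exp(lambdaPrior[["meanlog"]])
    r0 <- exp(rPrior[["meanlog"]])
    tt <- if (!is.null(initTree)) tt_from_phylo(initTree) else {
      # a fresh draw from an origin-conditioned Yule prior given the tip
      # count; an unrepresentative start (e.g. squeezed node ages) takes many
      # tree moves to forget and biases short chains. The birth rate of the
      # initialisation draw is moment-matched to the observed size (the
      # inference prior median may be wildly inconsistent with s, which is
      # the whole point of misspecification scenarios).
      t0 <- .simYuleOriginCondTT(max(log(s), 1) / tau, tau, s)
      if (is.null(t0)) t0 <- .simYuleNtipsTT(max(log(s), 1) / tau, s)
      t0$labels <- labels
      t0
    }
    if (tt$ntip != s) stop("initTree tip count differs from s")
    if (hasData) {
      x <<- as.numeric(traits[tt$labels])  # tip-node order; labels never move
      if (anyNA(x)) stop("traits must be named by the tree's tip labels")
    }
    rh <- tt_root_height(tt)
    if (rh >= tau) {   # squeeze the initial tree under the known origin
      int <- tt_internal_nodes(tt)
      tt$height[int] <- tt$height[int] * (0.95 * tau / rh)
    }
    tt$origin <- tau
    assemble(lambda0, r0, tt)
  }

  treeUpdate <- function(state, move) {
    res <- move(state$tt)
    if (is.null(res)) return(NULL)
    newState <- assemble(state$lambda, state$r, res$tt)
    list(state = newState, logHR = res$logHR)
  }

  proposals <- list(
    lambda = function(state) {
      p <- scaleProposal(state$lambda, tuning)
      d <- lpLambda(p$x) - lpLambda(state$lambda) +
        yuleTerm(p$x, state$sumH) - yuleTerm(state$lambda, state$sumH)
      state$lambda <- p$x
      state$lp <- state$lp + d
      list(state = state, logHR = p$logHR)
    },
    r = function(state) {
      p <- scaleProposal(state$r, tuning)
      d <- lpR(p$x) - lpR(state$r) +
        bmTerm(state$ss, p$x) - bmTerm(state$ss, state$r)
      state$r <- p$x
      state$lp <- state$lp + d
      list(state = state, logHR = p$logHR)
    },
    slide = function(state)
      treeUpdate(state, function(tt) .ttNodeSlide(tt, tuning)),
    exchange = function(state) treeUpdate(state, .ttNarrowExchange),
    rootTree = function(state) {
      if (stats::runif(1) < 0.5)
        treeUpdate(state, function(tt) .ttTreeScale(tt, tuning))
      else
        treeUpdate(state, function(tt) .ttRootMove(tt, tuning))
    }
  )

  list(
    init = init,
    logPost = function(state)
      lpLambda(state$lambda) + lpR(state$r) +
        yuleTerm(state$lambda, tt_sum_internal_heights(state$tt)) +
        bmTerm(suff(state$tt), state$r),
    proposals = proposals,
    weights = weights,
    monitor = function(state)
      c(lambda = state$lambda, r = state$r,
        root_height = tt_root_height(state$tt),
        tree_length = state$sumH + tt_root_height(state$tt)),
    treeNewick = if (logTrees)
      function(state) writeNewick(tt_to_phylo(state$tt)) else NULL
  )
}

#' Kingman coalescent prior-sampling model
#'
#' Targets the coalescent tree prior with a known effective population size
#' (no data), exercising the time-tree kernels: sampled trees should match
#' direct simulation in every functional.
#'
#' @param s tip count (>= 2).
#' @param Ne effective population size (fixed, known).
#' @param tuning scale-move tuning.
#' @param weights kernel weights: node slide, narrow exchange, root/tree scale.
#' @param logTrees store Newick tree samples (default `TRUE`).
#' @return a model list for [mhRun()].
#' @export
makeCoalescentModel <- function(s, Ne = 1, tuning = 0.75,
                                weights = c(slide = 2, exchange = 1,
                                            rootTree = 1),
                                logTrees = TRUE) {
  stopifnot(s >= 2, Ne > 0)
  assemble <- function(tt) list(tt = tt, lp = tt_coalescent_logdens(tt, Ne))
  treeUpdate <- function(state, move) {
    res <- move(state$tt)
    if (is.null(res)) return(NULL)
    list(state = assemble(res$tt), logHR = res$logHR)
  }
  list(
    init = function() assemble(.simCoalescentTT(as.integer(s), Ne)),
    logPost = function(state) tt_coalescent_logdens(state$tt, Ne),
    proposals = list(
      slide = function(state)
        treeUpdate(state, function(tt) .ttNodeSlide(tt, tuning)),
      exchange = function(state) treeUpdate(state, .ttNarrowExchange),
      rootTree = function(state) {
        if (stats::runif(1) < 0.5)
          treeUpdate(state, function(tt) .ttTreeScale(tt, tuning))
        else
          treeUpdate(state, function(tt) .ttRootMove(tt, tuning))
      }
    ),
    weights = weights,
    monitor = function(state)
      c(root_height = tt_root_height(state$tt),
        tree_length = tt_sum_internal_heights(state$tt) +
          tt_root_height(state$tt)),
    treeNewick = if (logTrees)
      function(state) writeNewick(tt_to_phylo(state$tt)) else NULL
  )
}

#' Conjugate normal-normal toy model
#'
#' Prior `theta ~ Normal(m0, sd0)`, data `y_j ~ Normal(theta, obsSd)`. The
#' closed-form posterior makes this the smoke test for the MH engine and the
#' whole calibration pipeline.
#'
#' @param y observation vector.
#' @param m0,sd0 prior mean and sd.
#' @param obsSd known observation sd.
#' @param rwSd random-walk proposal sd.
#' @return a model list for [mhRun()].
#' @export
makeNormalNormalModel <- function(y, m0 = 0, sd0 = 1, obsSd = 1, rwSd = 1) {
  lp <- function(theta)
    stats::dnorm(theta, m0, sd0, log = TRUE) +
      sum(stats::dnorm(y, theta, obsSd, log = TRUE))
  list(
    init = function() list(theta = m0, lp = lp(m0)),
    logPost = function(state) lp(state$theta),
    proposals = list(
      rw = function(state) {
        thetaNew <- state$theta + stats::rnorm(1, 0, rwSd)
        list(state = list(theta = thetaNew, lp = lp(thetaNew)), logHR = 0)
      }
    ),
    weights = 1,
    monitor = function(state) c(theta = state$theta),
    treeNewick = NULL
  )
}

#' Closed-form posterior of the normal-normal model
#'
#' @inheritParams makeNormalNormalModel
#' @return list with posterior `mean` and `sd`.
#' @export
normalNormalPosterior <- function(y, m0 = 0, sd0 = 1, obsSd = 1) {
  w0 <- 1 / sd0^2
  wl <- length(y) / obsSd^2
  list(mean = (m0 * w0 + mean(y) * wl) / (w0 + wl), sd = sqrt(1 / (w0 + wl)))
}
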