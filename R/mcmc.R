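# Model objects are plain lists with the fields
#   init()            -> initial state (list carrying $lp, the cached log
#                        posterior; -Inf initial states abort before iterating)
#   logPost(state)    -> full recomputation of the log posterior (cache audit)
#   proposals         -> named list of function(state) -> list(state, logHR)
#                        or NULL for an ineligible move (counts as rejection)
#   weights           -> proposal selection weights
#   monitor(state)    -> named numeric vector of logged scalars
#   treeNewick(state) -> Newick string of the current tree, or NULL field
# Proposals update the state's cached $lp themselves (incrementally where the
# factorisation allows it); mhRun audits the cache periodically.

#' Run a Metropolis-Hastings chain
#'
#' Standard MH accept/reject over the model's proposal mix, retaining every
#' `sampleEvery`-th state (plus the initial one). The cached posterior
#' log-density is compared against a full recomputation every `checkEvery`
#' iterations and the run aborts if they disagree beyond `1e-8` — a guard
#' against incremental-update bugs, which validation protocols exist to catch.
#'
#' @param model a model list (see [makeYuleBMModel()], [makeCoalescentModel()],
#'   [makeNormalNormalModel()]).
#' @param chainLength number of MH iterations.
#' @param sampleEvery sampling interval; the trace has
#'   `floor(chainLength / sampleEvery) + 1` rows.
#' @param checkEvery cache-audit interval.
#' @return a `traceLog` list: `trace` (data.frame with `Sample`, `posterior`
#'   and the model monitors), `trees` (character vector of Newick samples, or
#'   `NULL`), and `acceptance` (per-kernel acceptance rates).
#' @export
mhRun <- function(model, chainLength, sampleEvery = 10L, checkEvery = 1000L) {
  state <- model$init()
  if (!is.finite(state$lp))
    stop("initial state has non-finite posterior log-density (", state$lp, ")")
  nprop <- length(model$proposals)
  w <- model$weights / sum(model$weights)
  nrows <- floor(chainLength / sampleEvery) + 1L
  mon0 <- model$monitor(state)
  trace <- matrix(NA_real_, nrows, 2L + length(mon0))
  colnames(trace) <- c("Sample", "posterior", names(mon0))
  hasTree <- !is.null(model$treeNewick)
  trees <- if (hasTree) character(nrows) else NULL
  attempts <- accepted <- integer(nprop)
  row <- 1L
  trace[row, ] <- c(0, state$lp, mon0)
  if (hasTree) trees[row] <- model$treeNewick(state)
  kernelSeq <- sample.int(nprop, chainLength, replace = TRUE, prob = w)
  for (it in seq_len(chainLength)) {
    k <- kernelSeq[it]
    attempts[k] <- attempts[k] + 1L
    prop <- model$proposals[[k]](state)
    if (!is.null(prop)) {
      lpNew <- prop$state$lp
      if (is.nan(lpNew))
        stop("NaN posterior log-density at iteration ", it, " (kernel ",
             names(model$proposals)[k], ")")
      if (lpNew - state$lp + prop$logHR >= 0 ||
          log(stats::runif(1)) < lpNew - state$lp + prop$logHR) {
        state <- prop$state
        accepted[k] <- accepted[k] + 1L
      }
    }
    if (it %% checkEvery == 0L) {
      full <- model$logPost(state)
      if (abs(full - state$lp) > 1e-8)
        stop("cached posterior log-density drifted from recomputation by ",
             format(abs(full - state$lp)), " at iteration ", it)
      state$lp <- full
    }
    if (it %% sampleEvery == 0L) {
      row <- row + 1L
      trace[row, ] <- c(it, state$lp, model$monitor(state))
      if (hasTree) trees[row] <- model$treeNewick(state)
    }
  }
  structure(list(trace = as.data.frame(trace), trees = trees,
                 acceptance = stats::setNames(
                   ifelse(attempts > 0, accepted / attempts, NA_real_),
                   names(model$proposals))),
            class = "traceLog")
}

#' Effective sample size of an MCMC trace
#'
#' `N / (1 + 2 sum(rho_k))` with Geyer's initial-positive-sequence truncation
#' of the autocorrelation sum: paired autocorrelations
#' `Gamma_m = rho_{2m} + rho_{2m+1}` are summed while positive.
#'
#' @param x numeric vector of ordered samples (>= 10).
#' @return effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10L) stop("ESS needs at least 10 samples")
  if (stats::var(x) == 0) stop("constant chain: ESS undefined")
  lagMax <- min(n - 1L, 2000L)
  rho <- drop(stats::acf(x, lag.max = lagMax, plot = FALSE,
                         demean = TRUE)$acf)
  m <- 0L
  gsum <- 0
  while (2L * m + 2L <= length(rho)) {
    g <- rho[2L * m + 1L] + rho[2L * m + 2L]
    if (g <= 0) break
    gsum <- gsum + g
    m <- m + 1L
  }
  denom <- max(2 * gsum - 1, 1)
  n / denom
}

#' Burn-in removal and equidistant thinning
#'
#' Drops the first `ceiling(burninFraction * rows)` retained states and keeps
#' `L` equidistant rows of the remainder, always including the first and last
#' post-burn-in rows (for `L = 1`, the last row). The recommended ceiling for
#' `L` is the trace's ESS, so that the retained draws are close to independent.
#'
#' @param x a `traceLog`, data.frame, or vector.
#' @param burninFraction fraction of rows to drop, in `[0, 1)`.
#' @param L number of rows to keep.
#' @return object of the same shape restricted to the selected rows; the
#'   selected indices are attached as attribute `"indices"`.
#' @export
burninThin <- function(x, burninFraction = 0.1, L = 200L) {
  nrows <- if (inherits(x, "traceLog")) nrow(x$trace)
           else if (is.data.frame(x) || is.matrix(x)) nrow(x)
           else length(x)
  idx <- burninThinIndices(nrows, burninFraction, L)
  out <- if (inherits(x, "traceLog")) {
    structure(list(trace = x$trace[idx, , drop = FALSE],
                   trees = if (!is.null(x$trees)) x$trees[idx],
                   acceptance = x$acceptance), class = "traceLog")
  } else if (is.data.frame(x) || is.matrix(x)) {
    x[idx, , drop = FALSE]
  } else {
    x[idx]
  }
  attr(out, "indices") <- idx
  out
}

#' @rdname burninThin
#' @param nrows total number of retained states.
#' @export
burninThinIndices <- function(nrows, burninFraction = 0.1, L = 200L) {
  stopifnot(burninFraction >= 0, burninFraction < 1, L >= 1)
  drop <- ceiling(burninFraction * nrows)
  avail <- nrows - drop
  if (L > avail)
    stop("L = ", L, " exceeds the ", avail, " post-burn-in rows; ",
         "lower L (the ESS is the recommended ceiling)")
  if (L == 1L) return(nrows)
  drop + round(seq(1, avail, length.out = L))
}

#' Write / read trace logs
#'
#' The trace is a BEAST-log-like tab-separated file with a `Sample` column;
#' tree samples go to a parallel file with one Newick string per line, so the
#' diagnostics layer can also ingest externally produced logs.
#'
#' @param tl a `traceLog`.
#' @param path output TSV path; tree samples go to `sub("\\\\.tsv$", ".trees",
#'   path)`.
#' @return `path`, invisibly.
#' @export
writeTraceLog <- function(tl, path) {
  utils::write.table(tl$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tl$trees))
    writeLines(tl$trees, sub("\\.tsv$", ".trees", path))
  invisible(path)
}

#' @rdname writeTraceLog
#' @param treesPath optional path of a Newick tree-sample file (one per line;
#'   bracketed comments are stripped).
#' @export
readTraceLog <- function(path, treesPath = NULL) {
  trace <- utils::read.table(path, header = TRUE, sep = "\t")
  trees <- NULL
  if (!is.null(treesPath)) {
    lines <- readLines(treesPath)
    trees <- gsub("\\[[^]]*\\]", "", lines)
    trees <- trees[nzchar(trimws(trees))]
  }
  structure(list(trace = trace, trees = trees, acceptance = NULL),
            class = "traceLog")
}
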