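# Shared fixtures: exact-sampler pipelines (posterior draws taken iid from the
# generating conditional — calibrated by construction) and cached heavy runs.

# conjugate normal-normal pipeline, fully vectorised
exactConjugateReplicates <- function(n, L, nObs = 1, m0 = 0, sd0 = 1,
                                     obsSd = 1) {
  truths <- rnorm(n, m0, sd0)
  draws <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) {
    y <- rnorm(nObs, truths[i], obsSd)
    post <- normalNormalPosterior(y, m0, sd0, obsSd)
    draws[i, ] <- rnorm(L, post$mean, post$sd)
  }
  replicateSet("theta", truths, draws)
}

# SBC ranks of an exact conjugate pipeline without building the matrix
exactConjugateRanks <- function(n, L, nObs = 1) {
  rs <- exactConjugateReplicates(n, L, nObs)
  sbcRanks(rs)
}

# Kingman exact-sampler tree replicates (posterior = prior, no data)
kingmanExactTreeSet <- function(n, L, s = 5, Ne = 1, shared = TRUE) {
  sim <- function() simulateCoalescent(s, Ne)
  truths <- lapply(seq_len(n), function(i) sim())
  samples <- lapply(seq_len(n), function(i)
    lapply(seq_len(L), function(j) sim()))
  refs <- if (shared) sim() else lapply(seq_len(n), function(i) sim())
  treeReplicateSet(truths, samples, refs)
}

# all 15 labeled rooted binary 4-tip topologies, via merge-history enumeration
allRootedQuartets <- function() {
  tips <- c("A", "B", "C", "D")
  build <- function(groups, h) {
    if (length(groups) == 1L) return(list(groups[[1L]]$nwk))
    out <- list()
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        gi <- groups[[i]]; gj <- groups[[j]]
        merged <- list(nwk = sprintf("(%s:%g,%s:%g)", gi$nwk, h - gi$h,
                                     gj$nwk, h - gj$h), h = h)
        rest <- groups[-c(i, j)]
        out <- c(out, build(c(rest, list(merged)), h + 1))
      }
    }
    out
  }
  start <- lapply(tips, function(t) list(nwk = t, h = 0))
  nwks <- unique(unlist(build(start, 1)))
  trees <- lapply(paste0(nwks, ";"), parseNewick)
  # deduplicate by clade set (merge order can repeat a topology)
  keys <- vapply(trees, function(t)
    paste(sort(cladeSet(t, taxa = tips)), collapse = ";"), "")
  trees[!duplicated(keys)]
}

# brute-force rooted RF via independent clade enumeration (ape::prop.part)
bruteRF <- function(t1, t2) {
  cl <- function(t) {
    pp <- ape::prop.part(t)
    labs <- attr(pp, "labels")
    keys <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = ","), "")
    setdiff(keys, paste(sort(labs), collapse = ","))  # drop root clade
  }
  a <- cl(t1); b <- cl(t2)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

# cached heavy acceptance runs (shared across criterion blocks)
.accCache <- new.env(parent = emptyenv())
acceptanceScenarioRun <- function(name) {
  if (is.null(.accCache[[name]])) {
    cfg <- switch(name,
      scenario2_tips30 = scenarioPreset("scenario2", n = 100, tips = 30,
                                        masterSeed = 1),
      scenario3 = scenarioPreset("scenario3", n = 60, masterSeed = 1),
      scenarioPreset(name, n = 100, masterSeed = 1))
    .accCache[[name]] <- runExperiment(cfg)
  }
  .accCache[[name]]
}
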