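#' Experiment configuration
#'
#' Complete description of one validation experiment: the generative model and
#' its simulation-side priors, the inference-side priors (identical under
#' correct specification — any divergence is deliberate misspecification and is
#' flagged by `show()`), replicate count, chain settings, thinning, and the
#' rejection rule applied to simulated trees.
#'
#' @slot name preset name.
#' @slot model one of `"yule_bm"`, `"kingman_rf"`, `"normal_normal"`.
#' @slot scale `"desk"` (scaled-down) or `"full"` (full-scale reference
#'   settings).
#' @slot n number of replicates.
#' @slot alpha credibility level.
#' @slot bins rank-histogram bins.
#' @slot L retained posterior draws per replicate.
#' @slot burninFraction burn-in fraction.
#' @slot chainLength,sampleEvery MH chain settings.
#' @slot engine `"mh"` or `"exact"` (iid draws from the generating
#'   conditional — the exact-sampling oracle, available when the posterior
#'   equals the prior or is closed-form).
#' @slot simLambdaPrior,infLambdaPrior,simRPrior,infRPrior `(meanlog, sdlog)`.
#' @slot tauPrior `(meanlog, sdlog)` of the origin-age prior.
#' @slot y0 known root trait value.
#' @slot rejection tip-count window `(lo, hi)`, or empty for none.
#' @slot s tip count (coalescent model).
#' @slot Ne effective population size (coalescent model).
#' @slot nObs observations per replicate (normal-normal model).
#' @slot referenceMode `"per-replicate"` or `"shared"` reference tree.
#' @slot masterSeed master seed; per-replicate seeds are derived by a counter
#'   rule so replicates are independently re-runnable.
#' @export
setClass("ExperimentConfig",
         representation(name = "character", model = "character",
                        scale = "character", n = "integer", alpha = "numeric",
                        bins = "integer", L = "integer",
                        burninFraction = "numeric", chainLength = "integer",
                        sampleEvery = "integer", engine = "character",
                        simLambdaPrior = "numeric", infLambdaPrior = "numeric",
                        simRPrior = "numeric", infRPrior = "numeric",
                        tauPrior = "numeric", y0 = "numeric",
                        rejection = "numeric", s = "integer", Ne = "numeric",
                        nObs = "integer", referenceMode = "character",
                        masterSeed = "integer"),
         validity = function(object) {
           if (!object@model %in% c("yule_bm", "kingman_rf", "normal_normal"))
             return("unknown model")
           if (!object@engine %in% c("mh", "exact")) return("unknown engine")
           if (object@n < 2L) return("need n >= 2 replicates")
           TRUE
         })

setMethod("$", "ExperimentConfig", function(x, name) slot(x, name))

#' @rdname ExperimentConfig-class
#' @param object an `ExperimentConfig`.
#' @export
setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig '", object@name, "' (", object@model, ", ",
      object@scale, " scale): n = ", object@n, ", L = ", object@L,
      ", alpha = ", object@alpha, ", engine = ", object@engine, "\n", sep = "")
  mis <- character(0)
  if (!identical(object@simLambdaPrior, object@infLambdaPrior))
    mis <- c(mis, sprintf("lambda prior sim (%g, %g) vs inference (%g, %g)",
                          object@simLambdaPrior[1], object@simLambdaPrior[2],
                          object@infLambdaPrior[1], object@infLambdaPrior[2]))
  if (!identical(object@simRPrior, object@infRPrior))
    mis <- c(mis, "r prior differs between simulation and inference")
  if (length(mis))
    cat("  !! DELIBERATE MISSPECIFICATION:", paste(mis, collapse = "; "), "\n")
  if (length(object@rejection) == 2L)
    cat("  rejection: tip count in [", object@rejection[1], ", ",
        object@rejection[2], "]\n", sep = "")
})

#' Validation report
#'
#' Everything [runExperiment()] computes: per-parameter coverage reports and
#' RUV reports, tree-space results where applicable, the replicate sets, and a
#' settings echo for provenance.
#'
#' @slot config the [ExperimentConfig-class] that produced it.
#' @slot replicates named list of [ReplicateSet-class] objects.
#' @slot coverage named list of [CoverageReport-class] objects.
#' @slot ruv named list of [RuvReport-class] objects.
#' @slot tree list with `coverage`, `ruv`, `clades` for tree-space runs.
#' @slot treeReplicates a [TreeReplicateSet-class] or `NULL`.
#' @slot failures indices of replicates whose inference failed (excluded,
#'   reported — never silently resampled, which would bias coverage).
#' @export
setClass("ValidationReport",
         representation(config = "ExperimentConfig", replicates = "list",
                        coverage = "list", ruv = "list", tree = "list",
                        treeReplicates = "ANY", failures = "integer"))

#' @rdname ValidationReport-class
#' @param object a `ValidationReport`.
#' @export
setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport for '", object@config@name, "' (n = ",
      object@config@n, ")\n", sep = "")
  if (length(object@failures))
    cat("  !!", length(object@failures), "replicate(s) failed and were",
        "excluded:", paste(object@failures, collapse = ", "), "\n")
  for (p in names(object@coverage)) {
    cat("  "); show(object@coverage[[p]])
  }
  for (p in names(object@ruv)) {
    cat("  ", p, " ", sep = ""); show(object@ruv[[p]])
  }
  if (length(object@tree)) {
    cat("  tree space: ")
    show(object@tree$coverage)
    cat("  tree-space "); show(object@tree$ruv)
    cat("  "); show(object@tree$clades)
  }
})

#' Scenario presets
#'
#' Ready-made configurations of the demonstration experiments:
#' * `scenario1` — hierarchical Yule + phylogenetic BM, correctly specified up
#'   to a mild tip-count rejection filter;
#' * `scenario2` — same data-generating process, but the inference-side prior
#'   on the birth rate is shifted to log-mean -2.0 (simulation uses -3.25):
#'   the birth-rate coverage collapses to 0;
#' * `scenario3` — as scenario 1 but with a severe rejection window (only
#'   trees within the window are kept), a misspecification that coverage
#'   passes but rank-uniformity flags;
#' * `kingman_rf` — 5-taxon Kingman coalescent with Ne known and fixed at 1.0,
#'   validated in tree space via RF distances to a shared reference tree;
#' * `normal_normal` — conjugate smoke test of the whole pipeline.
#'
#' At `"full"` scale the reference settings are used (n = 100, tree sizes
#' around 150 tips, rejection window `[100, 200]` in scenario 3, L = 200 of
#' 10,000 retained states). The `"desk"` scale (default) keeps every
#' structural choice but shrinks tree sizes (`tips = 13` expected tips by
#' default; `tips = 30` for runs that need an informative trait rate),
#' replicate count (n = 20) and chain length so a full run fits in minutes.
#' Rejection windows at desk scale preserve the full-scale rejection fractions:
#' the mild filter drops the ~10% largest trees (plus a small-tree floor that
#' keeps the trait rate identifiable), the severe scenario-3 filter keeps a
#' `[0.9, 1.1] * tips` window, i.e. ~90% of trees rejected. Chains
#' are three times longer at `tips = 30`: the time-tree kernels need them to
#' mix, and under-mixed trees show up as a spurious rank shift in the trait
#' rate (which is exactly what these protocols are built to catch).
#'
#' @param name preset name.
#' @param scale `"desk"` or `"full"`.
#' @param n replicate-count override.
#' @param tips expected tree size at desk scale (13 or 30).
#' @param engine engine override (`"mh"` or `"exact"`; `kingman_rf` and
#'   `normal_normal` accept `"exact"`).
#' @param masterSeed master seed.
#' @return an [ExperimentConfig-class].
#' @export
scenarioPreset <- function(name = c("scenario1", "scenario2", "scenario3",
                                    "kingman_rf", "normal_normal"),
                           scale = c("desk", "full"), n = NULL, tips = 13,
                           engine = NULL, masterSeed = 1L) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1L], "'; available: scenario1, scenario2, ",
         "scenario3, kingman_rf, normal_normal"))
  scale <- match.arg(scale)
  desk <- scale == "desk"
  meanTips <- if (desk) tips else 150
  tauPrior <- c(log(log(meanTips) / exp(-3.25)), 0.1)
  ln325 <- c(-3.25, 0.2); ln25 <- c(-2.5, 0.5)
  big <- desk && tips >= 30
  mildCap <- ceiling(meanTips * log(10))  # ~90th percentile of the tip count
  cfg <- new("ExperimentConfig",
             name = name, model = "yule_bm", scale = scale,
             n = as.integer(if (!is.null(n)) n else if (desk) 20L else 100L),
             alpha = 0.95,
             bins = if (!is.null(n) && n >= 100L || !desk) 20L else 10L,
             L = 200L,
             burninFraction = 0.1,
             chainLength = if (!desk) 200000L else if (big) 60000L else 20000L,
             sampleEvery = if (!desk) 20L else if (big) 30L else 10L,
             engine = "mh",
             simLambdaPrior = ln325, infLambdaPrior = ln325,
             simRPrior = ln25, infRPrior = ln25,
             tauPrior = tauPrior, y0 = 0,
             rejection = if (desk) c(5, mildCap) else c(2, 345),
             s = 5L, Ne = 1, nObs = 5L,
             referenceMode = "per-replicate",
             masterSeed = as.integer(masterSeed))
  if (name == "scenario2") cfg@infLambdaPrior <- c(-2.0, 0.2)
  if (name == "scenario3")
    cfg@rejection <- if (desk) c(ceiling(meanTips * 0.9), floor(meanTips * 1.1))
                     else c(100, 200)
  if (name == "kingman_rf") {
    cfg@model <- "kingman_rf"
    cfg@rejection <- numeric(0)
    cfg@referenceMode <- "shared"
    cfg@n <- as.integer(if (!is.null(n)) n else if (desk) 50L else 100L)
  }
  if (name == "normal_normal") {
    cfg@model <- "normal_normal"
    cfg@rejection <- numeric(0)
    # generous L: the shortest-window HPD of L draws undercovers at small L,
    # and the conjugate draws are cheap (iid for the exact engine)
    cfg@chainLength <- 10000L; cfg@sampleEvery <- 5L; cfg@L <- 400L
  }
  if (!is.null(engine)) cfg@engine <- match.arg(engine, c("mh", "exact"))
  validObject(cfg)
  cfg
}

# counter-based per-replicate seed derivation (kept below 2^31)
.replicateSeed <- function(masterSeed, i) {
  (as.numeric(masterSeed) * 48271 + i * 1000003) %% 2147483647
}

#' Run a validation experiment end to end
#'
#' Executes the three pipeline stages: simulation (parameters from the
#' simulation-side priors, data from the likelihood, rejection rule applied),
#' inference (MH chains per replicate under the inference-side priors, or
#' exact conditional draws when `engine = "exact"`), and calibration (coverage
#' plus rank-uniformity for every scalar parameter and tree functional; tree
#' coverage, tree RUV and clade calibration for tree-space runs). Deterministic
#' given the master seed; failed replicates are excluded and reported, never
#' resampled.
#'
#' @param config an [ExperimentConfig-class].
#' @param outputDir optional directory for on-disk artifacts (replicate data,
#'   traces, report files).
#' @return a [ValidationReport-class].
#' @export
runExperiment <- function(config, outputDir = NULL) {
  res <- switch(config@model,
                yule_bm = .runYuleBM(config),
                kingman_rf = .runKingmanRF(config),
                normal_normal = .runNormalNormal(config))
  report <- res$report
  if (!is.null(outputDir)) makeReport(report, outputDir, trees = res$trees,
                                      traits = res$traits, params = res$params)
  report
}

.calibrateScalars <- function(config, sets) {
  coverage <- lapply(sets, coverageCount, alpha = config@alpha)
  ruv <- lapply(sets, function(rs) ruvVerdict(sbcRanks(rs), bins = config@bins))
  list(coverage = coverage, ruv = ruv)
}

.runYuleBM <- function(config) {
  n <- config@n
  simLambda <- logNormalParams(config@simLambdaPrior[1], config@simLambdaPrior[2])
  simR <- logNormalParams(config@simRPrior[1], config@simRPrior[2])
  infLambda <- logNormalParams(config@infLambdaPrior[1], config@infLambdaPrior[2])
  infR <- logNormalParams(config@infRPrior[1], config@infRPrior[2])
  rej <- config@rejection
  truths <- matrix(NA_real_, n, 4,
                   dimnames = list(NULL, c("lambda", "r", "root_height",
                                           "tree_length")))
  draws <- lapply(1:4, function(i) matrix(NA_real_, n, config@L))
  names(draws) <- colnames(truths)
  trees <- vector("list", n); traits <- vector("list", n)
  taus <- numeric(n)
  failures <- integer(0)
  for (i in seq_len(n)) {
    set.seed(.replicateSeed(config@masterSeed, i))
    ok <- tryCatch({
      draw <- rejectionSample(function() {
        tau <- stats::rlnorm(1, config@tauPrior[1], config@tauPrior[2])
        lambda <- sampleLogNormal(1, simLambda)
        tt <- .simYuleOriginTT(lambda, tau)
        list(tt = tt, lambda = lambda, tau = tau)
      }, predicate = function(d) {
        length(rej) != 2L ||
          (d$tt$ntip >= rej[1] && d$tt$ntip <= rej[2])
      }, maxAttempts = 5000L)$draw
      r <- sampleLogNormal(1, simR)
      x <- stats::setNames(.simBMTT(draw$tt, r, config@y0), draw$tt$labels)
      model <- makeYuleBMModel(traits = x, tau = draw$tau, y0 = config@y0,
                               lambdaPrior = infLambda, rPrior = infR)
      tl <- mhRun(model, config@chainLength, config@sampleEvery)
      bt <- burninThin(tl, config@burninFraction, config@L)
      truths[i, ] <- c(draw$lambda, r, tt_root_height(draw$tt),
                       tt_sum_internal_heights(draw$tt) +
                         tt_root_height(draw$tt))
      for (p in colnames(truths))
        draws[[p]][i, ] <- bt$trace[[p]]
      trees[[i]] <- tt_to_phylo(draw$tt)
      traits[[i]] <- x
      taus[i] <- draw$tau
      TRUE
    }, error = function(e) {
      warning("replicate ", i, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) failures <- c(failures, i)
  }
  keep <- setdiff(seq_len(n), failures)
  if (length(keep) < 2L) stop("fewer than 2 replicates succeeded")
  sets <- lapply(c("lambda", "r", "root_height"), function(p)
    replicateSet(p, truths[keep, p], draws[[p]][keep, , drop = FALSE]))
  names(sets) <- c("lambda", "r", "root_height")
  cal <- .calibrateScalars(config, sets)
  report <- new("ValidationReport", config = config, replicates = sets,
                coverage = cal$coverage, ruv = cal$ruv, tree = list(),
                treeReplicates = NULL, failures = failures)
  params <- data.frame(replicate = keep, lambda = truths[keep, "lambda"],
                       r = truths[keep, "r"], tau = taus[keep],
                       y0 = config@y0)
  list(report = report, trees = trees[keep], traits = traits[keep],
       params = params)
}

.runKingmanRF <- function(config) {
  n <- config@n; s <- config@s; Ne <- config@Ne; L <- config@L
  shared <- config@referenceMode == "shared"
  set.seed(.replicateSeed(config@masterSeed, 0L))
  refs <- if (shared) list(tt_to_phylo(.simCoalescentTT(s, Ne)))
          else vector("list", n)
  truthTrees <- vector("list", n)
  sampleTrees <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.replicateSeed(config@masterSeed, i))
    truthTrees[[i]] <- tt_to_phylo(.simCoalescentTT(s, Ne))
    if (!shared) refs[[i]] <- tt_to_phylo(.simCoalescentTT(s, Ne))
    if (config@engine == "exact") {
      sampleTrees[[i]] <- lapply(seq_len(L), function(j)
        tt_to_phylo(.simCoalescentTT(s, Ne)))
    } else {
      tl <- mhRun(makeCoalescentModel(s, Ne), config@chainLength,
                  config@sampleEvery)
      bt <- burninThin(tl, config@burninFraction, L)
      sampleTrees[[i]] <- lapply(bt$trees, parseNewick)
    }
  }
  trs <- treeReplicateSet(truthTrees, sampleTrees, refs)
  ranks <- referenceTreeRanks(trs)
  tree <- list(coverage = treeCoverage(trs, alpha = config@alpha),
               ruv = ruvVerdict(ranks, bins = config@bins),
               clades = cladeCalibration(trs))
  rootRs <- functionalReplicates(trs, rootHeight, "root_height")
  cal <- .calibrateScalars(config, list(root_height = rootRs))
  report <- new("ValidationReport", config = config,
                replicates = list(root_height = rootRs),
                coverage = cal$coverage, ruv = cal$ruv, tree = tree,
                treeReplicates = trs, failures = integer(0))
  params <- data.frame(replicate = seq_len(n), s = s, Ne = Ne)
  list(report = report, trees = truthTrees, traits = NULL, params = params)
}

.runNormalNormal <- function(config) {
  n <- config@n; L <- config@L
  truths <- numeric(n)
  draws <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) {
    set.seed(.replicateSeed(config@masterSeed, i))
    theta <- stats::rnorm(1)
    y <- stats::rnorm(config@nObs, theta, 1)
    post <- normalNormalPosterior(y)
    if (config@engine == "exact") {
      draws[i, ] <- stats::rnorm(L, post$mean, post$sd)
    } else {
      tl <- mhRun(makeNormalNormalModel(y), config@chainLength,
                  config@sampleEvery)
      bt <- burninThin(tl, config@burninFraction, L)
      draws[i, ] <- bt$trace$theta
    }
    truths[i] <- theta
  }
  sets <- list(theta = replicateSet("theta", truths, draws))
  cal <- .calibrateScalars(config, sets)
  report <- new("ValidationReport", config = config, replicates = sets,
                coverage = cal$coverage, ruv = cal$ruv, tree = list(),
                treeReplicates = NULL, failures = integer(0))
  list(report = report, trees = NULL, traits = NULL,
       params = data.frame(replicate = seq_len(n), theta = truths))
}

#' Write a validation report (and its artifacts) to disk
#'
#' Emits coverage tables (covered count against its acceptance band), rank
#' TSVs, a JSON verdict summary, the simulated replicate data when available,
#' and the diagnostic plots (true-vs-posterior-mean with HPD whiskers, rank
#' histogram with band, ECDF with band) as PNG files.
#'
#' @param report a [ValidationReport-class].
#' @param dir output directory.
#' @param trees,traits,params optional simulation artifacts (as produced
#'   internally by [runExperiment()]).
#' @param plots also write PNG diagnostics.
#' @return `dir`, invisibly.
#' @export
makeReport <- function(report, dir, trees = NULL, traits = NULL,
                       params = NULL, plots = TRUE) {
  if (length(report@coverage) == 0L) stop("empty results: nothing to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  covTab <- do.call(rbind, lapply(names(report@coverage), function(p) {
    cr <- report@coverage[[p]]
    data.frame(parameter = p, covered = coveredCount(cr),
               n = length(cr@covered), alpha = cr@alpha,
               lower = cr@lower, upper = cr@upper,
               verdict = if (verdict(cr)) "pass" else "fail")
  }))
  utils::write.table(covTab, file.path(dir, "coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (p in names(report@ruv)) {
    rv <- report@ruv[[p]]
    utils::write.table(data.frame(rank = rv@ranks),
                       file.path(dir, paste0("ranks_", p, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  verdicts <- list(
    config = list(name = report@config@name, n = report@config@n,
                  L = report@config@L, alpha = report@config@alpha,
                  masterSeed = report@config@masterSeed,
                  engine = report@config@engine),
    coverage = lapply(report@coverage, function(cr)
      list(covered = coveredCount(cr), n = length(cr@covered),
           lower = cr@lower, upper = cr@upper, pass = verdict(cr))),
    ruv = lapply(report@ruv, function(rv)
      list(chisqP = rv@chisqP, ecdfPass = rv@ecdfPass,
           pattern = rv@pattern, pass = verdict(rv))),
    failures = report@failures)
  if (length(report@tree))
    verdicts$tree <- list(
      coverage = verdict(report@tree$coverage),
      ruv = verdict(report@tree$ruv),
      cladeCalibration = verdict(report@tree$clades))
  jsonlite::write_json(verdicts, file.path(dir, "verdicts.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(trees))
    writeReplicateSet(file.path(dir, "replicates"), trees, traits,
                      if (is.null(params)) data.frame() else params,
                      manifest = list(name = report@config@name,
                                      masterSeed = report@config@masterSeed))
  if (length(report@tree)) {
    utils::write.table(report@tree$clades@bins,
                       file.path(dir, "clade_calibration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (plots) .writePlots(report, dir)
  invisible(dir)
}

.writePlots <- function(report, dir) {
  for (p in names(report@coverage)) {
    ggplot2::ggsave(file.path(dir, paste0("coverage_", p, ".png")),
                    plotCoverage(report@replicates[[p]], report@coverage[[p]]),
                    width = 5, height = 5, dpi = 120)
  }
  for (p in names(report@ruv)) {
    ggplot2::ggsave(file.path(dir, paste0("ranks_", p, ".png")),
                    plotRankHistogram(report@ruv[[p]]),
                    width = 5, height = 4, dpi = 120)
    ggplot2::ggsave(file.path(dir, paste0("ecdf_", p, ".png")),
                    plotRankEcdf(report@ruv[[p]]),
                    width = 5, height = 4, dpi = 120)
  }
  invisible(NULL)
}
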