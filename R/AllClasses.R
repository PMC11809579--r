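#' @import methods
NULL

#' Scalar replicate set
#'
#' The state of the validation pipeline for one scalar parameter or functional:
#' `n` generating ("true") values drawn from the prior and, for each, `L`
#' retained posterior draws.
#'
#' @slot parameter name of the parameter/functional.
#' @slot truths numeric vector of length `n`.
#' @slot draws `n x L` matrix of posterior draws (row i belongs to truth i).
#' @export
setClass("ReplicateSet",
         representation(parameter = "character", truths = "numeric",
                        draws = "matrix"),
         validity = function(object) {
           if (length(object@parameter) != 1L) return("one parameter name")
           if (nrow(object@draws) != length(object@truths))
             return("draws must have one row per truth")
           if (ncol(object@draws) < 20L)
             return("need L >= 20 posterior draws per replicate")
           TRUE
         })

#' @rdname ReplicateSet-class
#' @param parameter,truths,draws see slots.
#' @export
replicateSet <- function(parameter, truths, draws) {
  new("ReplicateSet", parameter = parameter, truths = as.numeric(truths),
      draws = as.matrix(draws))
}

#' @rdname ReplicateSet-class
#' @param object,x a `ReplicateSet`.
#' @export
setMethod("show", "ReplicateSet", function(object) {
  cat("ReplicateSet for '", object@parameter, "': n = ",
      length(object@truths), " replicates, L = ", ncol(object@draws),
      " posterior draws each\n", sep = "")
})

#' @rdname ReplicateSet-class
#' @export
nReplicates <- function(x) length(x@truths)

#' Coverage validation report
#'
#' Result of checking how often true values fall inside their
#' `alpha`-credibility HPD intervals, with the binomial acceptance band.
#'
#' @slot parameter name of the parameter/functional.
#' @slot covered logical per replicate.
#' @slot intervals `n x 2` matrix of HPD bounds.
#' @slot alpha credibility level.
#' @slot lower,upper binomial acceptance bounds on the covered count.
#' @slot level confidence level of the acceptance band.
#' @export
setClass("CoverageReport",
         representation(parameter = "character", covered = "logical",
                        intervals = "matrix", alpha = "numeric",
                        lower = "integer", upper = "integer",
                        level = "numeric"),
         validity = function(object) {
           if (nrow(object@intervals) != length(object@covered))
             return("one interval per replicate")
           if (object@alpha <= 0 || object@alpha >= 1)
             return("alpha must be in (0,1)")
           TRUE
         })

#' @rdname CoverageReport-class
#' @param x,object a `CoverageReport`.
#' @export
coveredCount <- function(x) sum(x@covered)

#' Pass/fail verdict of a validation report
#'
#' @param x a report object.
#' @return logical.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname CoverageReport-class
#' @export
setMethod("verdict", "CoverageReport", function(x) {
  k <- coveredCount(x)
  k >= x@lower && k <= x@upper
})

#' @rdname CoverageReport-class
#' @export
setMethod("show", "CoverageReport", function(object) {
  k <- coveredCount(object)
  n <- length(object@covered)
  cat(sprintf(
    "Coverage of '%s': %d/%d inside %d%%-HPD; acceptance band [%d, %d] -> %s\n",
    object@parameter, k, n, round(100 * object@alpha),
    object@lower, object@upper, if (verdict(object)) "PASS" else "FAIL"))
})

#' Rank-uniformity validation report
#'
#' SBC ranks of true values among their posterior draws, with histogram and
#' ECDF-band diagnostics and a qualitative failure-pattern tag.
#'
#' @slot ranks integer ranks on `1..L+1`.
#' @slot L posterior draws per replicate.
#' @slot bins histogram bin count.
#' @slot counts per-bin rank counts.
#' @slot bandLower,bandUpper per-bin 95% binomial band on counts.
#' @slot chisqP chi-square goodness-of-fit p-value against uniformity.
#' @slot ecdfPass logical: ECDF within its simultaneous band.
#' @slot pattern one of `uniform`, `central-hump`, `horns`, `left-shift`,
#'   `right-shift`.
#' @slot pass overall verdict.
#' @export
setClass("RuvReport",
         representation(ranks = "integer", L = "integer", bins = "integer",
                        counts = "numeric", bandLower = "numeric",
                        bandUpper = "numeric", chisqP = "numeric",
                        ecdfPass = "logical", pattern = "character",
                        pass = "logical"))

#' @rdname RuvReport-class
#' @param x,object a `RuvReport`.
#' @export
setMethod("verdict", "RuvReport", function(x) x@pass)

#' @rdname RuvReport-class
#' @export
rankPattern <- function(x) x@pattern

#' @rdname RuvReport-class
#' @export
setMethod("show", "RuvReport", function(object) {
  cat(sprintf(
    "RUV: n = %d ranks on 1..%d, %d bins; chi-square p = %.3g; ECDF band %s; pattern '%s' -> %s\n",
    length(object@ranks), object@L + 1L, object@bins, object@chisqP,
    if (object@ecdfPass) "ok" else "violated", object@pattern,
    if (object@pass) "PASS" else "FAIL"))
})

#' Tree replicate set
#'
#' Tree-space analogue of [ReplicateSet-class]: true trees, their posterior
#' tree samples, and reference trees (one per replicate, or one shared).
#'
#' @slot truths list of `phylo` trees.
#' @slot samples list (length n) of lists of `phylo` posterior samples.
#' @slot references list of `phylo`: length n, or length 1 when shared.
#' @slot taxa common taxon ordering.
#' @export
setClass("TreeReplicateSet",
         representation(truths = "list", samples = "list",
                        references = "list", taxa = "character"),
         validity = function(object) {
           n <- length(object@truths)
           if (length(object@samples) != n)
             return("one sample list per truth")
           if (!length(object@references) %in% c(1L, n))
             return("references: one per replicate or a single shared tree")
           L <- lengths(object@samples)
           if (length(unique(L)) != 1L)
             return("equal L across replicates")
           TRUE
         })

#' @rdname TreeReplicateSet-class
#' @param truths,samples,references,taxa see slots.
#' @export
treeReplicateSet <- function(truths, samples, references,
                             taxa = sort(truths[[1L]]$tip.label)) {
  if (inherits(references, "phylo")) references <- list(references)
  new("TreeReplicateSet", truths = truths, samples = samples,
      references = references, taxa = taxa)
}

#' @rdname TreeReplicateSet-class
#' @param object a `TreeReplicateSet`.
#' @export
setMethod("show", "TreeReplicateSet", function(object) {
  cat("TreeReplicateSet: n =", length(object@truths), "replicates, L =",
      length(object@samples[[1L]]), "tree samples each,",
      length(object@taxa), "taxa;",
      if (length(object@references) == 1L) "shared" else "per-replicate",
      "reference tree(s)\n")
})

#' Clade-support calibration result
#'
#' Pooled (clade, posterior support, is-true) records across replicates and the
#' per-support-bin calibration test: among clades with support in a bin, the
#' fraction that are true clades should match the bin midpoint.
#'
#' @slot table data.frame with columns `replicate`, `clade`, `support`,
#'   `isTrue`.
#' @slot bins data.frame with columns `bin`, `mid`, `nClades`, `fracTrue`,
#'   `p`, `pAdjusted`.
#' @slot pass overall verdict (no bin rejects at Bonferroni-corrected 5%).
#' @export
setClass("CladeCalibration",
         representation(table = "data.frame", bins = "data.frame",
                        pass = "logical"))

#' @rdname CladeCalibration-class
#' @param x,object a `CladeCalibration`.
#' @export
setMethod("verdict", "CladeCalibration", function(x) x@pass)

#' @rdname CladeCalibration-class
#' @export
setMethod("show", "CladeCalibration", function(object) {
  cat("Clade-support calibration over", nrow(object@table), "pooled clades in",
      nrow(object@bins), "support bins ->",
      if (object@pass) "PASS" else "FAIL", "\n")
})
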