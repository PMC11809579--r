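#' Parse a Newick string into a time tree
#'
#' Trees are represented as [ape::phylo] objects. All generative models in this
#' package produce rooted, binary, ultrametric time trees (every tip at age 0);
#' `parseNewick()` enforces those invariants unless `strict = FALSE`, which
#' admits non-ultrametric input for the diagnostics layer. A root edge, when
#' present, is interpreted as the stem from the origin of the process to the
#' root, i.e. origin age = root height + root edge length.
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @param strict enforce ultrametricity (tolerance `1e-6` relative to the root
#'   height) and binary topology.
#' @return an object of class `phylo`.
#' @seealso [writeNewick()], [rootHeight()], [originAge()]
#' @export
parseNewick <- function(text, strict = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  .checkBalanced(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("malformed Newick string (could not be parsed): ", substr(text, 1, 60))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (strict) validateTimeTree(phy)
  phy
}

# balanced-parenthesis scan so parse errors carry a character position
.checkBalanced <- function(text) {
  ch <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "(") depth <- depth + 1L
    if (ch[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         length(ch))
  invisible(TRUE)
}

#' Validate a rooted binary ultrametric time tree
#'
#' Checks that the tree is rooted and binary, that all branch lengths are
#' non-negative, and that all tips are contemporaneous (age 0) within a relative
#' tolerance. The origin age, when present as a root edge, must not be smaller
#' than the root height.
#'
#' @param phy a `phylo` object.
#' @param tol relative ultrametricity tolerance (fraction of the root height).
#' @return the tree, invisibly; errors describe the violated invariant.
#' @export
validateTimeTree <- function(phy, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels")
  if (n >= 2L) {
    if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge))
      stop("branch lengths are mandatory on all non-root edges")
    if (any(phy$edge.length < 0))
      stop("negative branch length")
    if (phy$Nnode != n - 1L)
      stop("tree is not binary (", phy$Nnode, " internal nodes for ", n,
           " tips)")
    depth <- ape::node.depth.edgelength(phy)
    tipd <- depth[seq_len(n)]
    h <- max(tipd)
    if (h > 0 && (max(tipd) - min(tipd)) > tol * h)
      stop("tree is not ultrametric: tip age spread ",
           format(max(tipd) - min(tipd)), " exceeds tolerance")
  }
  invisible(phy)
}

#' Write a tree as a Newick string
#'
#' Inverse of [parseNewick()]: topology and branch lengths round-trip within
#' floating-point formatting, and an origin age is written as a root edge.
#'
#' @param phy a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
writeNewick <- function(phy, digits = 12) {
  ape::write.tree(phy, digits = digits)
}

#' Scalar tree functionals
#'
#' `rootHeight()` is the age of the root (maximum tip-to-root path length);
#' `treeLength()` the sum of branch lengths (excluding any stem edge);
#' `tipCount()` the number of tips; `cherryCount()` the number of internal
#' nodes both of whose children are tips; `originAge()` the stem origin age
#' (root height + root edge), or `NA` if the tree has no stem.
#'
#' @param phy a `phylo` object.
#' @return a scalar.
#' @export
rootHeight <- function(phy) {
  if (length(phy$tip.label) == 1L) return(0)
  max(ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)])
}

#' @rdname rootHeight
#' @export
treeLength <- function(phy) {
  if (isTRUE(attr(phy, "single.tip"))) return(0)
  sum(phy$edge.length)
}

#' @rdname rootHeight
#' @export
tipCount <- function(phy) length(phy$tip.label)

#' @rdname rootHeight
#' @export
cherryCount <- function(phy) {
  n <- length(phy$tip.label)
  if (n < 2L) stop("cherry count is undefined for a single-tip tree")
  istip <- phy$edge[, 2L] <= n
  sum(tapply(istip, phy$edge[, 1L], all))
}

#' @rdname rootHeight
#' @export
originAge <- function(phy) {
  if (length(phy$tip.label) == 1L)
    return(if (!is.null(phy$root.edge)) phy$root.edge
           else if (nrow(phy$edge) == 1L) phy$edge.length[1L]
           else NA_real_)
  if (is.null(phy$root.edge)) return(NA_real_)
  rootHeight(phy) + phy$root.edge
}

#' Rooted clades of a tree
#'
#' Each internal node implies a clade: the set of tip labels descending from
#' it. Clades are encoded as canonical keys — tip indices under the fixed taxon
#' ordering (lexicographic over labels), joined by commas — so two trees on the
#' same taxa produce directly comparable keys. With `nontrivialOnly = TRUE`
#' (the default) the root clade (all taxa) is excluded, leaving `s - 2` clades
#' for a binary rooted tree with `s` tips.
#'
#' @param phy a `phylo` object.
#' @param nontrivialOnly drop the root clade.
#' @param taxa taxon ordering; defaults to `sort(phy$tip.label)`.
#' @return character vector of clade keys, with the taxon ordering attached as
#'   attribute `"taxa"`.
#' @export
cladeSet <- function(phy, nontrivialOnly = TRUE, taxa = sort(phy$tip.label)) {
  n <- length(phy$tip.label)
  if (n < 2L || (nontrivialOnly && n == 2L)) {
    out <- character(0); attr(out, "taxa") <- taxa; return(out)
  }
  idx <- match(phy$tip.label, taxa)
  if (anyNA(idx)) stop("tip labels not covered by the taxon ordering")
  tt <- tt_from_phylo(phy)
  sets <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) sets[[i]] <- idx[i]
  ord <- tt_postorder(tt)
  for (z in ord)
    sets[[z]] <- c(sets[[tt$kid1[z]]], sets[[tt$kid2[z]]])
  keep <- if (nontrivialOnly) setdiff(ord, tt$root) else ord
  out <- vapply(sets[keep],
                function(s) paste(sort.int(s), collapse = ","), "")
  attr(out, "taxa") <- taxa
  out
}

#' Robinson-Foulds distance between rooted trees
#'
#' Counts the clades implied by one tree but not the other: the size of the
#' symmetric difference of the two nontrivial rooted clade sets. Both trees
#' must carry the same taxon set. The distance is a metric on rooted
#' topologies, is 0 iff the topologies agree, and is at most `2 (s - 2)`.
#'
#' @param t1,t2 `phylo` objects on identical taxon sets.
#' @return integer distance.
#' @export
rfDistance <- function(t1, t2) {
  taxa <- sort(t1$tip.label)
  if (!identical(taxa, sort(t2$tip.label)))
    stop("trees have different taxon sets")
  c1 <- cladeSet(t1, taxa = taxa)
  c2 <- cladeSet(t2, taxa = taxa)
  length(setdiff(c1, c2)) + length(setdiff(c2, c1))
}

#' Build a scalar tree functional
#'
#' Returns a function `phylo -> numeric` for use with the calibration layer,
#' e.g. root-age coverage or distance-to-reference ranking. The metric registry
#' is open: any `(tree, tree) -> real` function can serve as the distance for
#' `"rf_to_reference"`-style functionals by passing it as `metric`.
#'
#' @param name one of `"root_height"`, `"tree_length"`, `"tip_count"`,
#'   `"cherry_count"`, `"rf_to_reference"`.
#' @param reference reference tree (required for `"rf_to_reference"`).
#' @param metric tree distance used by `"rf_to_reference"`; default
#'   [rfDistance()].
#' @return a function of one `phylo` argument.
#' @export
treeFunctional <- function(name = c("root_height", "tree_length", "tip_count",
                                    "cherry_count", "rf_to_reference"),
                           reference = NULL, metric = rfDistance) {
  name <- match.arg(name)
  switch(name,
    root_height  = rootHeight,
    tree_length  = treeLength,
    tip_count    = tipCount,
    cherry_count = cherryCount,
    rf_to_reference = {
      if (is.null(reference)) stop("'rf_to_reference' needs a reference tree")
      force(metric)
      function(phy) metric(reference, phy)
    })
}
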