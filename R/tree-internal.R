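# Internal time-tree representation used by the simulators and the MCMC engine.
#
# A "tt" is a plain list describing a rooted binary ultrametric tree:
#   ntip    number of tips; nodes 1..ntip are tips, ntip+1 .. 2*ntip-1 internal
#   parent  integer parent index per node (0 for the root)
#   kid1,   integer child indices per node (0 for tips)
#   kid2
#   height  node age (time before present); tips sit at 0
#   labels  tip labels, indexed by tip node id
#   origin  origin (stem) age, NA when the tree has no stem
#   root    index of the root node
#
# Heights, not branch lengths, are primary: every proposal and density here is
# a function of node ages, and parent > child ordering makes any height-sorted
# sweep over internal nodes a valid post-order traversal.

tt_new <- function(ntip, parent, kid1, kid2, height, labels, origin = NA_real_,
                   root = NULL) {
  if (is.null(root)) root <- which(parent == 0L)
  list(ntip = ntip, parent = parent, kid1 = kid1, kid2 = kid2,
       height = height, labels = labels, origin = origin, root = root)
}

# single-tip tree (stem only)
tt_single <- function(label = "t1", origin = NA_real_) {
  tt_new(1L, 0L, 0L, 0L, 0, label, origin = origin, root = 1L)
}

tt_root_height <- function(tt) tt$height[tt$root]

# total lineage time from origin to present equals origin + sum of internal
# heights; without an origin, tree length is 2*sum(internal) - ... computed
# directly from edges instead.
tt_sum_internal_heights <- function(tt) {
  if (tt$ntip == 1L) return(0)
  sum(tt$height[(tt$ntip + 1L):(2L * tt$ntip - 1L)])
}

tt_tree_length <- function(tt) {
  nonroot <- seq_len(2L * tt$ntip - 1L)[-tt$root]
  len <- sum(tt$height[tt$parent[nonroot]] - tt$height[nonroot])
  if (!is.na(tt$origin)) len <- len + (tt$origin - tt$height[tt$root])
  len
}

tt_internal_nodes <- function(tt) {
  if (tt$ntip == 1L) integer(0) else (tt$ntip + 1L):(2L * tt$ntip - 1L)
}

# post-order (children before parents) over internal nodes: increasing height
tt_postorder <- function(tt) {
  int <- tt_internal_nodes(tt)
  int[order(tt$height[int])]
}

tt_validate <- function(tt, tol = 1e-9) {
  n <- tt$ntip
  stopifnot(length(tt$parent) == 2L * n - 1L || n == 1L)
  if (n > 1L) {
    for (z in tt_internal_nodes(tt)) {
      c1 <- tt$kid1[z]; c2 <- tt$kid2[z]
      stopifnot(c1 > 0L, c2 > 0L, tt$parent[c1] == z, tt$parent[c2] == z,
                tt$height[z] >= tt$height[c1] - tol,
                tt$height[z] >= tt$height[c2] - tol)
    }
  }
  stopifnot(sum(tt$parent == 0L) == 1L, all(tt$height[seq_len(n)] == 0))
  if (!is.na(tt$origin)) stopifnot(tt$origin >= tt_root_height(tt) - tol)
  invisible(TRUE)
}

# -- conversion to/from ape::phylo (vectorised; no per-node loops) ------------

tt_to_phylo <- function(tt) {
  n <- tt$ntip
  if (n == 1L) {
    # ape cannot hold a 1-tip binary tree; encode as stem-only "phylo"
    tr <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                         edge.length = if (is.na(tt$origin)) 0 else tt$origin,
                         tip.label = tt$labels, Nnode = 1L),
                    class = "phylo", order = "cladewise")
    attr(tr, "single.tip") <- TRUE
    return(tr)
  }
  int <- tt_internal_nodes(tt)
  newid <- integer(2L * n - 1L)
  newid[seq_len(n)] <- seq_len(n)
  # ape convention: root is n+1; number internals root-first (decreasing age)
  newid[int[order(tt$height[int], decreasing = TRUE)]] <- (n + 1L):(2L * n - 1L)
  nonroot <- seq_len(2L * n - 1L)[-tt$root]
  edge <- cbind(newid[tt$parent[nonroot]], newid[nonroot])
  elen <- tt$height[tt$parent[nonroot]] - tt$height[nonroot]
  o <- order(edge[, 1L], edge[, 2L])
  tr <- structure(list(edge = edge[o, , drop = FALSE],
                       edge.length = elen[o],
                       tip.label = tt$labels, Nnode = n - 1L),
                  class = "phylo", order = NULL)
  if (!is.na(tt$origin)) tr$root.edge <- tt$origin - tt_root_height(tt)
  tr
}

tt_from_phylo <- function(phy) {
  if (isTRUE(attr(phy, "single.tip")) ||
      (length(phy$tip.label) == 1L)) {
    org <- if (!is.null(phy$root.edge)) phy$root.edge else
      if (nrow(phy$edge) == 1L) phy$edge.length[1L] else NA_real_
    return(tt_single(phy$tip.label[1L], origin = org))
  }
  phy <- ape::reorder.phylo(phy, "cladewise")  # parents before children
  n <- length(phy$tip.label)
  nn <- 2L * n - 1L
  if (phy$Nnode != n - 1L)
    stop("tree is not binary: expected ", n - 1L, " internal nodes, got ",
         phy$Nnode)
  parent <- integer(nn); kid1 <- integer(nn); kid2 <- integer(nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  first <- !duplicated(phy$edge[, 1L])
  kid1[phy$edge[first, 1L]] <- phy$edge[first, 2L]
  kid2[phy$edge[!first, 1L]] <- phy$edge[!first, 2L]
  depth <- numeric(nn)
  root <- n + 1L
  for (i in seq_len(nrow(phy$edge)))
    depth[phy$edge[i, 2L]] <- depth[phy$edge[i, 1L]] + phy$edge.length[i]
  h <- max(depth[seq_len(n)]) - depth
  org <- if (!is.null(phy$root.edge)) h[root] + phy$root.edge else NA_real_
  tt_new(n, parent, kid1, kid2, h, phy$tip.label, origin = org, root = root)
}

# -- sufficient statistics for the phylogenetic BM likelihood -----------------

# Felsenstein pruning on unit-rate branch lengths. Returns logdet(C) and the
# quadratic form Q = (y - y0)' C^{-1} (y - y0) where C is the shared-path
# matrix, so that the log-density at rate r is
#   -ntip/2 log(2 pi r) - logdet/2 - Q/(2 r).
tt_bm_suffstat <- function(tt, x, y0) {
  n <- tt$ntip
  if (n == 1L) {
    stop("phylogenetic BM needs >= 2 tips (single tip has zero-length paths)")
  }
  h <- tt$height; k1 <- tt$kid1; k2 <- tt$kid2
  xhat <- numeric(2L * n - 1L); v <- numeric(2L * n - 1L)
  xhat[seq_len(n)] <- x
  logdet <- 0; Q <- 0
  ord <- tt_postorder(tt)
  for (z in ord) {
    c1 <- k1[z]; c2 <- k2[z]
    v1 <- h[z] - h[c1] + v[c1]
    v2 <- h[z] - h[c2] + v[c2]
    vs <- v1 + v2
    if (vs <= 0)
      stop("singular trait covariance: zero-length cherry at the pair (",
           if (c1 <= n) tt$labels[c1] else "internal", ", ",
           if (c2 <= n) tt$labels[c2] else "internal", ")")
    d <- xhat[c1] - xhat[c2]
    Q <- Q + d * d / vs
    logdet <- logdet + log(vs)
    xhat[z] <- (xhat[c1] * v2 + xhat[c2] * v1) / vs
    v[z] <- v1 * v2 / vs
  }
  root <- ord[length(ord)]
  if (v[root] <= 0) stop("singular trait covariance at the root")
  d0 <- xhat[root] - y0
  Q <- Q + d0 * d0 / v[root]
  logdet <- logdet + log(v[root])
  list(logdet = logdet, Q = Q)
}

tt_bm_logdens <- function(ss, r, ntip) {
  -0.5 * ntip * log(2 * pi * r) - 0.5 * ss$logdet - ss$Q / (2 * r)
}

# origin-conditioned labeled pure-birth log-density:
#   (s - 1) log(lambda) - lambda * (origin + sum of internal node heights)
tt_yule_logdens <- function(tt, lambda, tau = tt$origin) {
  if (is.na(tau)) stop("Yule density needs an origin age")
  if (tau < tt_root_height(tt) - 1e-9)
    stop("origin age ", tau, " is below the root height ", tt_root_height(tt))
  s <- tt$ntip
  (s - 1) * log(lambda) - lambda * (tau + tt_sum_internal_heights(tt))
}

# Kingman coalescent log-density from internal node ages
tt_coalescent_logdens <- function(tt, Ne) {
  if (Ne <= 0) stop("effective population size must be positive")
  s <- tt$ntip
  if (s == 1L) return(0)
  ages <- sort(tt$height[tt_internal_nodes(tt)])
  k <- s:2
  dt <- diff(c(0, ages))
  sum(-k * (k - 1) / (2 * Ne) * dt) - (s - 1) * log(Ne)
}
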