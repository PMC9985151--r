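#' Neighbor joining
#'
#' Classic agglomerative NJ with the Studier-Keppler Q-criterion.  On an
#' additive distance matrix it recovers the generating unrooted topology and
#' branch lengths exactly; negative branch-length estimates are clamped to
#' zero.  Ties in the Q-criterion are broken deterministically (first pair in
#' row-major order).
#'
#' @param D symmetric non-negative numeric matrix with zero diagonal and
#'   unique labels as dimnames (>= 3 taxa).
#' @return an unrooted "phylo" tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  labs <- rownames(D)
  if (is.null(labs)) labs <- colnames(D)
  if (is.null(labs) || anyDuplicated(labs)) {
    abort_ri("distance matrix needs unique labels", "ri_invalid_matrix")
  }
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(diag(D) != 0)) {
    abort_ri("distance matrix must be symmetric with zero diagonal",
             "ri_invalid_matrix")
  }
  r <- nrow(D)
  if (r < 3L) abort_ri("need at least 3 taxa", "ri_parameter")
  node <- labs  # newick fragment per active node
  while (r > 3L) {
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    k <- arrayInd(which.min(t(Q)), dim(Q))  # row-major first minimum
    i <- min(k)
    j <- max(k)
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    li <- max(li, 0)
    lj <- max(lj, 0)
    merged <- sprintf("(%s:%.10g,%s:%.10g)", node[i], li, node[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], merged)
    D <- D2
    r <- r - 1L
  }
  l1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  l2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  l3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 node[1], l1, node[2], l2, node[3], l3)
  ape::read.tree(text = txt)
}

# Non-trivial bipartitions of an unrooted tree, each canonicalized as the
# sorted leaf set on the side *not* containing the overall smallest label,
# collapsed to a key string.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  ref <- min(tips)
  nnode <- max(tree$edge)
  below <- vector("list", nnode)
  for (i in seq_len(n)) below[[i]] <- tips[i]
  # accumulate tip sets in reverse edge order (ape edges are parent->child,
  # children appear after parents in pruningwise/postorder traversal)
  for (ei in ape::postorder(tree)) {
    p <- tree$edge[ei, 1L]
    ch <- tree$edge[ei, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  for (ei in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[ei, 2L]
    if (ch <= n) next  # trivial bipartition
    side <- below[[ch]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

check_leaf_sets <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    abort_ri("trees must have identical leaf sets", "ri_leaf_set")
  }
}

#' Normalized Robinson-Foulds distance
#'
#' Symmetric difference of the non-trivial bipartition sets of the two
#' unrooted trees, divided by the total number of non-trivial bipartitions
#' in both trees (so two fully resolved trees with no shared split score 1).
#'
#' @param t1,t2 "phylo" trees over the same leaf set (>= 4 leaves).
#' @return a fraction in `[0, 1]`; 0 iff the unrooted topologies agree.
#' @export
rf_normalized <- function(t1, t2) {
  check_leaf_sets(t1, t2)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  denom <- length(b1) + length(b2)
  if (denom == 0L) return(0)
  (length(setdiff(b1, b2)) + length(setdiff(b2, b1))) / denom
}

#' Quartet distance
#'
#' Fraction of the `choose(n, 4)` leaf quartets whose induced unrooted
#' topology differs between the trees, by explicit enumeration (intended for
#' n up to ~25).  A quartet agrees when both trees induce the same resolved
#' split, or when both leave it unresolved (star); a star never matches a
#' resolved split.
#'
#' @param t1,t2 "phylo" trees over the same leaf set (>= 4 leaves).
#' @return a fraction in `[0, 1]`; 0 for topologically identical binary
#'   trees.
#' @export
quartet_distance <- function(t1, t2) {
  check_leaf_sets(t1, t2)
  tips <- sort(t1$tip.label)
  n <- length(tips)
  if (n < 4L) abort_ri("need at least 4 leaves", "ri_parameter")
  d1 <- topo_dist_safe(t1)[tips, tips]
  d2 <- topo_dist_safe(t2)[tips, tips]
  quartets <- utils::combn(n, 4L)
  agree <- 0L
  for (q in seq_len(ncol(quartets))) {
    idx <- quartets[, q]
    if (quartet_split(d1, idx) == quartet_split(d2, idx)) agree <- agree + 1L
  }
  1 - agree / ncol(quartets)
}

# Topological (unit branch length) leaf-to-leaf distances.
topo_dist_safe <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  ape::cophenetic.phylo(tree)
}

# Induced quartet topology by the four-point condition: 1 = ab|cd,
# 2 = ac|bd, 3 = ad|bc, 0 = unresolved (star).
quartet_split <- function(d, idx) {
  a <- idx[1]; b <- idx[2]; c_ <- idx[3]; e <- idx[4]
  s <- c(d[a, b] + d[c_, e], d[a, c_] + d[b, e], d[a, e] + d[b, c_])
  m <- min(s)
  if (sum(s == m) == 1L) which.min(s) else 0L
}
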