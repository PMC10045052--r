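## Neighbor-joining trees, Newick output and the three evaluation metrics:
## Pearson correlation of distance matrices, Fowlkes-Mallows index of
## tree-cut clusterings, and the triplet distance of two trees.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining; exact on additive matrices
#' (recovers the generating topology and branch lengths).  Negative branch
#' length estimates are kept internally and clamped only on output.
#'
#' @param matrix Symmetric distance matrix with zero diagonal (validated).
#' @return An unrooted tree of class `phylo` (ape).
#' @export
neighbor_joining <- function(matrix) {
  matrix <- dist_matrix(matrix)
  n <- nrow(matrix)
  if (n < 2) stop("need at least two taxa")
  if (n == 2) {
    d <- matrix[1, 2]
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        rownames(matrix)[1], d / 2,
                                        rownames(matrix)[2], d / 2))
    return(tr)
  }
  ape::nj(matrix)
}

newick_label <- function(x) {
  if (grepl("[\\s()\\[\\]':;,]", x, perl = TRUE))
    paste0("'", gsub("'", "''", x), "'")
  else x
}

#' Write a tree in Newick format
#'
#' Branch lengths are included; negative neighbor-joining estimates are
#' clamped to zero.  Labels containing spaces or Newick metacharacters are
#' quoted.
#'
#' @param tree A `phylo` tree.
#' @param path Output path; `NULL` returns the Newick string invisibly
#'   without writing.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- if (!is.null(tree$edge)) setdiff(tree$edge[, 1], tree$edge[, 2])[1]
          else NA_integer_
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(node, edge_idx) {
    lab <- if (node <= n_tip) newick_label(tree$tip.label[node]) else ""
    sub <- if (node > n_tip) {
      idx <- kids[[as.character(node)]]
      paste0("(", paste(vapply(idx, function(e)
        fmt(tree$edge[e, 2], e), character(1)), collapse = ","), ")")
    } else ""
    br <- if (!is.null(tree$edge.length) && !is.na(edge_idx))
      sprintf(":%.10g", max(0, tree$edge.length[edge_idx])) else ""
    paste0(sub, lab, br)
  }
  s <- paste0(fmt(root, NA_integer_), ";")
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Pearson correlation of two distance matrices
#'
#' Correlation over the strictly-upper-triangle entries.  When either
#' vector has zero variance (all sequences equidistant) the correlation is
#' undefined and `NA` is returned with a warning.
#'
#' @param m1,m2 Distance matrices over the same labels in the same order.
#' @return Real in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson_matrices <- function(m1, m2) {
  m1 <- dist_matrix(m1); m2 <- dist_matrix(m2)
  if (!identical(rownames(m1), rownames(m2)))
    stop("matrices must share labels and order")
  if (nrow(m1) < 3) stop("need at least 3 taxa for a meaningful correlation")
  v1 <- m1[upper.tri(m1)]
  v2 <- m2[upper.tri(m2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("correlation undefined: all sequences equidistant")
    return(NA_real_)
  }
  stats::cor(v1, v2)
}

root_for_cut <- function(tree) {
  if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
}

# height of every node: maximal branch-length distance to a descendant leaf
node_heights <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  h <- rep(0, n_node)
  # edges ordered so children are processed before parents (postorder)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    len <- if (is.null(po$edge.length)) 1 else max(0, po$edge.length[e])
    h[par] <- max(h[par], h[child] + len)
  }
  h
}

#' Cut a tree into k clusters
#'
#' The tree is rooted (midpoint rooting unless already rooted), every
#' internal node is assigned its height (maximal distance to a descendant
#' leaf), and the `k - 1` highest internal nodes are removed; the leaves of
#' the resulting components form the clusters, exactly as cutting a
#' dendrogram at a merge-height level.
#'
#' @param tree A `phylo` tree.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector mapping leaf labels to cluster ids (class
#'   `leaf_clustering`).
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (k < 1 || k > n_tip) stop("k must be between 1 and the number of leaves")
  labels <- tree$tip.label
  if (k == 1)
    return(structure(setNames(rep(1L, n_tip), labels),
                     class = "leaf_clustering"))
  if (k == n_tip)
    return(structure(setNames(seq_len(n_tip), labels),
                     class = "leaf_clustering"))
  tr <- root_for_cut(tree)
  n_tip <- length(tr$tip.label)
  h <- node_heights(tr)
  internal <- (n_tip + 1):(n_tip + tr$Nnode)
  depth <- rep(0L, n_tip + tr$Nnode)
  pre <- ape::reorder.phylo(tr, "cladewise")
  for (e in seq_len(nrow(pre$edge)))
    depth[pre$edge[e, 2]] <- depth[pre$edge[e, 1]] + 1L
  # heights are monotone along root-to-leaf paths, so the top k-1 internal
  # nodes (ties broken toward the root) form an upward-closed cut set
  ord <- internal[order(-h[internal], depth[internal], internal)]
  cut <- integer(0)
  n_clusters <- 1L
  for (v in ord) {
    if (n_clusters >= k) break
    cut <- c(cut, v)
    n_clusters <- n_clusters + length(which(pre$edge[, 1] == v)) - 1L
  }
  if (n_clusters != k)
    stop("cannot cut this tree into exactly k clusters")
  # cluster roots: nodes whose parent is cut but that are not cut themselves
  parent <- rep(NA_integer_, n_tip + tr$Nnode)
  parent[pre$edge[, 2]] <- pre$edge[, 1]
  membership <- setNames(integer(n_tip), tr$tip.label)
  cluster_of <- function(node) {
    # walk up until just below a cut node (or the root)
    prev <- node
    while (!is.na(parent[prev]) && !(parent[prev] %in% cut) ) prev <- parent[prev]
    # if no ancestor is cut, prev ends at root (which is in cut); handled below
    prev
  }
  roots <- integer(0)
  for (tip in seq_len(n_tip)) {
    r <- tip
    while (!is.na(parent[r]) && !(parent[r] %in% cut)) r <- parent[r]
    idx <- match(r, roots)
    if (is.na(idx)) {
      roots <- c(roots, r)
      idx <- length(roots)
    }
    membership[tip] <- idx
  }
  structure(membership[labels], class = "leaf_clustering")
}

#' Fowlkes-Mallows index of two clusterings
#'
#' `B = TP / sqrt((TP + FP) (TP + FN))` over co-clustered pairs.  Trivial
#' clusterings with no co-clustered pairs on either side (for example all
#' singletons) score 1 when identical and 0 otherwise.
#'
#' @param c1,c2 Clusterings over the same labels (named membership vectors
#'   as returned by [cut_tree()]).
#' @return Real in `[0, 1]`.
#' @export
fowlkes_mallows <- function(c1, c2) {
  if (!setequal(names(c1), names(c2)))
    stop("clusterings must cover the same labels")
  c2 <- c2[names(c1)]
  tab <- table(c1, c2)
  tp <- sum(choose(tab, 2))
  p1 <- sum(choose(rowSums(tab), 2))
  p2 <- sum(choose(colSums(tab), 2))
  if (p1 == 0 || p2 == 0) {
    same <- length(unique(c1)) == length(unique(c2)) &&
      all(as.integer(factor(c1, levels = unique(c1))) ==
            as.integer(factor(c2, levels = unique(c2))))
    return(if (same) 1 else 0)
  }
  tp / sqrt(p1 * p2)
}

triplet_topologies <- function(tree) {
  # uniform convention: both trees are reduced to their unrooted topology
  # and midpoint-rooted, so the comparison never measures a difference in
  # how the inputs happened to be rooted
  tr <- if (!is.null(tree$edge.length))
    phangorn::midpoint(ape::unroot(tree))
  else tree  # no branch lengths: use the topology as given
  tr <- ape::reorder.phylo(tr, "cladewise")
  n_tip <- length(tr$tip.label)
  labels <- tr$tip.label
  # topological depth of every node from the root
  depth <- rep(0L, n_tip + tr$Nnode)
  pre <- ape::reorder.phylo(tr, "cladewise")
  for (e in seq_len(nrow(pre$edge)))
    depth[pre$edge[e, 2]] <- depth[pre$edge[e, 1]] + 1L
  mr <- ape::mrca(tr)
  trips <- utils::combn(seq_len(n_tip), 3)
  out <- character(ncol(trips))
  keys <- character(ncol(trips))
  pair_lab <- function(i, j) paste(sort(c(labels[i], labels[j])),
                                   collapse = "+")
  for (idx in seq_len(ncol(trips))) {
    a <- trips[1, idx]; b <- trips[2, idx]; c_ <- trips[3, idx]
    dab <- depth[mr[a, b]]; dac <- depth[mr[a, c_]]; dbc <- depth[mr[b, c_]]
    mx <- max(dab, dac, dbc)
    cherry <- c(dab == mx, dac == mx, dbc == mx)
    # the pair whose MRCA lies strictly deepest forms the cherry; ties mean
    # the triplet is unresolved (a star)
    out[idx] <- if (sum(cherry) > 1) "*"
    else switch(which(cherry), pair_lab(a, b), pair_lab(a, c_),
                pair_lab(b, c_))
    keys[idx] <- paste(sort(labels[c(a, b, c_)]), collapse = "|")
  }
  names(out) <- keys
  out
}

#' Triplet distance between two trees
#'
#' The number of 3-leaf subsets whose induced rooted topology differs
#' between the trees.  Both trees are first reduced to their unrooted
#' topology and midpoint-rooted (a uniform convention, so the score
#' reflects topology rather than the rooting of the inputs); trees without
#' branch lengths are used as given.  Unresolved triplets count as
#' agreement only with unresolved triplets.  Brute force over all
#' `choose(n, 3)` subsets.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Non-negative integer, at most `choose(n, 3)`.
#' @export
triplets_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  if (length(t1$tip.label) < 3) stop("need at least 3 leaves")
  s1 <- triplet_topologies(t1)
  s2 <- triplet_topologies(t2)
  s2 <- s2[names(s1)]
  sum(s1 != s2)
}
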