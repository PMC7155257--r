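# Rooted lineage trees. Internal representation: parent-pointer vectors plus
# children lists; node 1 is always the root. Leaves map to cell ids through
# their labels. Optional per-node character-state annotation ('states'
# matrix, nodes x characters) and per-edge mutation counts ('edge_len',
# indexed by the child node).

new_lineage_tree <- function(parent, label, edge_len = NULL, states = NULL,
                             depth_gen = NULL) {
  n <- length(parent)
  children <- vector("list", n)
  for (v in seq_len(n)) {
    p <- parent[v]
    if (!is.na(p)) children[[p]] <- c(children[[p]], v)
  }
  is_leaf <- lengths(children) == 0L
  if (is.null(edge_len)) edge_len <- rep(1, n)
  structure(
    list(parent = parent, children = children, label = label,
         is_leaf = is_leaf, edge_len = edge_len, states = states,
         depth_gen = depth_gen),
    class = "lineage_tree")
}

#' Leaf labels (cell ids) of a lineage tree
#' @param tree a \code{lineage_tree}.
#' @return character vector of cell ids.
#' @export
tree_leaves <- function(tree) tree$label[tree$is_leaf]

tree_root <- function(tree) which(is.na(tree$parent))[1L]

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d leaves, %d nodes%s\n",
              sum(x$is_leaf), length(x$parent),
              if (!is.null(x$states)) ", annotated" else ""))
  invisible(x)
}

# unweighted depth (edge count from root) per node
node_depths <- function(tree) {
  n <- length(tree$parent)
  d <- integer(n)
  ord <- tree_preorder(tree)
  for (v in ord) {
    p <- tree$parent[v]
    d[v] <- if (is.na(p)) 0L else d[p] + 1L
  }
  d
}

# mutation-weighted depth from root (uses edge_len)
node_depths_weighted <- function(tree) {
  n <- length(tree$parent)
  d <- numeric(n)
  for (v in tree_preorder(tree)) {
    p <- tree$parent[v]
    d[v] <- if (is.na(p)) 0 else d[p] + tree$edge_len[v]
  }
  d
}

tree_preorder <- function(tree) {
  n <- length(tree$parent)
  out <- integer(n); k <- 0L
  stack <- tree_root(tree)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; out[k] <- v
    kids <- tree$children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out
}

tree_postorder <- function(tree) rev(tree_preorder(tree))

# leaf index sets below each node (list of integer vectors of leaf node ids)
leaves_below <- function(tree) {
  n <- length(tree$parent)
  below <- vector("list", n)
  for (v in tree_postorder(tree)) {
    if (tree$is_leaf[v]) below[[v]] <- v
    else below[[v]] <- unlist(below[tree$children[[v]]], use.names = FALSE)
  }
  below
}

# LCA of two nodes by parent walking (trees here are small)
tree_lca <- function(tree, a, b, depth = NULL) {
  if (is.null(depth)) depth <- node_depths(tree)
  while (a != b) {
    if (depth[a] < depth[b]) b <- tree$parent[b]
    else if (depth[b] < depth[a]) a <- tree$parent[a]
    else { a <- tree$parent[a]; b <- tree$parent[b] }
  }
  a
}

#' Collapse single-child internal nodes
#'
#' Merges chains of single-child nodes, summing edge lengths additively.
#' Used after character bootstrapping, where replicate trees may contain
#' unresolved single-child chains.
#'
#' @param tree a \code{lineage_tree}.
#' @return a \code{lineage_tree} with every internal node having >= 2
#'   children (except possibly the root, which is kept).
#' @export
collapse_singles <- function(tree) {
  n <- length(tree$parent)
  root <- tree_root(tree)
  keep <- tree$is_leaf | lengths(tree$children) >= 2L
  keep[root] <- TRUE
  # new parent: nearest kept ancestor; accumulated edge length
  new_parent <- rep(NA_integer_, n); new_len <- numeric(n)
  for (v in tree_preorder(tree)) {
    if (v == root) next
    p <- tree$parent[v]; len <- tree$edge_len[v]
    while (!keep[p]) { len <- len + tree$edge_len[p]; p <- tree$parent[p] }
    new_parent[v] <- p; new_len[v] <- len
  }
  idx <- which(keep)
  remap <- integer(n); remap[idx] <- seq_along(idx)
  # ensure root first
  if (remap[root] != 1L) {
    idx <- c(root, setdiff(idx, root))
    remap[idx] <- seq_along(idx)
  }
  parent <- ifelse(is.na(new_parent[idx]), NA_integer_, remap[new_parent[idx]])
  new_lineage_tree(parent, tree$label[idx], edge_len = new_len[idx],
                   states = if (!is.null(tree$states)) tree$states[idx, , drop = FALSE],
                   depth_gen = tree$depth_gen[idx])
}

#' Convert between lineage_tree and ape phylo
#'
#' @param tree a \code{lineage_tree} with >= 2 leaves.
#' @return an \code{ape::phylo} object with node labels and branch lengths
#'   (mutation counts per edge).
#' @export
as_phylo <- function(tree) {
  n <- length(tree$parent)
  leaves <- which(tree$is_leaf)
  internals <- which(!tree$is_leaf)
  root <- tree_root(tree)
  internals <- c(root, setdiff(internals, root))
  id <- integer(n)
  id[leaves] <- seq_along(leaves)
  id[internals] <- length(leaves) + seq_along(internals)
  edges <- which(!is.na(tree$parent))
  edge <- cbind(id[tree$parent[edges]], id[edges])
  lab <- tree$label
  lab[!nzchar(lab)] <- ""
  phy <- structure(list(
    edge = edge,
    edge.length = tree$edge_len[edges],
    Nnode = length(internals),
    tip.label = lab[leaves],
    node.label = lab[internals]), class = "phylo", order = "cladewise")
  phy
}

#' @param phy an \code{ape::phylo} object (rooted).
#' @rdname as_phylo
#' @export
from_phylo <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  n <- nt + nn
  parent <- rep(NA_integer_, n)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  el <- rep(1, n)
  if (!is.null(phy$edge.length)) el[phy$edge[, 2L]] <- phy$edge.length
  lab <- c(phy$tip.label,
           if (!is.null(phy$node.label)) phy$node.label else rep("", nn))
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree is not rooted with a single root")
  # reorder so root is node 1
  ord <- c(root, setdiff(seq_len(n), root))
  remap <- integer(n); remap[ord] <- seq_len(n)
  new_lineage_tree(
    parent = ifelse(is.na(parent[ord]), NA_integer_, remap[parent[ord]]),
    label = lab[ord], edge_len = el[ord])
}

#' Newick input/output
#'
#' Trees are written with internal-node labels and branch lengths equal to
#' the number of mutations on each edge.
#'
#' @param tree a \code{lineage_tree}.
#' @param path file path.
#' @param collapse collapse single-child chains before writing.
#' @return [read_newick()] returns a \code{lineage_tree}.
#' @export
write_newick <- function(tree, path, collapse = FALSE) {
  if (collapse) tree <- collapse_singles(tree)
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  from_phylo(ape::read.tree(path))
}

# build a lineage_tree from a nested list-of-subsets recursion result:
# 'node' is list(label=, children=list(...), edge_len=, states=) recursive.
flatten_tree <- function(node) {
  parent <- integer(0); label <- character(0); edge_len <- numeric(0)
  states <- list()
  add <- function(nd, p) {
    parent <<- c(parent, p)
    label <<- c(label, nd$label %||% "")
    edge_len <<- c(edge_len, nd$edge_len %||% 1)
    states[[length(parent)]] <<- nd$states %||% NULL
    me <- length(parent)
    for (ch in nd$children) add(ch, me)
    me
  }
  add(node, NA_integer_)
  st <- NULL
  if (any(!vapply(states, is.null, logical(1)))) {
    m <- length(states[[1L]])
    st <- do.call(rbind, lapply(states, function(s)
      if (is.null(s)) rep(NA_integer_, m) else s))
  }
  new_lineage_tree(parent, label, edge_len = edge_len, states = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
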