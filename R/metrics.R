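# Evaluation statistics: minimal irreversible ancestral annotation and
# parsimony, depth-stratified triplets correct, meta purity, mean majority
# vote, allelic/phylogenetic distances, character bootstrapping, and the
# neighbor-joining baseline.

#' Annotate ancestral states under irreversible mutation
#'
#' Labels every internal node, per character, with state s if all
#' non-missing leaves below it carry s (missing leaves never break a
#' monochromatic subtree), and 0 otherwise. Under the irreversibility
#' constraint (each character changes at most once along any root-to-leaf
#' path, from 0 to a nonzero state), this labeling attains the minimal
#' number of 0 -> s origins: one per maximal monochromatic subtree. Edge
#' lengths are set to the number of mutations on each edge; mutations
#' carried by every leaf are charged to the implicit edge from the unedited
#' founder to the root (stored as the root's \code{edge_len}).
#'
#' @param tree a \code{lineage_tree} whose leaf labels are cells of \code{m}.
#' @param m a [character_matrix()].
#' @return the tree with \code{states} (nodes x characters) and
#'   \code{edge_len} filled in.
#' @export
annotate_ancestral_states <- function(tree, m) {
  m <- character_matrix(unclass(m))
  leaves <- which(tree$is_leaf)
  if (!all(tree$label[leaves] %in% rownames(m)))
    stop("unmapped leaf: every leaf label must be a cell id of the matrix")
  n <- length(tree$parent)
  C <- ncol(m)
  st <- matrix(0L, n, C)
  st[leaves, ] <- unclass(m)[tree$label[leaves], , drop = FALSE]
  post <- tree_postorder(tree)
  for (v in post) {
    if (tree$is_leaf[v]) next
    kids <- tree$children[[v]]
    kst <- st[kids, , drop = FALSE]
    for (i in seq_len(C)) {
      vals <- kst[, i]
      nz <- unique(vals[vals != MISSING_STATE])
      # all-missing subtrees keep the wildcard (they constrain nothing)
      st[v, i] <- if (length(nz) == 0L) MISSING_STATE
        else if (length(nz) == 1L && nz != 0L) nz else 0L
    }
  }
  root <- tree_root(tree)
  # edge mutation counts: parent -> child differences (missing = no change)
  el <- numeric(n)
  for (v in seq_len(n)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    a <- st[p, ]; b <- st[v, ]
    ok <- b != MISSING_STATE & a != MISSING_STATE
    el[v] <- sum(a[ok] != b[ok])
  }
  # founder (all-zero) -> root edge
  el[root] <- sum(st[root, ] != 0L & st[root, ] != MISSING_STATE)
  tree$states <- st
  tree$edge_len <- el
  tree
}

#' Parsimony score of an annotated tree
#'
#' Total number of mutation events implied along the tree's edges (sum of
#' per-edge mutation-set sizes, including the implicit founder-to-root
#' edge). Lower is more parsimonious.
#'
#' @param tree an annotated \code{lineage_tree} (see
#'   [annotate_ancestral_states()]).
#' @return integer mutation count.
#' @export
parsimony_score <- function(tree) {
  if (is.null(tree$states)) stop("tree is not annotated")
  sum(tree$edge_len)
}

# outgroup of a leaf triplet in a rooted tree: the leaf splitting off first.
# returns 1, 2, 3 or 0 (unresolved polytomy at the triplet LCA).
.triplet_outgroup <- function(tree, trip, depth) {
  l12 <- tree_lca(tree, trip[1L], trip[2L], depth)
  l13 <- tree_lca(tree, trip[1L], trip[3L], depth)
  l23 <- tree_lca(tree, trip[2L], trip[3L], depth)
  d <- c(depth[l23], depth[l13], depth[l12])  # depth of LCA excluding leaf i
  mx <- max(d)
  wh <- which(d == mx)
  if (length(wh) == 1L) {
    # the deepest pairwise LCA is the ingroup pair; outgroup is the third
    wh
  } else 0L
}

#' Depth-stratified triplets-correct statistic
#'
#' Samples leaf triplets uniformly (with replacement) and scores a triplet
#' correct when the outgroup leaf agrees between the true and reconstructed
#' trees. Fractions are computed per depth (edge count from the root to the
#' triplet's LCA in the true tree) and averaged across depths, optionally
#' restricted to depths whose true-tree cell count is at least
#' \code{min_cells} (falls back to the unthresholded average, with a
#' warning, when no depth qualifies).
#'
#' @param true_tree,recon_tree \code{lineage_tree}s over a shared leaf set.
#' @param n_triplets number of sampled triplets (default 10000).
#' @param min_cells depth-inclusion threshold on the number of true-tree
#'   cells at the depth (default 20).
#' @return a \code{triplet_report} list: \code{per_depth} (fraction correct
#'   and count by depth), \code{thresholded}, \code{unthresholded},
#'   \code{n_triplets}.
#' @export
triplets_correct <- function(true_tree, recon_tree, n_triplets = 10000L,
                             min_cells = 20L) {
  lt <- tree_leaves(true_tree); lr <- tree_leaves(recon_tree)
  shared <- intersect(lt, lr)
  if (length(shared) < 3L) stop("fewer than 3 shared leaves")
  t_idx <- which(true_tree$is_leaf)[match(shared, lt)]
  r_idx <- which(recon_tree$is_leaf)[match(shared, tree_leaves(recon_tree))]
  dt <- node_depths(true_tree)
  dr <- node_depths(recon_tree)
  # cells per depth in the true tree: leaves at or below each depth; a depth
  # d "has" the leaves below internal nodes at depth d
  below <- leaves_below(true_tree)
  internal_depths <- dt[!true_tree$is_leaf]
  n_at_depth <- vapply(sort(unique(internal_depths)), function(d) {
    nodes <- which(!true_tree$is_leaf & dt == d)
    length(unique(unlist(below[nodes])))
  }, numeric(1))
  names(n_at_depth) <- sort(unique(internal_depths))

  k <- length(shared)
  picks <- matrix(0L, n_triplets, 3L)
  for (r in seq_len(n_triplets)) picks[r, ] <- sample.int(k, 3L)
  correct <- logical(n_triplets); depth_of <- integer(n_triplets)
  for (r in seq_len(n_triplets)) {
    tt <- t_idx[picks[r, ]]
    rr <- r_idx[picks[r, ]]
    lca_t <- tree_lca(true_tree, tree_lca(true_tree, tt[1L], tt[2L], dt),
                      tt[3L], dt)
    depth_of[r] <- dt[lca_t]
    og_t <- .triplet_outgroup(true_tree, tt, dt)
    og_r <- .triplet_outgroup(recon_tree, rr, dr)
    correct[r] <- og_t == og_r
  }
  depths <- sort(unique(depth_of))
  frac <- vapply(depths, function(d) mean(correct[depth_of == d]), numeric(1))
  cnt <- vapply(depths, function(d) sum(depth_of == d), numeric(1))
  names(frac) <- names(cnt) <- depths
  cells_per_depth <- n_at_depth[as.character(depths)]
  cells_per_depth[is.na(cells_per_depth)] <- 0
  include <- cells_per_depth >= min_cells
  unthresh <- mean(frac)
  if (!any(include)) {
    warning("no depth reaches min_cells; falling back to unthresholded average")
    thresh <- unthresh
  } else {
    thresh <- mean(frac[include])
  }
  structure(list(per_depth = data.frame(depth = depths, fraction = frac,
                                        n_triplets = cnt,
                                        n_cells = as.numeric(cells_per_depth)),
                 thresholded = thresh, unthresholded = unthresh,
                 n_triplets = n_triplets),
            class = "triplet_report")
}

# clades from a horizontal cut: all nodes at the cut depth, plus leaves
# shallower than the cut; returns list of leaf-label vectors
.cut_clades <- function(tree, cut_depth) {
  d <- node_depths(tree)
  below <- leaves_below(tree)
  at <- which(d == cut_depth)
  shallow_leaves <- which(tree$is_leaf & d < cut_depth)
  cl <- c(lapply(at, function(v) tree$label[below[[v]]]),
          lapply(shallow_leaves, function(v) tree$label[v]))
  cl[lengths(cl) > 0L]
}

# smallest cut depth yielding >= target clades
.find_cut <- function(tree, n_clades) {
  d <- node_depths(tree)
  for (cut in 0:max(d)) {
    if (length(.cut_clades(tree, cut)) >= n_clades) return(cut)
  }
  stop("tree shallower than any cut yielding the requested clade count")
}

#' Meta purity statistic
#'
#' Cuts the tree horizontally at the smallest depth yielding at least
#' \code{n_clades} clades, tabulates clade membership against the leaf
#' labels, and returns the chi-squared test statistic of the contingency
#' table (no p-value; reported as a function of the clade count for
#' cross-method curves).
#'
#' @param tree a \code{lineage_tree}.
#' @param labels named vector: meta label per leaf (names = cell ids).
#' @param n_clades target clade count.
#' @return list(statistic, n_clades, cut_depth, table).
#' @export
meta_purity <- function(tree, labels, n_clades) {
  lv <- tree_leaves(tree)
  if (!all(lv %in% names(labels))) stop("every leaf must be labeled")
  cut <- .find_cut(tree, n_clades)
  clades <- .cut_clades(tree, cut)
  tab <- do.call(rbind, lapply(clades, function(cl) table(factor(
    labels[cl], levels = sort(unique(labels[lv]))))))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stat <- 0
  } else {
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - exp_tab)^2 / exp_tab)
  }
  list(statistic = as.numeric(stat), n_clades = length(clades),
       cut_depth = cut, table = tab)
}

#' Mean majority-vote statistic
#'
#' At the same horizontal cut as [meta_purity()], computes each clade's
#' majority-label fraction and returns the mean over clades; ranges from
#' 1/|M| (labels maximally mixed) to 1 (homogeneous clades).
#'
#' @inheritParams meta_purity
#' @return list(statistic, n_clades, cut_depth).
#' @export
mean_majority_vote <- function(tree, labels, n_clades) {
  lv <- tree_leaves(tree)
  if (!all(lv %in% names(labels))) stop("every leaf must be labeled")
  cut <- .find_cut(tree, n_clades)
  clades <- .cut_clades(tree, cut)
  votes <- vapply(clades, function(cl) {
    tb <- table(labels[cl])
    max(tb) / sum(tb)
  }, numeric(1))
  list(statistic = mean(votes), n_clades = length(clades), cut_depth = cut)
}

#' Normalized allelic distance between two cells
#'
#' Per character: identical states add 0; a difference where either side is
#' uncut or missing adds 1; two different nonzero states add 2. The total is
#' normalized by 2M (M = number of characters).
#'
#' @param a,b integer state vectors of equal length.
#' @return numeric in [0, 1].
#' @export
allelic_distance <- function(a, b) {
  if (length(a) != length(b)) stop("state vectors of unequal length")
  same <- a == b
  zero_or_missing <- (a <= 0L) | (b <= 0L)  # uncut (0) or missing (-1)
  d <- ifelse(same, 0L, ifelse(zero_or_missing, 1L, 2L))
  sum(d) / (2 * length(a))
}

#' Normalized phylogenetic distance between two leaves
#'
#' Number of mutations along the branches of the shortest path between the
#' two cells, divided by the tree's diameter (the maximum pairwise value).
#'
#' @param tree an annotated \code{lineage_tree}.
#' @param a,b leaf labels (cell ids).
#' @return numeric in [0, 1] (raw distance in attribute \code{"raw"}).
#' @export
phylogenetic_distance <- function(tree, a, b) {
  lv <- tree_leaves(tree)
  if (!(a %in% lv) || !(b %in% lv)) stop("leaf absent from tree")
  leaf_ids <- which(tree$is_leaf)
  wd <- node_depths_weighted(tree)
  d <- node_depths(tree)
  ia <- leaf_ids[match(a, lv)]; ib <- leaf_ids[match(b, lv)]
  raw <- wd[ia] + wd[ib] - 2 * wd[tree_lca(tree, ia, ib, d)]
  # diameter over all leaf pairs
  dm <- 0
  for (i in seq_along(leaf_ids)) for (j in seq_len(i - 1L)) {
    u <- leaf_ids[i]; v <- leaf_ids[j]
    dv <- wd[u] + wd[v] - 2 * wd[tree_lca(tree, u, v, d)]
    if (dv > dm) dm <- dv
  }
  out <- if (dm == 0) 0 else raw / dm
  attr(out, "raw") <- raw
  out
}

#' Bootstrap character resampling
#'
#' Each replicate samples the matrix's characters (columns) with
#' replacement; replicate trees built downstream should have single-child
#' nodes collapsed (see [collapse_singles()]).
#'
#' @param m a [character_matrix()].
#' @param B number of replicates.
#' @return list of B \code{character_matrix} objects.
#' @export
bootstrap_characters <- function(m, B) {
  stopifnot(B >= 1L)
  m <- character_matrix(unclass(m))
  lapply(seq_len(B), function(b) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    out <- unclass(m)[, cols, drop = FALSE]
    colnames(out) <- paste0(colnames(m)[cols], ".", seq_along(cols))
    res <- character_matrix(out)
    attr(res, "columns") <- cols
    res
  })
}

#' Neighbor-joining baseline reconstruction
#'
#' One-hot binarizes the matrix, computes pairwise identity-mismatch
#' dissimilarities (fraction of binary characters differing, missing
#' excluded pairwise), appends an all-zero pseudo-root cell, runs
#' neighbor joining, and roots the result at the pseudo-cell (then removes
#' it) so that depth-based statistics apply.
#'
#' @param m a [character_matrix()].
#' @return a rooted \code{lineage_tree}.
#' @export
build_nj <- function(m) {
  m <- character_matrix(unclass(m))
  b <- unclass(binarize_matrix(m))
  b <- rbind(b, "__root__" = rep(0L, ncol(b)))
  n <- nrow(b)
  # pairwise mismatch fraction over pairwise-complete binary columns
  M1 <- (b == 1L) + 0; M0 <- (b == 0L) + 0; Mo <- ((b != MISSING_STATE) + 0)
  mism <- M1 %*% t(M0) + M0 %*% t(M1)
  valid <- Mo %*% t(Mo)
  D <- ifelse(valid > 0, mism / pmax(valid, 1), 0)
  dimnames(D) <- list(rownames(b), rownames(b))
  phy <- ape::nj(stats::as.dist(D))
  phy <- ape::root(phy, outgroup = "__root__", resolve.root = TRUE)
  phy <- ape::drop.tip(phy, "__root__")
  phy$node.label <- NULL
  tr <- from_phylo(phy)
  tr$label[tree_root(tr)] <- "root"
  tr$edge_len <- rep(1, length(tr$parent))
  tr$edge_len[tree_root(tr)] <- 0
  tr
}
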