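# Hybrid reconstruction: greedy partitioning down to a cell-count cutoff,
# exact Steiner/ILP solving of each remaining subset, and order-independent
# merging of the subtrees back into the greedy scaffold.

#' Hybrid maximum-parsimony reconstruction
#'
#' Runs the greedy recursion but stops splitting any subset of at most
#' \code{cutoff} cells; each stopped subset becomes an independent Steiner
#' subproblem ([optimize_neighborhood()] + [solve_steiner()]) over the
#' recursion-time submatrix (split mutations consumed on the greedy path are
#' already zeroed, fixing the clade's ancestral string), and the resulting
#' subtree is grafted at the corresponding greedy node. Subproblems are independent,
#' so the merged result does not depend on their order of execution. A
#' subproblem whose ILP fails, or whose time-limited incumbent is less
#' parsimonious than the greedy solution of the same subset, falls back to
#' the greedy subtree (with a logged warning in the former case).
#'
#' @param m a [character_matrix()].
#' @param cutoff subset size at which to switch to the exact solver
#'   (default 200).
#' @param priors optional priors for the greedy phase.
#' @param max_neighborhood_size potential-graph cap per subproblem.
#' @param time_limit,gap_tolerance ILP controls per subproblem.
#' @return an annotated \code{lineage_tree}; attribute \code{"subproblems"}
#'   records per-subproblem size, solver status and whether the ILP subtree
#'   was used.
#' @export
build_hybrid <- function(m, cutoff = 200L, priors = NULL,
                         max_neighborhood_size = 10000,
                         time_limit = 12600, gap_tolerance = 0) {
  stopifnot(cutoff >= 1L)
  m <- character_matrix(unclass(m))
  if (cutoff <= 1L)
    return(annotate_ancestral_states(build_greedy(m, priors), m))
  acc <- rep(0L, ncol(m)); names(acc) <- colnames(m)
  pending <- new.env()
  pending$subsets <- list()
  node <- .greedy_recurse(m, priors, acc, stop_n = cutoff, pending = pending)
  if (length(node$children)) node$label <- "root"
  node$edge_len <- 0
  scaffold <- flatten_tree(node)
  scaffold$edge_len[tree_root(scaffold)] <- 0

  log <- list()
  subtrees <- list()
  for (id in seq_along(pending$subsets)) {
    sub <- pending$subsets[[id]]
    msub <- sub$mat
    # candidates are built from the recursion-time matrix but compared on
    # the original submatrix: characters consumed on the greedy path can
    # still vary within the subset (state vs missing) and affect parsimony
    morig <- character_matrix(unclass(m)[sub$cells, , drop = FALSE])
    greedy_sub <- build_greedy(msub, priors)
    greedy_cmp <- annotate_ancestral_states(greedy_sub, morig)
    used <- "greedy"; status <- NA_character_
    best <- greedy_cmp
    ilp_tree <- tryCatch({
      g <- optimize_neighborhood(msub, max_neighborhood_size)
      solve_steiner(g, time_limit = time_limit,
                    gap_tolerance = gap_tolerance)
    }, error = function(e) {
      warning("ILP subproblem ", id, " failed (", conditionMessage(e),
              "); falling back to greedy")
      NULL
    })
    if (!is.null(ilp_tree)) {
      status <- attr(ilp_tree, "status")
      ilp_cmp <- annotate_ancestral_states(ilp_tree, morig)
      if (parsimony_score(ilp_cmp) <= parsimony_score(greedy_cmp)) {
        best <- ilp_cmp; used <- "ilp"
      }
    }
    subtrees[[id]] <- best
    log[[id]] <- data.frame(subproblem = id, n_cells = length(sub$cells),
                            solver = used, status = status)
  }
  merged <- .graft_subtrees(scaffold, subtrees)
  merged <- annotate_ancestral_states(merged, m)
  attr(merged, "subproblems") <- if (length(log)) do.call(rbind, log) else NULL
  merged
}

# replace each "__pendingN__" placeholder leaf of the scaffold by subtree N
.graft_subtrees <- function(scaffold, subtrees) {
  n <- length(scaffold$parent)
  parent <- scaffold$parent; label <- scaffold$label
  edge_len <- scaffold$edge_len
  extra_parent <- integer(0); extra_label <- character(0)
  extra_len <- numeric(0)
  offset <- n
  for (v in seq_len(n)) {
    mm <- regmatches(label[v], regexec("^__pending([0-9]+)__$", label[v]))[[1L]]
    if (length(mm)) {
      id <- as.integer(mm[2L])
      sub <- subtrees[[id]]
      label[v] <- ""
      ns <- length(sub$parent)
      sroot <- tree_root(sub)
      map <- integer(ns)
      ord <- setdiff(seq_len(ns), sroot)
      map[sroot] <- v
      map[ord] <- offset + seq_along(ord)
      extra_parent <- c(extra_parent, map[sub$parent[ord]])
      extra_label <- c(extra_label, sub$label[ord])
      extra_len <- c(extra_len, sub$edge_len[ord])
      offset <- offset + length(ord)
    }
  }
  new_lineage_tree(c(parent, extra_parent), c(label, extra_label),
                   edge_len = c(edge_len, extra_len))
}
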