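# Greedy top-down partitioning: recursively split the cells on the most
# frequent (character, state) mutation (or, with priors, the mutation whose
# observed frequency is least probable under the prior), assigning cells
# with missing data to the side sharing the most mutated states.

# count n_ij for all (character, nonzero state) pairs in a sub-matrix;
# returns data.frame(char, state, n)
.mutation_counts <- function(m) {
  idx <- which(unclass(m) > 0L, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(char = integer(0), state = integer(0),
                                    n = integer(0)))
  key <- paste(idx[, 2L], unclass(m)[idx], sep = ":")
  tab <- table(key)
  parts <- strsplit(names(tab), ":", fixed = TRUE)
  data.frame(char = as.integer(vapply(parts, `[`, "", 1L)),
             state = as.integer(vapply(parts, `[`, "", 2L)),
             n = as.integer(tab))
}

#' Select the greedy split mutation
#'
#' Without priors, returns the (character, state) pair carried by the most
#' cells (argmax n_ij). With priors, returns the pair minimizing
#' p_i(0, s_j)^(n_ij), computed in log space as n_ij * log p; a frequent
#' mutation with a low prior is the strongest evidence of an early split.
#' Missing entries never count toward n_ij. Ties break on the lowest
#' (character, state) index pair.
#'
#' @param m a [character_matrix()].
#' @param priors optional prior set: a list, per character, of named numeric
#'   vectors mapping state -> conditional probability q_ij.
#' @return list(char, state, n) or NULL when no nonzero non-missing entry
#'   exists ("no split available").
#' @export
select_split <- function(m, priors = NULL) {
  counts <- .mutation_counts(m)
  if (!nrow(counts)) return(NULL)
  if (is.null(priors)) {
    score <- -counts$n   # minimize
  } else {
    pr <- vapply(seq_len(nrow(counts)), function(r) {
      q <- priors[[counts$char[r]]][as.character(counts$state[r])]
      if (is.null(q) || is.na(q)) 0.5 else as.numeric(q)
    }, numeric(1))
    score <- counts$n * log(pr)
  }
  ord <- order(score, counts$char, counts$state)
  best <- counts[ord[1L], ]
  list(char = best$char, state = best$state, n = best$n)
}

# shared mutated-state fraction between cell vector a and each row of mat:
# |chars where both non-missing, both nonzero, equal| / |chars both non-missing|
.shared_fraction <- function(a, mat) {
  ok <- a != MISSING_STATE
  vapply(seq_len(nrow(mat)), function(r) {
    b <- mat[r, ]
    both <- ok & b != MISSING_STATE
    if (!any(both)) return(NA_real_)
    sum(a[both] > 0L & a[both] == b[both]) / sum(both)
  }, numeric(1))
}

#' Partition cells on a split mutation, assigning missing-data cells
#'
#' Cells with state \code{state} at character \code{char} form the split set
#' O; cells with any other non-missing state form the complement. Each cell
#' missing at \code{char} is assigned to the side with which it shares the
#' greater mean fraction of mutated states (ties, and cells with no
#' comparable characters, go to the larger side).
#'
#' @param m a [character_matrix()].
#' @param char,state the split mutation.
#' @return list of two character vectors of cell ids: \code{O} and
#'   \code{complement}.
#' @export
partition_with_missing <- function(m, char, state) {
  v <- unclass(m)[, char]
  O <- rownames(m)[v == state]
  comp <- rownames(m)[v != state & v != MISSING_STATE]
  miss <- rownames(m)[v == MISSING_STATE]
  if (length(miss)) {
    mo <- unclass(m)[O, , drop = FALSE]
    mc <- unclass(m)[comp, , drop = FALSE]
    for (cell in miss) {
      a <- unclass(m)[cell, ]
      so <- mean(.shared_fraction(a, mo), na.rm = TRUE)
      sc <- if (nrow(mc)) mean(.shared_fraction(a, mc), na.rm = TRUE) else -Inf
      if (is.nan(so)) so <- -Inf
      if (is.nan(sc)) sc <- -Inf
      if (so == -Inf && sc == -Inf) {
        if (length(O) >= length(comp)) O <- c(O, cell) else comp <- c(comp, cell)
      } else if (so > sc) {
        O <- c(O, cell)
      } else if (sc > so) {
        comp <- c(comp, cell)
      } else {
        if (length(O) >= length(comp)) O <- c(O, cell) else comp <- c(comp, cell)
      }
    }
  }
  list(O = O, complement = comp)
}

# recursive greedy tree over a sub-matrix; returns nested node list for
# flatten_tree(). 'acc' is the accumulated ancestral state vector. 'stop_n'
# (hybrid cutoff) stops recursion for subsets of <= stop_n cells, recording
# them in 'pending' (environment) for downstream exact solving.
.greedy_recurse <- function(m, priors, acc, stop_n = 1L, pending = NULL) {
  ids <- rownames(m)
  if (length(ids) == 1L) {
    return(list(label = ids, edge_len = 1, children = list(),
                states = unclass(m)[1L, ]))
  }
  if (!is.null(pending) && length(ids) <= stop_n) {
    id <- length(pending$subsets) + 1L
    # keep the recursion-time matrix: split characters consumed on the path
    # are already zeroed, so the subproblem continues exactly where the
    # greedy recursion would have
    pending$subsets[[id]] <- list(cells = ids, acc = acc, mat = m)
    return(list(label = paste0("__pending", id, "__"), edge_len = 1,
                children = list(), states = acc))
  }
  sp <- select_split(m, priors)
  if (is.null(sp)) {
    # no split available: polytomy over the cells
    kids <- lapply(ids, function(cid)
      list(label = cid, edge_len = 0, children = list(),
           states = unclass(m)[cid, ]))
    return(list(label = "", edge_len = 1, children = kids, states = acc))
  }
  part <- partition_with_missing(m, sp$char, sp$state)
  if (!length(part$complement)) {
    # split mutation carried by all cells: record it on this clade and
    # recurse with the character fixed (prevents re-selection)
    acc2 <- acc; acc2[sp$char] <- sp$state
    m2 <- unclass(m)
    m2[, sp$char] <- 0L
    sub <- .greedy_recurse(character_matrix(m2), priors, acc2, stop_n, pending)
    sub$edge_len <- (sub$edge_len %||% 1) + 1
    return(sub)
  }
  accO <- acc; accO[sp$char] <- sp$state
  mO <- unclass(m)[part$O, , drop = FALSE]
  mO[, sp$char] <- 0L   # consume the split mutation inside O
  left <- .greedy_recurse(character_matrix(mO), priors, accO, stop_n, pending)
  right <- .greedy_recurse(
    character_matrix(unclass(m)[part$complement, , drop = FALSE]),
    priors, acc, stop_n, pending)
  left$edge_len <- 1
  right$edge_len <- 1
  list(label = "", edge_len = 1, children = list(left, right), states = acc)
}

#' Greedy maximum-parsimony reconstruction
#'
#' Builds a rooted tree top-down by recursive splits on the most frequent
#' (or prior-weighted) mutation, until subsets are singletons; subsets with
#' no remaining split become a polytomy. If the matrix admits a perfect
#' phylogeny, the returned tree is that perfect phylogeny.
#'
#' @param m a [character_matrix()].
#' @param priors optional prior set (see [select_split()]).
#' @return an annotated \code{lineage_tree} whose leaves are the input
#'   cells; internal nodes carry the split mutations accumulated from the
#'   root (other characters left 0).
#' @export
build_greedy <- function(m, priors = NULL) {
  m <- character_matrix(unclass(m))
  acc <- rep(0L, ncol(m)); names(acc) <- colnames(m)
  node <- .greedy_recurse(m, priors, acc)
  if (length(node$children)) node$label <- "root"
  node$edge_len <- 0
  tr <- flatten_tree(node)
  tr$edge_len[tree_root(tr)] <- 0
  tr
}

#' Precision of the first greedy split against the true phylogeny
#'
#' The greedy split selects mutation (i, j); G is the set of cells carrying
#' it. In the true tree the mutation may have arisen independently several
#' times; the true-positive set is the largest single-origin subset, and the
#' precision is its share of G.
#'
#' @param experiment a \code{sim_experiment} (truth tree + matrices).
#' @param priors optional priors for the split criterion.
#' @return list(char, state, precision, n_origins).
#' @export
greedy_split_precision <- function(experiment, priors = NULL) {
  m <- experiment$truth
  sp <- select_split(m, priors)
  if (is.null(sp)) stop("no split available")
  carriers <- rownames(m)[unclass(m)[, sp$char] == sp$state]
  origins <- .independent_origins(experiment$tree, m, sp$char, sp$state)
  if (!length(origins)) stop("selected mutation absent from the true tree")
  sizes <- lengths(origins)
  list(char = sp$char, state = sp$state,
       precision = max(sizes) / length(carriers),
       n_origins = length(origins))
}

# maximal subtrees of the true tree whose non-missing leaves all carry
# (char, state): each corresponds to one independent origin
.independent_origins <- function(tree, m, char, state) {
  below <- leaves_below(tree)
  v <- unclass(m)[, char]
  carries <- function(node) {
    labs <- tree$label[below[[node]]]
    st <- v[labs]
    any(st == state) && all(st %in% c(state, MISSING_STATE))
  }
  n <- length(tree$parent)
  mono <- vapply(seq_len(n), carries, logical(1))
  origins <- list()
  for (nd in which(mono)) {
    p <- tree$parent[nd]
    if (is.na(p) || !mono[p]) {
      origins[[length(origins) + 1L]] <- tree$label[below[[nd]]]
    }
  }
  origins
}
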