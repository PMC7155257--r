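# Shared fixtures: tiny matrices and graphs built in code.

# small multi-state matrix with one missing entry
tiny_matrix <- function() {
  m <- matrix(c(1L, 0L, 2L,
                1L, 2L, 0L,
                0L, 2L, 3L,
                -1L, 0L, 3L), nrow = 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), c("c1", "c2", "c3")))
  character_matrix(m)
}

# full state-product potential graph over all strings in {0..S}^C with an
# edge u -> v (weight 1) whenever v gains exactly one mutation 0 -> s over u;
# used as the exact playground for Steiner tests
full_product_graph <- function(C = 3L, S = 2L) {
  grids <- rep(list(0:S), C)
  nodes <- as.matrix(do.call(expand.grid, grids))
  colnames(nodes) <- NULL
  storage.mode(nodes) <- "integer"
  from <- integer(0); to <- integer(0)
  for (v in seq_len(nrow(nodes))) {
    for (ch in seq_len(C)) {
      if (nodes[v, ch] != 0L) {
        u <- nodes[v, ]
        u[ch] <- 0L
        ui <- which(apply(nodes, 1L, function(r) all(r == u)))
        from <- c(from, ui); to <- c(to, v)
      }
    }
  }
  root <- which(apply(nodes, 1L, function(r) all(r == 0L)))
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, weight = 1),
                 root = root, targets = integer(0),
                 cell_map = integer(0), d = NA_integer_, capped = FALSE),
            class = "potential_graph")
}

# random cells drawn from the product graph for ILP-vs-oracle checks
random_product_instance <- function(C = 4L, S = 2L, n_cells = 6L) {
  g <- full_product_graph(C, S)
  cells <- sample(setdiff(seq_len(nrow(g$nodes)), g$root), n_cells)
  g$targets <- unique(cells)
  g$cell_map <- setNames(cells, paste0("cell", seq_along(cells)))
  g
}

# random rooted binary lineage_tree over n leaves with random states
random_leaf_tree <- function(n_leaves, n_chars = 2L, n_states = 3L,
                             miss_prob = 0) {
  # random sequential joining
  subtrees <- lapply(seq_len(n_leaves), function(i)
    list(label = paste0("L", i), edge_len = 1, children = list(),
         states = NULL))
  while (length(subtrees) > 1L) {
    pick <- sample(length(subtrees), 2L)
    joined <- list(label = "", edge_len = 1,
                   children = subtrees[pick], states = NULL)
    subtrees <- c(subtrees[-pick], list(joined))
  }
  node <- subtrees[[1L]]
  node$label <- if (n_leaves == 1L) node$label else "root"
  tr <- flatten_tree(node)
  tr$edge_len[1L] <- 0
  st <- matrix(sample(0:n_states, n_leaves * n_chars, replace = TRUE),
               nrow = n_leaves)
  if (miss_prob > 0)
    st[matrix(runif(length(st)) < miss_prob, nrow = n_leaves)] <- -1L
  rownames(st) <- paste0("L", seq_len(n_leaves))
  colnames(st) <- paste0("c", seq_len(n_chars))
  list(tree = tr, matrix = character_matrix(st))
}

# exhaustive minimal irreversible labeling oracle: tries every assignment of
# internal-node states per character (0 or any observed leaf state), checks
# irreversibility along all paths, and counts mutations; independent of
# annotate_ancestral_states
exhaustive_min_parsimony <- function(tree, m) {
  m <- unclass(m)
  internals <- which(!tree$is_leaf)
  leaves <- which(tree$is_leaf)
  root <- which(is.na(tree$parent))
  total <- 0L
  for (ch in seq_len(ncol(m))) {
    leaf_states <- m[tree$label[leaves], ch]
    cand <- c(0L, sort(unique(leaf_states[leaf_states > 0L])))
    grids <- rep(list(cand), length(internals))
    best <- Inf
    for (combo in seq_len(length(cand)^length(internals))) {
      idx <- combo - 1L
      assign <- integer(length(internals))
      for (k in seq_along(internals)) {
        assign[k] <- cand[idx %% length(cand) + 1L]
        idx <- idx %/% length(cand)
      }
      st <- integer(length(tree$parent))
      st[internals] <- assign
      st[leaves] <- leaf_states
      # implicit unedited founder above the root
      ok <- TRUE; muts <- as.integer(st[root] != 0L)
      for (v in seq_along(tree$parent)) {
        p <- tree$parent[v]
        if (is.na(p)) next
        a <- st[p]; b <- st[v]
        if (b == -1L) next  # missing leaf: no constraint
        if (a != b) {
          if (a != 0L) { ok <- FALSE; break }  # irreversibility
          muts <- muts + 1L
        }
      }
      if (ok && muts < best) best <- muts
    }
    total <- total + best
  }
  total
}
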