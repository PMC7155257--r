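# Steiner-tree maximum parsimony: potential-graph approximation with
# neighborhood-size control, the network-flow integer linear program, and an
# exact Dreyfus-Wagner oracle for small instances.

#' Latest common ancestor of two character strings
#'
#' Per character: equal non-missing states keep that state; disagreement
#' resolves to the unmutated state 0 (irreversibility: any shared nonzero
#' state must predate the split, any disagreement must postdate it); a
#' missing entry acts as a wildcard and adopts the other side's state.
#'
#' @param a,b integer state vectors of equal length.
#' @return integer state vector.
#' @export
lca_string <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  out <- ifelse(a == MISSING_STATE & b == MISSING_STATE, MISSING_STATE,
         ifelse(a == MISSING_STATE, b,
         ifelse(b == MISSING_STATE, a,
         ifelse(a == b, a, 0L))))
  as.integer(out)
}

# wildcard edit distance: characters where both non-missing and different
string_distance <- function(a, b) {
  ok <- a != MISSING_STATE & b != MISSING_STATE
  sum(a[ok] != b[ok])
}

#' Build the potential graph
#'
#' Iteratively pairs up all current source nodes (observed cells first),
#' adds the latest common ancestor of every pair whose edit distance is
#' strictly below \code{d} together with edges to both (weighted by edit
#' distance), and
#' repeats until a single source, the root, remains. Missing entries are
#' wildcards. The graph's Steiner arborescence over the observed cells is a
#' maximum-parsimony phylogeny candidate.
#'
#' @param m a [character_matrix()] (cells are deduplicated on their strings).
#' @param d LCA edit-distance threshold.
#' @param max_nodes node-count cap; construction aborts (with
#'   \code{capped = TRUE}) when exceeded.
#' @param root_string ancestral string to root at (default all zeros; hybrid
#'   subproblems pass their accumulated clade string).
#' @return a \code{potential_graph} list: \code{nodes} (strings matrix),
#'   \code{edges} (data.frame from/to/weight), \code{root}, \code{targets}
#'   (node index per unique cell string), \code{cell_map} (cell id ->
#'   node index), \code{d}, \code{capped}.
#' @export
build_potential_graph <- function(m, d, max_nodes = Inf,
                                  root_string = NULL) {
  m <- character_matrix(unclass(m))
  if (is.null(root_string)) root_string <- rep(0L, ncol(m))
  strs <- unclass(m)
  key <- apply(strs, 1L, paste, collapse = ",")
  uniq <- !duplicated(key)
  cells <- strs[uniq, , drop = FALSE]
  cap <- if (is.finite(max_nodes)) as.integer(max_nodes) else .Machine$integer.max
  res <- .potential_graph_cpp(cells, as.integer(d), cap,
                              as.integer(root_string))
  edges <- data.frame(from = res$edges[, 1L], to = res$edges[, 2L],
                      weight = res$edges[, 3L])
  node_key <- apply(res$nodes, 1L, paste, collapse = ",")
  cell_map <- match(key, node_key)
  names(cell_map) <- rownames(m)
  structure(list(nodes = res$nodes, edges = edges, root = res$root,
                 targets = unique(cell_map), cell_map = cell_map,
                 d = d, capped = res$capped),
            class = "potential_graph")
}

#' @export
print.potential_graph <- function(x, ...) {
  cat(sprintf("potential_graph: %d nodes, %d edges, %d targets, d = %d%s\n",
              nrow(x$nodes), nrow(x$edges), length(x$targets), x$d,
              if (x$capped) " (capped)" else ""))
  invisible(x)
}

#' Choose the LCA threshold under a neighborhood-size cap
#'
#' Increases \code{d} from 1, building the potential graph at each value,
#' and returns the largest-\code{d} graph whose node count stays within
#' \code{max_neighborhood_size}; stops early when the graph saturates
#' (no change from the previous threshold). If even d = 1 exceeds the cap,
#' the d = 0 graph (cells attached directly to the root) is returned with a
#' warning.
#'
#' @param m a [character_matrix()].
#' @param max_neighborhood_size node-count cap (default 10000).
#' @param root_string optional ancestral root string.
#' @param d_max largest threshold to try (default: number of characters).
#' @return a \code{potential_graph} (its \code{d} records the chosen
#'   threshold).
#' @export
optimize_neighborhood <- function(m, max_neighborhood_size = 10000,
                                  root_string = NULL, d_max = NULL) {
  m <- character_matrix(unclass(m))
  if (is.null(d_max)) d_max <- ncol(m)
  best <- NULL
  prev_sig <- NULL
  for (d in seq_len(d_max)) {
    g <- build_potential_graph(m, d, max_nodes = max_neighborhood_size,
                               root_string = root_string)
    if (g$capped) break
    sig <- c(nrow(g$nodes), nrow(g$edges))
    best <- g
    if (!is.null(prev_sig) && all(sig == prev_sig)) break  # saturated
    prev_sig <- sig
  }
  if (is.null(best)) {
    warning("neighborhood cap exceeded at d = 1; returning star graph (d = 0)")
    best <- build_potential_graph(m, 0L, max_nodes = .Machine$integer.max,
                                  root_string = root_string)
    best$d <- 0L
  }
  best
}

.python_bin <- function() {
  py <- getOption("lintree.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the MILP backend")
  py
}

# run the MILP backend on an edge list; returns parsed solution list
.run_milp <- function(n, edges, root, targets, time_limit, gap) {
  script <- system.file("python", "steiner_milp.py", package = "lintree")
  inp <- tempfile(fileext = ".json"); outp <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, outp)), add = TRUE)
  jsonlite::write_json(
    list(n = n, edges = unname(as.matrix(edges)), root = root,
         targets = as.integer(targets), time_limit = time_limit, gap = gap),
    inp, auto_unbox = TRUE, digits = NA)
  status <- system2(.python_bin(), c(script, inp, outp),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(outp))
    stop("MILP backend failed (exit status ", status, ")")
  jsonlite::read_json(outp, simplifyVector = TRUE)
}

#' Solve the Steiner arborescence ILP over a potential graph
#'
#' Solves the network-flow integer linear program: integer flows d_uv in
#' {0..|S|} with binary selections b_uv >= d_uv/|S|, minimizing the
#' selected-edge weight subject to flow conservation, |S| units leaving the
#' root and one unit absorbed at each target. The selected subgraph is then
#' reduced to a tree (ties at in-degree > 1 broken by smallest incoming
#' weight, then lexicographically smallest parent string) and observed
#' cells are attached at their string nodes.
#'
#' @param graph a [build_potential_graph()] result.
#' @param time_limit solver wall-clock limit in seconds (default 12600).
#' @param gap_tolerance relative MIP gap at which to stop (default 0).
#' @return an annotated \code{lineage_tree}; attributes \code{objective},
#'   \code{status} ("optimal" or "incumbent"), \code{gap} and
#'   \code{d} record the solve.
#' @export
solve_steiner <- function(graph, time_limit = 12600, gap_tolerance = 0) {
  stopifnot(inherits(graph, "potential_graph"))
  n <- nrow(graph$nodes)
  targets <- setdiff(graph$targets, graph$root)
  if (!length(targets) || nrow(graph$edges) == 0L) {
    # degenerate: all cells identical to the root string
    tr <- .steiner_tree_from_edges(graph, integer(0))
    attr(tr, "objective") <- 0; attr(tr, "status") <- "optimal"
    attr(tr, "gap") <- 0; attr(tr, "d") <- graph$d
    return(tr)
  }
  # targets must be pure sinks for the flow formulation (a target that is
  # an ancestor of another would have to relay flow, but absorbs exactly
  # one unit); split each target t into a routing node plus a zero-weight
  # sink copy t'. The objective is unchanged.
  k <- length(targets)
  sink_edges <- data.frame(from = targets, to = n + seq_len(k), weight = 0)
  edges_aug <- rbind(graph$edges, sink_edges)
  sol <- .run_milp(n + k, edges_aug, graph$root, n + seq_len(k), time_limit,
                   gap_tolerance)
  if (is.null(sol$b)) stop("ILP infeasible or no incumbent: ", sol$message)
  chosen <- which(sol$b > 0.5 & sol$d > 1e-6)
  chosen <- chosen[chosen <= nrow(graph$edges)]  # drop sink edges
  tr <- .steiner_tree_from_edges(graph, chosen)
  attr(tr, "objective") <- sol$objective
  attr(tr, "status") <- if (isTRUE(sol$success) && sol$status == 0L)
    "optimal" else "incumbent"
  attr(tr, "gap") <- sol$gap
  attr(tr, "d") <- graph$d
  tr
}

# turn selected edges into a lineage_tree rooted at graph$root, attaching
# observed cell ids as leaves of their string nodes
.steiner_tree_from_edges <- function(graph, chosen) {
  ed <- graph$edges[chosen, , drop = FALSE]
  n <- nrow(graph$nodes)
  parent <- rep(NA_integer_, n); plen <- rep(NA_real_, n)
  if (nrow(ed)) {
    node_str <- apply(graph$nodes, 1L, paste, collapse = ",")
    ord <- order(ed$to, ed$weight, node_str[ed$from])
    ed <- ed[ord, , drop = FALSE]
    first <- !duplicated(ed$to)   # smallest weight, then lexicographic parent
    parent[ed$to[first]] <- ed$from[first]
    plen[ed$to[first]] <- ed$weight[first]
  }
  # keep nodes on root->target paths
  keep <- rep(FALSE, n); keep[graph$root] <- TRUE
  for (t in graph$targets) {
    v <- t
    path <- integer(0)
    while (!is.na(v) && !keep[v]) { path <- c(path, v); v <- parent[v] }
    if (!is.na(v)) keep[path] <- TRUE
    else keep[t] <- TRUE  # unreachable target: attach below root directly
  }
  idx <- which(keep)
  idx <- c(graph$root, setdiff(idx, graph$root))
  remap <- rep(NA_integer_, n); remap[idx] <- seq_along(idx)
  np <- length(idx)
  par2 <- remap[parent[idx]]
  len2 <- plen[idx]
  # orphaned kept nodes (unreachable targets) hang off the root
  orphan <- which(is.na(par2) & seq_len(np) != 1L)
  if (length(orphan)) {
    par2[orphan] <- 1L
    len2[orphan] <- vapply(orphan, function(o)
      string_distance(graph$nodes[graph$root, ], graph$nodes[idx[o], ]),
      numeric(1))
  }
  label <- rep("", np)
  label[1L] <- "root"
  parent_v <- par2; edge_v <- len2; edge_v[1L] <- 0
  states <- graph$nodes[idx, , drop = FALSE]
  # attach cells as leaves
  for (cell in names(graph$cell_map)) {
    nd <- remap[graph$cell_map[[cell]]]
    parent_v <- c(parent_v, nd)
    edge_v <- c(edge_v, 0)
    label <- c(label, cell)
    states <- rbind(states, graph$nodes[graph$cell_map[[cell]], ])
  }
  new_lineage_tree(parent_v, label, edge_len = edge_v, states = states)
}

#' Exact Steiner arborescence weight (Dreyfus-Wagner)
#'
#' Dynamic program over terminal subsets using all-pairs shortest-path
#' distances; exact, exponential in the number of terminals. Serves as the
#' independent oracle for [solve_steiner()] on small instances.
#'
#' @param graph a \code{potential_graph} (or list with \code{nodes},
#'   \code{edges}).
#' @param root root node index.
#' @param targets terminal node indices.
#' @param max_terminals guard on instance size (default 12).
#' @return optimal total weight (numeric; Inf if some terminal unreachable).
#' @export
exact_steiner_oracle <- function(graph, root = graph$root,
                                 targets = setdiff(graph$targets, graph$root),
                                 max_terminals = 12L) {
  targets <- unique(targets)
  k <- length(targets)
  if (k == 0L) return(0)
  if (k > max_terminals) stop("instance too large for the exact oracle")
  n <- nrow(graph$nodes)
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to),
    directed = TRUE, vertices = data.frame(name = seq_len(n)))
  distm <- igraph::distances(g, mode = "out", weights = graph$edges$weight)
  distm <- distm[as.character(seq_len(n)), as.character(seq_len(n))]
  # DP[[T]] = vector over nodes v: min arborescence weight rooted at v
  # spanning terminal subset T (bitmask)
  DP <- vector("list", 2^k)
  for (i in seq_len(k)) DP[[bitwShiftL(1L, i - 1L)]] <- distm[, targets[i]]
  masks <- seq_len(2^k - 1L)
  masks <- masks[order(vapply(masks, function(mk) sum(bitwAnd(
    bitwShiftR(mk, 0:(k - 1L)), 1L)), numeric(1)))]
  for (mk in masks) {
    if (!is.null(DP[[mk]])) next
    merge_v <- rep(Inf, n)
    sub <- bitwAnd(mk - 1L, mk)
    while (sub > 0L) {
      other <- bitwAnd(mk, bitwNot(sub))
      if (other > 0L && sub < other) {  # each unordered split once
        merge_v <- pmin(merge_v, DP[[sub]] + DP[[other]])
      }
      sub <- bitwAnd(sub - 1L, mk)
    }
    # relay through any node u
    DP[[mk]] <- vapply(seq_len(n), function(v) min(distm[v, ] + merge_v),
                       numeric(1))
  }
  unname(DP[[2^k - 1L]][root])
}
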