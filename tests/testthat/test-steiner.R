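test_that("LCA strings follow the agreement/wildcard rules", {
  expect_equal(lca_string(c(1L, 2L, 0L), c(1L, 3L, 0L)), c(1L, 0L, 0L))
  expect_equal(lca_string(c(1L, 2L, 3L), c(1L, 2L, 3L)), c(1L, 2L, 3L))
  expect_equal(lca_string(c(1L, MISSING_STATE), c(1L, 4L)), c(1L, 4L))
  expect_equal(lca_string(c(MISSING_STATE, MISSING_STATE), c(MISSING_STATE, 2L)),
               c(MISSING_STATE, 2L))
  expect_error(lca_string(1L, c(1L, 2L)), "length")
})

test_that("potential graph construction builds ancestors layer by layer", {
  # single cell: cell plus root
  m1 <- character_matrix(matrix(c(2L, 0L), 1, dimnames = list("a", NULL)))
  g1 <- build_potential_graph(m1, d = 2)
  expect_equal(nrow(g1$nodes), 2L)
  expect_equal(nrow(g1$edges), 1L)

  # two cells differing in one character: LCA = agreement string
  m2 <- character_matrix(matrix(c(1L, 1L, 2L, 3L), 2,
                                dimnames = list(c("a", "b"), NULL)))
  g2 <- build_potential_graph(m2, d = 2)
  expect_equal(nrow(g2$nodes), 4L)  # a, b, (1,0), root
  anc <- which(apply(g2$nodes, 1, function(r) all(r == c(1L, 0L))))
  expect_length(anc, 1L)
  w <- g2$edges$weight[g2$edges$from == anc]
  expect_equal(sort(w), c(1, 1))

  # irreversibility along every edge: where both ends are observed, a
  # mutated parent state is preserved in the child (missing is a wildcard)
  set.seed(11)
  e <- simulate_lineage(sim_params(num_characters = 10, num_states = 10,
                                   p = 0.1, depth = 5, subsample = 1,
                                   dropout = 0.1))
  g <- build_potential_graph(e$observed, d = 4)
  for (k in seq_len(nrow(g$edges))) {
    a <- g$nodes[g$edges$from[k], ]; b <- g$nodes[g$edges$to[k], ]
    ok <- a != MISSING_STATE & b != MISSING_STATE & a != 0L
    expect_true(all(a[ok] == b[ok]))
  }
  # without missing data, no LCA has more mutations than either child
  e2 <- simulate_lineage(sim_params(num_characters = 10, num_states = 10,
                                    p = 0.1, depth = 5, subsample = 1,
                                    dropout = 0))
  g2n <- build_potential_graph(e2$observed, d = 4)
  nmut <- rowSums(g2n$nodes > 0L)
  for (k in seq_len(nrow(g2n$edges))) {
    expect_lte(nmut[g2n$edges$from[k]], nmut[g2n$edges$to[k]])
  }
  # every target reachable from the root
  ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = TRUE,
                                      vertices = data.frame(
                                        name = seq_len(nrow(g$nodes))))
  reach <- igraph::subcomponent(ig, as.character(g$root), mode = "out")
  expect_true(all(as.character(g$targets) %in% names(reach)))
})

test_that("neighborhood optimization respects the cap and is monotone", {
  set.seed(12)
  e <- simulate_lineage(sim_params(num_characters = 12, num_states = 8,
                                   p = 0.08, depth = 5, subsample = 1,
                                   dropout = 0))
  g_small <- optimize_neighborhood(e$observed, max_neighborhood_size = 40)
  g_big <- optimize_neighborhood(e$observed, max_neighborhood_size = 5000)
  expect_lte(nrow(g_small$nodes), 40)
  expect_gte(g_big$d, g_small$d)

  # cap below even d = 1: star fallback with warning
  expect_warning(
    g0 <- optimize_neighborhood(e$observed, max_neighborhood_size =
                                  length(unique(apply(unclass(e$observed), 1,
                                                      paste, collapse = ",")))),
    "star")
  expect_equal(g0$d, 0L)
})

test_that("the flow ILP solves single-target and path instances exactly", {
  g <- full_product_graph(3, 2)
  # one target: shortest path, objective = number of its mutations
  t1 <- which(apply(g$nodes, 1, function(r) all(r == c(1L, 2L, 0L))))
  g$targets <- t1
  g$cell_map <- setNames(t1, "cellA")
  tr <- solve_steiner(g, time_limit = 60)
  expect_equal(attr(tr, "objective"), 2)
  expect_equal(attr(tr, "status"), "optimal")
  expect_equal(exact_steiner_oracle(g), 2)

  # nested targets on one root path: no extra Steiner nodes needed
  t2 <- vapply(list(c(1L, 0L, 0L), c(1L, 2L, 0L), c(1L, 2L, 2L)),
               function(s) which(apply(g$nodes, 1, function(r)
                 all(r == s))), integer(1))
  g$targets <- t2
  g$cell_map <- setNames(t2, paste0("cell", 1:3))
  tr2 <- solve_steiner(g, time_limit = 60)
  expect_equal(attr(tr2, "objective"), 3)
  expect_equal(exact_steiner_oracle(g), 3)
  expect_setequal(tree_leaves(tr2), paste0("cell", 1:3))
})

test_that("ILP objective matches the Dreyfus-Wagner oracle on random instances", {
  set.seed(13)
  for (i in 1:4) {
    g <- random_product_instance(C = 4, S = 2, n_cells = 5)
    tr <- solve_steiner(g, time_limit = 120)
    expect_equal(attr(tr, "objective"), exact_steiner_oracle(g),
                 tolerance = 1e-9)
  }
})

test_that("oracle degenerates to spanning arborescence with all-node terminals", {
  g <- full_product_graph(2, 1)  # 4 nodes: 00, 10, 01, 11
  w <- exact_steiner_oracle(g, root = g$root,
                            targets = setdiff(seq_len(nrow(g$nodes)), g$root))
  # spanning arborescence of the diamond: one unit edge per non-root node
  expect_equal(w, 3)
})
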