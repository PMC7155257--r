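test_that("split selection maximizes frequency, or the prior criterion", {
  m <- character_matrix(matrix(c(1L, 1L, 1L, 0L,
                                 2L, 2L, 0L, 0L,
                                 0L, 0L, 3L, 3L), ncol = 3))
  sp <- select_split(m)
  expect_equal(c(sp$char, sp$state, sp$n), c(1L, 1L, 3L))

  # priors: A (p=0.5, n=2, score 0.25) vs B (p=0.1, n=1, score 0.1) -> B
  m2 <- character_matrix(matrix(c(1L, 1L, 0L,
                                  2L, 0L, 0L), ncol = 2))
  pr <- list(c(`1` = 0.5), c(`2` = 0.1))
  sp2 <- select_split(m2, pr)
  expect_equal(c(sp2$char, sp2$state), c(2L, 2L))

  # tie in n: lowest (character, state) pair
  m3 <- character_matrix(matrix(c(2L, 2L, 0L,
                                  1L, 1L, 0L), ncol = 2))
  sp3 <- select_split(m3)
  expect_equal(c(sp3$char, sp3$state), c(1L, 2L))

  # all zero / missing: no split available
  expect_null(select_split(character_matrix(matrix(c(0L, -1L), 1))))

  # equal priors reduce to the frequency criterion
  set.seed(8)
  for (i in 1:10) {
    mm <- character_matrix(matrix(sample(0:3, 24, replace = TRUE), ncol = 4))
    if (is.null(select_split(mm))) next
    flat <- lapply(1:4, function(i) setNames(rep(0.25, 3), 1:3))
    expect_equal(select_split(mm, flat)[c("char", "state")],
                 select_split(mm)[c("char", "state")])
  }
})

test_that("missing cells go to the side sharing more mutated states", {
  # cell d missing at the split character shares 2 mutated states with the
  # O side and none with the complement
  m <- character_matrix(matrix(
    c(1L, 1L, 0L, -1L,
      5L, 5L, 0L, 5L,
      6L, 6L, 0L, 6L,
      0L, 0L, 7L, 0L), ncol = 4,
    dimnames = list(c("x1", "x2", "y", "d"), NULL)))
  part <- partition_with_missing(m, 1, 1)
  expect_true("d" %in% part$O)
  expect_setequal(part$O, c("x1", "x2", "d"))
  expect_setequal(part$complement, "y")

  # no missing: exact two-block partition
  m2 <- character_matrix(matrix(c(1L, 1L, 2L, 0L), ncol = 1,
                                dimnames = list(letters[1:4], NULL)))
  p2 <- partition_with_missing(m2, 1, 1)
  expect_setequal(p2$O, c("a", "b"))
  expect_setequal(p2$complement, c("c", "d"))

  # tie on shared fractions: larger subset wins
  m3 <- character_matrix(matrix(
    c(1L, 1L, 2L, -1L,
      0L, 0L, 0L, 0L), ncol = 2,
    dimnames = list(c("o1", "o2", "c1", "d"), NULL)))
  p3 <- partition_with_missing(m3, 1, 1)
  expect_true("d" %in% p3$O)
})

test_that("greedy recovers perfect phylogenies exactly (Theorem-1 property)", {
  set.seed(9)
  for (i in 1:5) {
    e <- simulate_lineage(sim_params(num_characters = 15, num_states = 40,
                                     depth = 4, subsample = 1, dropout = 0,
                                     unique_states = TRUE))
    tr <- build_greedy(e$observed)
    expect_setequal(tree_leaves(tr), rownames(e$observed))
    tc <- suppressWarnings(triplets_correct(e$tree, tr, n_triplets = 1500))
    expect_equal(tc$unthresholded, 1.0)
  }
})

test_that("greedy handles degenerate inputs", {
  single <- character_matrix(matrix(1L, 1, 2, dimnames = list("only", NULL)))
  tr <- build_greedy(single)
  expect_equal(tree_leaves(tr), "only")

  # all cells identical: one polytomy
  same <- character_matrix(matrix(rep(c(1L, 2L), each = 4), 4, 2,
                                  dimnames = list(letters[1:4], NULL)))
  tr2 <- build_greedy(same)
  expect_setequal(tree_leaves(tr2), letters[1:4])
  # all leaves share one parent (after the shared-mutation chain)
  leaf_parents <- unique(tr2$parent[tr2$is_leaf])
  expect_length(leaf_parents, 1L)
})

test_that("first-split precision counts independent origins in the truth", {
  set.seed(10)
  base <- simulate_lineage(sim_params(num_characters = 18, num_states = 40,
                                      depth = 5, subsample = 1, dropout = 0,
                                      unique_states = TRUE))
  # perfect phylogeny: single origin, precision 1
  expect_equal(greedy_split_precision(base)$precision, 1.0)

  # handmade double origin: two clades of 8 and 2 cells carry (c1, 1)
  st <- matrix(0L, 12, 3, dimnames = list(paste0("v", 1:12), NULL))
  st[1:8, 1] <- 1L; st[1:8, 2] <- 5L       # clade A: 8 cells
  st[9:10, 1] <- 1L; st[9:10, 3] <- 7L     # clade B: 2 cells
  m <- character_matrix(st)
  # true tree: ((A cells), (B cells), (rest))
  nodeA <- list(label = "", edge_len = 1, children = lapply(1:8, function(i)
    list(label = paste0("v", i), edge_len = 1, children = list())))
  nodeB <- list(label = "", edge_len = 1, children = lapply(9:10, function(i)
    list(label = paste0("v", i), edge_len = 1, children = list())))
  rest <- lapply(11:12, function(i)
    list(label = paste0("v", i), edge_len = 1, children = list()))
  truth <- flatten_tree(list(label = "root", edge_len = 0,
                             children = c(list(nodeA, nodeB), rest)))
  fake <- list(truth = m, tree = truth)
  class(fake) <- "sim_experiment"
  res <- greedy_split_precision(fake)
  expect_equal(res$precision, 0.8)
  expect_equal(res$n_origins, 2L)
})
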