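test_that("ancestral annotation is the minimal irreversible labeling", {
  # all leaves share state 5: one mutation on the root edge
  rt <- random_leaf_tree(4)
  m <- character_matrix(matrix(5L, 4, 1, dimnames = list(paste0("L", 1:4),
                                                         "c1")))
  ann <- annotate_ancestral_states(rt$tree, m)
  expect_equal(parsimony_score(ann), 1L)

  # missing leaves never break monochromatic subtrees
  m2 <- unclass(m); m2[2, 1] <- MISSING_STATE
  m2 <- character_matrix(m2)
  expect_equal(parsimony_score(annotate_ancestral_states(rt$tree, m2)), 1L)

  expect_error(annotate_ancestral_states(rt$tree,
    character_matrix(matrix(1L, 2, 1, dimnames = list(c("Z1", "Z2"), NULL)))),
    "unmapped leaf")

  # matches exhaustive minimal labeling on small random instances
  set.seed(16)
  for (i in 1:12) {
    inst <- random_leaf_tree(sample(4:6, 1), n_chars = 2, n_states = 3,
                             miss_prob = 0.1)
    ann <- annotate_ancestral_states(inst$tree, inst$matrix)
    expect_equal(parsimony_score(ann),
                 exhaustive_min_parsimony(inst$tree, inst$matrix))
  }
})

test_that("parsimony counts one origin per monochromatic clade", {
  # star over 5 cells sharing one mutation: 1 after annotation
  star <- flatten_tree(list(label = "root", edge_len = 0,
    children = lapply(1:5, function(i)
      list(label = paste0("L", i), edge_len = 1, children = list()))))
  m <- character_matrix(matrix(3L, 5, 1, dimnames = list(paste0("L", 1:5),
                                                         NULL)))
  expect_equal(parsimony_score(annotate_ancestral_states(star, m)), 1L)

  # two disjoint clades with the same state: 2 origins
  tr <- flatten_tree(list(label = "root", edge_len = 0, children = list(
    list(label = "", edge_len = 1, children = list(
      list(label = "L1", edge_len = 1, children = list()),
      list(label = "L2", edge_len = 1, children = list()))),
    list(label = "", edge_len = 1, children = list(
      list(label = "L3", edge_len = 1, children = list()),
      list(label = "L4", edge_len = 1, children = list()))))))
  m2 <- character_matrix(matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 7L, 7L), 4, 2,
                                dimnames = list(paste0("L", 1:4), NULL)))
  ann <- annotate_ancestral_states(tr, m2)
  expect_equal(parsimony_score(ann), 2L + 1L)  # 2 origins of (c1,1) + (c2,7)
})

test_that("triplets correct is 1 on identical trees, ~1/3 on random ones", {
  set.seed(17)
  inst <- random_leaf_tree(24)
  expect_equal(triplets_correct(inst$tree, inst$tree, 500)$unthresholded, 1)

  t1 <- random_leaf_tree(30)$tree
  t2 <- random_leaf_tree(30)$tree
  tc <- triplets_correct(t1, t2, n_triplets = 4000, min_cells = 1)
  overall <- sum(tc$per_depth$fraction * tc$per_depth$n_triplets) /
    sum(tc$per_depth$n_triplets)
  expect_lt(abs(overall - 1 / 3), 0.06)

  # min_cells excluding all depths falls back with a warning
  small <- random_leaf_tree(8)
  expect_warning(
    tc2 <- triplets_correct(small$tree, small$tree, 200, min_cells = 100),
    "unthresholded")
  expect_equal(tc2$thresholded, tc2$unthresholded)

  expect_error(triplets_correct(random_leaf_tree(2)$tree, t1), "3 shared")
})

test_that("meta purity equals the textbook chi-squared statistic", {
  # 2 clades perfectly separating 2 labels of n/2 cells each: statistic = n
  tr <- flatten_tree(list(label = "root", edge_len = 0, children = list(
    list(label = "", edge_len = 1, children = lapply(1:4, function(i)
      list(label = paste0("A", i), edge_len = 1, children = list()))),
    list(label = "", edge_len = 1, children = lapply(1:4, function(i)
      list(label = paste0("B", i), edge_len = 1, children = list()))))))
  labels <- setNames(rep(c("p0", "p1"), each = 4),
                     c(paste0("A", 1:4), paste0("B", 1:4)))
  mp <- meta_purity(tr, labels, n_clades = 2)
  expect_equal(mp$statistic, 8)

  # agrees with stats::chisq.test without continuity correction
  expect_equal(mp$statistic,
               unname(suppressWarnings(chisq.test(mp$table,
                                                  correct = FALSE)$statistic)))

  # identical labels: zero association
  same <- setNames(rep("p0", 8), names(labels))
  expect_equal(meta_purity(tr, same, 2)$statistic, 0)
})

test_that("mean majority vote ranges from 1/|M| to 1", {
  tr <- flatten_tree(list(label = "root", edge_len = 0, children = list(
    list(label = "", edge_len = 1, children = lapply(1:4, function(i)
      list(label = paste0("A", i), edge_len = 1, children = list()))),
    list(label = "", edge_len = 1, children = lapply(1:4, function(i)
      list(label = paste0("B", i), edge_len = 1, children = list()))))))
  leaves <- c(paste0("A", 1:4), paste0("B", 1:4))
  hom <- setNames(rep(c("x", "y"), each = 4), leaves)
  expect_equal(mean_majority_vote(tr, hom, 2)$statistic, 1)
  mix <- setNames(rep(c("x", "y"), 4), leaves)
  expect_equal(mean_majority_vote(tr, mix, 2)$statistic, 0.5)
  # single clade of 3 A + 1 B: 0.75
  one <- flatten_tree(list(label = "root", edge_len = 0,
    children = lapply(1:4, function(i)
      list(label = paste0("L", i), edge_len = 1, children = list()))))
  lab <- setNames(c("A", "A", "A", "B"), paste0("L", 1:4))
  expect_equal(mean_majority_vote(one, lab, 1)$statistic, 0.75)
})

test_that("allelic distance weights uncut/missing mismatches by 1, others 2", {
  a <- rep(0L, 10); b <- a
  expect_equal(allelic_distance(a, b), 0)
  b2 <- a; b2[1] <- 3L; a2 <- a; a2[1] <- MISSING_STATE
  expect_equal(allelic_distance(a2, b2), 1 / 20)
  a3 <- a; a3[1] <- 4L
  expect_equal(allelic_distance(a3, b2), 2 / 20)
  expect_error(allelic_distance(1:3, 1:4), "unequal")
})

test_that("phylogenetic distance is mutation-weighted and diameter-normalized", {
  # siblings each with 1 private mutation: raw distance 2
  tr <- flatten_tree(list(label = "root", edge_len = 0, children = list(
    list(label = "", edge_len = 1, children = list(
      list(label = "a", edge_len = 1, children = list()),
      list(label = "b", edge_len = 1, children = list()))),
    list(label = "c", edge_len = 4, children = list()))))
  d_ab <- phylogenetic_distance(tr, "a", "b")
  expect_equal(attr(d_ab, "raw"), 2)
  expect_equal(as.numeric(phylogenetic_distance(tr, "a", "a")), 0)
  # the diameter pair normalizes to 1
  d_ac <- phylogenetic_distance(tr, "a", "c")
  expect_equal(as.numeric(d_ac), 1)
  expect_error(phylogenetic_distance(tr, "a", "zz"), "absent")
})

test_that("bootstrap resamples characters with replacement", {
  set.seed(18)
  m <- character_matrix(matrix(sample(0:2, 60, TRUE), 6, 10))
  reps <- bootstrap_characters(m, B = 3)
  expect_length(reps, 3L)
  for (r in reps) expect_equal(ncol(r), 10L)

  set.seed(99); a <- bootstrap_characters(m, 1)[[1]]
  set.seed(99); b <- bootstrap_characters(m, 1)[[1]]
  expect_identical(attr(a, "columns"), attr(b, "columns"))

  # expected distinct-column fraction ~ 1 - (1 - 1/m)^m
  set.seed(19)
  fr <- mean(vapply(bootstrap_characters(m, 300), function(r)
    length(unique(attr(r, "columns"))) / 10, numeric(1)))
  expect_lt(abs(fr - (1 - (1 - 1 / 10)^10)), 0.03)
})

test_that("the NJ baseline returns a rooted tree over the input cells", {
  set.seed(20)
  e <- simulate_lineage(sim_params(num_characters = 10, num_states = 10,
                                   p = 0.1, depth = 5, subsample = 1,
                                   dropout = 0.1))
  tr <- build_nj(e$observed)
  expect_setequal(tree_leaves(tr), rownames(e$observed))
  expect_equal(sum(is.na(tr$parent)), 1L)
})
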