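make_tiny_table <- function() {
  allele_table(data.frame(
    cellBC = c("c1", "c1", "c2", "c2", "c3", "c3"),
    intBC = c("i1", "i2", "i1", "i2", "i3", "i4"),
    allele = c("1,0,0", "2,0,0", "1,0,0", "0,3,0", "2,0,0", "4,0,0"),
    UMI = c(5L, 3L, 4L, 2L, 6L, 1L)))
}

test_that("indel priors are intBC-presence frequencies", {
  tab <- make_tiny_table()
  q <- estimate_indel_priors(tab)
  # |I| = 4; state "2" seen in i2 and i3 -> 0.5; "1" in i1 only -> 0.25
  expect_equal(unname(q["2"]), 2 / 4)
  expect_equal(unname(q["1"]), 1 / 4)
  expect_true(all(q > 0 & q <= 1))
  expect_error(estimate_indel_priors(tab[0, ]), "empty")

  # present in every intBC -> 1
  tab2 <- allele_table(data.frame(cellBC = "c", intBC = c("a", "b"),
                                  allele = c("9,0", "9,0"), UMI = 1L))
  expect_equal(unname(estimate_indel_priors(tab2)["9"]), 1)

  # estimated priors rank-correlate with generating probabilities
  set.seed(23)
  sim <- simulate_allele_table(n_clones = 4, cells_per_clone = 40)
  q3 <- estimate_indel_priors(sim$table)
  gen <- sim$state_probs[names(q3)]
  expect_gt(cor(q3, gen, method = "spearman"), 0)
})

test_that("mutation-rate estimation inverts the saturation curve", {
  m0 <- character_matrix(matrix(0L, 5, 4))
  expect_equal(estimate_mutation_rate(m0, 10), 0)
  m1 <- character_matrix(matrix(1L, 5, 4))
  expect_warning(p1 <- estimate_mutation_rate(m1, 10), "saturated")
  expect_equal(p1, 1)

  # inversion identity: plugging the estimate back reproduces K/n
  set.seed(24)
  m <- character_matrix(matrix(rbinom(400, 1, 0.3) *
                                 sample(1:5, 400, TRUE), 20, 20))
  p <- estimate_mutation_rate(m, d = 7)
  K_n <- mean(rowSums(unclass(m) > 0)) / 20
  expect_equal(1 - (1 - p)^7, K_n, tolerance = 1e-12)

  # parameter recovery at the default regime; a single 400-cell replicate
  # has ~10% relative spread (shared ancestry), so average a few
  set.seed(25)
  est <- mean(replicate(4, {
    e <- simulate_lineage(sim_params())
    estimate_mutation_rate(e$truth, d = 11)
  }))
  expect_lt(abs(est - 0.025) / 0.025, 0.10)

  # monotone in K
  expect_gt(suppressWarnings(estimate_mutation_rate(m1, 10)),
            estimate_mutation_rate(m, 10))
})

test_that("clone calling recovers disjoint intBC groups and filters rare BCs", {
  set.seed(26)
  sim <- simulate_allele_table(n_clones = 3, cells_per_clone = 50,
                               dropout = 0.05)
  cl <- call_clones(sim$table, junk_fraction = 0.005)
  # perfect recovery: called clones refine the true clones
  called <- cl$clones[names(sim$clones)]
  tab <- table(called, sim$clones)
  expect_equal(sum(apply(tab, 1, function(r) sum(r > 0))), nrow(tab))
  expect_length(cl$junk_cells, 0)

  # an intBC in <10% of a clone's cells is dropped from its set
  extra <- data.frame(cellBC = "cell01_001", intBC = "rareBC",
                      allele = "1,0,0", UMI = 1L)
  cl2 <- call_clones(allele_table(rbind(sim$table, extra)))
  expect_false("rareBC" %in% unlist(lapply(cl2$intbc_sets, names)))
})

test_that("doublet scores separate injected doublets from singlets", {
  set.seed(27)
  sim <- simulate_allele_table(n_clones = 2, cells_per_clone = 40,
                               dropout = 0.05)
  cl <- call_clones(sim$table)

  # clean cell: one allele per intBC -> intra score 0
  d0 <- detect_doublets(sim$table[!duplicated(
    paste(sim$table$cellBC, sim$table$intBC)), ], cl)
  expect_true(all(d0$intra_score == 0))
  # membership rows normalize to 1
  ms <- attr(d0, "membership")
  expect_true(all(abs(rowSums(ms) - 1) < 1e-9))

  dbl <- simulate_doublets(sim$table, n = 30, mode = "intra", clones = cl)
  sc <- detect_doublets(dbl$table, cl)
  lab <- dbl$labels[sc$cellBC]
  expect_gt(mean(sc$intra_score[lab]), mean(sc$intra_score[!lab]))

  dbl2 <- simulate_doublets(sim$table, n = 30, mode = "inter", clones = cl)
  sc2 <- detect_doublets(dbl2$table, call_clones(dbl2$table))
  lab2 <- dbl2$labels[sc2$cellBC]
  expect_lt(mean(sc2$inter_score[lab2]), mean(sc2$inter_score[!lab2]))

  # structural contracts of the injection
  expect_identical(simulate_doublets(sim$table, 0, "intra", cl)$table,
                   sim$table)
  umi_tot <- tapply(dbl$table$UMI, dbl$table$cellBC, sum)
  expect_true(all(umi_tot[names(dbl$labels)[dbl$labels]] >=
                    2 * min(tapply(sim$table$UMI, sim$table$cellBC, sum))))
  expect_error(simulate_doublets(sim$table[sim$table$cellBC %in%
    names(cl$clones)[cl$clones == "clone1"], ], 5, "inter"), ">= 2 clones")
})

test_that("threshold tuning maximizes F over the 21-point grid", {
  # perfectly separated scores: F = 1 at some grid point
  ds <- list(list(scores = setNames(c(0.9, 0.8, 0.1, 0.2), paste0("c", 1:4)),
                  labels = setNames(c(TRUE, TRUE, FALSE, FALSE),
                                    paste0("c", 1:4))))
  res <- tune_doublet_threshold(ds)
  expect_equal(res$F, 1)
  expect_equal(nrow(res$grid), 21L)

  # the returned threshold is the argmax of the exhaustive scan
  set.seed(28)
  sc <- setNames(runif(50), paste0("x", 1:50))
  lb <- setNames(runif(50) < 0.3, paste0("x", 1:50))
  ds2 <- list(list(scores = sc, labels = lb))
  res2 <- tune_doublet_threshold(ds2)
  expect_equal(res2$F, max(res2$grid$F))
  expect_equal(res2$threshold, res2$grid$threshold[which.max(res2$grid$F)])

  expect_error(tune_doublet_threshold(list(list(
    scores = c(a = 1), labels = c(a = FALSE)))), "no positives")
})
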