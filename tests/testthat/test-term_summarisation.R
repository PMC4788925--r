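# scores 10, 9, ..., 1 give gene g01 rank 1, g02 rank 2, ...
ten_gene_table <- function(ann = NULL) {
  rank_genes(stats::setNames(10:1, sprintf("g%02d", 1:10)), ann)
}

test_that("average rank aggregates annotated genes, absent ones at N + 1", {
  ann <- make_ann(list(TOP5 = sprintf("g%02d", 1:5),
                       MIX = c("g02", "gABS"),
                       TAIL = c("g09", "g10")))
  gt <- ten_gene_table(ann)
  tt <- summarise_terms(gt, ann)

  # a five-gene term holding ranks 1..5 attains the best possible average, 3
  expect_identical(tt$avg_rank[tt$term_id == "TOP5"], 3)
  # one present gene at rank 2 plus one absent gene, N = 10 -> (2 + 11) / 2
  expect_identical(tt$avg_rank[tt$term_id == "MIX"], 6.5)
  expect_identical(tt$total_genes[tt$term_id == "MIX"], 2L)
  expect_identical(tt$data_genes[tt$term_id == "MIX"], 1L)
  # terms ordered by ascending average rank
  expect_identical(tt$term_id, c("TOP5", "MIX", "TAIL"))

  # mean score: {0.4, 0.0} -> 0.2
  gt2 <- rank_genes(c(a = 0.4, b = 0))
  ann2 <- make_ann(list(T1 = c("a", "b")))
  expect_identical(summarise_terms(gt2, ann2)$avg_score, 0.2)
})

test_that("a singleton term reproduces its gene's rank and score exactly", {
  ann <- make_ann(list(SOLO = "g04"))
  gt <- ten_gene_table(ann)
  tt <- summarise_terms(gt, ann)
  row <- gt[gt$gene_id == "g04", ]
  expect_identical(tt$avg_rank, row$rank)
  expect_identical(tt$avg_score, row$score)
})

test_that("aggregate rank respects its analytic bounds on random inputs", {
  for (seed in 1:8) {
    sim <- small_sim(seed = seed, n_present = 60, n_absent = 10, n_null = 8)
    gt <- rank_genes(score_genes_anova(sim$dataset, "group"),
                     sim$annotations)
    tt <- summarise_terms(gt, sim$annotations)
    n <- sum(gt$present)
    expect_true(all(tt$avg_rank >= (tt$total_genes + 1) / 2 - 1e-9))
    expect_true(all(tt$avg_rank <= n + 1 + 1e-9))
    # terms made only of absent genes sit exactly at the ceiling
    absent_terms <- sim$truth$absent_terms
    expect_true(all(tt$avg_rank[tt$term_id %in% absent_terms] == n + 1))
    expect_true(all(tt$avg_score[tt$term_id %in% absent_terms] == 0))
  }
})

test_that("custom aggregations are applied and failures name the term", {
  ann <- make_ann(list(T1 = c("g01", "g02", "g09")))
  gt <- ten_gene_table(ann)
  tt <- summarise_terms(gt, ann, func = stats::median)
  expect_identical(tt$avg_rank, 2)  # median of ranks {1, 2, 9}
  boom <- function(x) stop("no aggregation today")
  expect_error(summarise_terms(gt, ann, func = boom), "T1")
})

test_that("permutation p-values behave at the exchangeability extremes", {
  genes <- sprintf("g%02d", 1:8)
  ann <- make_ann(list(ALL = genes, SOME = genes[1:3]))
  gt <- rank_genes(stats::setNames(8:1, genes))
  tt <- pvalue_terms(gt, ann, B = 200, seed = 3)
  # a term annotated with the whole universe is invariant under shuffling
  expect_identical(tt$p_value[tt$term_id == "ALL"], 1)
  # top-packed small term: only a small fraction of draws beat ranks {1,2,3}
  expect_lt(tt$p_value[tt$term_id == "SOME"], 0.15)
  expect_error(pvalue_terms(gt, ann, B = 0), "positive integer")
})

test_that("permutation estimate converges to the exhaustive enumeration", {
  # universe of 6 measured genes, one 2-gene term: C(6,2) = 15 equally
  # likely rank pairs under the null
  genes <- sprintf("g%02d", 1:6)
  ann <- make_ann(list(T1 = c("g02", "g03")))
  gt <- rank_genes(stats::setNames(6:1, genes))
  obs <- summarise_terms(gt, ann)$avg_rank
  combos <- utils::combn(6, 2)
  exact <- mean(colMeans(combos) <= obs + 1e-9)
  tt <- pvalue_terms(gt, ann, B = 4000, seed = 17)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(tt$p_value - exact), 3 * se)
})

test_that("equal-size terms get p-values monotone in their observed rank", {
  sim <- small_sim(seed = 6, n_present = 80, n_absent = 8, n_null = 12)
  gt <- rank_genes(score_genes_anova(sim$dataset, "group"), sim$annotations)
  tt <- pvalue_terms(gt, sim$annotations, B = 300, seed = 2)
  same_size <- tt[tt$total_genes == 10L, ]
  o <- order(same_size$avg_rank)
  expect_true(all(diff(same_size$p_value[o]) >= 0))
})

test_that("permutation scope and estimator options are honoured", {
  genes <- sprintf("g%02d", 1:6)
  # MIX pairs the top gene (rank 1) with an unmeasured gene (rank N+1 = 7)
  ann <- make_ann(list(MIX = c("g01", "u1"), ABS = c("u1", "u2")))
  gt <- rank_genes(stats::setNames(6:1, genes), ann)

  # universe scope: both labels of MIX circulate; exact null P(mean <= 4)
  # over the label multiset {1..6, 7, 7} is 13/28 ~ 0.46
  tt2 <- pvalue_terms(gt, ann, B = 400, seed = 1, scope = "universe")
  expect_gt(tt2$p_value[tt2$term_id == "MIX"], 0.33)
  # present scope: u1 stays at rank 7, so only the measured slot moves and
  # P(mean <= 4) = P(label <= 1) = 1/6
  tt <- pvalue_terms(gt, ann, B = 400, seed = 1, scope = "present")
  expect_lt(tt$p_value[tt$term_id == "MIX"], 0.3)
  # a term at the rank ceiling can only be matched, never beaten
  expect_identical(tt$p_value[tt$term_id == "ABS"], 1)
  expect_identical(tt2$p_value[tt2$term_id == "ABS"], 1)

  # add-one estimator: strictly positive, (count + 1) / (B + 1)
  tt3 <- pvalue_terms(gt, ann, B = 400, seed = 1, estimator = "add_one")
  expect_true(all(tt3$p_value > 0))
  expect_equal(tt3$p_value, (tt2$p_value * 400 + 1) / 401)
})

test_that("term ordering ties break deterministically", {
  # both terms average rank 2.5; the higher average score comes first
  gt <- rank_genes(c(a = 8, b = 3, c = 2, d = 1))
  ann <- make_ann(list(T_z = c("a", "d"), T_a = c("b", "c")))
  tt <- summarise_terms(gt, ann)
  expect_identical(tt$avg_rank, c(2.5, 2.5))
  expect_identical(tt$term_id, c("T_z", "T_a"))
  # equal statistics throughout fall back to lexicographic term ids
  gt2 <- rank_genes(c(a = 4, b = 3, c = 2, d = 1))
  ann2 <- make_ann(list(T_z = c("a", "d"), T_a = c("b", "c")))
  expect_identical(summarise_terms(gt2, ann2)$term_id, c("T_a", "T_z"))
})
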