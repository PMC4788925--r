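test_that("one-way F ratio matches the hand-computed two-group example", {
  ds <- make_ds(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1), rep(c("a", "b"), each = 3))
  f <- suppressWarnings(score_genes_anova(ds, "group"))
  # SSB = 13.5, SSW = 4, df = (1, 4) -> F = 13.5 / 1 = 13.5
  expect_equal(as.vector(f), 13.5, tolerance = 1e-12)
})

test_that("constant genes score zero under both methods", {
  mat <- matrix(5, nrow = 4, ncol = 8)
  ds <- make_ds(mat, rep(c("a", "b"), each = 4))
  f <- suppressWarnings(score_genes_anova(ds, "group"))
  expect_identical(as.vector(f), rep(0, 4))
  rf <- suppressWarnings(score_genes_rf(ds, "group", ntree = 51L, seed = 1))
  expect_identical(as.vector(rf)[seq_len(4)], rep(0, 4))
})

test_that("F scores agree with the independent lm/anova oracle", {
  set.seed(10)
  ds <- make_ds(matrix(rnorm(100 * 15), nrow = 100),
                rep(c("a", "b", "c"), each = 5))
  f <- score_genes_anova(ds, "group")
  g <- factor(ds$sample_factors$group)
  oracle <- apply(ds$matrix, 1L, function(y)
    stats::anova(stats::lm(y ~ g))[["F value"]][1L])
  expect_equal(as.vector(f), unname(oracle), tolerance = 1e-10)
})

test_that("zero within-group variance is capped and flagged, not propagated", {
  mat <- rbind(det = rep(c(0, 1), each = 3),
               ok = c(0.1, 0.2, 0.3, 1.1, 1.2, 1.3))
  ds <- make_ds(mat, rep(c("a", "b"), each = 3))
  expect_warning(f <- score_genes_anova(ds, "group"), "capped")
  expect_true(is.finite(f[["det"]]))
  expect_identical(f[["det"]], unname(f[["ok"]]) * 10)
  expect_identical(attr(f, "capped"), "det")
})

test_that("degenerate designs are rejected with clear errors", {
  ds1 <- make_ds(matrix(rnorm(8), nrow = 2), rep("a", 4))
  expect_error(suppressWarnings(score_genes_anova(ds1, "group")), "single level")
  expect_error(suppressWarnings(score_genes_rf(ds1, "group")), "single level")

  ds2 <- make_ds(matrix(rnorm(8), nrow = 2), c("a", "b", "c", "d"))
  expect_error(score_genes_anova(ds2, "group"), "residual degrees")
  expect_error(suppressWarnings(score_genes_rf(ds2, "group")), "fewer than 2")

  ds3 <- make_ds(matrix(rnorm(12), nrow = 2), rep(c("a", "b"), each = 3))
  expect_warning(score_genes_rf(ds3, "group", ntree = 11L), "recommended 5")
})

test_that("random-forest scoring is reproducible and finds a separating gene", {
  ds <- make_separating_ds()
  s1 <- score_genes_rf(ds, "group", ntree = 301L, seed = 42)
  s2 <- score_genes_rf(ds, "group", ntree = 301L, seed = 42)
  expect_identical(s1, s2)
  expect_identical(attr(s1, "params"),
                   list(method = "rf", ntree = 301L,
                        mtry = as.integer(floor(sqrt(51))), seed = 42L))

  # the perfectly separating gene tops the score across independent seeds
  for (seed in 1:5) {
    s <- score_genes_rf(ds, "group", ntree = 1000L, seed = seed)
    expect_identical(names(which.max(s)), "sep")
  }

  # with permuted class labels the gene loses its standing
  ds_perm <- ds
  set.seed(99)
  ds_perm$sample_factors$group <- sample(ds_perm$sample_factors$group)
  sp <- score_genes_rf(ds_perm, "group", ntree = 1000L, seed = 1)
  expect_gt(rank(-sp)[["sep"]], 5)
})

test_that("forest scores are stable across forest seeds on planted signal", {
  sim <- generate_synthetic(sim_config(n_genes_present = 400,
                                       n_genes_absent = 0,
                                       n_null_terms = 0, seed = 8))
  a <- score_genes_rf(sim$dataset, "group", ntree = 1000L, seed = 1)
  b <- score_genes_rf(sim$dataset, "group", ntree = 1000L, seed = 2)
  expect_gt(cor(a, b), 0.7)
  planted <- sim$truth$planted[[1L]]
  expect_true(all(rank(-a)[planted] <= 40))
  expect_true(all(rank(-b)[planted] <= 40))
})

test_that("rank_genes applies fractional ties and the absent-gene rule", {
  scores <- c(g1 = 0.5, g2 = 0.2, g3 = 0.2, g4 = 0)
  gt <- rank_genes(scores)
  expect_identical(stats::setNames(gt$rank, gt$gene_id),
                   c(g1 = 1, g2 = 2.5, g3 = 2.5, g4 = 4))

  ann <- make_ann(list(T1 = c("g1", "g5")))
  gt5 <- rank_genes(scores, ann)
  g5 <- gt5[gt5$gene_id == "g5", ]
  expect_identical(g5$score, 0)
  expect_identical(g5$rank, 5)       # N + 1 with N = 4
  expect_false(g5$present)
  # measured but unannotated genes stay in the table and count towards N
  expect_true(all(c("g2", "g3", "g4") %in% gt5$gene_id))

  expect_error(rank_genes(numeric()), "empty")
  expect_error(rank_genes(c(1, 2)), "named")
})

test_that("present ranks always sum to N(N+1)/2 and survive monotone maps", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:40, 1L)
    scores <- stats::setNames(round(stats::rexp(n), 1L),  # forces ties
                              sprintf("g%03d", seq_len(n)))
    gt <- rank_genes(scores, universe = c("u1", "u2"))
    expect_equal(sum(gt$rank[gt$present]), n * (n + 1) / 2)
    expect_true(all(gt$rank[!gt$present] == n + 1))

    gt2 <- rank_genes(stats::setNames(sqrt(scores) + 1, names(scores)),
                      universe = c("u1", "u2"))
    expect_identical(gt2$rank, gt$rank)
    expect_identical(gt2$gene_id, gt$gene_id)
  }
})
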