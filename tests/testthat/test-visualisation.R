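# 4 treatments x 3 time points x 2 replicates, one gene with known means
viz_ds <- function(seed = 1) {
  set.seed(seed)
  trt <- rep(c("ctrl", "tb", "bcg", "map"), each = 6)
  time <- rep(rep(c(0, 2, 24), each = 2), 4)
  animal <- rep(c("a1", "a2"), 12)
  n <- length(trt)
  mat <- rbind(ccl5 = rnorm(n, 5 + as.numeric(factor(trt)), 0.3),
               flat = rnorm(n, 1, 0.1))
  colnames(mat) <- sprintf("s%02d", seq_len(n))
  expression_dataset(mat, data.frame(row.names = colnames(mat),
                                     treatment = trt, time = time,
                                     animal = animal))
}

test_that("expression_plot aggregates group means with an SE band", {
  ds <- viz_ds()
  d <- withr::local_tempdir()
  out <- expression_plot(ds, "ccl5", "time", "treatment",
                         out_path = file.path(d, "p.png"),
                         data_path = file.path(d, "p.tsv"))
  expect_identical(nrow(out$data), 12L)               # 4 groups x 3 times
  expect_identical(length(unique(out$data$group)), 4L)
  expect_true(all(out$data$n == 2L))
  expect_true(all(is.finite(out$data$se)))
  # aggregates match direct computation
  sel <- out$data$group == "tb" & out$data$x == "2"
  keep <- ds$sample_factors$treatment == "tb" & ds$sample_factors$time == "2"
  expect_equal(out$data$mean[sel], mean(ds$matrix["ccl5", keep]))
  expect_equal(out$data$se[sel],
               sd(ds$matrix["ccl5", keep]) / sqrt(2))
  expect_true(file.exists(file.path(d, "p.png")))
  expect_true(file.size(file.path(d, "p.png")) > 0)

  # single-sample cells carry an undefined SE and the band is dropped there
  ds1 <- subset_samples(ds, "animal", "a1")
  out1 <- expression_plot(ds1, "ccl5", "time", "treatment")
  expect_true(all(is.na(out1$data$se)))
  expect_identical(nrow(out1$data), 12L)

  expect_error(expression_plot(ds, "CCL5", "time", "treatment"),
               "feature id")
})

test_that("expression_profiles draws one unaggregated series per unit", {
  ds <- viz_ds()
  out <- expression_profiles(ds, "ccl5", "time", c("animal", "treatment"),
                             colour_factor = "treatment")
  expect_identical(length(unique(out$data$series)), 8L)  # 2 animals x 4 trt
  expect_identical(nrow(out$data), 24L)                  # every sample kept
  expect_setequal(unique(out$data$colour),
                  c("ctrl", "tb", "bcg", "map"))
})

test_that("plotting leaves the expression matrix untouched and is deterministic", {
  ds <- viz_ds()
  before <- ds$matrix
  d <- withr::local_tempdir()
  expression_plot(ds, "ccl5", "time", "treatment",
                  data_path = file.path(d, "a.tsv"))
  expression_plot(ds, "ccl5", "time", "treatment",
                  data_path = file.path(d, "b.tsv"))
  expect_identical(ds$matrix, before)
  expect_identical(readLines(file.path(d, "a.tsv")),
                   readLines(file.path(d, "b.tsv")))
})

test_that("heatmap_go clusters genes and samples as constructed", {
  # two perfectly anti-correlated gene blocks
  set.seed(2)
  n <- 12
  base <- sin(seq_len(n))
  up <- t(vapply(1:4, function(i) base + rnorm(n, 0, 0.05), numeric(n)))
  down <- t(vapply(1:4, function(i) -base + rnorm(n, 0, 0.05), numeric(n)))
  mat <- rbind(up, down)
  rownames(mat) <- c(paste0("up", 1:4), paste0("down", 1:4))
  colnames(mat) <- sprintf("s%02d", 1:n)
  ds <- make_ds(mat, rep(c("a", "b"), each = 6))
  ann <- make_ann(list(T1 = rownames(mat)))

  hm <- heatmap_go(ds, NULL, ann, "T1", "group")
  blocks <- stats::cutree(hm$gene_hclust, k = 2)
  expect_identical(length(unique(blocks[paste0("up", 1:4)])), 1L)
  expect_identical(length(unique(blocks[paste0("down", 1:4)])), 1L)
  expect_false(blocks[["up1"]] == blocks[["down1"]])

  # well-separated sample groups split at the root of the sample dendrogram
  set.seed(3)
  mat2 <- matrix(rnorm(6 * 10), nrow = 6,
                 dimnames = list(paste0("g", 1:6), sprintf("s%02d", 1:10)))
  mat2[, 6:10] <- mat2[, 6:10] + 10
  ds2 <- make_ds(mat2, rep(c("a", "b"), each = 5))
  ann2 <- make_ann(list(T1 = rownames(mat2)))
  hm2 <- heatmap_go(ds2, NULL, ann2, "T1", "group")
  cl <- stats::cutree(hm2$sample_hclust, k = 2)
  expect_identical(length(unique(cl[1:5])), 1L)
  expect_identical(length(unique(cl[6:10])), 1L)
  expect_false(cl[[1L]] == cl[[10L]])

  # determinism of the returned leaf orders
  hm2b <- heatmap_go(ds2, NULL, ann2, "T1", "group")
  expect_identical(hm2$gene_order, hm2b$gene_order)
  expect_identical(hm2$sample_order, hm2b$sample_order)

  # image file written on request
  d <- withr::local_tempdir()
  heatmap_go(ds2, NULL, ann2, "T1", "group",
             out_path = file.path(d, "h.png"))
  expect_true(file.size(file.path(d, "h.png")) > 0)
})

test_that("heatmap_go handles single-gene terms and rejects empty ones", {
  ds <- viz_ds()
  ann <- make_ann(list(SOLO = "ccl5", GONE = c("u1", "u2")))
  hm <- heatmap_go(ds, NULL, ann, "SOLO", "treatment")
  expect_identical(hm$gene_order, "ccl5")
  expect_null(hm$gene_hclust)
  expect_error(heatmap_go(ds, NULL, ann, "GONE", "treatment"),
               "no genes measured")
  expect_error(heatmap_go(ds, NULL, ann, "NOPE", "treatment"), "not found")
})
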