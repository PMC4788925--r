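# Per-gene scoring of classification power and the competition ranking over
# the full annotation universe. Two scorers: random-forest mean decrease in
# Gini index (default, non-parametric, multi-group) and the one-way ANOVA F
# ratio (parametric alternative). Ranking uses fractional (average) ranks for
# ties; genes known to the annotations but unmeasured in the dataset receive
# score 0 and the single worst rank N + 1.

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.check_groups <- function(y, factor, min_per_level = 2L, recommend = 5L) {
  tab <- table(y)
  if (length(tab) < 2L) {
    stop("factor '", factor, "' has a single level among the analysed samples;",
         " need >= 2 groups to classify", call. = FALSE)
  }
  small <- tab[tab < min_per_level]
  if (length(small) > 0L) {
    stop("factor '", factor, "' level(s) with fewer than ", min_per_level,
         " samples: ", paste(names(small), collapse = ", "), call. = FALSE)
  }
  under <- tab[tab < recommend]
  if (length(under) > 0L) {
    warning("factor '", factor, "' has level(s) below the recommended ",
            recommend, " biological replicates: ",
            paste(sprintf("%s (n=%d)", names(under), as.integer(under)),
                  collapse = ", "))
  }
  invisible(tab)
}

#' Score genes by random-forest variable importance
#'
#' Trains a random-forest classifier of the sample groups on the full
#' gene-by-sample matrix and scores every gene by its mean decrease in Gini
#' impurity: the impurity reduction attributable to splits on that gene,
#' averaged over all trees. Genes that help separate the groups — across any
#' number of levels, not just two — earn high scores; genes carrying no
#' group information score near zero.
#'
#' @param ds an `expression_dataset`.
#' @param factor name of the grouping factor in `ds$sample_factors`; needs at
#'   least two levels with at least two samples each (a warning is issued
#'   below five replicates per level).
#' @param ntree number of trees (default 1000).
#' @param mtry candidate genes sampled per split; default
#'   `floor(sqrt(P))` for P measured genes.
#' @param seed RNG seed for the forest; recorded so runs are reproducible.
#' @return Named numeric vector of non-negative scores, one per measured
#'   gene, with the scoring parameters in attribute `"params"`.
#' @seealso [score_genes_anova()], [rank_genes()]
#' @export
score_genes_rf <- function(ds, factor, ntree = 1000L, mtry = NULL, seed = 0L) {
  stopifnot(inherits(ds, "expression_dataset"))
  y <- factor(get_factor(ds, factor))
  .check_groups(y, factor)
  p <- nrow(ds$matrix)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- as.integer(mtry)
  ntree <- as.integer(ntree)
  if (ntree < 1L) stop("'ntree' must be >= 1", call. = FALSE)
  if (mtry < 1L || mtry > p) stop("'mtry' must be in [1, P]", call. = FALSE)

  if (sum((ds$matrix - rowMeans(ds$matrix))^2) == 0) {
    # no gene varies, no split can reduce impurity: all importances are zero
    scores <- stats::setNames(rep(0, p), rownames(ds$matrix))
    attr(scores, "params") <- list(method = "rf", ntree = ntree, mtry = mtry,
                                   seed = as.integer(seed))
    return(scores)
  }
  rf <- with_seed(seed,
    randomForest::randomForest(x = t(ds$matrix), y = y,
                               ntree = ntree, mtry = mtry))
  scores <- rf$importance[, "MeanDecreaseGini"]
  names(scores) <- rownames(ds$matrix)
  scores <- pmax(scores, 0)  # guard against -0 / tiny negatives
  attr(scores, "params") <- list(method = "rf", ntree = ntree, mtry = mtry,
                                 seed = as.integer(seed))
  scores
}

#' Score genes by the one-way ANOVA F ratio
#'
#' Parametric alternative: for each gene the ratio of between-group to
#' within-group mean squares,
#' `F = (SSB / (k - 1)) / (SSW / (n - k))` for k groups and n samples.
#' Computed in closed form simultaneously for all genes. A gene with zero
#' within-group variance but distinct group means has an infinite F; such
#' scores are capped at ten times the largest finite score (the affected
#' genes are flagged in attribute `"capped"`) so the ranking stays total.
#'
#' @inheritParams score_genes_rf
#' @return Named numeric vector of F ratios with attribute `"params"`.
#' @export
score_genes_anova <- function(ds, factor) {
  stopifnot(inherits(ds, "expression_dataset"))
  y <- factor(get_factor(ds, factor))
  tab <- table(y)
  if (length(tab) < 2L) {
    stop("factor '", factor, "' has a single level among the analysed samples",
         call. = FALSE)
  }
  n <- length(y)
  k <- length(tab)
  if (n <= k) {
    stop("no residual degrees of freedom: ", n, " samples for ", k,
         " groups", call. = FALSE)
  }
  if (all(tab < 2L)) {
    stop("within-group variance undefined: every level has a single sample",
         call. = FALSE)
  }

  x <- ds$matrix
  grand <- rowMeans(x)
  sst <- rowSums((x - grand)^2)
  ssb <- numeric(nrow(x))
  for (lev in levels(y)) {
    idx <- y == lev
    ssb <- ssb + sum(idx) * (rowMeans(x[, idx, drop = FALSE]) - grand)^2
  }
  ssw <- pmax(sst - ssb, 0)

  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(ssb <= sst * 1e-14, 0, msb / msw)  # constant genes score 0

  capped <- character()
  inf <- !is.finite(f)
  if (any(inf)) {
    finite_max <- if (any(!inf & f > 0)) max(f[!inf]) else 1
    f[inf] <- finite_max * 10
    capped <- rownames(x)[inf]
    warning(length(capped), " gene(s) with zero within-group variance; ",
            "F capped at 10x the largest finite score")
  }
  names(f) <- rownames(x)
  attr(f, "params") <- list(method = "anova")
  if (length(capped) > 0L) attr(f, "capped") <- capped
  f
}

#' Rank genes over the annotation universe
#'
#' Turns a score vector into the per-gene ranking table used for term
#' summarisation. Measured genes are ranked by descending score with
#' fractional (average) ranks for ties, so the ranks of N measured genes
#' always sum to N(N+1)/2. Every annotated gene absent from the dataset is
#' appended with score 0 and the single shared rank N + 1 — the worst rank
#' preserving continuity — which penalises the terms annotating it. Measured
#' genes without annotation are kept: they count towards N and form part of
#' the competitive background.
#'
#' @param scores named numeric vector of non-negative scores for the measured
#'   genes (from [score_genes_rf()] or [score_genes_anova()]).
#' @param ann optional `annotation_bundle`; its gene universe supplies the
#'   absent genes and its `gene_info` the name/description columns.
#' @param universe optional explicit character vector of universe gene ids
#'   (overrides `ann` for the universe; metadata still joined from `ann`).
#' @return data.frame with columns `gene_id`, `score`, `rank`, `present`,
#'   `name`, `description`, ordered by ascending rank (absent genes last,
#'   alphabetically). Attribute `"n_present"` holds N.
#' @examples
#' rank_genes(c(g1 = 0.5, g2 = 0.2, g3 = 0.2, g4 = 0))$rank
#' @export
rank_genes <- function(scores, ann = NULL, universe = NULL) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be uniquely named by gene id", call. = FALSE)
  }
  if (any(!is.finite(scores)) || any(scores < 0)) {
    stop("scores must be finite and non-negative", call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- if (!is.null(ann)) {
      union(names(scores), annotation_universe(ann))
    } else names(scores)
  } else {
    universe <- union(names(scores), as.character(universe))
  }

  n <- length(scores)
  r <- rank(-scores, ties.method = "average")
  present <- data.frame(gene_id = names(scores), score = as.numeric(scores),
                        rank = as.numeric(r), present = TRUE,
                        stringsAsFactors = FALSE)
  present <- present[order(present$rank, present$gene_id), , drop = FALSE]

  absent_ids <- sort(setdiff(universe, names(scores)))
  absent <- data.frame(gene_id = absent_ids,
                       score = rep(0, length(absent_ids)),
                       rank = rep(as.numeric(n + 1), length(absent_ids)),
                       present = rep(FALSE, length(absent_ids)),
                       stringsAsFactors = FALSE)
  gt <- rbind(present, absent)
  rownames(gt) <- NULL

  gt$name <- ""
  gt$description <- ""
  if (!is.null(ann) && nrow(ann$gene_info) > 0L) {
    m <- match(gt$gene_id, ann$gene_info$gene_id)
    hit <- !is.na(m)
    gt$name[hit] <- ann$gene_info$name[m[hit]]
    gt$description[hit] <- ann$gene_info$description[m[hit]]
  }
  attr(gt, "n_present") <- n
  validate_gene_table(gt)
  gt
}
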