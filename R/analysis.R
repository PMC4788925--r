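# End-to-end pipeline wrappers: score -> rank -> summarise as one traceable
# result, and the permutation stage applied to a result.

#' Run the scoring and summarisation pipeline
#'
#' Scores every measured gene's power to classify the groups defined by
#' `factor`, ranks genes over the full annotation universe and aggregates the
#' ranking per term. The returned result records every parameter (factor,
#' subset, method, hyperparameters, aggregation, seed) so it can be exported,
#' re-imported and reproduced exactly.
#'
#' @param ds an `expression_dataset`.
#' @param ann an `annotation_bundle`.
#' @param factor name of the grouping factor.
#' @param method `"rf"` (random-forest Gini importance, default) or
#'   `"anova"` (one-way F ratio).
#' @param subset optional named list of factor = levels pairs applied with
#'   [subset_samples()] before scoring (conjunctive across factors).
#' @param metric,func term aggregation, see [summarise_terms()].
#' @param ntree,mtry,seed random-forest parameters, see [score_genes_rf()]
#'   (ignored for `method = "anova"`).
#' @return An `analysis_result`.
#' @examples
#' sim <- generate_synthetic(sim_config(n_genes_present = 60,
#'                                      n_genes_absent = 5,
#'                                      n_null_terms = 5, seed = 1))
#' res <- go_analyse(sim$dataset, sim$annotations, factor = "group",
#'                   method = "anova")
#' head(res$term_table)
#' @export
go_analyse <- function(ds, ann, factor, method = c("rf", "anova"),
                       subset = NULL, metric = c("rank", "score"),
                       func = mean, ntree = 1000L, mtry = NULL, seed = 0L) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(ann, "annotation_bundle"))
  if (!is.null(subset)) {
    if (is.null(names(subset)) || any(!nzchar(names(subset)))) {
      stop("'subset' must be a named list of factor = levels", call. = FALSE)
    }
    for (f in names(subset)) {
      ds <- subset_samples(ds, f, subset[[f]])
    }
  }
  scores <- if (method == "rf") {
    score_genes_rf(ds, factor, ntree = ntree, mtry = mtry, seed = seed)
  } else {
    score_genes_anova(ds, factor)
  }
  sp <- attr(scores, "params")
  gt <- rank_genes(scores, ann)
  agg <- .resolve_agg(func)
  tt <- summarise_terms(gt, ann, metric, agg$fn)

  params <- c(list(factor = factor,
                   subset = lapply(subset, function(v) as.character(v)),
                   samples = sample_ids(ds)),
              sp,
              list(metric = metric, agg_fun = agg$name))
  analysis_result(gt, tt, params)
}

#' Add permutation P-values to an analysis result
#'
#' Runs [pvalue_terms()] with the result's own metric and aggregation and
#' attaches the P-values to its term table; the permutation settings join
#' the parameter record.
#'
#' @param result an `analysis_result` from [go_analyse()].
#' @param ann the `annotation_bundle` the result was computed against.
#' @param B,seed,scope,estimator see [pvalue_terms()].
#' @param func aggregation override; default uses the recorded one.
#' @return The augmented `analysis_result`.
#' @export
pvalue_go <- function(result, ann, B = 1000L, seed = 0L,
                      scope = c("universe", "present"),
                      estimator = c("proportion", "add_one"), func = NULL) {
  stopifnot(inherits(result, "analysis_result"))
  scope <- match.arg(scope)
  estimator <- match.arg(estimator)
  metric <- result$parameters$metric %||% "rank"
  if (is.null(func)) {
    func <- result$parameters$agg_fun %||% "mean"
    if (identical(func, "custom")) {
      stop("result was aggregated with a custom function; pass it via 'func'",
           call. = FALSE)
    }
  }
  tt <- pvalue_terms(result$gene_table, ann, metric = metric, func = func,
                     B = B, seed = seed, scope = scope, estimator = estimator)
  if ("position" %in% names(result$term_table)) {
    warning("recomputing p-values on a filtered result uses only its gene",
            " table; term table is rebuilt over all annotated terms")
  }
  params <- result$parameters
  params$permutations <- attr(tt, "permutations")
  analysis_result(result$gene_table, tt, params)
}
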