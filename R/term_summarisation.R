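# Aggregation of gene scores/ranks into per-term statistics, and permutation
# P-values for term ranking. A term's statistic is the aggregate (mean by
# default) of its annotated genes' ranks or scores over the FULL universe:
# annotated genes missing from the dataset contribute rank N + 1 and score 0,
# so terms whose annotation is poorly covered by the data are penalised.

.resolve_agg <- function(func) {
  if (is.character(func)) return(list(name = func, fn = match.fun(func)))
  if (!is.function(func)) {
    stop("'func' must be a function or function name", call. = FALSE)
  }
  name <- if (identical(func, base::mean)) "mean"
          else if (identical(func, stats::median)) "median"
          else "custom"
  list(name = name, fn = func)
}

# per-term integer index list into the gene table
.term_index <- function(gene_table, ann) {
  g2t <- ann$gene2term
  idx <- match(g2t$gene_id, gene_table$gene_id)
  if (anyNA(idx)) {
    stop("gene table does not cover the annotation universe; missing: ",
         paste(utils::head(unique(g2t$gene_id[is.na(idx)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  split(idx, g2t$term_id)
}

#' Summarise gene ranks and scores over terms
#'
#' Computes, for every term in the annotations, the aggregate rank and
#' aggregate score of all its annotated genes — absent genes included at
#' rank N + 1 / score 0 — together with gene counts. By default the
#' aggregate is the mean ("average rank"); any pure reduction over a vector
#' of reals can be supplied instead, in which case the table-level bound
#' checks specific to the mean are skipped.
#'
#' Terms are ordered by ascending aggregate rank when `metric = "rank"`
#' (descending aggregate score when `metric = "score"`); ties are broken by
#' the other statistic, then by term id, so output order is deterministic.
#'
#' @param genes gene table from [rank_genes()], covering the full universe.
#' @param ann an `annotation_bundle`.
#' @param metric which statistic drives the term ordering: `"rank"`
#'   (default) or `"score"`.
#' @param func aggregation function or its name (default `mean`).
#' @return data.frame with columns `term_id`, `name`, `namespace`,
#'   `avg_rank`, `avg_score`, `total_genes`, `data_genes`, `p_value`
#'   (`NA` until [pvalue_terms()] is run); attributes `"metric"`,
#'   `"agg_fun"`, `"n_present"`.
#' @examples
#' gt <- rank_genes(c(g1 = 3, g2 = 2, g3 = 1))
#' ann <- annotation_bundle(data.frame(gene_id = c("g1", "g2"),
#'                                     term_id = "T1"))
#' summarise_terms(gt, ann)
#' @export
summarise_terms <- function(genes, ann, metric = c("rank", "score"),
                            func = mean) {
  metric <- match.arg(metric)
  validate_gene_table(genes)
  stopifnot(inherits(ann, "annotation_bundle"))
  agg <- .resolve_agg(func)
  n_present <- sum(genes$present)

  idx <- .term_index(genes, ann)
  term_ids <- names(idx)
  agg_over <- function(values) {
    vapply(seq_along(idx), function(i) {
      out <- tryCatch(agg$fn(values[idx[[i]]]), error = function(e) {
        stop("aggregation '", agg$name, "' failed for term ", term_ids[i],
             ": ", conditionMessage(e), call. = FALSE)
      })
      as.numeric(out)
    }, numeric(1))
  }
  tt <- data.frame(
    term_id = term_ids,
    avg_rank = agg_over(genes$rank),
    avg_score = agg_over(genes$score),
    total_genes = lengths(idx),
    data_genes = vapply(idx, function(i) sum(genes$present[i]), integer(1)),
    p_value = rep(NA_real_, length(term_ids)),
    stringsAsFactors = FALSE)

  m <- match(tt$term_id, ann$term_info$term_id)
  tt$name <- ifelse(is.na(m), "", ann$term_info$name[m])
  tt$namespace <- ifelse(is.na(m), NA_character_, ann$term_info$namespace[m])

  ord <- if (metric == "rank") {
    order(tt$avg_rank, -tt$avg_score, tt$term_id)
  } else {
    order(-tt$avg_score, tt$avg_rank, tt$term_id)
  }
  tt <- tt[ord, c("term_id", "name", "namespace", "avg_rank", "avg_score",
                  "total_genes", "data_genes", "p_value")]
  rownames(tt) <- NULL
  attr(tt, "metric") <- metric
  attr(tt, "agg_fun") <- agg$name
  attr(tt, "n_present") <- n_present
  validate_term_table(tt, n_present, mean_agg = identical(agg$name, "mean"))
  tt
}

#' Permutation P-values for term statistics
#'
#' Estimates, for every term, the probability of reaching an aggregate
#' statistic at least as good as observed when the gene ranking carries no
#' information: the (score, rank) label pairs of the ranking table are
#' shuffled jointly across genes, term statistics are recomputed, and the
#' P-value is the proportion of the `B` permutations in which the permuted
#' statistic is at least as extreme (aggregate rank less than or equal to the
#' observed one for `metric = "rank"`; aggregate score greater than or equal
#' for `metric = "score"`). All terms are evaluated against the same
#' permutation draws, so among equally sized terms a better observed
#' statistic never earns a larger P-value.
#'
#' By default labels circulate over the full universe, absent genes' 0/N+1
#' labels included, mirroring how uninformative genes weigh terms down in the
#' observed table; `scope = "present"` instead keeps absent-gene labels fixed
#' and shuffles only the measured genes.
#'
#' The returned P-values are deliberately unadjusted: term statistics share
#' one competitive ranking and are strongly dependent, so familywise or FDR
#' adjustment over them is not meaningful.
#'
#' @inheritParams summarise_terms
#' @param B number of permutations (default 1000).
#' @param seed RNG seed for the permutation stream (independent of any
#'   scoring seed).
#' @param scope `"universe"` (default) or `"present"`; see Details.
#' @param estimator `"proportion"` for the plain count/B, or `"add_one"` for
#'   (count+1)/(B+1) when strictly positive P-values are required.
#' @return The term table of [summarise_terms()] with `p_value` filled in.
#' @export
pvalue_terms <- function(genes, ann, metric = c("rank", "score"),
                         func = mean, B = 1000L, seed = 0L,
                         scope = c("universe", "present"),
                         estimator = c("proportion", "add_one")) {
  metric <- match.arg(metric)
  scope <- match.arg(scope)
  estimator <- match.arg(estimator)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("'B' must be a positive integer", call. = FALSE)

  agg <- .resolve_agg(func)
  tt <- summarise_terms(genes, ann, metric, agg$fn)
  attr(tt, "agg_fun") <- agg$name

  idx <- .term_index(genes, ann)
  idx <- idx[tt$term_id]  # align with table order
  values <- if (metric == "rank") genes$rank else genes$score
  observed <- if (metric == "rank") tt$avg_rank else tt$avg_score
  # tolerance absorbs permutation-order float noise so that e.g. a term
  # annotated with the whole universe compares equal to itself
  tol <- pmax(1e-9, abs(observed) * 1e-12)

  # Under the exchangeable null a term's permuted statistic depends only on
  # how many of its labels circulate: all of them (universe scope) or only
  # the measured ones, the absent members keeping their fixed 0 / N+1 label
  # (present scope). Each permutation therefore shuffles the label pool once
  # and evaluates one statistic per (circulating, fixed) size class from a
  # prefix of the shuffled pool — equally sized terms face the identical
  # permuted stream, so a better observed statistic can never earn a larger
  # p-value, and prefix cumsums make the mean path O(universe) per draw.
  present_members <- vapply(idx, function(i) sum(genes$present[i]), integer(1))
  if (scope == "universe") {
    n_circ <- lengths(idx)
    n_fixed <- integer(length(idx))
    pool <- values
  } else {
    n_circ <- present_members
    n_fixed <- lengths(idx) - present_members
    pool <- values[genes$present]
  }
  fixed_label <- if (metric == "rank") sum(genes$present) + 1 else 0
  class_key <- paste(n_circ, n_fixed)
  classes <- !duplicated(class_key)
  cls_circ <- n_circ[classes]
  cls_fixed <- n_fixed[classes]
  term_class <- match(class_key, class_key[classes])

  mean_path <- identical(agg$name, "mean")
  count <- integer(nrow(tt))
  with_seed(seed, {
    for (bb in seq_len(B)) {
      perm <- pool[sample.int(length(pool))]
      stat_cls <- if (mean_path) {
        cs <- c(0, cumsum(perm))
        (cs[cls_circ + 1L] + cls_fixed * fixed_label) /
          (cls_circ + cls_fixed)
      } else {
        vapply(seq_along(cls_circ), function(k)
          as.numeric(agg$fn(c(perm[seq_len(cls_circ[k])],
                              rep(fixed_label, cls_fixed[k])))),
          numeric(1))
      }
      stat <- stat_cls[term_class]
      count <- count + if (metric == "rank") {
        as.integer(stat <= observed + tol)
      } else {
        as.integer(stat >= observed - tol)
      }
    }
  })

  tt$p_value <- if (estimator == "proportion") count / B
                else (count + 1) / (B + 1)
  validate_term_table(tt, attr(tt, "n_present"), mean_agg = mean_path)
  attr(tt, "permutations") <- list(B = B, seed = as.integer(seed),
                                   scope = scope, estimator = estimator)
  tt
}
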