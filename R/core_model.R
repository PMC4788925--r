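# In-memory model shared by all analysis stages: the expression dataset, the
# annotation bundle, the per-gene and per-term score tables, and the analysis
# result container. Constructors enforce the integrity rules; everything
# downstream may assume them.

#' Construct an expression dataset
#'
#' Bundles a normalised expression matrix (genes in rows, samples in columns)
#' with a per-sample table of experimental factors. Expression values are
#' taken as-is: the package never transforms them, so the matrix is expected
#' to arrive normalised and, typically, log-scaled (log2 intensities or log2
#' CPM). Missing or non-finite values are rejected rather than imputed.
#'
#' @param matrix numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene/probeset identifiers) and colnames (sample identifiers).
#' @param sample_factors data.frame of experimental factors, one row per
#'   sample. Rows are matched to samples by rownames, or by a `sample_id`
#'   column if present. Every sample in `matrix` must have a row; extra rows
#'   are dropped with a warning.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix` and `sample_factors` (row order matching `colnames(matrix)`).
#' @examples
#' m <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ph <- data.frame(row.names = colnames(m), group = rep(c("a", "b"), 2))
#' ds <- expression_dataset(m, ph)
#' @export
expression_dataset <- function(matrix, sample_factors) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("'matrix' must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  bad <- which(!is.finite(matrix), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "expression matrix contains %d missing/non-finite value(s); first at gene '%s', sample '%s'",
      nrow(bad), rownames(matrix)[bad[1L, 1L]], colnames(matrix)[bad[1L, 2L]]),
      call. = FALSE)
  }
  .check_unique_ids(rownames(matrix), "gene id")
  .check_unique_ids(colnames(matrix), "sample id")

  if (!is.data.frame(sample_factors)) {
    stop("'sample_factors' must be a data.frame", call. = FALSE)
  }
  sf <- sample_factors
  if ("sample_id" %in% names(sf)) {
    rownames(sf) <- as.character(sf$sample_id)
    sf$sample_id <- NULL
  }
  samples <- colnames(matrix)
  missing <- setdiff(samples, rownames(sf))
  if (length(missing) > 0L) {
    stop("samples in the expression matrix have no phenotype row: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(rownames(sf), samples)
  if (length(extra) > 0L) {
    warning("dropping ", length(extra),
            " phenotype row(s) without expression data: ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
  }
  sf <- sf[samples, , drop = FALSE]
  # factor values are compared as strings after whitespace trimming
  for (j in seq_along(sf)) {
    if (is.factor(sf[[j]])) sf[[j]] <- as.character(sf[[j]])
    if (is.character(sf[[j]])) sf[[j]] <- trimws(sf[[j]])
  }
  structure(list(matrix = matrix, sample_factors = sf),
            class = "expression_dataset")
}

.check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("empty or missing ", what, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate ", what, "(s): ",
         paste(utils::head(dup, 5L), collapse = ", "),
         if (length(dup) > 5L) ", ..." else "", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$matrix), "gene features x",
      ncol(x$matrix), "samples\n")
  cat("sample factors:", paste(names(x$sample_factors), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Gene and sample identifiers of a dataset
#' @param ds an `expression_dataset`.
#' @return Character vector of identifiers, in matrix order.
#' @export
gene_ids <- function(ds) rownames(ds$matrix)

#' @rdname gene_ids
#' @export
sample_ids <- function(ds) colnames(ds$matrix)

# Validated accessor: factor values as a trimmed character vector named by
# sample id. Numeric factors (e.g. time points) become their character form,
# so levels act as categorical groups.
get_factor <- function(ds, factor) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(factor) != 1L || !factor %in% names(ds$sample_factors)) {
    stop("unknown sample factor '", factor, "'; available: ",
         paste(names(ds$sample_factors), collapse = ", "), call. = FALSE)
  }
  v <- ds$sample_factors[[factor]]
  v <- trimws(as.character(v))
  if (anyNA(v)) {
    stop("factor '", factor, "' has missing values for sample(s): ",
         paste(sample_ids(ds)[is.na(v)], collapse = ", "), call. = FALSE)
  }
  names(v) <- sample_ids(ds)
  v
}

#' Subset samples by factor level
#'
#' Restricts a dataset to the samples whose value of `factor` lies in
#' `keep_levels`, leaving the gene set untouched. Analyses can thereby be run
#' on sample subsets defined on the fly (e.g. only post-infection time
#' points) without rebuilding the input. Levels are matched as
#' whitespace-trimmed strings, so numeric time points may be given as numbers
#' or strings.
#'
#' @param ds an `expression_dataset`.
#' @param factor name of a column of `ds$sample_factors`.
#' @param keep_levels non-empty vector of levels to retain; every element
#'   must be an observed level of `factor`.
#' @return A new `expression_dataset` with the retained samples.
#' @examples
#' m <- matrix(rnorm(12), nrow = 2, dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' ph <- data.frame(row.names = colnames(m), time = rep(c(0, 2, 24), 2))
#' ncol(subset_samples(m_ds <- expression_dataset(m, ph), "time", c(2, 24))$matrix)
#' @export
subset_samples <- function(ds, factor, keep_levels) {
  v <- get_factor(ds, factor)
  keep_levels <- trimws(as.character(keep_levels))
  if (length(keep_levels) == 0L) {
    stop("'keep_levels' must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(keep_levels, unique(v))
  if (length(unknown) > 0L) {
    stop("level(s) not observed for factor '", factor, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- v %in% keep_levels
  expression_dataset(ds$matrix[, keep, drop = FALSE],
                     ds$sample_factors[keep, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Annotation bundle

.go_namespaces <- c("biological_process", "molecular_function",
                    "cellular_component")

.normalise_namespace <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(as.character(x))))
}

#' Construct an annotation bundle
#'
#' The three-table annotation contract: a gene-to-term mapping, per-gene
#' metadata and per-term metadata. The mapping defines the gene universe and
#' deliberately may (and for an honest background, should) include genes that
#' are absent from any particular expression dataset; such genes later
#' receive score 0 and the worst rank, penalising the terms they annotate.
#'
#' @param gene2term data.frame with columns `gene_id`, `term_id` (extra
#'   columns ignored). Duplicate pairs are removed with a warning.
#' @param gene_info optional data.frame with columns `gene_id`, `name` and
#'   optionally `description` (empty string when missing).
#' @param term_info optional data.frame with columns `term_id`, `name`,
#'   `namespace`; namespaces must be one of `biological_process`,
#'   `molecular_function`, `cellular_component` (case/space insensitive).
#'   Terms present in the mapping but missing here are kept with an empty
#'   name and are reported.
#' @return An object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(gene2term, gene_info = NULL, term_info = NULL) {
  if (!is.data.frame(gene2term) ||
      !all(c("gene_id", "term_id") %in% names(gene2term))) {
    stop("'gene2term' must be a data.frame with columns gene_id, term_id",
         call. = FALSE)
  }
  g2t <- data.frame(gene_id = trimws(as.character(gene2term$gene_id)),
                    term_id = trimws(as.character(gene2term$term_id)),
                    stringsAsFactors = FALSE)
  ok <- nzchar(g2t$gene_id) & nzchar(g2t$term_id) &
    !is.na(g2t$gene_id) & !is.na(g2t$term_id)
  if (!all(ok)) {
    stop("gene2term contains empty/missing identifiers at row(s): ",
         paste(utils::head(which(!ok), 5L), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(g2t)
  if (any(dup)) {
    warning("removed ", sum(dup), " duplicate (gene, term) pair(s)")
    g2t <- g2t[!dup, , drop = FALSE]
  }
  rownames(g2t) <- NULL

  gi <- .tidy_gene_info(gene_info)
  ti <- .tidy_term_info(term_info)

  missing_terms <- setdiff(unique(g2t$term_id), ti$term_id)
  if (length(missing_terms) > 0L) {
    message(length(missing_terms),
            " term(s) in gene2term lack term_info entries; kept with empty name")
    ti <- rbind(ti, data.frame(term_id = missing_terms, name = "",
                               namespace = NA_character_,
                               stringsAsFactors = FALSE))
  }
  structure(list(gene2term = g2t, gene_info = gi, term_info = ti),
            class = "annotation_bundle")
}

.tidy_gene_info <- function(gene_info) {
  if (is.null(gene_info)) {
    return(data.frame(gene_id = character(), name = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  if (!is.data.frame(gene_info) ||
      !all(c("gene_id", "name") %in% names(gene_info))) {
    stop("'gene_info' must have columns gene_id, name", call. = FALSE)
  }
  gi <- data.frame(
    gene_id = trimws(as.character(gene_info$gene_id)),
    name = as.character(gene_info$name),
    description = if ("description" %in% names(gene_info)) {
      d <- as.character(gene_info$description)
      ifelse(is.na(d), "", d)
    } else "",
    stringsAsFactors = FALSE)
  gi[is.na(gi$name), "name"] <- ""
  if (anyDuplicated(gi$gene_id)) {
    stop("duplicate gene_id in gene_info: ",
         paste(utils::head(unique(gi$gene_id[duplicated(gi$gene_id)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  gi
}

.tidy_term_info <- function(term_info) {
  if (is.null(term_info)) {
    return(data.frame(term_id = character(), name = character(),
                      namespace = character(), stringsAsFactors = FALSE))
  }
  if (!is.data.frame(term_info) ||
      !all(c("term_id", "name", "namespace") %in% names(term_info))) {
    stop("'term_info' must have columns term_id, name, namespace",
         call. = FALSE)
  }
  ns <- .normalise_namespace(term_info$namespace)
  bad <- which(!is.na(ns) & !(ns %in% .go_namespaces))
  if (length(bad) > 0L) {
    stop("invalid namespace(s) in term_info (expected one of ",
         paste(.go_namespaces, collapse = ", "), ") at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), ": ",
         paste(utils::head(unique(term_info$namespace[bad]), 5L),
               collapse = ", "), call. = FALSE)
  }
  ti <- data.frame(term_id = trimws(as.character(term_info$term_id)),
                   name = as.character(term_info$name),
                   namespace = ns, stringsAsFactors = FALSE)
  ti[is.na(ti$name), "name"] <- ""
  if (anyDuplicated(ti$term_id)) {
    stop("duplicate term_id in term_info", call. = FALSE)
  }
  ti
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat("annotation_bundle:", nrow(x$gene2term), "gene-term pairs,",
      length(unique(x$gene2term$gene_id)), "genes,",
      length(unique(x$gene2term$term_id)), "terms\n")
  invisible(x)
}

#' Annotated gene universe
#'
#' All gene identifiers known to the annotations; together with the genes
#' measured in a dataset this is the background over which genes are ranked.
#' @param ann an `annotation_bundle`.
#' @return Character vector of gene identifiers.
#' @export
annotation_universe <- function(ann) {
  stopifnot(inherits(ann, "annotation_bundle"))
  unique(ann$gene2term$gene_id)
}

# ---------------------------------------------------------------------------
# Table validators. Invariants asserted on every construction.

validate_gene_table <- function(gt) {
  stopifnot(is.data.frame(gt))
  need <- c("gene_id", "score", "rank", "present", "name", "description")
  if (!all(need %in% names(gt))) {
    stop("gene table misses column(s): ",
         paste(setdiff(need, names(gt)), collapse = ", "), call. = FALSE)
  }
  .check_unique_ids(gt$gene_id, "gene id")
  if (any(gt$score < 0)) stop("gene scores must be non-negative", call. = FALSE)
  n <- sum(gt$present)
  abs_rows <- !gt$present
  if (any(abs_rows)) {
    if (any(gt$score[abs_rows] != 0) || any(gt$rank[abs_rows] != n + 1)) {
      stop("absent genes must have score 0 and rank N + 1", call. = FALSE)
    }
  }
  if (n > 0L) {
    if (abs(sum(gt$rank[gt$present]) - n * (n + 1) / 2) > 1e-6) {
      stop("present-gene ranks do not sum to N(N+1)/2; tie handling broken",
           call. = FALSE)
    }
    o <- order(-gt$score[gt$present], gt$rank[gt$present])
    r <- gt$rank[gt$present][o]
    if (is.unsorted(r)) {
      stop("gene ranks are not monotone in descending score", call. = FALSE)
    }
  }
  invisible(gt)
}

validate_term_table <- function(tt, n_present, mean_agg = TRUE) {
  stopifnot(is.data.frame(tt))
  need <- c("term_id", "name", "namespace", "avg_rank", "avg_score",
            "total_genes", "data_genes", "p_value")
  if (!all(need %in% names(tt))) {
    stop("term table misses column(s): ",
         paste(setdiff(need, names(tt)), collapse = ", "), call. = FALSE)
  }
  .check_unique_ids(tt$term_id, "term id")
  if (any(tt$data_genes > tt$total_genes)) {
    stop("data_genes exceeds total_genes", call. = FALSE)
  }
  if (mean_agg && nrow(tt) > 0L) {
    lo <- (tt$total_genes + 1) / 2
    if (any(tt$avg_rank < lo - 1e-9) || any(tt$avg_rank > n_present + 1 + 1e-9)) {
      stop("avg_rank outside [(total_genes+1)/2, N+1]", call. = FALSE)
    }
    none <- tt$data_genes == 0L
    if (any(none) && (any(tt$avg_score[none] != 0) ||
                      any(abs(tt$avg_rank[none] - (n_present + 1)) > 1e-9))) {
      stop("terms without measured genes must have avg_score 0, avg_rank N+1",
           call. = FALSE)
    }
  }
  pv <- tt$p_value[!is.na(tt$p_value)]
  if (length(pv) > 0L && (any(pv < 0) || any(pv > 1))) {
    stop("p_value outside [0, 1]", call. = FALSE)
  }
  invisible(tt)
}

# ---------------------------------------------------------------------------
# Analysis result container

#' Construct an analysis result
#'
#' Couples the per-gene and per-term score tables with the full parameter
#' record (factor, sample subset, scoring method and hyperparameters,
#' aggregation, seeds, permutation settings, filters) so that any result on
#' disk is traceable and reproducible.
#'
#' @param gene_table per-gene score table (see [rank_genes()]).
#' @param term_table per-term table (see [summarise_terms()]).
#' @param parameters named list recording how the tables were produced.
#' @return An object of class `analysis_result`.
#' @export
analysis_result <- function(gene_table, term_table, parameters = list()) {
  validate_gene_table(gene_table)
  n_present <- sum(gene_table$present)
  validate_term_table(term_table, n_present,
                      mean_agg = identical(parameters$agg_fun %||% "mean",
                                           "mean"))
  stopifnot(is.list(parameters))
  # canonical order: user-facing parameters first, sizes last
  parameters$n_present <- NULL
  parameters$n_universe <- NULL
  parameters$n_present <- n_present
  parameters$n_universe <- nrow(gene_table)
  structure(list(gene_table = gene_table, term_table = term_table,
                 parameters = parameters),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  p <- x$parameters
  cat("analysis_result:", p$n_present, "measured gene features,",
      p$n_universe - p$n_present, "annotated-only,",
      nrow(x$term_table), "terms\n")
  if (!is.null(p$method)) cat("scoring:", p$method, "on factor", p$factor, "\n")
  if (!is.null(p$permutations)) {
    cat("permutation p-values: B =", p$permutations$B, "\n")
  }
  if (!is.null(p$filters)) cat("filters applied:", length(p$filters), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
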