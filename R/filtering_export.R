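# Post-hoc filtering of the term table and per-term gene detail export.
# Filtering deliberately never recomputes P-values: selection happens after
# the permutation stage, and re-running the null on a filtered universe would
# change its meaning.

#' Filter the term table
#'
#' Restricts the term table of a result to the rows passing all supplied
#' predicates: GO namespace, minimum number of annotated genes, minimum
#' number of measured annotated genes, and maximum P-value. The gene table is
#' untouched, original statistics are preserved, and a `position` column
#' (1..M within the filtered table) is added; the filtering criteria are
#' appended to the parameter record. A typical report setting keeps terms
#' with at least 15 annotated genes and empirical P <= 0.05.
#'
#' @param result an `analysis_result`.
#' @param namespace optional GO namespace (`biological_process`,
#'   `molecular_function` or `cellular_component`).
#' @param min_total_genes optional minimum count of annotated genes.
#' @param min_data_genes optional minimum count of annotated genes measured
#'   in the dataset.
#' @param max_p optional P-value ceiling; requires [pvalue_go()] first.
#' @return A new `analysis_result` with the filtered term table.
#' @export
subset_scores <- function(result, namespace = NULL, min_total_genes = NULL,
                          min_data_genes = NULL, max_p = NULL) {
  stopifnot(inherits(result, "analysis_result"))
  tt <- result$term_table
  keep <- rep(TRUE, nrow(tt))
  applied <- list()

  if (!is.null(namespace)) {
    ns <- .normalise_namespace(namespace)
    if (length(ns) != 1L || !ns %in% .go_namespaces) {
      stop("invalid namespace '", namespace, "'; expected one of ",
           paste(.go_namespaces, collapse = ", "), call. = FALSE)
    }
    keep <- keep & !is.na(tt$namespace) & tt$namespace == ns
    applied$namespace <- ns
  }
  chk <- function(x, what) {
    if (length(x) != 1L || is.na(x) || x < 0) {
      stop("'", what, "' must be a single non-negative number", call. = FALSE)
    }
    x
  }
  if (!is.null(min_total_genes)) {
    keep <- keep & tt$total_genes >= chk(min_total_genes, "min_total_genes")
    applied$min_total_genes <- as.integer(min_total_genes)
  }
  if (!is.null(min_data_genes)) {
    keep <- keep & tt$data_genes >= chk(min_data_genes, "min_data_genes")
    applied$min_data_genes <- as.integer(min_data_genes)
  }
  if (!is.null(max_p)) {
    chk(max_p, "max_p")
    if (all(is.na(tt$p_value))) {
      stop("term table has no p-values; run pvalue_go() before filtering on",
           " 'max_p'", call. = FALSE)
    }
    keep <- keep & !is.na(tt$p_value) & tt$p_value <= max_p
    applied$max_p <- as.numeric(max_p)
  }

  out <- tt[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$position <- seq_len(nrow(out))
  if (nrow(out) == 0L && length(applied) > 0L) {
    warning("no terms pass the filtering criteria")
  }
  params <- result$parameters
  params$filters <- c(params$filters, list(applied))
  analysis_result(result$gene_table, out, params)
}

#' Per-gene detail table for one term
#'
#' Exports, for a single term, one row per annotated gene — measured genes
#' first by ascending rank, then the unmeasured genes at score 0 / rank
#' N + 1 — with scores, ranks and gene annotations. This is the per-term
#' report one would include in a manuscript table.
#'
#' @param result an `analysis_result`.
#' @param ann the `annotation_bundle` used for the analysis.
#' @param term_id term identifier, e.g. `"GO:0008009"`.
#' @return data.frame with columns `gene_id`, `score`, `rank`, `present`,
#'   `name`, `description`; exactly `total_genes` rows.
#' @export
table_genes <- function(result, ann, term_id) {
  stopifnot(inherits(result, "analysis_result"),
            inherits(ann, "annotation_bundle"))
  stopifnot(length(term_id) == 1L)
  members <- ann$gene2term$gene_id[ann$gene2term$term_id == term_id]
  if (length(members) == 0L) {
    known <- unique(ann$gene2term$term_id)
    knames <- ann$term_info$name[match(known, ann$term_info$term_id)]
    knames[is.na(knames)] <- ""
    near <- unique(c(
      known[tolower(known) == tolower(term_id)],
      utils::head(agrep(term_id, known, max.distance = 0.2,
                        ignore.case = TRUE, value = TRUE), 5L),
      utils::head(known[agrepl(term_id, knames, max.distance = 0.1,
                               ignore.case = TRUE)], 5L)))
    stop("term '", term_id, "' not found in the annotations",
         if (length(near) > 0L) paste0("; nearest matches: ",
                                       paste(near, collapse = ", ")),
         call. = FALSE)
  }
  gt <- result$gene_table
  rows <- gt[gt$gene_id %in% members, , drop = FALSE]
  # annotated genes outside the result's universe (e.g. annotations grew
  # after the analysis) still count as absent: score 0, rank N + 1
  extra <- setdiff(unique(members), gt$gene_id)
  if (length(extra) > 0L) {
    n <- sum(gt$present)
    add <- data.frame(gene_id = extra, score = 0, rank = as.numeric(n + 1),
                      present = FALSE, name = "", description = "",
                      stringsAsFactors = FALSE)
    m <- match(extra, ann$gene_info$gene_id)
    hit <- !is.na(m)
    add$name[hit] <- ann$gene_info$name[m[hit]]
    add$description[hit] <- ann$gene_info$description[m[hit]]
    rows <- rbind(rows[names(add)], add)
  }
  rows <- rows[order(!rows$present, rows$rank, rows$gene_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows[, c("gene_id", "score", "rank", "present", "name", "description")]
}

#' Write the per-term gene table to a TSV file
#'
#' File is named after the term with `:` replaced by `_` (e.g.
#' `GO_0008009.tsv`) so the id stays filesystem-safe.
#'
#' @inheritParams table_genes
#' @param dir output directory (created if needed).
#' @return The written file path, invisibly.
#' @export
write_term_genes <- function(result, ann, term_id, dir) {
  tab <- table_genes(result, ann, term_id)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  path <- file.path(dir, paste0(gsub(":", "_", term_id, fixed = TRUE), ".tsv"))
  .write_tsv(tab, path)
  invisible(path)
}
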