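# On-disk formats: TSV tables (header row, UTF-8, LF) for the expression
# matrix, phenotypes, the three annotation tables and the result tables, plus
# a parameters.yaml for the traceability record. Readers fail loudly with
# file/row/column coordinates; nothing is silently coerced. Floating point is
# written with 17 significant digits so write -> read is the identity.

.read_table <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = delim, header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL, quote = "", encoding = "UTF-8")
  if (anyDuplicated(names(dt))) {
    stop(path, ": duplicate column header(s): ",
         paste(unique(names(dt)[duplicated(names(dt))]), collapse = ", "),
         call. = FALSE)
  }
  dt
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(path, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# parse character column to numeric; error names file, line and column
.as_numeric_col <- function(x, col, path) {
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y))
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-numeric value '%s' at line %d, column '%s'",
                 path, x[bad[1L]], bad[1L] + 1L, col), call. = FALSE)
  }
  y
}

#' Read an expression matrix from TSV
#'
#' Expects a header row; first column holds the gene/probeset identifier and
#' each remaining column one sample. The body must be entirely numeric and
#' finite — `NA`, `NaN`, `Inf` and blanks are rejected with the offending
#' cell's coordinates, because the model assumes a complete, pre-normalised
#' matrix.
#'
#' @param path TSV file path.
#' @param delim field delimiter (default tab).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, delim = "\t") {
  df <- .read_table(path, delim)
  if (ncol(df) < 2L) {
    stop(path, ": expected a gene id column plus at least one sample column",
         call. = FALSE)
  }
  ids <- trimws(df[[1L]])
  .check_unique_ids(ids, paste0("gene id (", path, ")"))
  body <- as.matrix(vapply(names(df)[-1L], function(cn)
    .as_numeric_col(df[[cn]], cn, path), numeric(nrow(df))))
  if (nrow(df) == 1L) body <- matrix(body, nrow = 1L,
                                     dimnames = list(NULL, names(df)[-1L]))
  if (any(!is.finite(body))) {
    bad <- which(!is.finite(body), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-finite value at line %d, column '%s'",
                 path, bad[1L] + 1L, colnames(body)[bad[2L]]), call. = FALSE)
  }
  rownames(body) <- ids
  body
}

#' Read a sample phenotype table from TSV
#'
#' First column (or a column named `sample_id`) identifies the sample; the
#' remaining columns are experimental factors kept as character strings
#' (levels are compared as trimmed strings throughout).
#'
#' @inheritParams read_expression
#' @return data.frame of factors with sample ids as rownames.
#' @export
read_phenotypes <- function(path, delim = "\t") {
  df <- .read_table(path, delim)
  idcol <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1L]
  ids <- trimws(df[[idcol]])
  .check_unique_ids(ids, paste0("sample id (", path, ")"))
  out <- df[setdiff(names(df), idcol)]
  rownames(out) <- ids
  out
}

#' Read an expression dataset (matrix + phenotypes)
#'
#' @param expr_path expression matrix TSV (see [read_expression()]).
#' @param pheno_path phenotype TSV (see [read_phenotypes()]).
#' @param delim field delimiter.
#' @return An `expression_dataset`.
#' @export
read_dataset <- function(expr_path, pheno_path, delim = "\t") {
  expression_dataset(read_expression(expr_path, delim),
                     read_phenotypes(pheno_path, delim))
}

#' Read the three annotation tables
#'
#' The canonical custom-annotation contract: `gene2term` maps genes to terms
#' (and should include genes absent from the expression data so the full
#' known universe forms the ranking background), `gene_info` carries gene
#' names and optional descriptions, `term_info` carries term names and GO
#' namespaces.
#'
#' @param gene2term_path TSV with columns `gene_id`, `term_id`.
#' @param gene_info_path optional TSV with columns `gene_id`, `name`
#'   and optionally `description`.
#' @param term_info_path optional TSV with columns `term_id`, `name`,
#'   `namespace`.
#' @param delim field delimiter.
#' @return An `annotation_bundle`.
#' @export
read_annotations <- function(gene2term_path, gene_info_path = NULL,
                             term_info_path = NULL, delim = "\t") {
  g2t <- .require_cols(.read_table(gene2term_path, delim),
                       c("gene_id", "term_id"), gene2term_path)
  gi <- if (!is.null(gene_info_path)) {
    .require_cols(.read_table(gene_info_path, delim),
                  c("gene_id", "name"), gene_info_path)
  }
  ti <- if (!is.null(term_info_path)) {
    .require_cols(.read_table(term_info_path, delim),
                  c("term_id", "name", "namespace"), term_info_path)
  }
  annotation_bundle(g2t, gi, ti)
}

#' Read annotations from a conventional directory layout
#'
#' Convenience wrapper over [read_annotations()] expecting `gene2term.tsv`,
#' and optionally `gene_info.tsv` and `term_info.tsv`, inside `dir`.
#' @param dir directory path.
#' @param delim field delimiter.
#' @return An `annotation_bundle`.
#' @export
read_annotation_dir <- function(dir, delim = "\t") {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (file.exists(fp)) fp else NULL
  }
  g2t <- p("gene2term.tsv")
  if (is.null(g2t)) stop("no gene2term.tsv under ", dir, call. = FALSE)
  read_annotations(g2t, p("gene_info.tsv"), p("term_info.tsv"), delim)
}

#' Read a bare two-column gene-to-term extract
#'
#' Convenience reader for GAF-style two-column extracts (gene id, term id)
#' without metadata tables. The canonical interface remains the three-table
#' contract of [read_annotations()].
#'
#' @inheritParams read_expression
#' @return An `annotation_bundle` with empty gene/term metadata.
#' @export
read_gene2term <- function(path, delim = "\t") {
  df <- .read_table(path, delim)
  if (ncol(df) < 2L) {
    stop(path, ": expected two columns (gene id, term id)", call. = FALSE)
  }
  names(df)[1:2] <- c("gene_id", "term_id")
  suppressMessages(annotation_bundle(df[1:2]))
}

# ---------------------------------------------------------------------------
# Result serialisation

# 17 significant digits round-trips IEEE doubles exactly
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
    else if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
    else out[[j]] <- as.character(out[[j]])
  }
  con <- file(path, open = "wb")  # LF line endings on every platform
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Write an analysis result to a directory
#'
#' Produces `gene_table.tsv`, `term_table.tsv` and `parameters.yaml` under
#' `dir`. Numeric columns are serialised with round-trip precision so that
#' [read_result()] reproduces the tables exactly; identical inputs and
#' parameters yield byte-identical files.
#'
#' @param result an `analysis_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "analysis_result"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  .write_tsv(result$gene_table, file.path(dir, "gene_table.tsv"))
  .write_tsv(result$term_table, file.path(dir, "term_table.tsv"))
  yaml::write_yaml(result$parameters, file.path(dir, "parameters.yaml"),
                   precision = 17L)
  invisible(dir)
}

#' Read an analysis result written by [write_result()]
#'
#' @param dir directory containing `gene_table.tsv`, `term_table.tsv`,
#'   `parameters.yaml`.
#' @return An `analysis_result`.
#' @export
read_result <- function(dir) {
  gt <- .read_table(file.path(dir, "gene_table.tsv"))
  tt <- .read_table(file.path(dir, "term_table.tsv"))
  pars <- yaml::read_yaml(file.path(dir, "parameters.yaml"))

  num <- function(df, col, path) {
    x <- df[[col]]
    y <- suppressWarnings(as.numeric(x))
    y[x == "NA"] <- NA_real_
    bad <- which(is.na(y) & x != "NA")
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric value '%s' at line %d, column '%s'",
                   path, x[bad[1L]], bad[1L] + 1L, col), call. = FALSE)
    }
    y
  }
  gp <- file.path(dir, "gene_table.tsv")
  gt$score <- num(gt, "score", gp)
  gt$rank <- num(gt, "rank", gp)
  gt$present <- gt$present == "TRUE"
  tp <- file.path(dir, "term_table.tsv")
  for (cc in intersect(c("avg_rank", "avg_score", "p_value", "position"),
                       names(tt))) {
    tt[[cc]] <- num(tt, cc, tp)
  }
  for (cc in intersect(c("total_genes", "data_genes", "position"), names(tt))) {
    tt[[cc]] <- as.integer(tt[[cc]])
  }
  if ("namespace" %in% names(tt)) tt$namespace[tt$namespace == "NA"] <- NA
  # restore the table attributes the in-memory constructors attach
  attr(gt, "n_present") <- sum(gt$present)
  attr(tt, "metric") <- pars$metric
  attr(tt, "agg_fun") <- pars$agg_fun
  attr(tt, "n_present") <- sum(gt$present)
  if (!is.null(pars$permutations)) {
    attr(tt, "permutations") <- pars$permutations
  }
  analysis_result(gt, tt, pars)
}
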