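# Per-gene and per-term visualisation: group-mean expression profiles with a
# dispersion band, individual sample series, and a clustered heat map of all
# measured genes annotated to one term. Plot data can be exported alongside
# the image so downstream checks operate on numbers, not pixels. None of the
# plotting functions modify the expression values.

.plot_gene_df <- function(ds, gene_id, factors) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(gene_id) != 1L || !gene_id %in% gene_ids(ds)) {
    stop("gene feature '", gene_id, "' is not present in the expression ",
         "data; if you searched by gene name, look up its feature id in ",
         "the gene table (name column) first", call. = FALSE)
  }
  df <- data.frame(sample_id = sample_ids(ds),
                   expression = ds$matrix[gene_id, ],
                   stringsAsFactors = FALSE)
  for (f in factors) df[[f]] <- get_factor(ds, f)
  rownames(df) <- NULL
  df
}

# x axis: numeric when all levels parse as numbers, otherwise a factor in
# level-sorted order
.as_x <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  if (!anyNA(num)) num else factor(v, levels = sort(unique(v)))
}

.save_plot <- function(p, out_path, width = 7, height = 5) {
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = width, height = height, dpi = 150)
  }
  invisible(p)
}

#' Group-mean expression profile of one gene
#'
#' One line per level of `group_factor`: the mean expression of the gene at
#' each level of `x_factor`, with a mean +/- standard error band (the band is
#' omitted where a group has a single sample, since the SE is undefined
#' there).
#'
#' @param ds an `expression_dataset`.
#' @param gene_id a measured gene/probeset identifier.
#' @param x_factor factor for the x axis (numeric levels, e.g. time, are
#'   plotted on a numeric axis).
#' @param group_factor factor defining the lines.
#' @param out_path optional image path (extension selects the device,
#'   e.g. `.png` or `.svg`).
#' @param data_path optional TSV path for the plotted aggregates
#'   (group, x, n, mean, se).
#' @return Invisibly, a list with the `ggplot` object (`plot`) and the
#'   aggregated data (`data`).
#' @export
expression_plot <- function(ds, gene_id, x_factor, group_factor,
                            out_path = NULL, data_path = NULL) {
  df <- .plot_gene_df(ds, gene_id, c(x_factor, group_factor))
  agg <- do.call(rbind, lapply(
    split(df, list(df[[group_factor]], df[[x_factor]]), drop = TRUE),
    function(d) data.frame(group = d[[group_factor]][1L],
                           x = d[[x_factor]][1L],
                           n = nrow(d),
                           mean = mean(d$expression),
                           se = if (nrow(d) > 1L) {
                             stats::sd(d$expression) / sqrt(nrow(d))
                           } else NA_real_,
                           stringsAsFactors = FALSE)))
  agg <- agg[order(agg$group, .as_x(agg$x)), , drop = FALSE]
  rownames(agg) <- NULL
  if (!is.null(data_path)) .write_tsv(agg, data_path)

  pd <- agg
  pd$x <- .as_x(pd$x)
  p <- ggplot2::ggplot(pd, ggplot2::aes(x = x, y = mean,
                                        colour = group,
                                        group = group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - se,
                                      ymax = mean + se,
                                      fill = group),
                         alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = x_factor, y = "expression (normalised)",
                  colour = group_factor, fill = group_factor,
                  title = gene_id,
                  subtitle = "line: group mean; band: mean ± SE") +
    ggplot2::theme_bw()
  .save_plot(p, out_path)
  invisible(list(plot = p, data = agg))
}

#' Individual expression series of one gene
#'
#' One polyline per biological series (e.g. one animal under one treatment),
#' with no aggregation; colours follow `colour_factor`. Series with a single
#' observation appear as points.
#'
#' @inheritParams expression_plot
#' @param series_factor factor (or character vector of factors, combined)
#'   identifying individual series.
#' @param colour_factor factor used for colouring; defaults to the series.
#' @return Invisibly, a list with the `ggplot` object and the plotted data.
#' @export
expression_profiles <- function(ds, gene_id, x_factor, series_factor,
                                colour_factor = NULL, out_path = NULL,
                                data_path = NULL) {
  facs <- unique(c(x_factor, series_factor, colour_factor))
  df <- .plot_gene_df(ds, gene_id, facs)
  df$series <- do.call(paste, c(df[series_factor], sep = "."))
  df$colour <- if (is.null(colour_factor)) df$series else df[[colour_factor]]
  df <- df[order(df$series, .as_x(df[[x_factor]])), , drop = FALSE]
  rownames(df) <- NULL
  out <- df[, c("sample_id", x_factor, "series", "colour", "expression")]
  if (!is.null(data_path)) .write_tsv(out, data_path)

  pd <- df
  pd$x <- .as_x(pd[[x_factor]])
  p <- ggplot2::ggplot(pd, ggplot2::aes(x = x, y = expression,
                                        group = series,
                                        colour = colour)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = x_factor, y = "expression (normalised)",
                  colour = colour_factor %||% "series", title = gene_id) +
    ggplot2::theme_bw()
  .save_plot(p, out_path)
  invisible(list(plot = p, data = out))
}

#' Clustered heat map of a term's measured genes
#'
#' Draws the expression of every measured gene annotated to `term_id` across
#' all samples, with hierarchical clustering (Euclidean distance, average
#' linkage by default) of both genes and samples; sample annotation colours
#' follow `group_factor`. Returns the dendrogram leaf orders so callers and
#' tests can assert on the clustering rather than on pixels.
#'
#' @param ds an `expression_dataset`.
#' @param result an `analysis_result` (used to confirm term membership; may
#'   be `NULL` to plot straight from the annotations).
#' @param ann an `annotation_bundle`.
#' @param term_id term to display; must have at least one measured gene.
#' @param group_factor factor used to colour sample labels.
#' @param out_path optional image path (`.png` or `.pdf`).
#' @param distance,linkage clustering options passed to [stats::dist()] and
#'   [stats::hclust()].
#' @return Invisibly, a list with `gene_order` and `sample_order` (leaf
#'   orders, left to right) and the plotted matrix.
#' @export
heatmap_go <- function(ds, result = NULL, ann, term_id, group_factor,
                       out_path = NULL, distance = "euclidean",
                       linkage = "average") {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(ann, "annotation_bundle"))
  members <- unique(ann$gene2term$gene_id[ann$gene2term$term_id == term_id])
  if (length(members) == 0L) {
    stop("term '", term_id, "' not found in the annotations", call. = FALSE)
  }
  present <- intersect(gene_ids(ds), members)
  if (length(present) == 0L) {
    stop("term '", term_id, "' has no genes measured in the dataset",
         call. = FALSE)
  }
  mat <- ds$matrix[present, , drop = FALSE]

  hc_genes <- if (nrow(mat) >= 2L) {
    stats::hclust(stats::dist(mat, method = distance), method = linkage)
  }
  hc_samples <- if (ncol(mat) >= 2L) {
    stats::hclust(stats::dist(t(mat), method = distance), method = linkage)
  }
  gene_order <- if (is.null(hc_genes)) rownames(mat) else
    rownames(mat)[hc_genes$order]
  sample_order <- if (is.null(hc_samples)) colnames(mat) else
    colnames(mat)[hc_samples$order]

  ann_col <- data.frame(row.names = sample_ids(ds))
  ann_col[[group_factor]] <- get_factor(ds, group_factor)
  ttl <- term_id
  if (nrow(ann$term_info) > 0L) {
    nm <- ann$term_info$name[match(term_id, ann$term_info$term_id)]
    if (!is.na(nm) && nzchar(nm)) ttl <- paste0(nm, " (", term_id, ")")
  }
  ph <- pheatmap::pheatmap(
    mat,
    cluster_rows = if (is.null(hc_genes)) FALSE else hc_genes,
    cluster_cols = if (is.null(hc_samples)) FALSE else hc_samples,
    annotation_col = ann_col, main = ttl,
    silent = TRUE,
    filename = if (is.null(out_path)) NA else out_path)

  invisible(list(gene_order = gene_order, sample_order = sample_order,
                 matrix = mat, heatmap = ph,
                 gene_hclust = hc_genes, sample_hclust = hc_samples))
}
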