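# Synthetic multi-group expression datasets with planted, known structure:
# a configurable number of sample groups, Gaussian background genes, planted
# terms whose discriminative member genes carry group-specific mean offsets,
# null terms drawn from the background, and annotated genes deliberately
# absent from the matrix. Every stage of the pipeline is testable against
# the recorded truth without external downloads.

#' Configure a synthetic dataset
#'
#' Defaults emulate a typical designed transcriptomics experiment at desk
#' scale: three experimental groups of five biological replicates, 1000
#' measured genes with unit-variance Gaussian noise on the (log) expression
#' scale, one planted 10-gene term whose genes separate the groups by
#' 2 standard deviations per group step, 200 null 10-gene terms, and 100
#' annotated genes absent from the matrix.
#'
#' @param n_groups number of sample groups.
#' @param samples_per_group biological replicates per group.
#' @param n_genes_present measured genes.
#' @param n_genes_absent annotated genes absent from the matrix (they join
#'   dedicated background terms in the annotations only).
#' @param planted_terms list of planted terms; each element a list with
#'   `term_id`, `size` (annotated genes), `n_discriminative` (how many carry
#'   signal) and `delta` (group-mean spacing, in units of `noise_sd`).
#' @param noise_sd standard deviation of the Gaussian background.
#' @param n_null_terms number of terms drawn from non-discriminative genes.
#' @param term_size_null genes per null term (and per absent-gene term).
#' @param model `"gaussian"` (default; normalised log-scale intensities) or
#'   `"nb"` (negative-binomial counts converted to log2 CPM, an RNA-seq-like
#'   fixture).
#' @param nb_dispersion negative-binomial dispersion for `model = "nb"`.
#' @param seed RNG seed; fixed seed gives bitwise-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_groups = 3L, samples_per_group = 5L,
                       n_genes_present = 1000L, n_genes_absent = 100L,
                       planted_terms = list(list(term_id = "GO:1000001",
                                                 size = 10L,
                                                 n_discriminative = 10L,
                                                 delta = 2)),
                       noise_sd = 1, n_null_terms = 200L,
                       term_size_null = 10L,
                       model = c("gaussian", "nb"), nb_dispersion = 0.1,
                       seed = 0L) {
  model <- match.arg(model)
  cfg <- list(n_groups = as.integer(n_groups),
              samples_per_group = as.integer(samples_per_group),
              n_genes_present = as.integer(n_genes_present),
              n_genes_absent = as.integer(n_genes_absent),
              planted_terms = planted_terms,
              noise_sd = as.numeric(noise_sd),
              n_null_terms = as.integer(n_null_terms),
              term_size_null = as.integer(term_size_null),
              model = model, nb_dispersion = as.numeric(nb_dispersion),
              seed = as.integer(seed))
  if (cfg$n_groups < 2L || cfg$samples_per_group < 1L ||
      cfg$n_genes_present < 1L || cfg$n_genes_absent < 0L ||
      cfg$noise_sd <= 0 || cfg$n_null_terms < 0L || cfg$term_size_null < 1L) {
    stop("invalid simulation configuration", call. = FALSE)
  }
  for (pt in cfg$planted_terms) {
    if (!all(c("term_id", "size", "n_discriminative", "delta") %in% names(pt))) {
      stop("each planted term needs term_id, size, n_discriminative, delta",
           call. = FALSE)
    }
    if (pt$n_discriminative > pt$size || pt$size < 1L || pt$delta < 0) {
      stop("invalid planted term '", pt$term_id, "'", call. = FALSE)
    }
  }
  n_disc <- sum(vapply(cfg$planted_terms,
                       function(p) as.integer(p$n_discriminative), integer(1)))
  if (n_disc > cfg$n_genes_present) {
    stop("more discriminative genes (", n_disc,
         ") than measured genes (", cfg$n_genes_present, ")", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.sim_namespaces <- function(n) {
  rep(c("molecular_function", "biological_process", "cellular_component"),
      length.out = max(n, 0L))
}

#' Generate a synthetic dataset, annotations and ground truth
#'
#' Background genes are i.i.d. Normal(0, `noise_sd`) across all samples.
#' Each planted term's discriminative genes additionally receive a
#' group-specific mean offset of `(g - 1) * delta * noise_sd` for group g,
#' so consecutive group means are `delta` standard deviations apart. Null
#' terms sample their members uniformly (without replacement) from the
#' non-discriminative measured genes; absent annotated genes are grouped
#' into their own background terms and appear only in the gene-to-term
#' mapping. With a fixed seed the output is bitwise reproducible.
#'
#' @param config a [sim_config()].
#' @return A list with elements `dataset` (`expression_dataset`),
#'   `annotations` (`annotation_bundle`) and `truth` (group assignment,
#'   discriminative gene ids per planted term, null/absent term ids, and the
#'   config).
#' @export
generate_synthetic <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_groups * cfg$samples_per_group
  group <- rep(paste0("g", seq_len(cfg$n_groups)),
               each = cfg$samples_per_group)
  sample_id <- sprintf("s%03d", seq_len(n))
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes_present))
  absent <- if (cfg$n_genes_absent > 0L) {
    sprintf("absent%04d", seq_len(cfg$n_genes_absent))
  } else character()

  with_seed(cfg$seed, {
    mat <- matrix(stats::rnorm(cfg$n_genes_present * n, 0, cfg$noise_sd),
                  nrow = cfg$n_genes_present,
                  dimnames = list(genes, sample_id))

    # allocate discriminative genes sequentially across planted terms
    planted <- list()
    g2t <- list()
    cursor <- 0L
    for (pt in cfg$planted_terms) {
      nd <- as.integer(pt$n_discriminative)
      disc <- genes[cursor + seq_len(nd)]
      cursor <- cursor + nd
      offs <- (match(group, unique(group)) - 1) * pt$delta * cfg$noise_sd
      mat[disc, ] <- mat[disc, , drop = FALSE] +
        matrix(offs, nrow = nd, ncol = n, byrow = TRUE)
      extra <- if (pt$size > nd) {
        sample(setdiff(genes, genes[seq_len(cursor)]), pt$size - nd)
      } else character()
      planted[[pt$term_id]] <- disc
      g2t[[pt$term_id]] <- c(disc, extra)
    }
    disc_all <- genes[seq_len(cursor)]

    null_ids <- if (cfg$n_null_terms > 0L) {
      sprintf("GO:2%06d", seq_len(cfg$n_null_terms))
    } else character()
    pool <- setdiff(genes, disc_all)
    if (cfg$n_null_terms > 0L && cfg$term_size_null > length(pool)) {
      stop("null term size exceeds the non-discriminative gene pool",
           call. = FALSE)
    }
    for (tid in null_ids) g2t[[tid]] <- sample(pool, cfg$term_size_null)

    absent_ids <- character()
    if (length(absent) > 0L) {
      chunks <- split(absent, ceiling(seq_along(absent) / cfg$term_size_null))
      absent_ids <- sprintf("GO:3%06d", seq_along(chunks))
      for (i in seq_along(chunks)) g2t[[absent_ids[i]]] <- chunks[[i]]
    }

    gene2term <- data.frame(
      gene_id = unlist(g2t, use.names = FALSE),
      term_id = rep(names(g2t), lengths(g2t)),
      stringsAsFactors = FALSE)

    if (cfg$model == "nb") {
      # NB counts around gene-specific baselines; group offsets act on the
      # log2 scale; expression reported as log2 CPM
      base <- 2 ^ stats::runif(cfg$n_genes_present, 3, 10)
      mu <- base * 2 ^ mat  # mean structure carried on the log2 scale
      counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                      size = 1 / cfg$nb_dispersion),
                       nrow = nrow(mat), dimnames = dimnames(mat))
      cpm <- t(t(counts + 0.5) / (colSums(counts) + 1)) * 1e6
      mat <- log2(cpm)
    }

    pheno <- data.frame(row.names = sample_id, group = group,
                        replicate = rep(seq_len(cfg$samples_per_group),
                                        times = cfg$n_groups),
                        stringsAsFactors = FALSE)

    all_terms <- names(g2t)
    term_info <- data.frame(
      term_id = all_terms,
      name = ifelse(all_terms %in% names(planted),
                    paste("planted signal", all_terms),
                    ifelse(all_terms %in% absent_ids,
                           paste("unmeasured background", all_terms),
                           paste("null background", all_terms))),
      namespace = .sim_namespaces(length(all_terms)),
      stringsAsFactors = FALSE)
    all_genes <- c(genes, absent)
    gene_info <- data.frame(
      gene_id = all_genes,
      name = toupper(all_genes),
      description = ifelse(all_genes %in% disc_all,
                           "synthetic discriminative gene",
                           ifelse(all_genes %in% absent,
                                  "synthetic annotated-only gene",
                                  "synthetic background gene")),
      stringsAsFactors = FALSE)

    list(dataset = expression_dataset(mat, pheno),
         annotations = annotation_bundle(gene2term, gene_info, term_info),
         truth = list(groups = stats::setNames(group, sample_id),
                      planted = planted,
                      planted_terms = names(planted),
                      null_terms = null_ids,
                      absent_terms = absent_ids,
                      config = cfg))
  })
}

#' Write a synthetic dataset to the on-disk TSV contract
#'
#' Emits exactly the files the readers consume: `expression.tsv`,
#' `phenotypes.tsv`, `gene2term.tsv`, `gene_info.tsv`, `term_info.tsv`, plus
#' a `parameters.yaml` recording the generator configuration.
#'
#' @param sim output of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(is.list(sim), inherits(sim$dataset, "expression_dataset"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  ds <- sim$dataset
  expr <- data.frame(gene_id = gene_ids(ds), ds$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(expr, file.path(dir, "expression.tsv"))
  ph <- data.frame(sample_id = sample_ids(ds), ds$sample_factors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(ph, file.path(dir, "phenotypes.tsv"))
  ann <- sim$annotations
  .write_tsv(ann$gene2term, file.path(dir, "gene2term.tsv"))
  .write_tsv(ann$gene_info, file.path(dir, "gene_info.tsv"))
  .write_tsv(ann$term_info, file.path(dir, "term_info.tsv"))
  cfg <- sim$truth$config
  attr(cfg, "class") <- NULL
  yaml::write_yaml(list(generator = cfg), file.path(dir, "parameters.yaml"),
                   precision = 17L)
  invisible(dir)
}
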