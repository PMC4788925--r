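# Fixture builders shared across the suite. Everything is generated in code;
# no files ship with the tests.

# dataset from an explicit genes x samples matrix and a group vector
make_ds <- function(mat, groups, extra = NULL) {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  }
  ph <- data.frame(row.names = colnames(mat), group = groups,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) for (nm in names(extra)) ph[[nm]] <- extra[[nm]]
  expression_dataset(mat, ph)
}

# dataset of pure noise plus one gene that separates two groups completely
make_separating_ds <- function(n_noise = 50, n_per_group = 10, gap = 10,
                               sd = 0.1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  mat <- matrix(rnorm(n_noise * n), nrow = n_noise)
  sep <- c(rnorm(n_per_group, 0, sd), rnorm(n_per_group, gap, sd))
  mat <- rbind(sep = sep, mat)
  rownames(mat) <- c("sep", sprintf("noise%02d", seq_len(n_noise)))
  make_ds(mat, rep(c("a", "b"), each = n_per_group))
}

# annotation bundle from a named list term_id -> gene ids
make_ann <- function(terms, gene_info = NULL, namespaces = NULL) {
  g2t <- data.frame(gene_id = unlist(terms, use.names = FALSE),
                    term_id = rep(names(terms), lengths(terms)),
                    stringsAsFactors = FALSE)
  ti <- data.frame(term_id = names(terms),
                   name = paste("term", names(terms)),
                   namespace = if (is.null(namespaces)) {
                     rep(c("biological_process", "molecular_function",
                           "cellular_component"),
                         length.out = length(terms))
                   } else namespaces,
                   stringsAsFactors = FALSE)
  annotation_bundle(g2t, gene_info, ti)
}

# gene table with prescribed distinct scores (named vector), optional universe
make_gene_table <- function(scores, ann = NULL, universe = NULL) {
  rank_genes(scores, ann = ann, universe = universe)
}

# small planted-signal simulation used by several files
small_sim <- function(seed = 1, n_present = 120, n_absent = 12,
                      n_null = 10, delta = 2) {
  generate_synthetic(sim_config(
    n_genes_present = n_present, n_genes_absent = n_absent,
    planted_terms = list(list(term_id = "GO:1000001", size = 10L,
                              n_discriminative = 10L, delta = delta)),
    n_null_terms = n_null, seed = seed))
}
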