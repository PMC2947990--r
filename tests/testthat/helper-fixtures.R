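# Shared builders for small in-code fixtures.

# expression matrix with 4 genotypes x n_rep replicates from a genes x 12
# value matrix (or a function of genotype means)
toy_em <- function(values, n_rep = 3, genotypes = c("DxD", "MxM", "DxM", "MxD")) {
  meta <- data.frame(
    sample_id = paste0(rep(genotypes, each = n_rep), "_", seq_len(n_rep)),
    genotype = rep(genotypes, each = n_rep),
    replicate = rep(seq_len(n_rep), length(genotypes)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  colnames(values) <- meta$sample_id
  expression_matrix(values, meta, log2_scale = TRUE)
}

# matrix whose genotype means are given and replicates add small fixed jitter
em_from_genotype_means <- function(means, jitter = c(-0.01, 0, 0.01)) {
  v <- do.call(cbind, lapply(seq_len(ncol(means)), function(j)
    outer(means[, j], jitter, `+`)))
  v <- matrix(v, nrow = nrow(means))
  rownames(v) <- rownames(means)
  toy_em(v, n_rep = length(jitter))
}

# minimal annotation table
toy_annotations <- function(gene_id, chromosome, cell_class = "unassigned",
                            x_class = NULL) {
  if (is.null(x_class)) x_class <- ifelse(chromosome == "X", "A", "none")
  data.frame(gene_id = gene_id, chromosome = chromosome,
             position_mb = seq_along(gene_id), cell_class = cell_class,
             x_class = x_class, stringsAsFactors = FALSE)
}

# small fast simulation config
small_cfg <- function(n_genes = 200, seed = 1, ...) {
  sim_config(n_genes = n_genes, seed = seed, n_probes_per_gene = 8L, ...)
}

# cell-fraction matrix with every genotype at the fertile composition
equal_fractions <- function() {
  cf <- default_cell_fractions()
  cf["MxD", ] <- cf["DxD", ]
  cf
}
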