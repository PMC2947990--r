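#' Generate per-gene annotations for a simulated expression universe
#'
#' Draws chromosome, genomic position, spermatogenic cell class and (for
#' X-linked genes) the X-expression timing class for each gene. X-linked genes
#' are never meiotic: the X weight vector in the configuration carries zero
#' meiotic mass, mirroring meiotic sex chromosome inactivation.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `gene_id`, `chromosome`, `position_mb`,
#'   `cell_class` (one of somatic/mitotic/meiotic/postmeiotic/unassigned) and
#'   `x_class` (Namekawa-style A/B/C/D/E for X-linked genes, "none" otherwise).
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(stage_seed(config, "annotations"))
  n <- config$n_genes
  chrom_mb <- c(195, 182, 160, 157, 152, 150, 145, 130, 124, 131, 122, 120,
                120, 125, 104, 98, 95, 91, 61, 171, 91)
  names(chrom_mb) <- MOUSE_CHROMOSOMES

  chromosome <- sample(names(config$chrom_weights), n, replace = TRUE,
                       prob = config$chrom_weights)
  position_mb <- stats::runif(n, 0, chrom_mb[chromosome])

  on_x <- chromosome == "X"
  cell_class <- character(n)
  assigned <- stats::runif(n) >= config$unassigned_prob
  cell_class[!assigned] <- "unassigned"
  if (any(assigned & on_x))
    cell_class[assigned & on_x] <- sample(
      CELL_CLASSES, sum(assigned & on_x), replace = TRUE,
      prob = config$cellclass_weights_X)
  if (any(assigned & !on_x))
    cell_class[assigned & !on_x] <- sample(
      CELL_CLASSES, sum(assigned & !on_x), replace = TRUE,
      prob = config$cellclass_weights_autosome)

  # X spermatogenic timing classes: A mitotic-only, B mitotic+postmeiotic,
  # C postmeiotic-only, D variable, E repressed; drawn independently of
  # cell_class, roughly proportional to reported class sizes
  x_class <- rep("none", n)
  if (any(on_x))
    x_class[on_x] <- sample(c("A", "B", "C", "D", "E"), sum(on_x),
                            replace = TRUE,
                            prob = c(0.30, 0.25, 0.17, 0.05, 0.23))

  data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chromosome = chromosome,
    position_mb = position_mb,
    cell_class = cell_class,
    x_class = x_class,
    stringsAsFactors = FALSE
  )
}

# cell-activity profile: a gene is maximally active (1) in its own class and
# leaks a small constant into the others; unassigned genes are flat
cell_activity <- function(cell_class, leakage) {
  a <- matrix(leakage, length(cell_class), length(CELL_CLASSES),
              dimnames = list(NULL, CELL_CLASSES))
  for (cc in CELL_CLASSES) a[cell_class == cc, cc] <- 1
  a[cell_class == "unassigned", ] <- 0.25
  a
}

simulated_sample_meta <- function(config) {
  data.frame(
    sample_id = paste0(rep(GENOTYPES, each = config$n_replicates), "_",
                       rep(seq_len(config$n_replicates), length(GENOTYPES))),
    genotype = rep(GENOTYPES, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(GENOTYPES)),
    stringsAsFactors = FALSE
  )
}

# fraction of M. musculus genome per genotype: species effects act additively,
# so hybrids sit halfway between the parental lines
species_dose <- c(DxD = 0, DxM = 0.5, MxD = 0.5, MxM = 1)

draw_effects <- function(config, annotations, null_mode) {
  set.seed(stage_seed(config, "effects"))
  n <- nrow(annotations)
  p_div <- pmin(1, config$divergence_prob *
                  ifelse(annotations$cell_class == "meiotic",
                         config$divergence_meiotic_multiplier, 1))
  divergent <- stats::runif(n) < p_div
  delta <- ifelse(divergent,
                  config$divergence_effect_log2 *
                    sample(c(-1, 1), n, replace = TRUE), 0)
  base_log2 <- stats::rnorm(n, config$base_log2_mean, config$base_log2_sd)
  if (null_mode) {
    divergent <- rep(FALSE, n)
    delta <- rep(0, n)
  }
  data.frame(
    gene_id = annotations$gene_id,
    base_log2 = base_log2,
    divergent = divergent,
    delta_log2 = delta,
    x_over = !null_mode & annotations$chromosome == "X",
    stringsAsFactors = FALSE
  )
}

# noiseless log2 tissue signal per gene x genotype:
#   log2( base * sum_c f_c(t) a_gc ) + delta_g * dose(t) + beta * [X & MxD]
tissue_signal_log2 <- function(config, annotations, effects, null_mode) {
  frac <- config$cell_fractions
  if (null_mode) frac[] <- rep(frac["DxD", ], each = nrow(frac))
  act <- cell_activity(annotations$cell_class, config$cellclass_leakage)
  mix <- act %*% t(frac[GENOTYPES, , drop = FALSE])  # genes x genotypes
  sig <- effects$base_log2 + log2(mix)
  sig <- sig + outer(effects$delta_log2, species_dose[GENOTYPES])
  beta <- if (null_mode) 0 else config$x_overexpression_log2
  sig[, STERILE_GENOTYPE] <- sig[, STERILE_GENOTYPE] +
    beta * (annotations$chromosome == "X")
  sig
}

#' Simulate an analysis-ready log2 expression matrix
#'
#' Skips the probe layer and returns the log2 tissue signal plus replicate
#' noise directly, which is what the contrast, profile and enrichment stages
#' consume. Useful for fast calibration and recovery experiments; the full
#' probe-level path is [generate_dataset()].
#'
#' @param config A [sim_config()].
#' @param annotations Output of [generate_annotations()] for the same config.
#' @param null_mode If TRUE, all species and sterility effects are zeroed and
#'   all genotypes share the fertile cell fractions, so every between-genotype
#'   difference is pure noise.
#' @return list with `matrix` (an [expression_matrix()] on the log2 scale) and
#'   `truth` (per-gene implanted effects).
#' @export
simulate_expression <- function(config, annotations, null_mode = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  effects <- draw_effects(config, annotations, null_mode)
  sig <- tissue_signal_log2(config, annotations, effects, null_mode)
  meta <- simulated_sample_meta(config)
  set.seed(stage_seed(config, "expression"))
  vals <- sig[, meta$genotype, drop = FALSE] +
    stats::rnorm(length(sig[, meta$genotype]), 0, config$noise_sd_log2)
  dimnames(vals) <- list(annotations$gene_id, meta$sample_id)
  list(matrix = expression_matrix(vals, meta, log2_scale = TRUE),
       truth = effects)
}

#' Generate a probe-level PM/MM dataset
#'
#' Implements the full generative model: the whole-tissue signal of each gene in
#' each sample is the cell-fraction-weighted mixture of its per-cell-class
#' activities, times species-divergence and sterile-X effects, times log-normal
#' replicate noise. Each gene is measured by `n_probes_per_gene` probe pairs:
#' PM = signal x probe affinity + optical background, and the mismatch probe
#' picks up a configured fraction of the PM signal plus its own background.
#'
#' @inheritParams simulate_expression
#' @return list with `probes` (long data.frame: gene_id, probe_index,
#'   sample_id, pm, mm), `sample_meta`, and `truth` (implanted per-gene
#'   effects, for recovery tests).
#' @export
generate_dataset <- function(config, annotations, null_mode = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(annotations) != config$n_genes)
    stop("annotations were not generated from this config", call. = FALSE)
  sim <- simulate_expression(config, annotations, null_mode)
  meta <- sim$matrix$sample_meta
  signal <- 2^sim$matrix$values  # linear, noise included

  set.seed(stage_seed(config, "probes"))
  n_g <- nrow(annotations); n_p <- config$n_probes_per_gene
  n_s <- nrow(meta)
  affinity <- stats::rlnorm(n_g * n_p, 0, config$probe_affinity_sdlog)

  long_n <- n_g * n_p * n_s
  gene_i <- rep(seq_len(n_g), times = n_p * n_s)
  probe_i <- rep(rep(seq_len(n_p), each = n_g), times = n_s)
  sample_i <- rep(seq_len(n_s), each = n_g * n_p)
  aff <- affinity[(probe_i - 1L) * n_g + gene_i]
  bg_pm <- stats::rlnorm(long_n, config$background_meanlog, config$background_sdlog)
  bg_mm <- stats::rlnorm(long_n, config$background_meanlog, config$background_sdlog)
  pm <- signal[cbind(gene_i, sample_i)] * aff + bg_pm
  mm <- config$mm_cross_fraction * pm + bg_mm

  probes <- data.frame(
    gene_id = annotations$gene_id[gene_i],
    probe_index = probe_i,
    sample_id = meta$sample_id[sample_i],
    pm = pm,
    mm = mm,
    stringsAsFactors = FALSE
  )
  list(probes = probes, sample_meta = meta, truth = sim$truth)
}

#' Simulate a dN/dS table matching an annotation universe
#'
#' Draws log-normal dN/dS ratios with a higher typical value on the X than on
#' the autosomes (defaults anchored at medians 0.160 and 0.112), emulating the
#' faster protein evolution of X-linked testis-expressed genes. dS is drawn
#' log-normally and dN derived as dnds * ds.
#'
#' @param annotations Gene annotation table.
#' @param seed Integer seed.
#' @param x_median,auto_median Median dN/dS per stratum.
#' @param sdlog Log-scale spread of dN/dS.
#' @return data.frame: gene_id, dn, ds, dnds.
#' @export
generate_dnds <- function(annotations, seed = 1L,
                          x_median = 0.160, auto_median = 0.112,
                          sdlog = 0.9) {
  set.seed(seed)
  on_x <- annotations$chromosome == "X"
  meanlog <- ifelse(on_x, log(x_median), log(auto_median))
  dnds <- stats::rlnorm(nrow(annotations), meanlog, sdlog)
  ds <- stats::rlnorm(nrow(annotations), log(0.18), 0.4)
  data.frame(gene_id = annotations$gene_id,
             dn = dnds * ds, ds = ds, dnds = dnds,
             stringsAsFactors = FALSE)
}
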