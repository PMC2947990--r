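#' Default chromosome sampling weights for the simulated gene universe
#'
#' Autosome weights are proportional to physical chromosome length, rescaled so
#' that the X chromosome carries the fraction of the expressed universe seen on
#' the array (212 of 6,998 detected genes, about 3\%) and the Y is nearly absent
#' (a single detected gene). The X fraction is deliberately much lower than the
#' X's share of the genome: meiotic sex chromosome inactivation and postmeiotic
#' repression deplete testis-expressed genes from the X.
#'
#' @return Named numeric vector over chromosomes 1-19, X, Y summing to 1.
#' @export
default_chrom_weights <- function() {
  auto_mb <- c(195, 182, 160, 157, 152, 150, 145, 130, 124, 131,
               122, 120, 120, 125, 104, 98, 95, 91, 61)
  x_w <- 212 / 6998
  y_w <- 1 / 6998
  w <- c(auto_mb / sum(auto_mb) * (1 - x_w - y_w), x_w, y_w)
  stats::setNames(w, MOUSE_CHROMOSOMES)
}

#' Default tissue cell-type fractions per genotype
#'
#' Fertile testis is dominated by postmeiotic round spermatids (~85\% of cells);
#' the sterile MxD hybrid shows a dramatic loss of postmeiotic cells, modelled
#' here as a drop to 55\% with the remaining classes rescaled proportionally.
#' The fertile split of the non-postmeiotic 15\% across somatic, mitotic and
#' meiotic cells is a documented package default, not a measured quantity.
#'
#' @return 4x4 numeric matrix, genotypes in rows, cell classes in columns,
#'   each row summing to 1.
#' @export
default_cell_fractions <- function() {
  fertile <- c(somatic = 0.02, mitotic = 0.08, meiotic = 0.05, postmeiotic = 0.85)
  sterile_post <- 0.55
  sterile <- c(fertile[1:3] * (1 - sterile_post) / sum(fertile[1:3]),
               postmeiotic = sterile_post)
  m <- rbind(DxD = fertile, MxM = fertile, DxM = fertile, MxD = sterile)
  colnames(m) <- CELL_CLASSES
  m
}

#' Simulation configuration for the synthetic testis-expression generator
#'
#' Bundles and validates every parameter of the generative model: the gene
#' universe (chromosome and cell-class composition), the cell-type mixture
#' fractions per genotype, species-divergence effects, the X over-expression
#' effect restricted to the sterile genotype, residual noise, and the
#' probe-level perfect-match/mismatch (PM/MM) layer.
#'
#' Cell-class weights default to the composition of the expressed universe
#' behind the enrichment expectations shipped in `inst/extdata`
#' (autosomes 420/1077/1144/758 somatic/mitotic/meiotic/postmeiotic of 3399;
#' X 31/94/0/48 of 173). The X weight vector has meiotic weight exactly 0
#' (MSCI selects against meiotic expression on the X) and an elevated mitotic
#' share.
#'
#' @param n_genes Number of genes to simulate.
#' @param chrom_weights Named probability vector over chromosomes.
#' @param cellclass_weights_autosome Probabilities over the four cell classes
#'   for autosomal genes that receive a class.
#' @param cellclass_weights_X Same for X-linked genes; meiotic entry must be 0.
#' @param unassigned_prob Probability a gene has no cell-class association
#'   (mirrors the roughly half of expressed genes without one).
#' @param cell_fractions Genotype x cell-class matrix of tissue fractions,
#'   rows summing to 1.
#' @param divergence_prob Probability an autosomal-or-X gene carries a
#'   species-divergence expression effect.
#' @param divergence_effect_log2 Absolute log2 effect size of a species effect
#'   (sign drawn at random per gene).
#' @param divergence_meiotic_multiplier Relative enrichment of species effects
#'   among meiotic genes (probability multiplied, capped at 1).
#' @param x_overexpression_log2 log2 effect added to X-linked genes in the
#'   sterile MxD genotype only. Default log2(1.17), i.e. a 17\% increase.
#' @param noise_sd_log2 Residual between-replicate standard deviation on the
#'   log2 scale.
#' @param cellclass_leakage Cell-activity of a gene in classes other than its
#'   own (its own class has activity 1). Cell-class labels mean "greatest
#'   induction", not exclusive expression; leakage models that.
#' @param n_probes_per_gene Probes per gene on the simulated array.
#' @param mm_cross_fraction Fraction of the PM signal bleeding into the MM probe.
#' @param probe_affinity_sdlog Log-normal sdlog of fixed per-probe affinities.
#' @param background_meanlog,background_sdlog Log-normal parameters of additive
#'   optical background per probe cell.
#' @param base_log2_mean,base_log2_sd Per-gene baseline abundance distribution
#'   (log2 scale).
#' @param n_replicates Males per genotype.
#' @param seed Integer root seed; all stage streams derive from it.
#'
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 7000,
                       chrom_weights = default_chrom_weights(),
                       cellclass_weights_autosome =
                         c(somatic = 420, mitotic = 1077, meiotic = 1144,
                           postmeiotic = 758) / 3399,
                       cellclass_weights_X =
                         c(somatic = 31, mitotic = 94, meiotic = 0,
                           postmeiotic = 48) / 173,
                       unassigned_prob = 0.49,
                       cell_fractions = default_cell_fractions(),
                       divergence_prob = 0.25,
                       divergence_effect_log2 = 0.5,
                       divergence_meiotic_multiplier = 1.5,
                       x_overexpression_log2 = log2(1.17),
                       noise_sd_log2 = 0.15,
                       cellclass_leakage = 0.05,
                       n_probes_per_gene = 17L,
                       mm_cross_fraction = 0.35,
                       probe_affinity_sdlog = 0.3,
                       background_meanlog = log(50),
                       background_sdlog = 0.3,
                       base_log2_mean = 9,
                       base_log2_sd = 1.5,
                       n_replicates = 3L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    chrom_weights = chrom_weights,
    cellclass_weights_autosome = cellclass_weights_autosome,
    cellclass_weights_X = cellclass_weights_X,
    unassigned_prob = unassigned_prob,
    cell_fractions = cell_fractions,
    divergence_prob = divergence_prob,
    divergence_effect_log2 = divergence_effect_log2,
    divergence_meiotic_multiplier = divergence_meiotic_multiplier,
    x_overexpression_log2 = x_overexpression_log2,
    noise_sd_log2 = noise_sd_log2,
    cellclass_leakage = cellclass_leakage,
    n_probes_per_gene = as.integer(n_probes_per_gene),
    mm_cross_fraction = mm_cross_fraction,
    probe_affinity_sdlog = probe_affinity_sdlog,
    background_meanlog = background_meanlog,
    background_sdlog = background_sdlog,
    base_log2_mean = base_log2_mean,
    base_log2_sd = base_log2_sd,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  chk_prob <- function(v, name) {
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
      stop_cfg(sprintf("'%s' must be a probability vector summing to 1", name))
  }
  if (cfg$n_genes < 1) stop_cfg("n_genes must be positive")
  chk_prob(cfg$chrom_weights, "chrom_weights")
  chk_prob(cfg$cellclass_weights_autosome, "cellclass_weights_autosome")
  chk_prob(cfg$cellclass_weights_X, "cellclass_weights_X")
  if (cfg$cellclass_weights_X[["meiotic"]] != 0)
    stop_cfg("meiotic weight on the X must be exactly 0 (MSCI)")
  if (cfg$unassigned_prob < 0 || cfg$unassigned_prob >= 1)
    stop_cfg("unassigned_prob must be in [0, 1)")
  cf <- cfg$cell_fractions
  if (!is.matrix(cf) || !identical(colnames(cf), CELL_CLASSES))
    stop_cfg("cell_fractions must be a matrix with cell-class columns")
  if (!all(rownames(cf) %in% GENOTYPES) || !all(GENOTYPES %in% rownames(cf)))
    stop_cfg(paste("cell_fractions rows must be the genotypes",
                   paste(GENOTYPES, collapse = ", ")))
  if (any(cf < 0) || any(abs(rowSums(cf) - 1) > 1e-9))
    stop_cfg("each cell_fractions row must sum to 1")
  if (cfg$n_probes_per_gene < 1) stop_cfg("n_probes_per_gene must be >= 1")
  if (cfg$mm_cross_fraction < 0 || cfg$mm_cross_fraction > 1)
    stop_cfg("mm_cross_fraction must be in [0, 1]")
  if (cfg$noise_sd_log2 < 0) stop_cfg("noise_sd_log2 must be >= 0")
  if (cfg$n_replicates < 2) stop_cfg("n_replicates must be >= 2")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic testis-expression configuration\n")
  cat(sprintf("  %d genes, %d genotypes x %d replicates, seed %d\n",
              x$n_genes, nrow(x$cell_fractions), x$n_replicates, x$seed))
  cat(sprintf("  X weight %.3f | divergence prob %.2f (x%.1f meiotic), effect %.2f log2\n",
              x$chrom_weights[["X"]], x$divergence_prob,
              x$divergence_meiotic_multiplier, x$divergence_effect_log2))
  cat(sprintf("  X over-expression in %s: %.4f log2 | noise sd %.2f log2\n",
              STERILE_GENOTYPE, x$x_overexpression_log2, x$noise_sd_log2))
  invisible(x)
}

# one root seed; fixed per-stage offsets keep the streams of different stages
# independent of each other (kept below 2^31)
stage_seed <- function(cfg, stage) {
  offs <- c(annotations = 11L, effects = 23L, expression = 37L,
            probes = 53L, dnds = 71L)
  (cfg$seed %% 100000L) * 10007L + offs[[stage]]
}
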