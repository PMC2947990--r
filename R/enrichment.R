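#' Chromosome-wise hypergeometric enrichment of a gene set
#'
#' For each chromosome with at least one universe gene, tests whether the set
#' contains more (or fewer) genes from that chromosome than expected under
#' random draws from the universe. The p-value is the two-sided hypergeometric
#' (doubled smaller tail, capped at 1), Bonferroni-corrected by the number of
#' chromosomes tested. Expected counts are n * K / N with n the set size, K the
#' universe genes on the chromosome and N the universe size.
#'
#' @param gene_set Character vector of gene ids (subset of `universe`).
#' @param universe Character vector of gene ids defining the sampling frame
#'   (here, the detected-expressed genes).
#' @param annotations Annotation table with gene_id and chromosome.
#' @return data.frame (one row per chromosome): chromosome, n_universe,
#'   observed, expected, p_raw, p_corrected; attribute `family_size`.
#' @export
chromosome_enrichment <- function(gene_set, universe, annotations) {
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe", call. = FALSE)
  ann <- annotations[match(universe, annotations$gene_id), ]
  if (anyNA(ann$chromosome))
    stop("every universe gene must be annotated", call. = FALSE)
  N <- length(universe); n <- length(gene_set)
  in_set <- universe %in% gene_set

  chroms <- MOUSE_CHROMOSOMES[MOUSE_CHROMOSOMES %in% ann$chromosome]
  skipped <- setdiff(unique(ann$chromosome), chroms)
  fam <- length(chroms)
  rows <- lapply(chroms, function(ch) {
    K <- sum(ann$chromosome == ch)
    k <- sum(in_set & ann$chromosome == ch)
    lower <- stats::phyper(k, K, N - K, n)
    upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    data.frame(chromosome = ch, n_universe = K, observed = k,
               expected = n * K / N, p_raw = p,
               p_corrected = min(1, p * fam), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "family_size") <- fam
  out
}

#' Stratified expected cell-class counts for a gene panel
#'
#' Expectations are generated independently for the X chromosome and the
#' autosomes from the observed cell-class distribution of all expressed genes
#' in the stratum: expected_c = panel_total * universe_c / sum(universe_c).
#'
#' @param universe_counts Named nonnegative counts of expressed genes per cell
#'   class within the stratum (meiotic must be 0 on the X).
#' @param panel_total Number of panel genes in the stratum.
#' @return Named numeric vector of expected counts.
#' @export
celltype_expected <- function(universe_counts, panel_total) {
  if (any(universe_counts < 0)) stop("negative universe counts", call. = FALSE)
  tot <- sum(universe_counts)
  if (tot == 0) stop("stratum universe is empty", call. = FALSE)
  panel_total * universe_counts / tot
}

#' Bonferroni-corrected exact binomial test for one cell-class cell
#'
#' Exact binomial test of the observed panel count against the stratified
#' expected proportion, multiplied by the family size and capped at 1. The
#' default tail is the central two-sided exact test (sum of all outcome
#' probabilities no larger than the observed one, as in R's `binom.test`);
#' this convention, with the family equal to the number of cell classes tested
#' within the stratum (4 on the autosomes, 3 on the X where no meiotic genes
#' exist), reproduces the published table p-values to their printed precision.
#' A one-sided tail toward the observed deviation is available for comparison.
#'
#' @param observed Observed panel count in the class.
#' @param panel_total Panel size in the stratum.
#' @param expected_proportion Universe proportion of the class in the stratum.
#' @param family_size Bonferroni multiplier.
#' @param tail "central" (two-sided exact, default) or "directional".
#' @return Corrected p-value in [0, 1].
#' @export
celltype_binomial <- function(observed, panel_total, expected_proportion,
                              family_size = 1,
                              tail = c("central", "directional")) {
  tail <- match.arg(tail)
  if (expected_proportion < 0 || expected_proportion > 1)
    stop("expected_proportion must lie in [0, 1]", call. = FALSE)
  stopifnot(observed >= 0, observed <= panel_total, family_size >= 1)
  if (panel_total == 0) return(1)  # empty panel: nothing to deviate
  p <- if (tail == "central") {
    stats::binom.test(observed, panel_total, expected_proportion)$p.value
  } else {
    if (observed > panel_total * expected_proportion)
      stats::pbinom(observed - 1, panel_total, expected_proportion,
                    lower.tail = FALSE)
    else
      stats::pbinom(observed, panel_total, expected_proportion)
  }
  min(1, p * family_size)
}

#' Cell-class enrichment table for a gene panel, stratified X vs autosomes
#'
#' Builds the observed/expected/corrected-p table for one panel of genes
#' (e.g. all sterility-correlated genes, or the higher-in-sterile bin),
#' with expectations and Bonferroni families computed independently within
#' the autosomes and the X chromosome. Genes without a cell-class association
#' and Y-linked genes are excluded from panels and universe alike.
#'
#' @param panel_genes Gene ids in the panel.
#' @param universe Gene ids of all expressed genes.
#' @param annotations Annotation table.
#' @return data.frame: stratum, cell_class, n_universe, observed, expected,
#'   p_corrected; attribute `family_size` (named, per stratum).
#' @export
celltype_enrichment_table <- function(panel_genes, universe, annotations) {
  ann <- annotations[match(universe, annotations$gene_id), ]
  keep <- ann$cell_class %in% CELL_CLASSES & ann$chromosome != "Y"
  ann <- ann[keep, ]
  stratum <- ifelse(ann$chromosome == "X", "X", "autosomes")
  in_panel <- ann$gene_id %in% panel_genes

  fams <- c(autosomes = NA_real_, X = NA_real_)
  rows <- list()
  for (st in c("autosomes", "X")) {
    idx <- stratum == st
    ucounts <- vapply(CELL_CLASSES, function(cc)
      sum(idx & ann$cell_class == cc), 0L)
    tested <- ucounts > 0
    fams[st] <- sum(tested)
    n_panel <- sum(idx & in_panel)
    exp_c <- celltype_expected(ucounts, n_panel)
    for (cc in CELL_CLASSES[tested]) {
      obs <- sum(idx & in_panel & ann$cell_class == cc)
      rows[[paste(st, cc)]] <- data.frame(
        stratum = st, cell_class = cc,
        n_universe = ucounts[[cc]], observed = obs,
        expected = exp_c[[cc]],
        p_corrected = celltype_binomial(obs, n_panel,
                                        ucounts[[cc]] / sum(ucounts),
                                        family_size = sum(tested)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "family_size") <- fams
  out
}

#' X-expression-class bias between the sterile hybrid and M. musculus
#'
#' Both MxD and MxM males carry the same hemizygous M. musculus X, so comparing
#' them isolates the effect of the hybrid autosomal background from X-linked
#' probe artifacts. For each X-expression timing class (A, B, C, E; the small
#' "variable" class D is excluded) and pooled across them, counts how many
#' genes have higher mean expression in the first genotype and tests the split
#' against the binomial expectation of equal proportions (two-sided exact).
#' The same comparison over all autosomal genes is reported as a baseline row.
#'
#' @param em [expression_matrix()], log2 scale.
#' @param annotations Annotation table with x_class.
#' @param genotype_a,genotype_b Genotypes to compare (defaults MxD vs MxM).
#' @return data.frame: group, n, n_higher, prop_higher, p_binomial. Empty
#'   classes are skipped.
#' @export
xclass_bias <- function(em, annotations, genotype_a = "MxD", genotype_b = "MxM") {
  gm <- genotype_means(em)
  ann <- annotations[match(rownames(gm), annotations$gene_id), ]
  higher <- gm[, genotype_a] > gm[, genotype_b]

  groups <- list()
  for (cl in c("A", "B", "C", "E")) {
    idx <- which(ann$x_class == cl)
    if (length(idx) == 0) next
    groups[[cl]] <- idx
  }
  groups[["X_pooled"]] <- which(ann$x_class %in% c("A", "B", "C", "E"))
  groups[["autosomes"]] <- which(!ann$chromosome %in% c("X", "Y"))

  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    k <- sum(higher[idx]); n <- length(idx)
    data.frame(group = g, n = n, n_higher = k, prop_higher = k / n,
               p_binomial = stats::binom.test(k, n, 0.5)$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
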