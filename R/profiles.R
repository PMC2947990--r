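#' Chromosome-wide expression deviation profile
#'
#' For every gene, deviations of each genotype's mean log2 expression from the
#' per-gene median over all samples are computed; deviations are then averaged
#' over the genes of each chromosome. Because all genotypes of a gene share one
#' median anchor, a genotype-specific chromosome-wide shift (such as X
#' over-expression in sterile males) stands out directly. Chromosome-mean
#' deviations d are also reported in percent form as 100 * (2^d - 1).
#'
#' @param em [expression_matrix()], log2 scale, all genotypes present.
#' @param annotations Annotation table.
#' @return list with `profile` (data.frame: genotype, chromosome, n_genes,
#'   mean_log2_deviation, percent_deviation), `gene_deviations` (genes x
#'   genotypes matrix) and `gene_median` (the per-gene anchors). Chromosomes
#'   with no genes are omitted.
#' @export
chromosome_deviation_profile <- function(em, annotations) {
  stopifnot(inherits(em, "expression_matrix"))
  med <- apply(em$values, 1, stats::median)
  dev <- genotype_means(em) - med
  ann <- annotations[match(rownames(em$values), annotations$gene_id), ]

  chroms <- MOUSE_CHROMOSOMES[MOUSE_CHROMOSOMES %in% ann$chromosome]
  rows <- list()
  for (g in colnames(dev)) for (ch in chroms) {
    idx <- ann$chromosome == ch
    d <- mean(dev[idx, g])
    rows[[paste(g, ch)]] <- data.frame(
      genotype = g, chromosome = ch, n_genes = sum(idx),
      mean_log2_deviation = d, percent_deviation = 100 * (2^d - 1),
      stringsAsFactors = FALSE)
  }
  profile <- do.call(rbind, c(rows, make.row.names = FALSE))
  profile$chromosome <- factor(profile$chromosome, levels = chroms)
  list(profile = profile, gene_deviations = dev, gene_median = med)
}

#' X-versus-autosome shift test for a pairwise genotype comparison
#'
#' Computes per-gene differences in mean log2 expression between two genotypes
#' and compares the distribution of differences for X-linked genes against the
#' pooled autosomes with a two-sample Kolmogorov-Smirnov test. A chromosome-wide
#' expression shift restricted to the X displaces the red curve wholesale.
#'
#' @param em [expression_matrix()], log2 scale.
#' @param genotype_a,genotype_b Genotypes; differences are a minus b.
#' @param annotations Annotation table.
#' @return list: statistic (KS D), p_value, n_x, n_autosome, mean_diff_x,
#'   mean_diff_autosome, unreliable (TRUE with a warning when fewer than 5
#'   X-linked genes are available).
#' @export
pairwise_shift_ks <- function(em, genotype_a, genotype_b, annotations) {
  gm <- genotype_means(em)
  for (g in c(genotype_a, genotype_b))
    if (!g %in% colnames(gm)) stop("genotype absent: ", g, call. = FALSE)
  diffs <- gm[, genotype_a] - gm[, genotype_b]
  ann <- annotations[match(rownames(gm), annotations$gene_id), ]
  dx <- diffs[ann$chromosome == "X"]
  da <- diffs[!ann$chromosome %in% c("X", "Y")]
  unreliable <- length(dx) < 5
  if (unreliable)
    warning("fewer than 5 X-linked genes; KS p-value unreliable", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(dx, da))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_x = length(dx), n_autosome = length(da),
       mean_diff_x = mean(dx), mean_diff_autosome = mean(da),
       unreliable = unreliable)
}

#' Bar plot of the per-chromosome deviation profile
#'
#' One panel per genotype, chromosomes in karyotype order, the X highlighted.
#' Requires ggplot2.
#'
#' @param profile The `profile` data.frame from
#'   [chromosome_deviation_profile()].
#' @return A ggplot object.
#' @export
plot_deviation_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  profile$is_x <- profile$chromosome == "X"
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = chromosome, y = mean_log2_deviation,
                               fill = is_x)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue4",
                                          `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::labs(x = "chromosome",
                  y = "mean deviation from per-gene median (log2)") +
    ggplot2::theme_bw()
}
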