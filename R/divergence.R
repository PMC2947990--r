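#' Compare protein evolutionary rates of X-linked vs autosomal genes
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test on dN/dS ratios of
#' X-linked versus autosomal testis-expressed genes, with per-stratum sample
#' sizes, means and medians. The comparison is unpaired: the two strata contain
#' different genes. Y-linked genes are excluded.
#'
#' @param records data.frame with gene_id and dnds (see [read_dnds_table()]);
#'   rows with missing dnds are dropped.
#' @param annotations Annotation table giving each gene a chromosome.
#' @return list: p_value, statistic (rank-sum W), and `summary` data.frame with
#'   one row per stratum (n, mean, median).
#' @export
dnds_rank_compare <- function(records, annotations) {
  ann <- annotations[match(records$gene_id, annotations$gene_id), ]
  if (anyNA(ann$chromosome))
    stop("every dN/dS record must be annotated with a chromosome", call. = FALSE)
  keep <- !is.na(records$dnds) & ann$chromosome != "Y"
  x <- records$dnds[keep & ann$chromosome == "X"]
  a <- records$dnds[keep & ann$chromosome != "X"]
  if (length(x) == 0 || length(a) == 0)
    stop("empty stratum: need both X-linked and autosomal genes", call. = FALSE)
  exact <- length(x) <= 10 && length(a) <= 10 && !any(duplicated(c(x, a)))
  wt <- suppressWarnings(stats::wilcox.test(x, a, exact = exact))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       summary = data.frame(
         stratum = c("X", "autosomes"),
         n = c(length(x), length(a)),
         mean = c(mean(x), mean(a)),
         median = c(stats::median(x), stats::median(a)),
         stringsAsFactors = FALSE))
}
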