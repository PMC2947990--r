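#' Gene-by-gene two-sample t contrast between genotypes
#'
#' Equal-variance (Student) two-sample t-test per gene on log2 expression, the
#' classical gene-by-gene contrast for 3-vs-3 array designs. Genes with zero
#' pooled variance (no variation between individuals) carry no p-value and are
#' listed in `excluded_genes`. Welch's unequal-variance form is available
#' behind a flag but is not the default.
#'
#' @param em [expression_matrix()] on the log2 scale.
#' @param group_a,group_b Genotype labels; the contrast is A minus B.
#' @param welch Use Welch's t instead of the pooled-variance Student t.
#' @return A `contrast_result`: list with `contrast_name`, `table` (gene_id,
#'   t_statistic, p_value, mean_diff_log2, direction) and `excluded_genes`.
#' @export
ttest_contrast <- function(em, group_a, group_b, welch = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  for (g in c(group_a, group_b)) {
    n <- length(samples_of(em, g))
    if (n == 0) stop("genotype absent from matrix: ", g, call. = FALSE)
    if (n < 2) stop("genotype ", g, " has a single replicate", call. = FALSE)
  }
  ia <- match(samples_of(em, group_a), colnames(em$values))
  ib <- match(samples_of(em, group_b), colnames(em$values))
  res <- row_ttest(em$values, ia, ib, welch = welch)
  keep <- !res$zero_var
  tab <- data.frame(
    gene_id = rownames(em$values)[keep],
    t_statistic = res$t[keep],
    p_value = res$p[keep],
    mean_diff_log2 = res$mean_diff[keep],
    direction = ifelse(res$mean_diff[keep] > 0, "up_in_A", "down_in_A"),
    stringsAsFactors = FALSE
  )
  structure(list(contrast_name = paste0(group_a, "_vs_", group_b),
                 table = tab,
                 excluded_genes = rownames(em$values)[!keep],
                 groups = c(group_a, group_b)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast %s: %d genes tested, %d excluded (zero variance), %d at p<0.05\n",
              x$contrast_name, nrow(x$table), length(x$excluded_genes),
              sum(x$table$p_value < 0.05)))
  invisible(x)
}

# vectorized two-sample t over matrix rows; textbook pooled-variance form,
# cross-checked against stats::t.test in the test suite
row_ttest <- function(values, ia, ib, welch = FALSE) {
  a <- values[, ia, drop = FALSE]; b <- values[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  }
  zero_var <- se2 <= 0 | !is.finite(se2)
  t <- ifelse(zero_var, NA_real_, (ma - mb) / sqrt(se2))
  p <- ifelse(zero_var, NA_real_, 2 * stats::pt(-abs(t), df))
  list(t = t, p = p, mean_diff = ma - mb, zero_var = zero_var)
}

#' Enumerate all distinct relabelings of two groups
#'
#' All distinct unordered assignments of the pooled samples into groups of the
#' given sizes. For equal group sizes each split and its mirror image give the
#' same t-test p-values, so complements are collapsed: 3v3 yields the 10
#' relabelings of the classical exhaustive sample-label permutation scheme,
#' 2v2 yields 3, 4v4 yields 35. The observed labeling (the first n_a pooled
#' indices as group A) is always included and always comes first.
#'
#' @param n_a,n_b Group sizes, both at least 2.
#' @return List of integer vectors: pooled-sample indices assigned to group A.
#' @export
enumerate_relabelings <- function(n_a, n_b) {
  stopifnot(n_a >= 2, n_b >= 2)
  splits <- utils::combn(n_a + n_b, n_a, simplify = FALSE)
  if (n_a == n_b)
    splits <- splits[vapply(splits, function(s) 1L %in% s, TRUE)]
  observed <- seq_len(n_a)
  is_obs <- vapply(splits, function(s) identical(s, observed), TRUE)
  c(splits[is_obs], splits[!is_obs])
}

#' Permutation-based FDR for a two-group contrast
#'
#' Reruns the gene-by-gene t-tests under every distinct sample relabeling
#' (exhaustive enumeration, no sampling, hence fully deterministic) and
#' estimates the false discovery rate at the chosen cutoff as
#' median(significant counts across relabelings) / observed significant count.
#' The observed labeling is included among the relabelings. When nothing is
#' significant under the true labels the FDR is undefined and reported as NA
#' with `undefined = TRUE` rather than dividing by zero.
#'
#' @param em [expression_matrix()], log2 scale.
#' @param group_a,group_b Genotype labels.
#' @param alpha Significance cutoff applied to every labeling, in (0,1).
#' @return An `fdr_estimate`: contrast_name, alpha, n_observed_significant,
#'   permutation_counts (observed labeling first), fdr, undefined.
#' @export
permutation_fdr <- function(em, group_a, group_b, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  sa <- samples_of(em, group_a); sb <- samples_of(em, group_b)
  pooled <- match(c(sa, sb), colnames(em$values))
  labelings <- enumerate_relabelings(length(sa), length(sb))
  counts <- vapply(labelings, function(idx_a) {
    ia <- pooled[idx_a]
    ib <- pooled[setdiff(seq_along(pooled), idx_a)]
    res <- row_ttest(em$values, ia, ib)
    sum(res$p < alpha, na.rm = TRUE)
  }, 0L)
  observed <- counts[1]
  fdr <- if (observed > 0) stats::median(counts) / observed else NA_real_
  structure(list(contrast_name = paste0(group_a, "_vs_", group_b),
                 alpha = alpha,
                 n_observed_significant = observed,
                 permutation_counts = counts,
                 fdr = fdr,
                 undefined = observed == 0),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("%s: %d significant at p<%g over %d relabelings; FDR %s\n",
              x$contrast_name, x$n_observed_significant, x$alpha,
              length(x$permutation_counts),
              if (x$undefined) "undefined" else sprintf("%.3f", x$fdr)))
  invisible(x)
}

#' Benjamini-Hochberg p-value cutoff for a target FDR
#'
#' Step-up rule: the largest sorted p-value p(i) with p(i) <= q * i / m. Returns
#' 0 when no p-value qualifies (nothing would be called significant). This is a
#' documented substitute for density-based local-FDR thresholding: the global
#' patterns downstream only need a monotone FDR-controlling cutoff.
#'
#' @param p_values Numeric vector of p-values (NAs dropped).
#' @param q Target FDR in (0,1).
#' @return The p-value cutoff (0 if no discovery).
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) stop("no p-values supplied", call. = FALSE)
  stopifnot(q > 0, q < 1)
  sp <- sort(p)
  m <- length(sp)
  ok <- sp <= q * seq_len(m) / m
  if (!any(ok)) 0 else sp[max(which(ok))]
}
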