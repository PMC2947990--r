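#' Detection calls from paired PM/MM probe intensities
#'
#' A gene is called expressed in a sample when its perfect-match signals are
#' significantly higher than its mismatch signals by a one-sided Wilcoxon
#' signed-rank test on the paired probe intensities. Genes detected in at least
#' `required_samples` samples (default: every sample) are retained; this mirrors
#' the whole-dataset filter used with 12 arrays and P < 0.01.
#'
#' The signed-rank p-value is exact when there are fewer than 20 nonzero paired
#' differences and no tied ranks, and uses the normal approximation with tie
#' correction otherwise; zero differences are dropped. Genes with fewer than 5
#' probes in some sample are excluded with a warning, since the one-sided exact
#' test cannot reach p < 0.01 below 7 pairs (2^-7 < 0.01 but 2^-4 is not) and
#' such calls would be vacuous.
#'
#' @param probes Long probe table (gene_id, probe_index, sample_id, pm, mm).
#' @param alpha Per-sample detection significance level, in (0,1).
#' @param required_samples Number of samples a gene must be detected in;
#'   default all samples present in `probes`.
#' @return Character vector of retained gene ids (the detected universe), with
#'   attribute `detection_p` holding the gene x sample p-value matrix.
#' @export
detect_and_filter <- function(probes, alpha = 0.01, required_samples = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  samples <- unique(probes$sample_id)
  if (is.null(required_samples)) required_samples <- length(samples)

  genes <- unique(probes$gene_id)
  pmat <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  few_probes <- character(0)

  by_gene <- split(probes[c("sample_id", "pm", "mm")], probes$gene_id)
  for (g in genes) {
    gp <- by_gene[[g]]
    by_s <- split(gp[c("pm", "mm")], gp$sample_id)
    if (any(vapply(by_s, nrow, 0L) < 5) || length(by_s) < length(samples)) {
      few_probes <- c(few_probes, g)
      next
    }
    for (s in names(by_s))
      pmat[g, s] <- pm_mm_signed_rank(by_s[[s]]$pm, by_s[[s]]$mm)
  }
  if (length(few_probes) > 0)
    warning(length(few_probes), " gene(s) excluded with < 5 probes in a sample: ",
            paste(utils::head(few_probes, 5), collapse = ", "),
            if (length(few_probes) > 5) ", ..." else "", call. = FALSE)

  detected <- rowSums(pmat < alpha, na.rm = TRUE) >= required_samples &
    !(genes %in% few_probes)
  retained <- genes[detected]
  attr(retained, "detection_p") <- pmat
  retained
}

# one-sided signed-rank p for PM > MM; exact below 20 nonzero differences
# (ties handled by enumerating over doubled midranks), normal approximation
# with tie correction otherwise
pm_mm_signed_rank <- function(pm, mm) {
  d <- pm - mm
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  if (length(d) < 20) exact_signed_rank_greater(d)
  else suppressWarnings(
    stats::wilcox.test(d, alternative = "greater", mu = 0,
                       exact = FALSE, correct = TRUE)$p.value
  )
}

# P(W >= w_obs) over all 2^n sign assignments, computed by convolution over
# doubled midranks (integers even under ties) rather than explicit enumeration
exact_signed_rank_greater <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  w2_obs <- sum(r2[d > 0])
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in r2)
    counts <- counts + c(rep(0, r), counts[seq_len(total + 1 - r)])
  sum(counts[seq(w2_obs + 1, total + 1)]) / 2^length(r2)
}

#' Summarize probe intensities to one value per gene and sample
#'
#' Replaces the original model-based summarizer (PLIER) with a pluggable,
#' documented alternative. `median_polish` fits an additive probe + sample
#' decomposition to log2 intensities by Tukey's median polish (the RMA-style
#' summary), making the gene summary robust to single aberrant probes;
#' `trimmed_mean` is a simpler 10\%-trimmed column mean on the log2 scale.
#' With `background = "mm"`, the per-probe mismatch intensity is subtracted
#' first; intensities are floored at 1 before taking logs either way.
#'
#' @param probes Long probe table.
#' @param retained Gene ids to summarize (subset of genes in `probes`).
#' @param sample_meta Sample sheet (sample_id, genotype, replicate).
#' @param method "median_polish" (default) or "trimmed_mean".
#' @param background "none" (default) or "mm" for PM - MM.
#' @param trim Trim fraction for `trimmed_mean`.
#' @return [expression_matrix()] of linear-scale summaries.
#' @export
summarize_probes <- function(probes, retained, sample_meta,
                             method = c("median_polish", "trimmed_mean"),
                             background = c("none", "mm"), trim = 0.1) {
  method <- match.arg(method)
  background <- match.arg(background)
  if (!all(retained %in% probes$gene_id))
    stop("retained contains genes absent from the probe table", call. = FALSE)
  probes <- probes[probes$gene_id %in% retained, , drop = FALSE]
  samples <- sample_meta$sample_id
  sig <- if (background == "mm") probes$pm - probes$mm else probes$pm
  lg <- log2(pmax(sig, 1))

  vals <- matrix(NA_real_, length(retained), length(samples),
                 dimnames = list(retained, samples))
  key <- split(seq_len(nrow(probes)), probes$gene_id)
  for (g in retained) {
    idx <- key[[g]]
    m <- matrix(NA_real_,
                length(unique(probes$probe_index[idx])), length(samples),
                dimnames = list(NULL, samples))
    m[cbind(match(probes$probe_index[idx], sort(unique(probes$probe_index[idx]))),
            match(probes$sample_id[idx], samples))] <- lg[idx]
    if (method == "median_polish") {
      mp <- stats::medpolish(m, trace.iter = FALSE, na.rm = TRUE)
      vals[g, ] <- mp$overall + mp$col
    } else {
      vals[g, ] <- apply(m, 2, mean, trim = trim, na.rm = TRUE)
    }
  }
  expression_matrix(2^vals, sample_meta, log2_scale = FALSE)
}

#' Quantile normalization followed by log2 transform
#'
#' Forces every array to share the same intensity distribution (rank-wise means
#' of the sorted columns, ties receiving the mean of the tied reference
#' quantiles), then log2-transforms. Non-positive input values are floored at 1
#' with a warning. Within-column rank order is preserved, and the normalization
#' is idempotent: normalizing an already-normalized matrix changes nothing.
#'
#' @param em [expression_matrix()] of positive linear-scale values.
#' @param log2 Apply the final log2 transform (set FALSE to inspect the
#'   normalized linear values, e.g. for idempotence checks).
#' @return [expression_matrix()], log2 scale when `log2 = TRUE`.
#' @export
quantile_normalize_log2 <- function(em, log2 = TRUE) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  if (any(v <= 0)) {
    warning("non-positive intensities floored at 1 before normalization",
            call. = FALSE)
    v[v < 1] <- 1
  }
  nv <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(nv) <- dimnames(v)
  if (log2) expression_matrix(base::log2(nv), em$sample_meta, log2_scale = TRUE)
  else expression_matrix(nv, em$sample_meta, log2_scale = FALSE)
}
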