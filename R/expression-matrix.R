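#' Expression matrix with sample metadata
#'
#' Light container pairing a genes x samples value matrix with a per-sample
#' metadata table (`sample_id`, `genotype`, `replicate`). Values are linear
#' intensities straight after probe summarization and log2 intensities after
#' [quantile_normalize_log2()]; the `log2_scale` flag records which.
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param sample_meta data.frame with columns sample_id, genotype, replicate,
#'   one row per column of `values` (matched by sample_id).
#' @param log2_scale Logical; TRUE if `values` are on the log2 scale.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_meta, log2_scale = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  req <- c("sample_id", "genotype", "replicate")
  if (!all(req %in% names(sample_meta)))
    stop("sample_meta needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (!setequal(colnames(values), sample_meta$sample_id))
    stop("sample_meta does not describe the matrix columns", call. = FALSE)
  if (anyNA(values)) stop("expression values must not contain NA", call. = FALSE)
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta,
                 log2_scale = isTRUE(log2_scale)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2_scale) "log2" else "linear"))
  tab <- table(x$sample_meta$genotype)
  cat("  genotypes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

samples_of <- function(em, genotype) {
  em$sample_meta$sample_id[em$sample_meta$genotype == genotype]
}

#' Per-genotype mean expression
#'
#' @param em An [expression_matrix()].
#' @return genes x genotypes matrix of row means within genotype.
#' @export
genotype_means <- function(em) {
  gts <- unique(em$sample_meta$genotype)
  out <- vapply(gts, function(g)
    rowMeans(em$values[, samples_of(em, g), drop = FALSE]),
    numeric(nrow(em$values)))
  out <- matrix(out, nrow = nrow(em$values),
                dimnames = list(rownames(em$values), gts))
  out
}
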