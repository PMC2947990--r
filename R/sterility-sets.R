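#' Hierarchical selection of sterility-correlated genes
#'
#' The sterile genotype (MxD) is contrasted against each fertile genotype; the
#' hierarchy then intersects those per-contrast calls instead of adjusting
#' per-gene p-values:
#'
#' * `hybrid_and_one_parent` - significant versus the fertile reciprocal hybrid
#'   (DxM) AND versus at least one parental line (MxM or DxD). This is the
#'   primary "sterility-correlated" definition (the 902-gene set of the study).
#' * `all_three` - significant in all three sterile-vs-fertile contrasts.
#' * `all_three_clean` - additionally not significant in ANY
#'   fertile-vs-fertile contrast.
#'
#' Significance is the unadjusted per-contrast p < alpha: the hierarchy manages
#' the FDR by intersection, which is the point of the design.
#'
#' @param contrasts Named list of `contrast_result` objects; names must include
#'   MxD_vs_DxM, MxD_vs_MxM, MxD_vs_DxD (and DxM_vs_MxM, DxM_vs_DxD, MxM_vs_DxD
#'   for `all_three_clean`).
#' @param mode Selection mode, see above.
#' @param alpha Per-contrast significance level.
#' @return A `sterility_set`: list(mode, alpha, gene_ids, direction) where
#'   direction is unset (NULL) until [bin_direction()] is applied.
#' @export
select_sterility_correlated <- function(contrasts,
                                        mode = c("hybrid_and_one_parent",
                                                 "all_three",
                                                 "all_three_clean"),
                                        alpha = 0.05) {
  mode <- match.arg(mode)
  need <- c("MxD_vs_DxM", "MxD_vs_MxM", "MxD_vs_DxD")
  if (mode == "all_three_clean")
    need <- c(need, "DxM_vs_MxM", "DxM_vs_DxD", "MxM_vs_DxD")
  missing <- setdiff(need, names(contrasts))
  if (length(missing) > 0)
    stop("missing contrasts for mode ", mode, ": ",
         paste(missing, collapse = ", "), call. = FALSE)

  sig <- function(nm) {
    tab <- contrasts[[nm]]$table
    tab$gene_id[tab$p_value < alpha]
  }
  s_hyb <- sig("MxD_vs_DxM")
  s_mxm <- sig("MxD_vs_MxM")
  s_dxd <- sig("MxD_vs_DxD")
  ids <- switch(mode,
    hybrid_and_one_parent = intersect(s_hyb, union(s_mxm, s_dxd)),
    all_three = Reduce(intersect, list(s_hyb, s_mxm, s_dxd)),
    all_three_clean = {
      core <- Reduce(intersect, list(s_hyb, s_mxm, s_dxd))
      dirty <- unique(c(sig("DxM_vs_MxM"), sig("DxM_vs_DxD"), sig("MxM_vs_DxD")))
      setdiff(core, dirty)
    })
  structure(list(mode = mode, alpha = alpha, gene_ids = sort(ids),
                 direction = NULL),
            class = "sterility_set")
}

#' @export
print.sterility_set <- function(x, ...) {
  cat(sprintf("sterility_set (%s, alpha %g): %d genes",
              x$mode, x$alpha, length(x$gene_ids)))
  if (!is.null(x$direction)) {
    tb <- table(factor(x$direction, c("higher", "lower", "intermediate")))
    cat(sprintf(" [higher %d / lower %d / intermediate %d]",
                tb[1], tb[2], tb[3]))
  }
  cat("\n")
  invisible(x)
}

#' Three-way direction binning against all fertile genotypes
#'
#' A gene is `higher` when its mean expression in sterile MxD males exceeds the
#' mean of every fertile genotype, `lower` when it is below every fertile mean,
#' and `intermediate` otherwise. Exact ties bin as intermediate (conservative;
#' zero-measure for continuous data).
#'
#' @param em [expression_matrix()] containing all four genotypes.
#' @param genes Gene ids to bin; all must be present in the matrix.
#' @return Named character vector over `genes` with values
#'   higher/lower/intermediate.
#' @export
bin_direction <- function(em, genes) {
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing) > 0)
    stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  if (!all(GENOTYPES %in% em$sample_meta$genotype))
    stop("all four genotypes must be present", call. = FALSE)
  gm <- genotype_means(em)[genes, , drop = FALSE]
  sterile <- gm[, STERILE_GENOTYPE]
  fert <- gm[, FERTILE_GENOTYPES, drop = FALSE]
  out <- rep("intermediate", length(genes))
  out[sterile > apply(fert, 1, max)] <- "higher"
  out[sterile < apply(fert, 1, min)] <- "lower"
  stats::setNames(out, genes)
}

#' Attach direction bins to a sterility set
#'
#' @param sset A `sterility_set`.
#' @param em [expression_matrix()] with all four genotypes.
#' @return The set with its `direction` field filled in.
#' @export
set_directions <- function(sset, em) {
  stopifnot(inherits(sset, "sterility_set"))
  sset$direction <- bin_direction(em, sset$gene_ids)
  sset
}
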