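#' Apparent-direction predictions under the cellular composition hypothesis
#'
#' When sterile testis loses postmeiotic cells, a fixed amount of RNA from
#' whole tissue over-represents transcripts from the remaining cell types.
#' Purely compositional shifts therefore make mitotic genes appear higher and
#' postmeiotic genes appear lower in sterile males even when per-cell
#' transcription is unchanged. Somatic and meiotic classes have no stated
#' prediction and default to unconstrained (sterile males retain meiotic
#' cells, so the sign of their compositional shift is not pinned down by the
#' phenotype).
#'
#' @param somatic,meiotic Optional overrides ("higher", "lower",
#'   "unconstrained") for the classes the hypothesis leaves open.
#' @return Named character vector over the four cell classes, class
#'   `composition_prediction`.
#' @export
composition_prediction <- function(somatic = "unconstrained",
                                   meiotic = "unconstrained") {
  ok <- c("higher", "lower", "unconstrained")
  stopifnot(somatic %in% ok, meiotic %in% ok)
  structure(c(somatic = somatic, mitotic = "higher",
              meiotic = meiotic, postmeiotic = "lower"),
            class = "composition_prediction")
}

#' Worked example of the compositional fold change
#'
#' Given the postmeiotic cell fraction in fertile and sterile testis, returns
#' the non-postmeiotic share of sterile tissue (percent) and the proportional
#' fold increase in relative abundance of non-postmeiotic transcripts:
#' (1 - f_sterile) / (1 - f_fertile). The canonical example: a drop from 85\%
#' to 55\% postmeiotic cells takes the non-postmeiotic share from 15\% to 45\%
#' of tissue, a three-fold increase.
#'
#' @param postmeiotic_fraction_fertile,postmeiotic_fraction_sterile Fractions
#'   in [0, 1); the fertile fraction must be < 1 (the ratio is undefined at 1).
#' @return list(non_postmeiotic_percent_sterile, fold_change).
#' @export
composition_fold <- function(postmeiotic_fraction_fertile,
                             postmeiotic_fraction_sterile) {
  f <- postmeiotic_fraction_fertile; s <- postmeiotic_fraction_sterile
  stopifnot(f >= 0, s >= 0, s < 1)
  if (f >= 1) stop("fertile postmeiotic fraction of 1 leaves no non-postmeiotic tissue",
                   call. = FALSE)
  list(non_postmeiotic_percent_sterile = 100 * (1 - s),
       fold_change = (1 - s) / (1 - f))
}

#' Sterility-correlated genes robust to the composition confound
#'
#' Returns the members of a direction-binned sterility set whose observed
#' direction CONTRADICTS the compositional prediction for their cell class:
#' postmeiotic genes that are higher in sterile males, and mitotic genes that
#' are lower. Only these can reflect true per-cell expression changes; all
#' co-directional calls are explainable by the shifted cell-type make-up of
#' sterile testis. Genes without a cell-class assignment are excluded (with a
#' message), as are classes with unconstrained predictions.
#'
#' @param sset A `sterility_set` with directions set (see [set_directions()]).
#' @param annotations Annotation table.
#' @param prediction A [composition_prediction()].
#' @return data.frame of robust genes: gene_id, chromosome, cell_class,
#'   direction.
#' @export
robust_genes <- function(sset, annotations, prediction = composition_prediction()) {
  stopifnot(inherits(sset, "sterility_set"))
  if (is.null(sset$direction))
    stop("sterility set has no directions; run set_directions() first",
         call. = FALSE)
  ann <- annotations[match(sset$gene_ids, annotations$gene_id), ]
  unass <- !(ann$cell_class %in% CELL_CLASSES)
  if (any(unass))
    message(sum(unass), " set member(s) without cell-class assignment excluded")
  ann <- ann[!unass, ]
  dir <- sset$direction[ann$gene_id]
  pred <- unclass(prediction)[ann$cell_class]
  contradicts <- (pred == "higher" & dir == "lower") |
    (pred == "lower" & dir == "higher")
  data.frame(gene_id = ann$gene_id[contradicts],
             chromosome = ann$chromosome[contradicts],
             cell_class = ann$cell_class[contradicts],
             direction = unname(dir[contradicts]),
             stringsAsFactors = FALSE)
}
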