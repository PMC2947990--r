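write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_ <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read / write gene annotation tables
#'
#' Tab-separated with columns gene_id, chromosome, position_mb, cell_class,
#' x_class.
#'
#' @param path File path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- read_tsv_(path)
  need <- c("gene_id", "chromosome", "position_mb", "cell_class", "x_class")
  if (!all(need %in% names(ann)))
    stop("annotation file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ann$chromosome <- as.character(ann$chromosome)
  ann
}

#' @rdname read_annotations
#' @param annotations Annotation data.frame.
#' @export
write_annotations <- function(annotations, path) write_tsv_(annotations, path)

#' Export annotations as BED-like intervals
#'
#' 0-based half-open single-base intervals at each gene's position
#' (bp = Mb * 1e6), for interoperability with genome-arithmetic tools.
#'
#' @param annotations Annotation data.frame.
#' @param path Output path.
#' @export
write_annotations_bed <- function(annotations, path) {
  start <- as.integer(round(annotations$position_mb * 1e6))
  bed <- data.frame(chrom = paste0("chr", annotations$chromosome),
                    start = start, end = start + 1L,
                    name = annotations$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write long-format probe tables
#'
#' @param path File path.
#' @return data.frame: gene_id, probe_index, sample_id, pm, mm.
#' @export
read_probe_table <- function(path) {
  pr <- read_tsv_(path)
  need <- c("gene_id", "probe_index", "sample_id", "pm", "mm")
  if (!all(need %in% names(pr)))
    stop("probe table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(pr$pm)) || any(!is.finite(pr$mm)) ||
      any(pr$pm < 0) || any(pr$mm < 0))
    stop("probe intensities must be finite and nonnegative", call. = FALSE)
  pr
}

#' @rdname read_probe_table
#' @param probes Probe data.frame.
#' @export
write_probe_table <- function(probes, path) write_tsv_(probes, path)

#' Read a sample sheet
#'
#' @param path TSV with columns sample_id, genotype, replicate.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sm <- read_tsv_(path)
  need <- c("sample_id", "genotype", "replicate")
  if (!all(need %in% names(sm)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(sm$genotype), GENOTYPES)
  if (length(bad) > 0)
    stop("unknown genotype(s): ", paste(bad, collapse = ", "), call. = FALSE)
  sm
}

#' Read / write an expression matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param path File path.
#' @param sample_meta Sample sheet data.frame.
#' @param log2_scale Whether the stored values are log2.
#' @return [expression_matrix()].
#' @export
read_expression_tsv <- function(path, sample_meta, log2_scale = TRUE) {
  df <- read_tsv_(path)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  expression_matrix(v, sample_meta, log2_scale = log2_scale)
}

#' @rdname read_expression_tsv
#' @param em [expression_matrix()].
#' @export
write_expression_tsv <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  write_tsv_(df, path)
}

#' Write an expression matrix in GCT dialect (versioned header "#1.2")
#'
#' @param em [expression_matrix()].
#' @param path Output path.
#' @export
write_gct <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(sprintf("%d\t%d", nrow(em$values), ncol(em$values)), con)
  df <- data.frame(NAME = rownames(em$values),
                   Description = "na", em$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dN/dS table
#'
#' @param path TSV with columns gene_id, dn, ds, dnds. When all three rate
#'   columns are present, dnds must equal dn/ds within 1e-9 and ds must be
#'   positive.
#' @return data.frame.
#' @export
read_dnds_table <- function(path) {
  d <- read_tsv_(path)
  if (!all(c("gene_id", "dnds") %in% names(d)))
    stop("dN/dS table needs at least gene_id and dnds", call. = FALSE)
  if (all(c("dn", "ds") %in% names(d))) {
    if (any(d$ds <= 0, na.rm = TRUE)) stop("ds must be positive", call. = FALSE)
    ok <- stats::complete.cases(d[, c("dn", "ds", "dnds")])
    if (any(abs(d$dnds[ok] - d$dn[ok] / d$ds[ok]) > 1e-9))
      stop("dnds must equal dn/ds", call. = FALSE)
  }
  d
}

#' Load the published cell-class tables shipped with the package
#'
#' `read_celltype_table()` loads a transcription of a published
#' observed/expected cell-class enrichment table (panels: all genes and the
#' higher / lower / intermediate direction bins; strata: autosomes and X).
#' `read_celltype_universe()` loads the per-stratum cell-class composition of
#' the expressed-gene universe behind those expectations; the integer counts
#' were reconstructed from the printed expected columns (they reproduce every
#' expectation at printed rounding) and are marked as derived in the file
#' header.
#'
#' @param which "species" (between-species differences) or "sterility"
#'   (sterility-correlated genes).
#' @return data.frame.
#' @export
read_celltype_table <- function(which = c("sterility", "species")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("celltype_table_%s.tsv", which),
                   package = "sterileX", mustWork = TRUE)
  read_tsv_(f, comment.char = "#")
}

#' @rdname read_celltype_table
#' @export
read_celltype_universe <- function() {
  f <- system.file("extdata", "celltype_universe.tsv",
                   package = "sterileX", mustWork = TRUE)
  read_tsv_(f, comment.char = "#")
}
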