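#' Configuration for an end-to-end pipeline run
#'
#' @param sim A [sim_config()] describing the synthetic dataset (or NULL when
#'   `probes` and `annotations` are supplied directly to [run_pipeline()]).
#' @param alpha_primary Per-contrast significance level for the main analysis.
#' @param alpha_strict The conservative mirror threshold.
#' @param set_mode Sterility-set definition passed to
#'   [select_sterility_correlated()].
#' @param detection_alpha Per-sample detection level.
#' @param null_mode Simulate with all effects zeroed.
#' @param out_dir Optional directory; when given, every stage writes its TSV
#'   outputs there.
#' @param stages Character vector of stages to run after simulation/preprocess;
#'   subset of contrasts, sets, enrichment, composition, profiles, divergence.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       alpha_primary = 0.05,
                       alpha_strict = 0.01,
                       set_mode = "hybrid_and_one_parent",
                       detection_alpha = 0.01,
                       null_mode = FALSE,
                       out_dir = NULL,
                       stages = c("contrasts", "sets", "enrichment",
                                  "composition", "profiles", "divergence")) {
  stopifnot(alpha_primary > 0, alpha_primary < 1,
            alpha_strict > 0, alpha_strict < 1)
  structure(list(sim = sim, alpha_primary = alpha_primary,
                 alpha_strict = alpha_strict, set_mode = set_mode,
                 detection_alpha = detection_alpha, null_mode = null_mode,
                 out_dir = out_dir, stages = stages),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> detect -> summarize -> normalize -> contrasts (with
#' permutation FDR) -> sterility sets -> enrichment -> composition -> profiles
#' -> divergence on synthetic data (or on a supplied probe table), and returns
#' a structured report. Fully deterministic given the configuration seed.
#'
#' @param config A [run_config()].
#' @param probes,annotations,sample_meta Optional externally supplied inputs
#'   replacing the simulation stage (all three must be given together).
#' @return list report with one element per executed stage.
#' @export
run_pipeline <- function(config = run_config(), probes = NULL,
                         annotations = NULL, sample_meta = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- list(config = config)
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE))
  }

  truth <- NULL
  if (is.null(probes)) {
    stage("simulate", {
      annotations <- generate_annotations(config$sim)
      ds <- generate_dataset(config$sim, annotations, null_mode = config$null_mode)
      probes <- ds$probes; sample_meta <- ds$sample_meta; truth <- ds$truth
    })
  }
  out$annotations <- annotations
  out$truth <- truth

  stage("preprocess", {
    retained <- detect_and_filter(probes, alpha = config$detection_alpha)
    em_lin <- summarize_probes(probes, retained, sample_meta)
    out$matrix <- quantile_normalize_log2(em_lin)
    out$detection <- list(n_input = length(unique(probes$gene_id)),
                           n_detected = length(retained))
  })
  em <- out$matrix
  ann <- annotations[annotations$gene_id %in% rownames(em$values), ]

  if ("contrasts" %in% config$stages) stage("contrasts", {
    pairs <- list(c("MxD", "DxM"), c("MxD", "MxM"), c("MxD", "DxD"),
                  c("DxM", "MxM"), c("DxM", "DxD"), c("MxM", "DxD"))
    contrasts <- list(); fdrs <- list()
    for (pr in pairs) {
      cr <- ttest_contrast(em, pr[1], pr[2])
      contrasts[[cr$contrast_name]] <- cr
      fdrs[[cr$contrast_name]] <-
        permutation_fdr(em, pr[1], pr[2], alpha = config$alpha_primary)
    }
    out$contrasts <- contrasts
    out$fdr <- fdrs
  })

  if ("sets" %in% config$stages) stage("sets", {
    ss <- select_sterility_correlated(out$contrasts, mode = config$set_mode,
                                      alpha = config$alpha_primary)
    out$sterility_set <- set_directions(ss, em)
  })

  if ("enrichment" %in% config$stages) stage("enrichment", {
    universe <- rownames(em$values)
    set_ids <- out$sterility_set$gene_ids
    dir <- out$sterility_set$direction
    out$enrichment <- list(
      chromosome = chromosome_enrichment(set_ids, universe, ann),
      celltype_all = celltype_enrichment_table(set_ids, universe, ann),
      celltype_higher = celltype_enrichment_table(
        names(dir)[dir == "higher"], universe, ann),
      celltype_lower = celltype_enrichment_table(
        names(dir)[dir == "lower"], universe, ann),
      xclass = xclass_bias(em, ann))
  })

  if ("composition" %in% config$stages) stage("composition", {
    out$composition <- list(
      worked_example = composition_fold(0.85, 0.55),
      robust = robust_genes(out$sterility_set, ann))
  })

  if ("profiles" %in% config$stages) stage("profiles", {
    prof <- chromosome_deviation_profile(em, ann)
    shifts <- list()
    for (pr in list(c("MxD", "DxM"), c("MxD", "MxM"), c("MxD", "DxD"),
                    c("DxM", "MxM"), c("DxM", "DxD"), c("MxM", "DxD")))
      shifts[[paste0(pr[1], "_vs_", pr[2])]] <-
        pairwise_shift_ks(em, pr[1], pr[2], ann)
    out$profiles <- list(deviation = prof, ks = shifts)
  })

  if ("divergence" %in% config$stages) stage("divergence", {
    dnds <- generate_dnds(ann, seed = stage_seed(config$sim, "dnds"))
    out$divergence <- dnds_rank_compare(dnds, ann)
  })

  if (!is.null(config$out_dir)) stage("write", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(x, f) write_tsv_(x, file.path(config$out_dir, f))
    write_annotations(ann, file.path(config$out_dir, "annotations.tsv"))
    write_expression_tsv(em, file.path(config$out_dir, "expression_log2.tsv"))
    if (!is.null(out$contrasts))
      for (nm in names(out$contrasts))
        wp(out$contrasts[[nm]]$table, paste0("contrast_", nm, ".tsv"))
    if (!is.null(out$fdr))
      wp(data.frame(contrast = names(out$fdr),
                    n_significant = vapply(out$fdr, `[[`, 0, "n_observed_significant"),
                    fdr = vapply(out$fdr, `[[`, 0, "fdr")),
         "fdr_summary.tsv")
    if (!is.null(out$sterility_set))
      wp(data.frame(gene_id = out$sterility_set$gene_ids,
                    mode = out$sterility_set$mode,
                    direction = unname(out$sterility_set$direction)),
         "sterility_set.tsv")
    if (!is.null(out$enrichment)) {
      wp(out$enrichment$chromosome, "enrichment_chromosome.tsv")
      wp(out$enrichment$celltype_all, "enrichment_celltype_all.tsv")
      wp(out$enrichment$xclass, "xclass_bias.tsv")
    }
    if (!is.null(out$composition)) wp(out$composition$robust, "robust_genes.tsv")
    if (!is.null(out$profiles)) wp(out$profiles$deviation$profile, "deviation_profile.tsv")
  })

  out
}
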