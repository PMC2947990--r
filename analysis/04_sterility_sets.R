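#!/usr/bin/env Rscript
# Stage 4: hierarchical sterility-correlated gene sets and direction binning.
#
# Builds all three nested definitions at alpha = 0.05 plus the conservative
# alpha = 0.01 mirror of the primary definition, and bins every member as
# higher / lower / intermediate in sterile MxD males versus all three fertile
# genotypes.

suppressPackageStartupMessages(library(sterileX))

meta <- read_sample_sheet("scratch/pipeline/sample_sheet.tsv")
em <- read_expression_tsv("scratch/pipeline/expression_log2.tsv", meta)

contrasts <- list()
for (nm in c("MxD_vs_DxM", "MxD_vs_MxM", "MxD_vs_DxD",
             "DxM_vs_MxM", "DxM_vs_DxD", "MxM_vs_DxD")) {
  tab <- read.delim(sprintf("scratch/pipeline/contrast_%s.tsv", nm))
  contrasts[[nm]] <- structure(list(contrast_name = nm, table = tab,
                                    excluded_genes = character(0)),
                               class = "contrast_result")
}

rows <- list()
for (mode in c("hybrid_and_one_parent", "all_three", "all_three_clean")) {
  ss <- set_directions(select_sterility_correlated(contrasts, mode), em)
  print(ss)
  write.table(data.frame(gene_id = ss$gene_ids, mode = mode, alpha = 0.05,
                         direction = unname(ss$direction)),
              sprintf("scratch/pipeline/sterility_set_%s.tsv", mode),
              sep = "\t", quote = FALSE, row.names = FALSE, append = FALSE)
  tb <- table(factor(ss$direction, c("higher", "lower", "intermediate")))
  rows[[mode]] <- data.frame(mode = mode, alpha = 0.05,
                             n_genes = length(ss$gene_ids),
                             n_higher = tb[["higher"]], n_lower = tb[["lower"]],
                             n_intermediate = tb[["intermediate"]])
}
# strict-alpha mirror of the primary definition
ss01 <- set_directions(
  select_sterility_correlated(contrasts, "hybrid_and_one_parent", alpha = 0.01), em)
tb <- table(factor(ss01$direction, c("higher", "lower", "intermediate")))
rows[["strict"]] <- data.frame(mode = "hybrid_and_one_parent", alpha = 0.01,
                               n_genes = length(ss01$gene_ids),
                               n_higher = tb[["higher"]], n_lower = tb[["lower"]],
                               n_intermediate = tb[["intermediate"]])

summary_tab <- do.call(rbind, c(rows, make.row.names = FALSE))
write.table(summary_tab, "results/sterility_set_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(summary_tab)
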