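#!/usr/bin/env Rscript
# Stage 5: genomic and cell-class enrichment of the sterility-correlated set.
#
# Chromosome-wise hypergeometric tests against the detected universe; cell-
# class binomial enrichment with expectations stratified X vs autosomes for
# the full set and each direction bin; X-expression-class bias between the
# genotypes sharing the M. musculus X (sterile MxD vs fertile MxM).

suppressPackageStartupMessages(library(sterileX))

meta <- read_sample_sheet("scratch/pipeline/sample_sheet.tsv")
em <- read_expression_tsv("scratch/pipeline/expression_log2.tsv", meta)
ann <- read_annotations("scratch/pipeline/annotations.tsv")
sset <- read.delim("scratch/pipeline/sterility_set_hybrid_and_one_parent.tsv")

universe <- rownames(em$values)
ann_u <- ann[ann$gene_id %in% universe, ]

chrom <- chromosome_enrichment(sset$gene_id, universe, ann_u)
write.table(chrom, "results/enrichment_chromosome.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
xr <- chrom[chrom$chromosome == "X", ]
cat(sprintf("X chromosome: %d observed vs %.1f expected (corrected p = %.3g)\n",
            xr$observed, xr$expected, xr$p_corrected))

cell_tabs <- list(all = sset$gene_id)
for (d in c("higher", "lower", "intermediate"))
  cell_tabs[[d]] <- sset$gene_id[sset$direction == d]
ct <- do.call(rbind, lapply(names(cell_tabs), function(nm) {
  tab <- celltype_enrichment_table(cell_tabs[[nm]], universe, ann_u)
  cbind(panel = nm, tab)
}))
write.table(ct, "results/enrichment_celltype.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(subset(ct, stratum == "X" & cell_class == "postmeiotic"))

xb <- xclass_bias(em, ann_u, "MxD", "MxM")
write.table(xb, "results/xclass_bias.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(xb)
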