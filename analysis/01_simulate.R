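#!/usr/bin/env Rscript
# Stage 1: generate the synthetic whole-testis probe-level dataset.
#
# Study conditions: 7,000 genes, 4 genotypes (DxD, MxM, DxM, sterile MxD) x 3
# males, 17 PM/MM probe pairs per gene. The sterile genotype loses postmeiotic
# cells (85% -> 55% of tissue) and carries a +log2(1.17) X-chromosome
# over-expression effect; a quarter of genes carry species-divergence effects,
# enriched among meiotic genes. Bulky intermediates go to scratch/, small
# summaries to results/.

suppressPackageStartupMessages(library(sterileX))

seed <- 20100930
dir.create("scratch/pipeline", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_genes = 7000, seed = seed)
print(cfg)

ann <- generate_annotations(cfg)
ds <- generate_dataset(cfg, ann)

write_annotations(ann, "scratch/pipeline/annotations.tsv")
write_annotations_bed(ann, "scratch/pipeline/annotations.bed")
write_probe_table(ds$probes, "scratch/pipeline/probes.tsv")
write.table(ds$sample_meta, "scratch/pipeline/sample_sheet.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$truth, "scratch/pipeline/truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("\nsimulated %d genes (%d X-linked, %d with species effects)\n",
            nrow(ann), sum(ann$chromosome == "X"), sum(ds$truth$divergent)))
cat(sprintf("probe table: %d rows -> scratch/pipeline/probes.tsv\n",
            nrow(ds$probes)))
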