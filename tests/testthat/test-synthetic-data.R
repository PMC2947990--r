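test_that("config validation rejects malformed probability structures", {
  expect_error(sim_config(chrom_weights = c(X = 0.5, Y = 0.4)),
               "summing to 1")
  expect_error(sim_config(cellclass_weights_X =
                            c(somatic = 0.2, mitotic = 0.3,
                              meiotic = 0.2, postmeiotic = 0.3)),
               "meiotic weight on the X")
  cf <- default_cell_fractions()
  cf["MxD", 1] <- cf["MxD", 1] + 0.1
  expect_error(sim_config(cell_fractions = cf), "sum to 1")
  rownames(cf) <- c("DxD", "MxM", "DxM", "weird")
  expect_error(sim_config(cell_fractions = cf), "genotypes")
  expect_error(sim_config(n_probes_per_gene = 0), "n_probes_per_gene")
})

test_that("annotations respect weights, MSCI constraint and x_class rules", {
  cfg <- sim_config(n_genes = 6000, seed = 3)
  ann <- generate_annotations(cfg)
  expect_equal(nrow(ann), 6000)

  # X-linked genes are never meiotic; x_class is X-only
  expect_false(any(ann$cell_class == "meiotic" & ann$chromosome == "X"))
  expect_true(all((ann$x_class == "none") == (ann$chromosome != "X")))

  # binomial sampling check: X fraction within 3 s.e. of its weight
  p <- cfg$chrom_weights[["X"]]
  se <- sqrt(p * (1 - p) / nrow(ann))
  expect_lt(abs(mean(ann$chromosome == "X") - p), 3 * se)

  # all mass on X forces every gene X-linked and none meiotic
  w <- setNames(rep(0, 21), names(default_chrom_weights()))
  w["X"] <- 1
  annx <- generate_annotations(sim_config(n_genes = 300, chrom_weights = w,
                                          seed = 1))
  expect_true(all(annx$chromosome == "X"))
  expect_false(any(annx$cell_class == "meiotic"))
})

test_that("identical config and seed reproduce the dataset bitwise", {
  cfg <- small_cfg(n_genes = 60, seed = 42)
  a1 <- generate_annotations(cfg); a2 <- generate_annotations(cfg)
  expect_identical(a1, a2)
  d1 <- generate_dataset(cfg, a1); d2 <- generate_dataset(cfg, a2)
  expect_identical(d1, d2)
  d3 <- generate_dataset(small_cfg(n_genes = 60, seed = 43),
                         generate_annotations(small_cfg(n_genes = 60, seed = 43)))
  expect_false(identical(d1$probes$pm, d3$probes$pm))
})

test_that("whole-tissue signal equals the per-cell mixture oracle", {
  cfg <- small_cfg(n_genes = 8, seed = 5, noise_sd_log2 = 0,
                   divergence_prob = 0, x_overexpression_log2 = 0)
  ann <- generate_annotations(cfg)
  sim <- simulate_expression(cfg, ann)

  # oracle: explicit loop over cell classes and genotypes
  classes <- c("somatic", "mitotic", "meiotic", "postmeiotic")
  for (g in seq_len(8)) {
    act <- rep(cfg$cellclass_leakage, 4); names(act) <- classes
    if (ann$cell_class[g] %in% classes) act[ann$cell_class[g]] <- 1
    if (ann$cell_class[g] == "unassigned") act[] <- 0.25
    for (geno in c("DxD", "MxM", "DxM", "MxD")) {
      mix <- 0
      for (cc in classes)
        mix <- mix + cfg$cell_fractions[geno, cc] * act[[cc]]
      expected <- sim$truth$base_log2[g] + log2(mix)
      got <- sim$matrix$values[g, paste0(geno, "_1")]
      expect_equal(unname(got), expected, tolerance = 1e-12)
    }
  }
})

test_that("implanted effects have their closed-form means", {
  # equal fractions, no divergence: MxD - MxM on X recovers beta, autosomes 0
  beta <- 0.23
  cfg <- sim_config(n_genes = 4000, seed = 11, cell_fractions = equal_fractions(),
                    divergence_prob = 0, x_overexpression_log2 = beta,
                    noise_sd_log2 = 0.15)
  ann <- generate_annotations(cfg)
  sim <- simulate_expression(cfg, ann)
  gm <- genotype_means(sim$matrix)
  d <- gm[, "MxD"] - gm[, "MxM"]
  on_x <- ann$chromosome == "X"
  mc <- 3 * cfg$noise_sd_log2 / sqrt(3 * sum(on_x))     # generous MC margin
  expect_lt(abs(mean(d[on_x]) - beta), mc)
  expect_lt(abs(mean(d[!on_x])), 3 * cfg$noise_sd_log2 / sqrt(3 * sum(!on_x)))

  # species effect: DxD - MxM mean difference is -delta per divergent gene
  cfg2 <- sim_config(n_genes = 2000, seed = 12, cell_fractions = equal_fractions(),
                     divergence_prob = 1, divergence_effect_log2 = 0.8,
                     x_overexpression_log2 = 0, noise_sd_log2 = 0.05)
  ann2 <- generate_annotations(cfg2)
  sim2 <- simulate_expression(cfg2, ann2)
  gm2 <- genotype_means(sim2$matrix)
  d2 <- (gm2[, "DxD"] - gm2[, "MxM"]) * sign(-sim2$truth$delta_log2)
  expect_equal(mean(d2), 0.8, tolerance = 0.02)
  # hybrids sit halfway
  dh <- (gm2[, "DxM"] - gm2[, "MxM"]) * sign(-sim2$truth$delta_log2)
  expect_equal(mean(dh), 0.4, tolerance = 0.02)
})

test_that("loss of postmeiotic cells triples non-postmeiotic transcript share", {
  # a purely mitotic transcript (no leakage) at fertile 8% vs sterile 24%
  # of tissue appears exactly three-fold more abundant in sterile males
  cfg <- sim_config(n_genes = 40, seed = 2, cellclass_leakage = 0,
                    divergence_prob = 0, x_overexpression_log2 = 0,
                    noise_sd_log2 = 0, unassigned_prob = 0)
  ann <- generate_annotations(cfg)
  sim <- simulate_expression(cfg, ann)
  mit <- which(ann$cell_class == "mitotic" & ann$chromosome != "X")
  ratio <- 2^(sim$matrix$values[mit, "MxD_1"] - sim$matrix$values[mit, "DxD_1"])
  expect_equal(unname(ratio), rep(3, length(mit)), tolerance = 1e-9)
})

test_that("null mode removes every systematic between-genotype difference", {
  cfg <- small_cfg(n_genes = 400, seed = 9)
  ann <- generate_annotations(cfg)
  sim <- simulate_expression(cfg, ann, null_mode = TRUE)
  expect_true(all(sim$truth$delta_log2 == 0))
  expect_false(any(sim$truth$x_over))
  gm <- genotype_means(sim$matrix)
  d <- gm[, "MxD"] - gm[, "DxD"]
  se <- cfg$noise_sd_log2 * sqrt(2 / 3) / sqrt(length(d))
  expect_lt(abs(mean(d)), 4 * se)
})

test_that("probe tables are complete, nonnegative and PM-dominant", {
  cfg <- small_cfg(n_genes = 50, seed = 21)
  ann <- generate_annotations(cfg)
  ds <- generate_dataset(cfg, ann)
  counts <- table(ds$probes$gene_id, ds$probes$sample_id)
  expect_true(all(counts == cfg$n_probes_per_gene))
  expect_true(all(is.finite(ds$probes$pm)) && all(ds$probes$pm >= 0))
  expect_true(all(is.finite(ds$probes$mm)) && all(ds$probes$mm >= 0))
  # mismatch picks up only a fraction of PM: PM > MM for most probe pairs
  expect_gt(mean(ds$probes$pm > ds$probes$mm), 0.7)
})

test_that("annotation mismatch is rejected", {
  cfg <- small_cfg(n_genes = 30, seed = 1)
  ann <- generate_annotations(cfg)
  expect_error(generate_dataset(small_cfg(n_genes = 40, seed = 1), ann),
               "not generated from this config")
})
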