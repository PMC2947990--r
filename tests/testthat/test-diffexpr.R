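test_that("t contrast reproduces hand-computed and oracle values", {
  # gene "example": groups (1,2,3) vs (4,5,6); "null": identical groups;
  # "constant": no variation at all
  meta <- data.frame(sample_id = paste0(rep(c("DxD", "MxM"), each = 3), "_", 1:3),
                     genotype = rep(c("DxD", "MxM"), each = 3),
                     replicate = rep(1:3, 2))
  vals <- rbind(example = c(1, 2, 3, 4, 5, 6),
                null = c(1, 2, 3, 1, 2, 3),
                constant = rep(7, 6))
  colnames(vals) <- meta$sample_id
  em <- expression_matrix(vals, meta, log2_scale = TRUE)
  cr <- ttest_contrast(em, "DxD", "MxM")

  ex <- cr$table[cr$table$gene_id == "example", ]
  expect_equal(ex$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(ex$p_value, 0.0213, tolerance = 1e-3)
  expect_equal(ex$mean_diff_log2, -3)
  expect_identical(ex$direction, "down_in_A")

  # identical group values: t exactly 0, p exactly 1
  nl <- cr$table[cr$table$gene_id == "null", ]
  expect_equal(nl$t_statistic, 0)
  expect_equal(nl$p_value, 1)

  # constant gene excluded with no p-value
  expect_identical(cr$excluded_genes, "constant")
  expect_false("constant" %in% cr$table$gene_id)

  expect_error(ttest_contrast(em, "DxD", "MxD"), "absent")
})

test_that("vectorized t agrees with stats::t.test on random cases", {
  set.seed(31)
  for (i in 1:100) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- rnorm(na); y <- rnorm(nb)
    meta <- data.frame(
      sample_id = c(paste0("DxD_", seq_len(na)), paste0("MxM_", seq_len(nb))),
      genotype = rep(c("DxD", "MxM"), c(na, nb)),
      replicate = c(seq_len(na), seq_len(nb)))
    vals <- matrix(c(x, y), 1, dimnames = list("g", meta$sample_id))
    em <- expression_matrix(vals, meta, log2_scale = TRUE)

    cr <- ttest_contrast(em, "DxD", "MxM")
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(cr$table$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(cr$table$p_value, ref$p.value, tolerance = 1e-10)

    bw <- ttest_contrast(em, "DxD", "MxM", welch = TRUE)
    refw <- t.test(x, y)
    expect_equal(bw$table$p_value, refw$p.value, tolerance = 1e-10)

    # and against the textbook formula oracle
    bf <- bf_student_t(x, y)
    expect_equal(cr$table$t_statistic, bf$t, tolerance = 1e-10)
    expect_equal(cr$table$p_value, bf$p, tolerance = 1e-10)
  }
})

test_that("relabeling enumeration has the exhaustive counts", {
  expect_length(enumerate_relabelings(3, 3), 10)
  expect_length(enumerate_relabelings(2, 2), 3)
  expect_length(enumerate_relabelings(4, 4), 35)
  expect_length(enumerate_relabelings(2, 3), choose(5, 2))
  # observed labeling included, first, and all splits distinct
  rl <- enumerate_relabelings(3, 3)
  expect_identical(rl[[1]], 1:3)
  expect_equal(length(unique(lapply(rl, sort))), 10)
  # for equal sizes, no split coexists with its complement
  comp <- lapply(rl, function(s) sort(setdiff(1:6, s)))
  expect_length(intersect(lapply(rl, sort), comp), 0)
  expect_error(enumerate_relabelings(1, 3))
})

test_that("permutation FDR saturates, vanishes and stays order-invariant", {
  set.seed(41)
  n_genes <- 120
  meta <- simmeta <- data.frame(
    sample_id = paste0(rep(c("DxD", "MxM"), each = 3), "_", 1:3),
    genotype = rep(c("DxD", "MxM"), each = 3),
    replicate = rep(1:3, 2))
  base <- matrix(rnorm(n_genes * 6, 8, 0.2), n_genes, 6,
                 dimnames = list(sprintf("g%03d", 1:n_genes), meta$sample_id))

  # huge implanted effects in half the genes -> FDR far below 1
  strong <- base
  strong[1:60, 4:6] <- strong[1:60, 4:6] + 5
  em_strong <- expression_matrix(strong, meta, log2_scale = TRUE)
  f <- permutation_fdr(em_strong, "DxD", "MxM", alpha = 0.05)
  expect_gte(f$n_observed_significant, 60)
  expect_lt(f$fdr, 0.3)
  expect_length(f$permutation_counts, 10)

  # alpha = 1: every gene significant under every relabeling -> FDR 1
  f1 <- permutation_fdr(em_strong, "DxD", "MxM", alpha = 1 - 1e-12)
  expect_equal(f1$fdr, 1)
  expect_equal(f1$n_observed_significant, n_genes)

  # permuting sample order within groups changes nothing
  perm <- c(3, 1, 2, 5, 6, 4)
  em_perm <- expression_matrix(strong[, perm], meta[perm, ], log2_scale = TRUE)
  f_perm <- permutation_fdr(em_perm, "DxD", "MxM", alpha = 0.05)
  expect_equal(sort(f_perm$permutation_counts), sort(f$permutation_counts))
  expect_equal(f_perm$fdr, f$fdr)

  # nothing significant -> undefined marker, not division by zero
  flat <- matrix(8, 4, 6, dimnames = list(paste0("g", 1:4), meta$sample_id))
  flat <- flat + rep(c(0, 0.01, -0.01), each = 4 * 2)[1:24] # some variance
  em_flat <- expression_matrix(flat, meta, log2_scale = TRUE)
  f0 <- permutation_fdr(em_flat, "DxD", "MxM", alpha = 1e-12)
  expect_true(f0$undefined)
  expect_true(is.na(f0$fdr))
})

test_that("BH threshold follows the step-up rule", {
  expect_equal(fdr_threshold(c(0.001, 0.002, 0.9), q = 0.05), 0.002)
  expect_equal(fdr_threshold(rep(1, 10), q = 0.05), 0)
  expect_error(fdr_threshold(numeric(0)), "no p-values")

  # agreement with p.adjust on random vectors: genes passing the returned
  # cutoff are exactly those with BH-adjusted p <= q
  set.seed(8)
  for (i in 1:20) {
    p <- c(runif(40), rbeta(10, 0.2, 5))
    q <- runif(1, 0.01, 0.2)
    cut <- fdr_threshold(p, q)
    expect_identical(p <= cut, p.adjust(p, "BH") <= q)
  }
})

test_that("type-I error is calibrated on null synthetic data", {
  cfg <- sim_config(n_genes = 3000, seed = 19)
  ann <- generate_annotations(cfg)
  sim <- simulate_expression(cfg, ann, null_mode = TRUE)
  cr <- ttest_contrast(sim$matrix, "MxD", "DxM")
  rate <- mean(cr$table$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(cr$table))
  expect_lt(abs(rate - 0.05), 3 * se)
})
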