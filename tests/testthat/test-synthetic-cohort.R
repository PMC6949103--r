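test_that("generation is deterministic: same seed gives a byte-identical bundle", {
  cfg <- analysis_config(seed = 77)
  b1 <- generate_cohort(cfg, n_tumor = 40, n_normal = 10, n_cell_lines = 20,
                        truth = default_truth())
  b2 <- generate_cohort(cfg, n_tumor = 40, n_normal = 10, n_cell_lines = 20,
                        truth = default_truth())
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(b1, d1)
  write_cohort(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  b3 <- generate_cohort(analysis_config(seed = 78), n_tumor = 40,
                        n_normal = 10, n_cell_lines = 20,
                        truth = default_truth())
  expect_false(identical(b1$expression$values, b3$expression$values))
})

test_that("planted IDs outside the panel or annotation sets are hard errors", {
  cfg <- analysis_config(seed = 1)
  expect_error(generate_cohort(cfg, truth = planted_truth(
    silenced_genes = data.frame(gene = "TP53", delta_beta = 0.2,
                                meth_expr_rho = -0.4))), "TP53")
  expect_error(generate_cohort(cfg, truth = planted_truth(
    activating_pairs = data.frame(gene = "RORA", pathway = "NoSuchPathway",
                                  effect_sd = 1))), "NoSuchPathway")
  expect_error(generate_cohort(cfg, truth = planted_truth(
    immune_pairs = data.frame(gene = "RORA", cell_type = "Mast cells",
                              rho = 0.3))), "Mast cells")
})

test_that("planted Spearman correlations land within 0.1 of target for n = 200", {
  truth <- planted_truth(
    silenced_genes = data.frame(gene = "PER1", delta_beta = 0.2,
                                meth_expr_rho = -0.5),
    immune_pairs = data.frame(gene = "NR1D1", cell_type = "CD8+ T cells",
                              rho = 0.4),
    drug_pairs = data.frame(gene = "CLOCK", drug = "drug_1", rho = 0.4))
  me <- imm <- dr <- numeric(50)
  for (s in 1:50) {
    b <- generate_cohort(analysis_config(seed = 100 + s), n_tumor = 200,
                         n_normal = 20, n_cell_lines = 200, truth = truth)
    me[s] <- cor(b$methylation$values["PER1", b$tumor_ids],
                 b$expression$values["PER1", b$tumor_ids], method = "spearman")
    imm[s] <- cor(b$expression$values["NR1D1", b$tumor_ids],
                  b$immune_scores$values["CD8+ T cells", ],
                  method = "spearman")
    dr[s] <- cor(b$cellline_expression$values["CLOCK", ],
                 b$auc$values["drug_1", ], method = "spearman")
  }
  expect_lt(abs(mean(me) - (-0.5)), 0.1)
  expect_lt(abs(mean(imm) - 0.4), 0.1)
  expect_lt(abs(mean(dr) - 0.4), 0.1)
})

test_that("planted methylation shift moves tumor betas by about delta_beta", {
  means <- numeric(20)
  for (s in 1:20) {
    b <- generate_cohort(analysis_config(seed = 300 + s), n_tumor = 200,
                         n_normal = 50,
                         truth = planted_truth(silenced_genes = data.frame(
                           gene = "PER1", delta_beta = 0.2,
                           meth_expr_rho = -0.5)))
    means[s] <- mean(b$methylation$values["PER1", b$tumor_ids]) -
      mean(b$methylation$values["PER1", b$normal_ids])
  }
  expect_lt(abs(mean(means) - 0.2), 0.05)
})

test_that("a null-truth cohort carries no systematic structure", {
  cfg <- analysis_config(seed = 55)
  b <- generate_cohort(cfg, n_tumor = 100, n_normal = 30)
  # roughly 30% censoring from the uniform mechanism
  expect_gt(mean(b$survival$event), 0.55)
  expect_lt(mean(b$survival$event), 0.85)
  # methylation betas respect the [0,1] contract, CNV the status contract
  expect_true(all(b$methylation$values >= 0 & b$methylation$values <= 1))
  expect_true(all(b$cnv$values %in% c(-2, -1, 0, 1, 2)))
  # no planted silencing: tumor-normal beta differences stay near zero
  dm <- differential_methylation(b$methylation, b$tumor_ids, b$normal_ids, cfg)
  expect_lt(max(abs(dm$effect)), 0.15)
})

test_that("a written cohort reads back with identical assay values", {
  b <- generate_cohort(analysis_config(seed = 88), n_tumor = 30,
                       n_normal = 10, n_cell_lines = 15,
                       truth = default_truth())
  d <- withr::local_tempdir()
  write_cohort(b, d)
  r <- read_cohort(d)
  expect_equal(r$expression$values, b$expression$values, tolerance = 1e-12)
  expect_equal(r$methylation$values, b$methylation$values, tolerance = 1e-12)
  expect_equal(r$auc$values, b$auc$values, tolerance = 1e-12)
  expect_identical(r$tumor_ids, b$tumor_ids)
  expect_equal(r$times_hours, b$times_hours, tolerance = 1e-12)
  expect_equal(r$survival$time, b$survival$time, tolerance = 1e-9)
  expect_identical(r$survival$event, b$survival$event)
})
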