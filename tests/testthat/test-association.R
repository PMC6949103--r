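test_that("Fisher Z matches the closed form and atanh/tanh invert each other", {
  expect_equal(atanh(0.5), 0.5493061443, tolerance = 1e-9)
  z <- seq(-5, 5, by = 0.25)
  expect_equal(atanh(tanh(z)), z, tolerance = 1e-12)
})

test_that("drug correlation: null, perfect, and planted cases behave as specified", {
  cfg <- analysis_config(gene_panel = "CLOCK")
  ids <- sprintf("cl%03d", 1:20)
  e <- c(1:20)
  # construct a vector exactly orthogonal to e (r = 0)
  a0 <- resid(lm(rnorm(20) ~ e))
  expr <- omics_matrix(matrix(exp(e / 5), 1, 20, dimnames = list("CLOCK", ids)),
                       kind = "expression")
  # use the raw ranks as expression so Pearson sees e itself
  expr_lin <- omics_matrix(matrix(e, 1, 20, dimnames = list("CLOCK", ids)),
                           kind = "expression")
  auc0 <- omics_matrix(matrix(a0, 1, 20, dimnames = list("drugX", ids)),
                       kind = "auc")
  res0 <- drug_correlation(expr_lin, auc0, cfg)
  expect_equal(res0$pearson_r, 0, tolerance = 1e-10)
  expect_equal(res0$fisher_z, 0, tolerance = 1e-10)
  expect_equal(res0$p_value, 1, tolerance = 1e-8)
  expect_identical(res0$label, "none")

  auc1 <- omics_matrix(matrix(2 * e + 3, 1, 20, dimnames = list("drugY", ids)),
                       kind = "auc")
  expect_warning(res1 <- drug_correlation(expr_lin, auc1, cfg), "infinite")
  expect_identical(res1$fisher_z, Inf)
  expect_equal(res1$p_value, 0)
  expect_identical(res1$label, "resistance")
})

test_that("normal-approximation p-values track the exact t-test for n >= 50", {
  set.seed(61)
  cfg <- analysis_config(gene_panel = "CLOCK")
  ids <- sprintf("cl%03d", 1:60)
  e <- rnorm(60)
  a <- 0.3 * e + rnorm(60, sd = 1)
  expr <- omics_matrix(matrix(e, 1, 60, dimnames = list("CLOCK", ids)),
                       kind = "expression")
  auc <- omics_matrix(matrix(a, 1, 60, dimnames = list("drug1", ids)),
                      kind = "auc")
  pz <- drug_correlation(expr, auc, cfg, p_method = "fisher_z")$p_value
  pt <- drug_correlation(expr, auc, cfg, p_method = "t")$p_value
  expect_lt(abs(pz - pt) / pt, 0.10)
})

test_that("immune signature scores match the loop-based oracle", {
  set.seed(62)
  sigs <- read_immune_signatures()
  genes <- c(unique(sigs$gene), "CLOCK", "PER1")
  ids <- sprintf("s%03d", 1:30)
  v <- matrix(rlnorm(length(genes) * 30, 2, 1), length(genes), 30,
              dimnames = list(genes, ids))
  expr <- omics_matrix(v, kind = "expression", units = "RPKM")
  scores <- score_immune_signatures(expr, sigs)
  expect_equal(scores$values, immune_score_oracle(v, sigs), tolerance = 1e-12)
})

test_that("single-marker and duplicate-marker signatures reduce to the z-scored gene", {
  ids <- sprintf("s%03d", 1:12)
  v <- matrix(rlnorm(2 * 12), 2, 12, dimnames = list(c("CD8A", "CD8B"), ids))
  expr <- omics_matrix(v, kind = "expression")
  one <- score_immune_signatures(expr, data.frame(cell_type = "CD8+ T cells",
                                                  gene = "CD8A"))
  lz <- log2(v["CD8A", ] + 1)
  expect_equal(unname(one$values[1, ]), unname((lz - mean(lz)) / sd(lz)),
               tolerance = 1e-12)
  # markers with identical vectors average to the same shared z-score
  v2 <- rbind(m1 = v[1, ], m2 = v[1, ])
  two <- score_immune_signatures(
    omics_matrix(v2, kind = "expression"),
    data.frame(cell_type = "ct", gene = c("m1", "m2")))
  expect_equal(unname(two$values[1, ]), unname((lz - mean(lz)) / sd(lz)),
               tolerance = 1e-12)
  # no observed marker: missing row plus warning
  expect_warning(
    none <- score_immune_signatures(expr,
                                    data.frame(cell_type = "ghost",
                                               gene = "NOPE")),
    "ghost")
  expect_true(all(is.na(none$values["ghost", ])))
})

test_that("immune correlation is invariant to monotone transforms and dies with broken pairing", {
  cfg <- analysis_config(seed = 63, gene_panel = "NR1D1")
  b <- generate_cohort(cfg, n_tumor = 100, n_normal = 0,
                       truth = planted_truth(
                         immune_pairs = data.frame(gene = "NR1D1",
                                                   cell_type = "CD8+ T cells",
                                                   rho = 0.5)))
  base <- immune_correlation(b$expression, b$immune_scores, cfg)
  i <- base$target == "CD8+ T cells"
  expect_true(base$significant[i])
  expect_gt(base$effect[i], 0.3)
  # monotone transform of expression leaves Spearman untouched
  tr <- b$expression
  tr$values <- log1p(tr$values)
  trans <- immune_correlation(tr, b$immune_scores, cfg)
  expect_equal(trans$effect, base$effect, tolerance = 1e-12)
  expect_equal(trans$p_value, base$p_value, tolerance = 1e-12)
  # permuting samples breaks the pairing: correlation collapses
  set.seed(64)
  perm <- b$immune_scores
  colnames(perm$values) <- sample(colnames(perm$values))
  pres <- immune_correlation(b$expression, perm, cfg)
  expect_lt(abs(pres$effect[pres$target == "CD8+ T cells"]), 0.25)
})
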