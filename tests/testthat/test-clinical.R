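test_that("product-limit estimator matches hand computations", {
  # three deaths, no censoring: S = 2/3, 1/3, 0
  km <- km_estimate(survival_table(c("a", "b", "c"), c(5, 8, 12), c(1, 1, 1)))
  expect_equal(km$times, c(5, 8, 12))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # all censored: S stays at 1 (no event times)
  km2 <- km_estimate(survival_table(c("a", "b"), c(4, 9), c(0, 0)))
  expect_identical(length(km2$times), 0L)

  # mixed 6-subject example: events at 3, 6, 9; censored at 4, 7, 10
  # S(3) = 5/6; S(6) = 5/6 * 3/4 = 5/8; S(9) = 5/8 * 1/2 = 5/16
  km3 <- km_estimate(survival_table(letters[1:6], c(3, 4, 6, 7, 9, 10),
                                    c(1, 0, 1, 0, 1, 0)))
  expect_equal(km3$times, c(3, 6, 9))
  expect_equal(km3$survival, c(5 / 6, 5 / 8, 5 / 16))
  expect_equal(km3$at_risk, c(6, 4, 2))
  expect_error(km_estimate(survival_table("a", 1, 1)[0, ]))
})

test_that("log-rank of a group against its copy is null", {
  a <- survival_table(sprintf("a%d", 1:8), c(2, 3, 5, 7, 8, 9, 11, 13),
                      c(1, 0, 1, 1, 0, 1, 0, 1))
  b <- a
  b$sample <- sprintf("b%d", 1:8)
  lr <- logrank_test(a, b)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
})

test_that("KM and log-rank agree with the risk-set enumeration oracle and the survival package", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    time <- round(rexp(n, 0.1), 1) + 0.1
    event <- rbinom(n, 1, 0.7)
    in_a <- rep(c(TRUE, FALSE), length.out = n)
    if (sum(event) == 0) event[1] <- 1
    tab <- survival_table(sprintf("s%d", 1:n), time, event)
    km <- km_estimate(tab)
    orc <- km_oracle(time, event)
    expect_equal(km$times, orc$times)
    expect_equal(km$survival, orc$survival, tolerance = 1e-12)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    expect_equal(km$survival,
                 summary(sf, times = km$times)$surv, tolerance = 1e-10)

    a <- survival_table(sprintf("a%d", 1:sum(in_a)), time[in_a], event[in_a])
    b <- survival_table(sprintf("b%d", 1:sum(!in_a)), time[!in_a], event[!in_a])
    lr <- logrank_test(a, b)
    orc2 <- logrank_oracle(time, event, in_a)
    expect_equal(lr$chi2, orc2$chi2, tolerance = 1e-12)
    grp <- ifelse(in_a, "a", "b")
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(lr$chi2, unname(sd_fit$chisq), tolerance = 1e-10)
  }
})

test_that("log-rank statistic is invariant under common time rescaling", {
  set.seed(18)
  time <- rexp(30, 0.05)
  event <- rbinom(30, 1, 0.7)
  a <- survival_table(sprintf("a%d", 1:15), time[1:15], event[1:15])
  b <- survival_table(sprintf("b%d", 1:15), time[16:30], event[16:30])
  base <- logrank_test(a, b)
  a$time <- a$time * 365.25
  b$time <- b$time * 365.25
  expect_equal(logrank_test(a, b)$chi2, base$chi2, tolerance = 1e-12)
})

test_that("median-split survival is symmetric in group labels", {
  cfg <- analysis_config(seed = 51, gene_panel = "PER3")
  set.seed(51)
  ids <- sprintf("s%03d", 1:60)
  e <- matrix(rlnorm(60), 1, 60, dimnames = list("PER3", ids))
  expr <- omics_matrix(e, kind = "expression")
  surv <- survival_table(ids, rexp(60, 1 / 500), rbinom(60, 1, 0.7))
  res <- survival_by_median_split(expr, surv, cfg)
  # negating expression swaps the high/low groups exactly (even n, no ties)
  neg <- omics_matrix(-e + 100, kind = "expression")
  res_neg <- survival_by_median_split(neg, surv, cfg)
  expect_equal(res_neg$logrank_chi2, res$logrank_chi2, tolerance = 1e-10)
  expect_equal(res_neg$p_value, res$p_value, tolerance = 1e-10)
  expect_equal(res_neg$n_high, res$n_low)
})

test_that("constant expression is skipped with a warning", {
  cfg <- analysis_config(gene_panel = c("PER3", "FLAT"))
  ids <- sprintf("s%03d", 1:40)
  e <- rbind(PER3 = rlnorm(40), FLAT = rep(2, 40))
  colnames(e) <- ids
  expr <- omics_matrix(e, kind = "expression")
  set.seed(1)
  surv <- survival_table(ids, rexp(40, 1 / 500), rbinom(40, 1, 0.8))
  expect_warning(res <- survival_by_median_split(expr, surv, cfg), "FLAT")
  expect_identical(res$gene, "PER3")
})

test_that("the joint |log2FC| and FDR filter keeps exactly the designed genes", {
  ids_a <- sprintf("a%d", 1:6)
  ids_b <- sprintf("b%d", 1:6)
  base <- c(10, 10.2, 9.8, 10.1, 9.9, 10.05)
  v <- rbind(
    hit1 = c(base * 4, base),            # 4-fold, cleanly separated
    hit2 = c(base * 5, base),
    hit3 = c(base * 4.2, base),
    bigfc_noisy = c(c(100, 1, 200, 2, 150, 3), c(10, 30, 5, 50, 8, 20)),
    smallfc_clean = c(base * 1.5, base), # separated but below the FC cut
    const1 = rep(7, 12), const2 = rep(3, 12), const3 = rep(9, 12),
    const4 = rep(1, 12), const5 = rep(5, 12))
  colnames(v) <- c(ids_a, ids_b)
  expr <- omics_matrix(v, kind = "expression", units = "RPKM")
  res <- differential_expression(expr, ids_a, ids_b, analysis_config())
  expect_identical(sort(res$gene[res$significant]),
                   c("hit1", "hit2", "hit3"))
  expect_identical(sum(res$significant), 3L)
  # log2 linearity: doubling group a adds exactly 1 to every effect
  # (up to the tiny pseudocount)
  v2 <- v
  v2[, ids_a] <- 2 * v2[, ids_a]
  res2 <- differential_expression(omics_matrix(v2, kind = "expression"),
                                  ids_a, ids_b, analysis_config())
  expect_equal(res2$effect, res$effect + 1, tolerance = 1e-3)
})
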