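#' Kaplan-Meier product-limit estimator
#'
#' Implements the product-limit estimator from first principles:
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} over the distinct event
#' times, where \eqn{d_i} is the number of deaths at \eqn{t_i} and
#' \eqn{n_i} the number still at risk.
#'
#' @param table A [survival_table()].
#' @param group Optional label stored on the curve.
#' @return Object of class `km_curve`: list with `times` (distinct event
#'   times, increasing), `survival`, `at_risk`, `events`, `n`, `group`.
#' @export
km_estimate <- function(table, group = NA_character_) {
  stopifnot(nrow(table) >= 1)
  if (any(table$time < 0)) stop("negative follow-up time")
  et <- sort(unique(table$time[table$event == 1]))
  surv <- numeric(length(et))
  at_risk <- integer(length(et))
  events <- integer(length(et))
  s <- 1
  for (i in seq_along(et)) {
    n_i <- sum(table$time >= et[i])
    d_i <- sum(table$time == et[i] & table$event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
    at_risk[i] <- n_i
    events[i] <- d_i
  }
  structure(list(times = et, survival = surv, at_risk = at_risk,
                 events = events, n = nrow(table), group = group),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> group=%s n=%d events=%d\n",
              x$group, x$n, sum(x$events)))
  if (length(x$times) > 0) {
    print(data.frame(time = x$times, at_risk = x$at_risk, events = x$events,
                     survival = x$survival))
  }
  invisible(x)
}

# Restricted mean survival time: area under the KM step function on [0, tau].
restricted_mean_survival <- function(curve, tau) {
  ts <- c(0, curve$times[curve$times <= tau], tau)
  ss <- c(1, curve$survival[curve$times <= tau])
  sum(diff(ts) * ss)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank: at each distinct event time the observed
#' minus expected number of events in group `a` is accumulated, with the
#' hypergeometric variance; the statistic
#' \eqn{\chi^2 = (\sum (O - E))^2 / \sum V} is referred to a chi-square
#' distribution with 1 df. Zero total variance (e.g. no events) yields
#' chi2 = 0, p = 1.
#'
#' @param a,b [survival_table()]s for the two groups.
#' @return list with `chi2`, `p`, `observed` and `expected` (events in
#'   group a).
#' @export
logrank_test <- function(a, b) {
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  in_a <- rep(c(TRUE, FALSE), c(nrow(a), nrow(b)))
  if (sum(event) < 1) return(list(chi2 = 0, p = 1, observed = 0, expected = 0))
  et <- sort(unique(time[event == 1]))
  o_minus_e <- 0; vsum <- 0; obs <- 0; expd <- 0
  for (t in et) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & in_a)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & in_a)
    e1_j <- d_j * n1_j / n_j
    v_j <- if (n_j > 1)
      d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    else 0
    o_minus_e <- o_minus_e + (d1_j - e1_j)
    vsum <- vsum + v_j
    obs <- obs + d1_j
    expd <- expd + e1_j
  }
  if (vsum <= 0) return(list(chi2 = 0, p = 1, observed = obs, expected = expd))
  chi2 <- o_minus_e^2 / vsum
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = obs, expected = expd)
}

#' Median-split survival analysis per gene
#'
#' For each panel gene, patients are split at the gene's median expression
#' (ties go to the low group) and the two groups are compared with the
#' log-rank test. The reported direction ("high_better"/"low_better")
#' compares the restricted mean survival of the two Kaplan-Meier curves and
#' is reported regardless of significance; the `significant` flag uses the
#' raw per-gene log-rank p-value against the configured threshold, with no
#' multiplicity correction.
#'
#' @param expr `omics_matrix` of kind `"expression"`.
#' @param surv A [survival_table()].
#' @param config An [analysis_config()].
#' @return data.frame with columns gene, logrank_chi2, p_value, n_high,
#'   n_low, rmst_high, rmst_low, direction, significant.
#' @export
survival_by_median_split <- function(expr, surv, config = analysis_config()) {
  stopifnot(inherits(expr, "omics_matrix"))
  shared <- intersect(colnames(expr$values), surv$sample)
  if (length(shared) < 20) stop("need >=20 samples with expression and survival")
  sv <- surv[match(shared, surv$sample), ]
  rows <- list()
  for (g in intersect(config$gene_panel, rownames(expr$values))) {
    e <- expr$values[g, shared]
    keep <- !is.na(e)
    if (length(unique(e[keep])) <= 1) {
      warning(sprintf("gene '%s': constant expression, skipped", g))
      next
    }
    med <- stats::median(e[keep])
    hi_ids <- shared[keep & e > med]
    lo_ids <- shared[keep & e <= med]
    a <- survival_table(hi_ids, sv$time[match(hi_ids, sv$sample)],
                        sv$event[match(hi_ids, sv$sample)])
    b <- survival_table(lo_ids, sv$time[match(lo_ids, sv$sample)],
                        sv$event[match(lo_ids, sv$sample)])
    lr <- logrank_test(a, b)
    tau <- min(max(a$time), max(b$time))
    rm_hi <- restricted_mean_survival(km_estimate(a, "high"), tau)
    rm_lo <- restricted_mean_survival(km_estimate(b, "low"), tau)
    dir <- if (rm_hi > rm_lo) "high_better"
           else if (rm_hi < rm_lo) "low_better" else "none"
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, logrank_chi2 = lr$chi2, p_value = lr$p,
      n_high = nrow(a), n_low = nrow(b), rmst_high = rm_hi, rmst_lo = rm_lo,
      direction = dir, significant = lr$p <= config$fdr_threshold,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(gene = character(), logrank_chi2 = numeric(),
                      p_value = numeric(), n_high = integer(),
                      n_low = integer(), rmst_high = numeric(),
                      rmst_lo = numeric(), direction = character(),
                      significant = logical(), stringsAsFactors = FALSE)
  }
  names(res)[names(res) == "rmst_lo"] <- "rmst_low"
  res
}

#' Threshold-based differential expression
#'
#' Per gene: effect = log2((mean_a + eps) / (mean_b + eps)) with pseudocount
#' eps = 1e-3 on the RPKM scale; two-sided Wilcoxon rank-sum p; BH correction
#' across genes. A gene is significant when |log2 FC| exceeds the configured
#' threshold AND the FDR passes. All features of the matrix are tested.
#'
#' @param expr `omics_matrix` of kind `"expression"` (non-negative values).
#' @param group_a_ids,group_b_ids Sample IDs of the two groups (e.g. tumor
#'   and normal).
#' @param config An [analysis_config()].
#' @param pseudocount Added to group means before the ratio (default 1e-3).
#' @return data.frame of association records (target `"group_a_vs_b"`,
#'   statistic = Wilcoxon W, effect = log2 fold change) plus `significant`.
#' @export
differential_expression <- function(expr, group_a_ids, group_b_ids,
                                    config = analysis_config(),
                                    pseudocount = 1e-3) {
  stopifnot(inherits(expr, "omics_matrix"))
  a_ids <- intersect(group_a_ids, colnames(expr$values))
  b_ids <- intersect(group_b_ids, colnames(expr$values))
  if (length(a_ids) < 3 || length(b_ids) < 3) {
    stop("need >=3 samples per group")
  }
  rows <- lapply(rownames(expr$values), function(g) {
    av <- expr$values[g, a_ids]; av <- av[!is.na(av)]
    bv <- expr$values[g, b_ids]; bv <- bv[!is.na(bv)]
    if (length(av) < 3 || length(bv) < 3) {
      return(association_record(g, "group_a_vs_b", NA_real_, NA_real_,
                                NA_real_, n = length(av) + length(bv)))
    }
    eff <- log2((mean(av) + pseudocount) / (mean(bv) + pseudocount))
    if (length(unique(c(av, bv))) == 1) {
      return(association_record(g, "group_a_vs_b",
                                length(av) * length(bv) / 2, eff, 1,
                                n = length(av) + length(bv)))
    }
    wt <- suppressWarnings(stats::wilcox.test(av, bv, exact = FALSE))
    association_record(g, "group_a_vs_b", unname(wt$statistic), eff,
                       wt$p.value, n = length(av) + length(bv))
  })
  res <- do.call(rbind, rows)
  res$fdr <- benjamini_hochberg(res$p_value)
  res$significant <- !is.na(res$fdr) &
    abs(res$effect) > config$log2fc_threshold &
    res$fdr <= config$fdr_threshold
  res
}
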