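# Independent brute-force oracles and fixture builders used across tests.
# These deliberately take the dumbest possible route (explicit loops,
# textbook formulas) so they share no code with the package implementation.

# Random omics matrix with optional missingness.
rand_omics <- function(kind, nf = 5, ns = 4, miss_frac = 0.1) {
  v <- switch(kind,
    methylation = matrix(runif(nf * ns), nf, ns),
    cnv = matrix(sample(c(-2, -1, 0, 1, 2), nf * ns, replace = TRUE,
                        prob = c(.05, .1, .7, .1, .05)), nf, ns),
    matrix(rnorm(nf * ns, 10, 3), nf, ns))
  if (miss_frac > 0) {
    v[sample(length(v), floor(miss_frac * length(v)))] <- NA
  }
  rownames(v) <- sprintf("f%03d", seq_len(nf))
  colnames(v) <- sprintf("s%03d", seq_len(ns))
  omics_matrix(v, kind = kind, units = "x")
}

# Textbook BH step-up: sort ascending, q_(i) = p_(i) * n / i, enforce
# monotonicity from the largest down, cap at 1, restore input order.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- ps * n / seq_len(n)
  if (n > 1) {
    for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

# Loop-based PAS oracle: explicit per-pathway, per-sample, per-member sums.
pas_oracle <- function(rppa_norm_values, pathways) {
  pnames <- unique(pathways$pathway)
  out <- matrix(NA_real_, length(pnames), ncol(rppa_norm_values),
                dimnames = list(pnames, colnames(rppa_norm_values)))
  for (pw in pnames) {
    mem <- pathways[pathways$pathway == pw, ]
    for (s in seq_len(ncol(rppa_norm_values))) {
      acc <- NA_real_
      for (k in seq_len(nrow(mem))) {
        prot <- mem$protein[k]
        if (!prot %in% rownames(rppa_norm_values)) next
        x <- rppa_norm_values[prot, s]
        if (is.na(x)) next
        acc <- if (is.na(acc)) mem$sign[k] * x else acc + mem$sign[k] * x
      }
      out[pw, s] <- acc
    }
  }
  out
}

# Risk-set enumeration oracle for the product-limit estimator.
km_oracle <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- numeric(length(et))
  cur <- 1
  for (i in seq_along(et)) {
    n_i <- 0; d_i <- 0
    for (j in seq_along(time)) {
      if (time[j] >= et[i]) n_i <- n_i + 1
      if (time[j] == et[i] && event[j] == 1) d_i <- d_i + 1
    }
    cur <- cur * (1 - d_i / n_i)
    s[i] <- cur
  }
  list(times = et, survival = s)
}

# Risk-set enumeration oracle for the two-group log-rank statistic.
logrank_oracle <- function(time, event, in_a) {
  et <- sort(unique(time[event == 1]))
  num <- 0; var_sum <- 0
  for (t in et) {
    n_j <- sum(time >= t)
    n1_j <- sum(time >= t & in_a)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & in_a)
    num <- num + d1_j - d_j * n1_j / n_j
    if (n_j > 1) {
      var_sum <- var_sum + d_j * (n1_j / n_j) * ((n_j - n1_j) / n_j) *
        (n_j - d_j) / (n_j - 1)
    }
  }
  if (var_sum <= 0) return(list(chi2 = 0, p = 1))
  chi2 <- num^2 / var_sum
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Loop-based immune signature oracle: z-score each marker's log2(x+1) row
# with an explicit mean/sd loop, then average over markers per sample.
immune_score_oracle <- function(expr_values, signatures) {
  lv <- log2(expr_values + 1)
  cts <- unique(signatures$cell_type)
  out <- matrix(NA_real_, length(cts), ncol(lv),
                dimnames = list(cts, colnames(lv)))
  for (ct in cts) {
    markers <- intersect(signatures$gene[signatures$cell_type == ct],
                         rownames(lv))
    zs <- matrix(NA_real_, length(markers), ncol(lv))
    for (k in seq_along(markers)) {
      row <- lv[markers[k], ]
      m <- mean(row, na.rm = TRUE)
      s <- sd(row, na.rm = TRUE)
      zs[k, ] <- (row - m) / s
    }
    for (j in seq_len(ncol(lv))) out[ct, j] <- mean(zs[, j], na.rm = TRUE)
  }
  out
}

# Small pathway set used where the shipped annotation would be overkill.
toy_pathways <- function() {
  data.frame(
    pathway = c("pwA", "pwA", "pwA", "pwB", "pwB"),
    protein = c("p1", "p2", "p3", "p2", "p4"),
    sign = c(1L, -1L, 1L, 1L, -1L),
    stringsAsFactors = FALSE)
}
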