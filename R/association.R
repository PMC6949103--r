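#' Drug-sensitivity correlation with Fisher's Z normalization
#'
#' For each panel gene and each drug, the Pearson correlation between
#' transcript level and drug-response AUC is computed across the shared cell
#' lines (pairwise-complete, >= 10 required). The correlation is
#' variance-stabilized with Fisher's Z transform, z = atanh(r); the test
#' statistic z*sqrt(n-3) is referred to the standard normal (two-sided).
#' Because higher AUC means a less responsive line, a significant positive
#' correlation is labelled "resistance" and a significant negative one
#' "sensitivity". BH correction is applied within each gene's family of
#' drugs. A correlation of exactly +/-1 is reported as an infinite Fisher Z
#' sentinel with p = 0 and a warning.
#'
#' @param expr `omics_matrix`: expression of the panel genes across cell
#'   lines (samples are cell-line IDs).
#' @param auc `omics_matrix` of kind `"auc"`: drugs x cell lines.
#' @param config An [analysis_config()].
#' @param p_method `"fisher_z"` (default, normal approximation) or
#'   `"t"` (exact t-distribution p from [stats::cor.test()]).
#' @return data.frame with columns gene, drug, pearson_r, fisher_z, z_score,
#'   p_value, fdr, n, label.
#' @export
drug_correlation <- function(expr, auc, config = analysis_config(),
                             p_method = c("fisher_z", "t")) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(expr, "omics_matrix"), inherits(auc, "omics_matrix"))
  shared <- intersect(colnames(expr$values), colnames(auc$values))
  genes <- intersect(config$gene_panel, rownames(expr$values))
  rows <- list()
  for (g in genes) {
    for (d in rownames(auc$values)) {
      e <- expr$values[g, shared]
      a <- auc$values[d, shared]
      ok <- !is.na(e) & !is.na(a)
      n <- sum(ok)
      if (n < 10) next
      if (length(unique(e[ok])) == 1 || length(unique(a[ok])) == 1) next
      r <- stats::cor(e[ok], a[ok])
      if (abs(r) >= 1 - 1e-15) {
        warning(sprintf("gene '%s' / drug '%s': |r| = 1, Fisher Z infinite", g, d))
        z <- sign(r) * Inf
        zs <- sign(r) * Inf
        p <- 0
      } else {
        z <- atanh(r)
        zs <- z * sqrt(n - 3)
        p <- if (p_method == "fisher_z") 2 * stats::pnorm(-abs(zs))
             else stats::cor.test(e[ok], a[ok])$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, drug = d, pearson_r = r, fisher_z = z, z_score = zs,
        p_value = p, n = n, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(gene = character(), drug = character(),
                      pearson_r = numeric(), fisher_z = numeric(),
                      z_score = numeric(), p_value = numeric(),
                      fdr = numeric(), n = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  # BH within each gene's drug family
  res$fdr <- NA_real_
  for (g in unique(res$gene)) {
    idx <- res$gene == g
    res$fdr[idx] <- benjamini_hochberg(res$p_value[idx])
  }
  res$label <- "none"
  sig <- !is.na(res$fdr) & res$fdr <= config$fdr_threshold
  res$label[sig & res$pearson_r > 0] <- "resistance"
  res$label[sig & res$pearson_r < 0] <- "sensitivity"
  res[, c("gene", "drug", "pearson_r", "fisher_z", "z_score", "p_value",
          "fdr", "n", "label")]
}

#' Marker-mean immune signature scores
#'
#' A deliberately simple marker-gene summary of immune infiltration: per cell
#' type, the score of a sample is the mean of the per-gene z-scored
#' log2(RPKM + 1) values over the cell type's observed marker genes. This is
#' a transparent stand-in for full deconvolution methods; externally computed
#' infiltration matrices can be supplied to [immune_correlation()] through
#' the same matrix contract instead.
#'
#' @param expr `omics_matrix` of kind `"expression"` (non-negative values).
#' @param signatures data.frame with columns cell_type, gene
#'   (see [read_immune_signatures()]).
#' @return `omics_matrix` (cell types x samples), kind `"expression"`,
#'   units `"signature z"`.
#' @export
score_immune_signatures <- function(expr,
                                    signatures = read_immune_signatures()) {
  stopifnot(inherits(expr, "omics_matrix"))
  lv <- log2(expr$values + 1)
  ctr <- lv - rowMeans(lv, na.rm = TRUE)
  sds <- apply(lv, 1, stats::sd, na.rm = TRUE)
  z <- ctr / sds
  cell_types <- unique(signatures$cell_type)
  out <- matrix(NA_real_, nrow = length(cell_types), ncol = ncol(lv),
                dimnames = list(cell_types, colnames(lv)))
  for (ct in cell_types) {
    markers <- intersect(signatures$gene[signatures$cell_type == ct],
                         rownames(z))
    markers <- markers[is.finite(sds[markers])]
    if (length(markers) == 0) {
      warning(sprintf("cell type '%s': no marker gene observed", ct))
      next
    }
    out[ct, ] <- colMeans(z[markers, , drop = FALSE], na.rm = TRUE)
  }
  omics_matrix(out, kind = "expression", units = "signature z")
}

#' Correlate panel genes with immune infiltration
#'
#' Spearman correlation between each panel gene's expression and each immune
#' cell-type score across shared samples (>= 20 required), BH-corrected
#' across all gene-by-cell-type tests.
#'
#' @param expr `omics_matrix` of kind `"expression"`.
#' @param immune_scores `omics_matrix`: cell types x samples, e.g. from
#'   [score_immune_signatures()] or an external deconvolution tool.
#' @param config An [analysis_config()].
#' @return data.frame of association records (target = cell type,
#'   statistic = effect = Spearman rho) plus `significant`.
#' @export
immune_correlation <- function(expr, immune_scores,
                               config = analysis_config()) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(immune_scores, "omics_matrix"))
  shared <- intersect(colnames(expr$values), colnames(immune_scores$values))
  if (length(shared) < 20) stop("need >=20 shared samples")
  rows <- list()
  for (g in intersect(config$gene_panel, rownames(expr$values))) {
    for (ct in rownames(immune_scores$values)) {
      e <- expr$values[g, shared]
      s <- immune_scores$values[ct, shared]
      ok <- !is.na(e) & !is.na(s)
      if (sum(ok) < 20) next
      if (length(unique(s[ok])) == 1 || length(unique(e[ok])) == 1) {
        warning(sprintf("constant vector for gene '%s' / cell type '%s'", g, ct))
        next
      }
      ct_test <- suppressWarnings(stats::cor.test(e[ok], s[ok],
                                                  method = "spearman",
                                                  exact = FALSE))
      rows[[length(rows) + 1]] <- association_record(
        g, ct, unname(ct_test$estimate), unname(ct_test$estimate),
        ct_test$p.value, n = sum(ok))
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- association_record(character(), character(), numeric(), numeric(),
                              numeric(), n = integer())
    res$significant <- logical()
    return(res)
  }
  res$fdr <- benjamini_hochberg(res$p_value)
  res$significant <- !is.na(res$fdr) & res$fdr <= config$fdr_threshold
  res
}
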