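#' Tumor-vs-normal differential methylation
#'
#' Gene-level beta values (assumed pre-aggregated, e.g. promoter means) are
#' compared between tumor and normal samples with a two-sided Wilcoxon
#' rank-sum test; the effect is mean beta(tumor) - mean beta(normal). BH
#' correction is applied across the panel. A gene absent from the matrix, or
#' with fewer than 5 non-missing samples in either group, yields a record
#' with missing statistics and a warning.
#'
#' @param meth `omics_matrix` of kind `"methylation"`.
#' @param tumor_ids,normal_ids Character vectors of sample IDs.
#' @param config An [analysis_config()]; genes tested are
#'   `config$gene_panel`.
#' @return data.frame of association records (gene, target
#'   `"tumor_vs_normal"`, statistic = Wilcoxon W, effect = mean beta
#'   difference, p_value, fdr, n) plus a `significant` flag
#'   (fdr strictly below the threshold).
#' @export
differential_methylation <- function(meth, tumor_ids, normal_ids,
                                     config = analysis_config()) {
  stopifnot(inherits(meth, "omics_matrix"), meth$kind == "methylation")
  tumor_ids <- intersect(tumor_ids, colnames(meth$values))
  normal_ids <- intersect(normal_ids, colnames(meth$values))
  rows <- lapply(config$gene_panel, function(g) {
    if (!g %in% rownames(meth$values)) {
      warning(sprintf("gene '%s' absent from methylation matrix", g))
      return(association_record(g, "tumor_vs_normal", NA_real_, NA_real_,
                                NA_real_, n = 0L))
    }
    tv <- meth$values[g, tumor_ids]
    nv <- meth$values[g, normal_ids]
    tv <- tv[!is.na(tv)]; nv <- nv[!is.na(nv)]
    if (length(tv) < 5 || length(nv) < 5) {
      warning(sprintf("gene '%s': <5 samples per group after missing removal", g))
      return(association_record(g, "tumor_vs_normal", NA_real_, NA_real_,
                                NA_real_, n = length(tv) + length(nv)))
    }
    if (length(unique(c(tv, nv))) == 1) {
      return(association_record(g, "tumor_vs_normal",
                                length(tv) * length(nv) / 2, 0, 1,
                                n = length(tv) + length(nv)))
    }
    wt <- suppressWarnings(stats::wilcox.test(tv, nv, exact = FALSE))
    association_record(g, "tumor_vs_normal", unname(wt$statistic),
                       mean(tv) - mean(nv), wt$p.value,
                       n = length(tv) + length(nv))
  })
  res <- do.call(rbind, rows)
  res$fdr <- benjamini_hochberg(res$p_value)
  res$significant <- !is.na(res$fdr) & res$fdr < config$fdr_threshold
  res
}

#' Methylation-expression effect within tumors
#'
#' Spearman correlation between a gene's beta value and its expression across
#' tumor samples (pairwise-complete); promoter hypermethylation that silences
#' a gene shows up as a negative rho. P-values come from the asymptotic null
#' distribution of rho; BH across the panel.
#'
#' @param meth `omics_matrix` of kind `"methylation"`.
#' @param expr `omics_matrix` of kind `"expression"`.
#' @param tumor_ids Tumor sample IDs (intersected with both matrices).
#' @param config An [analysis_config()].
#' @return data.frame of association records (target `"expression"`,
#'   statistic = effect = Spearman rho) with a `significant` flag.
#' @export
methylation_expression_effect <- function(meth, expr, tumor_ids,
                                          config = analysis_config()) {
  stopifnot(inherits(meth, "omics_matrix"), inherits(expr, "omics_matrix"))
  shared <- Reduce(intersect, list(tumor_ids, colnames(meth$values),
                                   colnames(expr$values)))
  if (length(shared) < 10) stop("need >=10 shared tumor samples with both assays")
  rows <- lapply(config$gene_panel, function(g) {
    if (!g %in% rownames(meth$values) || !g %in% rownames(expr$values)) {
      warning(sprintf("gene '%s' absent from methylation or expression matrix", g))
      return(association_record(g, "expression", NA_real_, NA_real_, NA_real_,
                                n = 0L))
    }
    b <- meth$values[g, shared]
    e <- expr$values[g, shared]
    ok <- !is.na(b) & !is.na(e)
    if (sum(ok) < 10 || length(unique(b[ok])) == 1 || length(unique(e[ok])) == 1) {
      warning(sprintf("gene '%s': degenerate or insufficient paired values", g))
      return(association_record(g, "expression", NA_real_, NA_real_, NA_real_,
                                n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(b[ok], e[ok], method = "spearman",
                                           exact = FALSE))
    association_record(g, "expression", unname(ct$estimate),
                       unname(ct$estimate), ct$p.value, n = sum(ok))
  })
  res <- do.call(rbind, rows)
  res$fdr <- benjamini_hochberg(res$p_value)
  res$significant <- !is.na(res$fdr) & res$fdr < config$fdr_threshold
  res
}

#' Copy-number frequency summary
#'
#' Per gene, the fraction of samples carrying heterozygous (-1/+1) or
#' homozygous (-2/+2) deletions and amplifications. A gene is flagged
#' `displayed` when any single category exceeds (strictly) the configured
#' display fraction.
#'
#' @param cnv `omics_matrix` of kind `"cnv"` (values in -2..+2).
#' @param config An [analysis_config()]; `cnv_display_fraction` sets the
#'   display threshold (default 0.05, i.e. >5 percent of samples).
#' @return data.frame with columns gene, het_amp_frac, het_del_frac,
#'   hom_amp_frac, hom_del_frac, n, displayed.
#' @export
summarize_cnv <- function(cnv, config = analysis_config()) {
  stopifnot(inherits(cnv, "omics_matrix"), cnv$kind == "cnv")
  v <- cnv$values
  res <- do.call(rbind, lapply(rownames(v), function(g) {
    x <- v[g, ]
    x <- x[!is.na(x)]
    n <- length(x)
    fr <- if (n == 0) rep(0, 4) else
      c(mean(x == 1), mean(x == -1), mean(x == 2), mean(x == -2))
    data.frame(gene = g, het_amp_frac = fr[1], het_del_frac = fr[2],
               hom_amp_frac = fr[3], hom_del_frac = fr[4], n = n,
               stringsAsFactors = FALSE)
  }))
  res$displayed <- pmax(res$het_amp_frac, res$het_del_frac,
                        res$hom_amp_frac, res$hom_del_frac) >
    config$cnv_display_fraction
  res
}
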