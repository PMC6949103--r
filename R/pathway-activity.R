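#' Standardize an RPPA matrix by protein
#'
#' Each protein (row) is mean-centered and divided by its across-sample
#' standard deviation (denominator n-1), so that signed sums across proteins
#' are on a common scale. Proteins with fewer than two distinct non-missing
#' values carry no standardizable signal and are dropped with a warning.
#'
#' @param rppa An `omics_matrix` of kind `"rppa"`.
#' @return An `omics_matrix` of kind `"rppa"`, units `"sd units"`, with every
#'   row having mean 0 and sd 1 over its non-missing entries.
#' @export
normalize_rppa <- function(rppa) {
  stopifnot(inherits(rppa, "omics_matrix"), rppa$kind == "rppa")
  v <- rppa$values
  n_distinct <- apply(v, 1, function(r) length(unique(r[!is.na(r)])))
  drop <- n_distinct < 2
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance protein(s): %s",
                    sum(drop), paste(utils::head(rownames(v)[drop], 5),
                                     collapse = ", ")))
    v <- v[!drop, , drop = FALSE]
  }
  if (nrow(v) == 0) stop("no proteins left after dropping zero-variance rows")
  ctr <- rowMeans(v, na.rm = TRUE)
  v <- v - ctr
  sds <- apply(v, 1, stats::sd, na.rm = TRUE)
  v <- v / sds
  omics_matrix(v, kind = "rppa", units = "sd units")
}

#' Compute pathway activity scores (PAS)
#'
#' The PAS of a pathway in a sample is the sum of the standardized abundances
#' of its positive-regulator proteins minus the sum over its
#' negative-regulator proteins. Member proteins absent from the matrix, or
#' missing in a given sample, are omitted from the sum. A pathway with no
#' observed member at all yields a row of missing values and a warning.
#'
#' @param rppa_norm Standardized RPPA matrix from [normalize_rppa()].
#' @param pathways data.frame with columns pathway, protein, sign
#'   (see [read_pathways()]).
#' @return A `pas_matrix`: list with `values` (pathways x samples),
#'   `pathway_names`, `sample_ids`.
#' @export
compute_pas <- function(rppa_norm, pathways) {
  stopifnot(inherits(rppa_norm, "omics_matrix"))
  v <- rppa_norm$values
  pnames <- unique(pathways$pathway)
  out <- matrix(NA_real_, nrow = length(pnames), ncol = ncol(v),
                dimnames = list(pnames, colnames(v)))
  for (pw in pnames) {
    mem <- pathways[pathways$pathway == pw, ]
    present <- mem$protein %in% rownames(v)
    if (!any(present)) {
      warning(sprintf("pathway '%s': no member protein observed; PAS is missing", pw))
      next
    }
    mem <- mem[present, ]
    signed <- v[mem$protein, , drop = FALSE] * mem$sign
    obs <- colSums(!is.na(signed)) > 0
    s <- colSums(signed, na.rm = TRUE)
    s[!obs] <- NA_real_
    out[pw, ] <- s
  }
  structure(list(values = out, pathway_names = pnames,
                 sample_ids = colnames(v)),
            class = "pas_matrix")
}

#' @export
print.pas_matrix <- function(x, ...) {
  cat(sprintf("<pas_matrix> %d pathways x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Call per-gene pathway activation/inhibition
#'
#' For each panel gene, samples shared between the expression matrix and the
#' PAS matrix are split at the gene's median expression (ties go to the low
#' group). Each pathway's PAS is compared between the two groups with a
#' two-sided Mann-Whitney U test (configurable to Welch's t); `pas_diff` is
#' mean PAS(high) - mean PAS(low). BH correction is applied across all
#' gene-by-pathway tests, and a direction of "activate" (pas_diff > 0) or
#' "inhibit" (pas_diff < 0) is called when the FDR passes the configured
#' threshold; otherwise "none". `pct_influenced` is the absolute rank-biserial
#' effect size clipped to \[0, 1\] — a stand-in summary of how much of the
#' cohort the gene's expression level shifts the pathway for, not a per-patient
#' fraction.
#'
#' @param expression `omics_matrix` of kind `"expression"`.
#' @param pas A `pas_matrix` from [compute_pas()].
#' @param config An [analysis_config()].
#' @param test `"wilcox"` (default) or `"welch"`.
#' @return data.frame with columns gene, pathway, direction, pas_diff,
#'   p_value, fdr, pct_influenced, n_high, n_low.
#' @export
call_pathway_effects <- function(expression, pas, config = analysis_config(),
                                 test = c("wilcox", "welch")) {
  test <- match.arg(test)
  stopifnot(inherits(expression, "omics_matrix"), inherits(pas, "pas_matrix"))
  shared <- intersect(colnames(expression$values), colnames(pas$values))
  if (length(shared) < 8) stop("need >=8 samples shared between expression and PAS")
  genes <- intersect(config$gene_panel, rownames(expression$values))
  rows <- list()
  for (g in genes) {
    e <- expression$values[g, shared]
    keep <- !is.na(e)
    med <- stats::median(e[keep])
    high <- keep & e > med          # ties -> low group
    low <- keep & e <= med
    for (pw in rownames(pas$values)) {
      pvec <- pas$values[pw, shared]
      hi <- pvec[high & !is.na(pvec)]
      lo <- pvec[low & !is.na(pvec)]
      if (length(hi) < 4 || length(lo) < 4) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, pathway = pw, pas_diff = NA_real_, p_value = NA_real_,
          pct_influenced = NA_real_, n_high = length(hi), n_low = length(lo),
          stringsAsFactors = FALSE)
        next
      }
      diff <- mean(hi) - mean(lo)
      if (length(unique(c(hi, lo))) == 1) {   # fully tied: no evidence
        p <- 1
        rb <- 0
      } else if (test == "wilcox") {
        wt <- suppressWarnings(stats::wilcox.test(hi, lo, exact = FALSE))
        u <- unname(wt$statistic)
        rb <- 2 * u / (length(hi) * length(lo)) - 1   # rank-biserial
        p <- wt$p.value
      } else {
        tt <- stats::t.test(hi, lo)
        p <- tt$p.value
        rb <- diff / stats::sd(c(hi, lo))
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, pathway = pw, pas_diff = diff, p_value = p,
        pct_influenced = min(1, abs(rb)), n_high = length(hi),
        n_low = length(lo), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(gene = character(), pathway = character(),
                      direction = character(), pas_diff = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      pct_influenced = numeric(), n_high = integer(),
                      n_low = integer(), stringsAsFactors = FALSE))
  }
  res$fdr <- benjamini_hochberg(res$p_value)
  res$direction <- "none"
  sig <- !is.na(res$fdr) & res$fdr <= config$fdr_threshold & res$pas_diff != 0
  res$direction[sig & res$pas_diff > 0] <- "activate"
  res$direction[sig & res$pas_diff < 0] <- "inhibit"
  res[, c("gene", "pathway", "direction", "pas_diff", "p_value", "fdr",
          "pct_influenced", "n_high", "n_low")]
}
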