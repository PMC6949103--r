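#' Specify planted effects for a synthetic cohort
#'
#' Every argument is a data.frame (or NULL for none) describing effects the
#' generator plants and the analysis stages are expected to recover:
#' \describe{
#'   \item{activating_pairs}{columns gene, pathway, effect_sd: positive
#'     regulators of the pathway are shifted by `effect_sd` (in protein SD
#'     units) in samples where the gene's expression is above its median.}
#'   \item{silenced_genes}{columns gene, delta_beta, meth_expr_rho: tumor
#'     methylation is shifted up by about `delta_beta` on the beta scale and
#'     coupled to expression with target Spearman `meth_expr_rho`
#'     (typically negative).}
#'   \item{prognostic_genes}{columns gene, hazard_ratio: the event hazard is
#'     multiplied by `hazard_ratio` for patients with above-median
#'     expression.}
#'   \item{drug_pairs}{columns gene, drug, rho: target Spearman correlation
#'     between expression and AUC across cell lines.}
#'   \item{rhythmic_genes}{columns gene, amplitude, acrophase_hours: 24 h
#'     cosine rhythm planted in the time-series matrix.}
#'   \item{immune_pairs}{columns gene, cell_type, rho: target Spearman
#'     correlation between expression and the cell type's infiltration
#'     score.}
#' }
#'
#' @param activating_pairs,silenced_genes,prognostic_genes,drug_pairs,rhythmic_genes,immune_pairs
#'   data.frames as described above, or NULL.
#' @return Object of class `planted_truth`.
#' @export
planted_truth <- function(activating_pairs = NULL, silenced_genes = NULL,
                          prognostic_genes = NULL, drug_pairs = NULL,
                          rhythmic_genes = NULL, immune_pairs = NULL) {
  empty <- function(...) {
    cols <- c(...)
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  coerce <- function(x, cols, num_cols) {
    if (is.null(x)) x <- empty(cols)
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (!all(cols %in% names(x))) {
      stop(sprintf("expected columns: %s", paste(cols, collapse = ", ")))
    }
    for (nc in num_cols) x[[nc]] <- as.numeric(x[[nc]])
    x[, cols]
  }
  tr <- structure(list(
    activating_pairs = coerce(activating_pairs,
                              c("gene", "pathway", "effect_sd"), "effect_sd"),
    silenced_genes = coerce(silenced_genes,
                            c("gene", "delta_beta", "meth_expr_rho"),
                            c("delta_beta", "meth_expr_rho")),
    prognostic_genes = coerce(prognostic_genes, c("gene", "hazard_ratio"),
                              "hazard_ratio"),
    drug_pairs = coerce(drug_pairs, c("gene", "drug", "rho"), "rho"),
    rhythmic_genes = coerce(rhythmic_genes,
                            c("gene", "amplitude", "acrophase_hours"),
                            c("amplitude", "acrophase_hours")),
    immune_pairs = coerce(immune_pairs, c("gene", "cell_type", "rho"), "rho")),
    class = "planted_truth")
  stopifnot(all(abs(tr$silenced_genes$meth_expr_rho) < 1),
            all(abs(tr$drug_pairs$rho) < 1),
            all(abs(tr$immune_pairs$rho) < 1),
            all(tr$prognostic_genes$hazard_ratio > 0),
            all(tr$rhythmic_genes$amplitude >= 0),
            all(tr$rhythmic_genes$acrophase_hours >= 0 &
                  tr$rhythmic_genes$acrophase_hours < 24))
  tr
}

#' Default planted truth for demonstration cohorts
#'
#' A qualitative portrait of the effects the pipeline is designed to find:
#' RORA activating the RTK pathway, PER1 silenced by promoter methylation,
#' high ARNTL expression hazardous, CLOCK-linked drug resistance and
#' PER2-linked sensitivity, strong 24 h rhythms in the canonical clock genes
#' and an NR1D1 / CD8+ T-cell infiltration association.
#'
#' @return A [planted_truth()].
#' @export
default_truth <- function() {
  planted_truth(
    activating_pairs = data.frame(gene = "RORA", pathway = "RTK",
                                  effect_sd = 0.8),
    silenced_genes = data.frame(gene = "PER1", delta_beta = 0.2,
                                meth_expr_rho = -0.5),
    prognostic_genes = data.frame(gene = "ARNTL", hazard_ratio = 2.0),
    drug_pairs = data.frame(gene = c("CLOCK", "PER2"),
                            drug = c("drug_1", "drug_2"),
                            rho = c(0.4, -0.4)),
    rhythmic_genes = data.frame(
      gene = c("ARNTL", "NR1D1", "PER1", "PER2", "PER3", "CRY1", "CRY2",
               "CLOCK", "RORA"),
      amplitude = c(1.2, 1.0, 0.8, 1.0, 0.7, 0.6, 0.5, 0.3, 0.4),
      acrophase_hours = c(6, 10, 20, 21, 22, 18, 19, 4, 2)),
    immune_pairs = data.frame(gene = "NR1D1", cell_type = "CD8+ T cells",
                              rho = 0.4))
}

# Spearman target -> latent Gaussian correlation (bivariate normal identity
# rho_s = (6/pi) asin(r/2)); rank-preserving marginal transforms keep the
# Spearman value.
latent_corr_for_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Mix a correlated latent: r * z + sqrt(1-r^2) * fresh noise.
mix_latent <- function(z, r) r * z + sqrt(1 - r^2) * stats::rnorm(length(z))

#' Generate a synthetic multi-omics cohort with planted effects
#'
#' Produces a full cohort bundle — tumor/normal expression, methylation,
#' RPPA, CNV, survival, drug AUC with matched cell-line expression, immune
#' infiltration scores and a time-stamped expression series — in which the
#' effects listed in `truth` are planted by construction and everything else
#' is null. Correlation targets are planted through a Gaussian copula
#' (rank-preserving), so Spearman targets hold under the log-normal and
#' logit-normal marginals used. Deterministic given `config$seed`.
#'
#' @param config An [analysis_config()]; the seed and gene panel come from
#'   here.
#' @param n_tumor,n_normal Number of tumor and normal samples (defaults 200
#'   and 50).
#' @param n_cell_lines Number of drug-screen cell lines (default 100).
#' @param n_timepoints Number of time-series samples (default 24, spanning
#'   `timeseries_span_hours`).
#' @param truth A [planted_truth()]; defaults to no planted effects.
#' @param pathways Pathway definitions (see [read_pathways()]).
#' @param signatures Immune marker lists (see [read_immune_signatures()]).
#' @param n_background_genes Extra null genes added to the expression,
#'   methylation and time-series matrices (default 30).
#' @param n_drugs Number of drugs in the AUC screen (default 6); planted
#'   drug names are added if not already among them.
#' @param timeseries_span_hours Span of the time series (default 48 h, i.e.
#'   two full cycles at 2 h spacing with the default 24 points).
#' @param timeseries_noise_sd Gaussian noise SD on the time series
#'   (default 0.5).
#' @param rppa_fraction Fraction of tumor samples with RPPA (default 1).
#' @return Object of class `cohort_bundle`; see [write_cohort()] for the
#'   on-disk layout.
#' @export
generate_cohort <- function(config = analysis_config(),
                            n_tumor = 200, n_normal = 50,
                            n_cell_lines = 100, n_timepoints = 24,
                            truth = planted_truth(),
                            pathways = read_pathways(),
                            signatures = read_immune_signatures(),
                            n_background_genes = 30, n_drugs = 6,
                            timeseries_span_hours = 48,
                            timeseries_noise_sd = 0.5,
                            rppa_fraction = 1) {
  stopifnot(n_tumor >= 20, n_normal >= 0, n_cell_lines >= 10,
            n_timepoints >= 4)
  set.seed(config$seed)
  panel <- config$gene_panel
  marker_genes <- setdiff(unique(signatures$gene), panel)
  bg_genes <- sprintf("BG%03d", seq_len(n_background_genes))
  genes <- c(panel, marker_genes, bg_genes)
  planted_genes <- unique(c(truth$activating_pairs$gene,
                            truth$silenced_genes$gene,
                            truth$prognostic_genes$gene,
                            truth$drug_pairs$gene,
                            truth$rhythmic_genes$gene,
                            truth$immune_pairs$gene))
  missing_ids <- setdiff(planted_genes, panel)
  if (length(missing_ids) > 0) {
    stop(sprintf("planted gene(s) not in the configured panel: %s",
                 paste(missing_ids, collapse = ", ")))
  }
  bad_pw <- setdiff(truth$activating_pairs$pathway, unique(pathways$pathway))
  if (length(bad_pw) > 0) {
    stop(sprintf("planted pathway(s) not in the pathway set: %s",
                 paste(bad_pw, collapse = ", ")))
  }
  bad_ct <- setdiff(truth$immune_pairs$cell_type, unique(signatures$cell_type))
  if (length(bad_ct) > 0) {
    stop(sprintf("planted cell type(s) not in the signature set: %s",
                 paste(bad_ct, collapse = ", ")))
  }
  if (anyDuplicated(truth$drug_pairs$drug)) stop("one planted gene per drug")
  if (anyDuplicated(truth$immune_pairs$cell_type)) {
    stop("one planted gene per immune cell type")
  }

  tumor_ids <- sprintf("T%04d", seq_len(n_tumor))
  normal_ids <- sprintf("N%04d", seq_len(n_normal))
  all_ids <- c(tumor_ids, normal_ids)
  cl_ids <- sprintf("CL%04d", seq_len(n_cell_lines))
  tp_ids <- sprintf("TP%03d", seq_len(n_timepoints))

  ## --- expression (log-normal; latent z kept for copula coupling) ---
  mu_g <- stats::setNames(stats::rnorm(length(genes), log(10), 1), genes)
  sdlog <- 0.5
  z_expr <- matrix(stats::rnorm(length(genes) * length(all_ids)),
                   nrow = length(genes),
                   dimnames = list(genes, all_ids))
  expr_vals <- exp(mu_g + sdlog * z_expr)
  expression <- omics_matrix(expr_vals, kind = "expression", units = "RPKM")

  ## --- methylation (logit-normal; silenced genes shifted and coupled) ---
  b0 <- stats::setNames(stats::runif(length(genes), 0.2, 0.6), genes)
  sigma_m <- 0.5
  z_meth <- matrix(stats::rnorm(length(genes) * length(all_ids)),
                   nrow = length(genes),
                   dimnames = list(genes, all_ids))
  mu_logit <- matrix(stats::qlogis(b0), nrow = length(genes),
                     ncol = length(all_ids), dimnames = list(genes, all_ids))
  for (i in seq_len(nrow(truth$silenced_genes))) {
    g <- truth$silenced_genes$gene[i]
    db <- truth$silenced_genes$delta_beta[i]
    rho <- truth$silenced_genes$meth_expr_rho[i]
    r <- latent_corr_for_spearman(rho)
    mu_logit[g, tumor_ids] <- stats::qlogis(min(0.95, b0[g] + db))
    z_meth[g, tumor_ids] <- mix_latent(z_expr[g, tumor_ids], r)
  }
  meth_vals <- stats::plogis(mu_logit + sigma_m * z_meth)
  methylation <- omics_matrix(meth_vals, kind = "methylation", units = "beta")

  ## --- RPPA (tumor subset; activation shift on positive regulators) ---
  rppa_ids <- tumor_ids[seq_len(max(8, round(rppa_fraction * n_tumor)))]
  proteins <- unique(pathways$protein)
  rppa_vals <- matrix(stats::rnorm(length(proteins) * length(rppa_ids)),
                      nrow = length(proteins),
                      dimnames = list(proteins, rppa_ids))
  for (i in seq_len(nrow(truth$activating_pairs))) {
    g <- truth$activating_pairs$gene[i]
    pw <- truth$activating_pairs$pathway[i]
    eff <- truth$activating_pairs$effect_sd[i]
    pos <- pathways$protein[pathways$pathway == pw & pathways$sign == 1]
    e <- expression$values[g, rppa_ids]
    high <- e > stats::median(e)
    rppa_vals[pos, ] <- rppa_vals[pos, , drop = FALSE] +
      eff * matrix(high, nrow = length(pos), ncol = length(rppa_ids),
                   byrow = TRUE)
  }
  rppa <- omics_matrix(rppa_vals, kind = "rppa", units = "normalized protein")

  ## --- CNV (independent per-gene category frequencies, tumors only) ---
  cnv_vals <- matrix(0, nrow = length(genes), ncol = n_tumor,
                     dimnames = list(genes, tumor_ids))
  for (g in genes) {
    p <- c(stats::runif(2, 0, 0.08), stats::runif(2, 0, 0.02))
    cnv_vals[g, ] <- sample(c(1, -1, 2, -2, 0), n_tumor, replace = TRUE,
                            prob = c(p, 1 - sum(p)))
  }
  cnv <- omics_matrix(cnv_vals, kind = "cnv", units = "status")

  ## --- survival (exponential; HR multiplier for high-expression groups) ---
  lambda0 <- log(2) / 730   # median event time ~2 years (days)
  mult <- rep(1, n_tumor)
  for (i in seq_len(nrow(truth$prognostic_genes))) {
    g <- truth$prognostic_genes$gene[i]
    hr <- truth$prognostic_genes$hazard_ratio[i]
    e <- expression$values[g, tumor_ids]
    mult <- mult * hr^(e > stats::median(e))
  }
  t_event <- stats::rexp(n_tumor, rate = lambda0 * mult)
  cens <- stats::runif(n_tumor, 0, 4.5 * stats::median(t_event))
  survival <- survival_table(tumor_ids, pmin(t_event, cens),
                             as.integer(t_event <= cens))

  ## --- cell lines: expression + AUC with copula-planted correlations ---
  z_cl <- matrix(stats::rnorm(length(panel) * n_cell_lines),
                 nrow = length(panel), dimnames = list(panel, cl_ids))
  cl_expr_vals <- exp(mu_g[panel] + 0.35 * z_cl)
  cellline_expression <- omics_matrix(cl_expr_vals, kind = "expression",
                                      units = "RPKM")
  drugs <- unique(c(truth$drug_pairs$drug, sprintf("drug_%d", seq_len(n_drugs))))
  auc_vals <- matrix(NA_real_, nrow = length(drugs), ncol = n_cell_lines,
                     dimnames = list(drugs, cl_ids))
  for (d in drugs) {
    j <- match(d, truth$drug_pairs$drug)
    z_d <- if (!is.na(j)) {
      mix_latent(z_cl[truth$drug_pairs$gene[j], ],
                 latent_corr_for_spearman(truth$drug_pairs$rho[j]))
    } else stats::rnorm(n_cell_lines)
    auc_vals[d, ] <- 0.5 + 0.1 * z_d
  }
  auc <- omics_matrix(auc_vals, kind = "auc", units = "AUC")

  ## --- immune infiltration scores (copula-coupled to planted genes) ---
  cell_types <- unique(signatures$cell_type)
  imm_vals <- matrix(NA_real_, nrow = length(cell_types), ncol = n_tumor,
                     dimnames = list(cell_types, tumor_ids))
  for (ct in cell_types) {
    j <- match(ct, truth$immune_pairs$cell_type)
    imm_vals[ct, ] <- if (!is.na(j)) {
      mix_latent(z_expr[truth$immune_pairs$gene[j], tumor_ids],
                 latent_corr_for_spearman(truth$immune_pairs$rho[j]))
    } else stats::rnorm(n_tumor)
  }
  immune_scores <- omics_matrix(imm_vals, kind = "expression",
                                units = "signature z")

  ## --- time series (cosine + noise on panel and background genes) ---
  ts_genes <- c(panel, bg_genes)
  times <- (seq_len(n_timepoints) - 1) * timeseries_span_hours / n_timepoints
  ts_vals <- matrix(stats::rnorm(length(ts_genes) * n_timepoints,
                                 sd = timeseries_noise_sd),
                    nrow = length(ts_genes),
                    dimnames = list(ts_genes, tp_ids))
  mesor <- 5
  ts_vals <- ts_vals + mesor
  for (i in seq_len(nrow(truth$rhythmic_genes))) {
    g <- truth$rhythmic_genes$gene[i]
    a <- truth$rhythmic_genes$amplitude[i]
    acro <- truth$rhythmic_genes$acrophase_hours[i]
    ts_vals[g, ] <- ts_vals[g, ] +
      a * cos(2 * pi * (times - acro) / config$rhythm_period_hours)
  }
  timeseries <- omics_matrix(ts_vals, kind = "expression", units = "RPKM")

  structure(list(expression = expression, methylation = methylation,
                 rppa = rppa, cnv = cnv, auc = auc,
                 cellline_expression = cellline_expression,
                 survival = survival, immune_scores = immune_scores,
                 timeseries = timeseries, times_hours = times,
                 tumor_ids = tumor_ids, normal_ids = normal_ids,
                 truth = truth, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d tumor / %d normal samples\n",
              length(x$tumor_ids), length(x$normal_ids)))
  if (!is.null(x$truth)) {
    cat(sprintf("  planted effects: %d (seed %d)\n",
                sum(vapply(unclass(x$truth), nrow, integer(1))),
                x$config$seed))
  }
  invisible(x)
}

#' Write a cohort bundle to a directory of TSV files
#'
#' Writes expression.tsv, methylation.tsv, rppa.tsv, cnv.tsv, auc.tsv,
#' cellline_expression.tsv, immune_scores.tsv, timeseries.tsv plus
#' survival.tsv (sample, time, event), samples.tsv (sample, group),
#' times.tsv (sample, hour) and truth.yaml.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(bundle$expression, file.path(dir, "expression.tsv"))
  write_matrix(bundle$methylation, file.path(dir, "methylation.tsv"))
  write_matrix(bundle$rppa, file.path(dir, "rppa.tsv"))
  write_matrix(bundle$cnv, file.path(dir, "cnv.tsv"))
  write_matrix(bundle$auc, file.path(dir, "auc.tsv"))
  write_matrix(bundle$cellline_expression,
               file.path(dir, "cellline_expression.tsv"))
  write_matrix(bundle$immune_scores, file.path(dir, "immune_scores.tsv"))
  write_matrix(bundle$timeseries, file.path(dir, "timeseries.tsv"))
  write_survival(bundle$survival, file.path(dir, "survival.tsv"))
  utils::write.table(
    data.frame(sample = c(bundle$tumor_ids, bundle$normal_ids),
               group = rep(c("tumor", "normal"),
                           c(length(bundle$tumor_ids),
                             length(bundle$normal_ids)))),
    file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample = sample_ids(bundle$timeseries),
               hour = bundle$times_hours),
    file.path(dir, "times.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  yaml::write_yaml(lapply(unclass(bundle$truth), function(df)
    lapply(as.list(df), as.vector)), file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Any subset of the assay files may be present; absent assays come back as
#' NULL, and downstream pipeline stages skip them.
#'
#' @param dir Cohort directory.
#' @return A list with the `cohort_bundle` fields (class `cohort_bundle`).
#' @export
read_cohort <- function(dir) {
  rd <- function(name, kind, units = "") {
    p <- file.path(dir, name)
    if (file.exists(p)) read_matrix(p, kind = kind, units = units) else NULL
  }
  samples_path <- file.path(dir, "samples.tsv")
  tumor_ids <- normal_ids <- character(0)
  if (file.exists(samples_path)) {
    sm <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
    tumor_ids <- sm$sample[sm$group == "tumor"]
    normal_ids <- sm$sample[sm$group == "normal"]
  }
  times_path <- file.path(dir, "times.tsv")
  times_hours <- if (file.exists(times_path)) {
    utils::read.delim(times_path, stringsAsFactors = FALSE)$hour
  } else NULL
  surv_path <- file.path(dir, "survival.tsv")
  structure(list(
    expression = rd("expression.tsv", "expression", "RPKM"),
    methylation = rd("methylation.tsv", "methylation", "beta"),
    rppa = rd("rppa.tsv", "rppa", "normalized protein"),
    cnv = rd("cnv.tsv", "cnv", "status"),
    auc = rd("auc.tsv", "auc", "AUC"),
    cellline_expression = rd("cellline_expression.tsv", "expression", "RPKM"),
    immune_scores = rd("immune_scores.tsv", "expression", "signature z"),
    timeseries = rd("timeseries.tsv", "expression", "RPKM"),
    times_hours = times_hours,
    survival = if (file.exists(surv_path)) read_survival(surv_path) else NULL,
    tumor_ids = tumor_ids, normal_ids = normal_ids,
    truth = NULL, config = NULL), class = "cohort_bundle")
}
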