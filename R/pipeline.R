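#' Run the full analysis pipeline over one or more cohorts
#'
#' For each cohort directory (the TSV layout of [write_cohort()]; any subset
#' of assays may be present), runs every stage whose inputs are available —
#' differential methylation, methylation-expression effect, CNV summary,
#' pathway-activity calls, median-split survival, tumor-vs-normal
#' differential expression, drug and immune correlation, and cosinor
#' rhythmicity — and writes each stage's table under
#' `out_dir/<cohort>/`. Multiple-testing correction is applied within each
#' cohort-by-stage family, never pooled across cohorts. A combined
#' long-format `results.tsv` (cohort, stage, gene, target, statistic,
#' effect, p_value, fdr, n) and a `manifest.yaml` (config, seed, package
#' version) sufficient to re-run bit-identically are written at the top
#' level. Stages lacking an input assay are skipped with a logged notice.
#'
#' @param config An [analysis_config()].
#' @param cohort_dirs Character vector of cohort directories; cohort names
#'   are the directory basenames.
#' @param out_dir Output directory (created if needed).
#' @param pathways Pathway annotation table; the default ships with the
#'   package. Immune correlation runs off the cohort's `immune_scores.tsv`
#'   (computed upstream with [score_immune_signatures()] or externally).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list (per cohort) of stage result tables.
#' @export
run_pipeline <- function(config, cohort_dirs, out_dir,
                         pathways = read_pathways(),
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  combined <- list()
  all_results <- list()
  for (cd in cohort_dirs) {
    cohort <- basename(cd)
    say("[%s] reading cohort from %s", cohort, cd)
    b <- read_cohort(cd)
    cout <- file.path(out_dir, cohort)
    dir.create(cout, recursive = TRUE, showWarnings = FALSE)
    stage_results <- list()
    add_long <- function(stage, df, gene, target, statistic, effect,
                         p_value, fdr, n) {
      if (nrow(df) == 0) return()
      combined[[length(combined) + 1]] <<- data.frame(
        cohort = cohort, stage = stage, gene = df[[gene]],
        target = df[[target]], statistic = df[[statistic]],
        effect = df[[effect]], p_value = df[[p_value]], fdr = df[[fdr]],
        n = df[[n]], stringsAsFactors = FALSE)
    }

    if (!is.null(b$methylation) && length(b$tumor_ids) > 0 &&
        length(b$normal_ids) > 0) {
      dm <- differential_methylation(b$methylation, b$tumor_ids,
                                     b$normal_ids, config)
      write_result_table(dm, file.path(cout, "methylation_diff.tsv"))
      say("[%s] differential methylation: %d genes, %d significant",
          cohort, nrow(dm), sum(dm$significant, na.rm = TRUE))
      stage_results$methylation_diff <- dm
      add_long("methylation_diff", dm, "gene", "target", "statistic",
               "effect", "p_value", "fdr", "n")
    } else say("[%s] differential methylation skipped (missing assay)", cohort)

    if (!is.null(b$methylation) && !is.null(b$expression) &&
        length(b$tumor_ids) > 0) {
      me <- methylation_expression_effect(b$methylation, b$expression,
                                          b$tumor_ids, config)
      write_result_table(me, file.path(cout, "meth_expr_effect.tsv"))
      say("[%s] methylation-expression effect: %d genes, %d significant",
          cohort, nrow(me), sum(me$significant, na.rm = TRUE))
      stage_results$meth_expr_effect <- me
      add_long("meth_expr_effect", me, "gene", "target", "statistic",
               "effect", "p_value", "fdr", "n")
    } else say("[%s] methylation-expression effect skipped (missing assay)",
               cohort)

    if (!is.null(b$cnv)) {
      cs <- summarize_cnv(b$cnv, config)
      cs <- cs[cs$gene %in% config$gene_panel, ]
      write_result_table(cs, file.path(cout, "cnv_summary.tsv"))
      say("[%s] CNV summary: %d genes, %d displayed", cohort, nrow(cs),
          sum(cs$displayed))
      stage_results$cnv_summary <- cs
    } else say("[%s] CNV summary skipped (missing assay)", cohort)

    if (!is.null(b$rppa) && !is.null(b$expression)) {
      pas <- compute_pas(normalize_rppa(b$rppa), pathways)
      pas_df <- data.frame(pathway = rownames(pas$values), pas$values,
                           check.names = FALSE, stringsAsFactors = FALSE)
      write_result_table(pas_df, file.path(cout, "pas_matrix.tsv"))
      pc <- call_pathway_effects(b$expression, pas, config)
      write_result_table(pc, file.path(cout, "pathway_calls.tsv"))
      say("[%s] pathway calls: %d tests, %d non-null", cohort, nrow(pc),
          sum(pc$direction != "none"))
      stage_results$pathway_calls <- pc
      add_long("pathway_activity", pc, "gene", "pathway", "pas_diff",
               "pas_diff", "p_value", "fdr", "n_high")
    } else say("[%s] pathway activity skipped (missing assay)", cohort)

    if (!is.null(b$expression) && !is.null(b$survival)) {
      sr <- survival_by_median_split(b$expression, b$survival, config)
      write_result_table(sr, file.path(cout, "survival_results.tsv"))
      say("[%s] survival: %d genes, %d significant at raw p", cohort,
          nrow(sr), sum(sr$significant))
      stage_results$survival <- sr
    } else say("[%s] survival skipped (missing assay)", cohort)

    if (!is.null(b$expression) && length(b$tumor_ids) > 0 &&
        length(b$normal_ids) > 0) {
      de <- differential_expression(b$expression, b$tumor_ids, b$normal_ids,
                                    config)
      write_result_table(de, file.path(cout, "diff_expr.tsv"))
      say("[%s] differential expression: %d genes, %d pass joint filter",
          cohort, nrow(de), sum(de$significant, na.rm = TRUE))
      stage_results$diff_expr <- de
      add_long("diff_expr", de, "gene", "target", "statistic", "effect",
               "p_value", "fdr", "n")
    } else say("[%s] differential expression skipped (missing groups)", cohort)

    if (!is.null(b$cellline_expression) && !is.null(b$auc)) {
      da <- drug_correlation(b$cellline_expression, b$auc, config)
      write_result_table(da, file.path(cout, "drug_associations.tsv"))
      say("[%s] drug associations: %d pairs, %d labelled", cohort, nrow(da),
          sum(da$label != "none"))
      stage_results$drug_associations <- da
      add_long("drug_association", da, "gene", "drug", "pearson_r",
               "fisher_z", "p_value", "fdr", "n")
    } else say("[%s] drug association skipped (missing assay)", cohort)

    if (!is.null(b$expression) && !is.null(b$immune_scores)) {
      ic <- immune_correlation(b$expression, b$immune_scores, config)
      write_result_table(ic, file.path(cout, "immune_correlations.tsv"))
      say("[%s] immune correlations: %d pairs, %d significant", cohort,
          nrow(ic), sum(ic$significant, na.rm = TRUE))
      stage_results$immune_correlations <- ic
      add_long("immune_correlation", ic, "gene", "target", "statistic",
               "effect", "p_value", "fdr", "n")
    } else say("[%s] immune correlation skipped (missing scores)", cohort)

    if (!is.null(b$timeseries) && !is.null(b$times_hours)) {
      rf <- rhythm_panel(b$timeseries, b$times_hours, config)
      write_result_table(rf, file.path(cout, "rhythm_fits.tsv"))
      say("[%s] rhythm fits: %d genes, %d rhythmic at FDR %.3g", cohort,
          nrow(rf), sum(rf$fdr <= config$fdr_threshold, na.rm = TRUE),
          config$fdr_threshold)
      stage_results$rhythm_fits <- rf
      add_long("rhythm", rf, "gene", "gene", "amplitude", "amplitude",
               "p_value", "fdr", "n")
    } else say("[%s] rhythm skipped (missing time series)", cohort)

    all_results[[cohort]] <- stage_results
  }
  results <- if (length(combined) > 0) do.call(rbind, combined) else
    data.frame(cohort = character(), stage = character(), gene = character(),
               target = character(), statistic = numeric(),
               effect = numeric(), p_value = numeric(), fdr = numeric(),
               n = integer(), stringsAsFactors = FALSE)
  results <- results[order(results$cohort, results$stage, results$gene,
                           results$target), ]
  write_result_table(results, file.path(out_dir, "results.tsv"))
  yaml::write_yaml(list(config = unclass(config),
                        cohorts = basename(cohort_dirs),
                        package = "clockscape",
                        version = as.character(utils::packageVersion("clockscape"))),
                   file.path(out_dir, "manifest.yaml"))
  say("wrote %s (%d rows) and manifest.yaml", file.path(out_dir, "results.tsv"),
      nrow(results))
  invisible(all_results)
}

#' Simulate a default set of synthetic cohorts
#'
#' Writes `n_cohorts` cohort directories (`cohort_1`, `cohort_2`, ...) under
#' `out_dir`, each generated with [generate_cohort()] under
#' [default_truth()] and seed `config$seed + i - 1`.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory.
#' @param n_cohorts Number of cohorts (default 3).
#' @param ... Passed to [generate_cohort()] (sizes, truth, ...).
#' @return Character vector of cohort directories, invisibly.
#' @export
simulate_cohorts <- function(config = analysis_config(), out_dir,
                             n_cohorts = 3, ...) {
  dirs <- character(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    args <- list(...)
    if (is.null(args$truth)) args$truth <- default_truth()
    b <- do.call(generate_cohort, c(list(config = cfg_i), args))
    dirs[i] <- file.path(out_dir, sprintf("cohort_%d", i))
    write_cohort(b, dirs[i])
  }
  invisible(dirs)
}
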