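#' Analysis configuration
#'
#' Bundles the tunable thresholds shared by all pipeline stages.
#'
#' @param gene_panel Character vector of panel gene IDs. Defaults to the nine
#'   core clock genes ([clock_gene_panel()]).
#' @param fdr_threshold FDR significance cutoff (default 0.05).
#' @param log2fc_threshold Differential-expression |log2 fold change| cutoff
#'   (default 1, i.e. two-fold).
#' @param cnv_display_fraction Minimum per-category CNV fraction for a gene to
#'   be flagged as displayed; strictly greater-than (default 0.05).
#' @param rhythm_period_hours Cosinor period in hours (default 24).
#' @param seed Integer RNG seed used by the synthetic cohort generator.
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(gene_panel = clock_gene_panel(),
                            fdr_threshold = 0.05,
                            log2fc_threshold = 1.0,
                            cnv_display_fraction = 0.05,
                            rhythm_period_hours = 24.0,
                            seed = 1L) {
  stopifnot(length(gene_panel) >= 1,
            fdr_threshold > 0, log2fc_threshold > 0,
            cnv_display_fraction > 0, rhythm_period_hours > 0)
  structure(list(gene_panel = as.character(gene_panel),
                 fdr_threshold = fdr_threshold,
                 log2fc_threshold = log2fc_threshold,
                 cnv_display_fraction = cnv_display_fraction,
                 rhythm_period_hours = rhythm_period_hours,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [analysis_config()] defaults.
#'
#' @param path Path to a YAML file whose keys mirror [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to YAML
#' @param config An `analysis_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read pathway definitions
#'
#' Pathway membership file: TSV with columns `pathway`, `protein`, `sign`
#' (+1 for positive regulators, -1 for negative regulators). Each pathway
#' must have at least one member and no duplicate proteins.
#'
#' @param path TSV path; defaults to the annotation shipped with the package
#'   (ten RPPA hallmark pathways: TSC/mTOR, RTK, RAS/MAPK, PI3K/AKT,
#'   Hormone ER, Hormone AR, EMT, DNA Damage Response, Cell Cycle, Apoptosis).
#' @return data.frame with columns pathway, protein, sign.
#' @export
read_pathways <- function(path = system.file("extdata", "pathways_rppa.tsv",
                                             package = "clockscape")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("pathway", "protein", "sign")
  if (!all(need %in% names(df))) {
    stop("pathway file must have columns: pathway, protein, sign")
  }
  df$sign <- as.integer(df$sign)
  if (!all(df$sign %in% c(-1L, 1L))) stop("sign must be +1 or -1")
  dup <- duplicated(df[, c("pathway", "protein")])
  if (any(dup)) {
    stop(sprintf("duplicate protein within pathway: %s/%s",
                 df$pathway[dup][1], df$protein[dup][1]))
  }
  df[, need]
}

#' Read immune signature marker lists
#'
#' TSV with columns `cell_type`, `gene`. The default file covers six immune
#' cell types (B cells, CD4+ T cells, CD8+ T cells, Neutrophils, Macrophages,
#' Dendritic cells) with canonical lineage markers.
#'
#' @param path TSV path; defaults to the marker file shipped with the package.
#' @return data.frame with columns cell_type, gene.
#' @export
read_immune_signatures <- function(path = system.file("extdata", "immune_markers.tsv",
                                                      package = "clockscape")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(df))) {
    stop("immune signature file must have columns: cell_type, gene")
  }
  df[, c("cell_type", "gene")]
}

#' Read a survival table
#'
#' TSV with columns `sample`, `time` (non-negative, days) and `event`
#' (0 censored / 1 death); an optional `group` column is carried through.
#'
#' @param path TSV path.
#' @return data.frame of class `survival_table`.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  survival_table(df$sample, df$time, df$event,
                 group = if ("group" %in% names(df)) df$group else NULL)
}

#' Construct a survival table
#'
#' @param sample_id Unique sample identifiers.
#' @param time Non-negative follow-up times (days).
#' @param event Event indicator: 0 censored, 1 death.
#' @param group Optional group label per sample.
#' @return data.frame of class `survival_table` with columns sample, time,
#'   event and (optionally) group.
#' @export
survival_table <- function(sample_id, time, event, group = NULL) {
  sample_id <- as.character(sample_id)
  time <- as.numeric(time)
  event <- as.integer(event)
  check_unique_ids(sample_id, "sample")
  if (any(is.na(time)) || any(time < 0)) stop("time must be non-negative")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0 or 1")
  df <- data.frame(sample = sample_id, time = time, event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- as.character(group)
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Write a survival table to TSV
#' @param x A `survival_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Long-format association result row shared by several stages.
association_record <- function(gene, target, statistic, effect, p_value, fdr = NA_real_,
                               n = NA_integer_) {
  data.frame(gene = gene, target = target, statistic = statistic,
             effect = effect, p_value = p_value, fdr = fdr, n = as.integer(n),
             stringsAsFactors = FALSE)
}

write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
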