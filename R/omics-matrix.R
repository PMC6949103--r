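#' Construct an omics matrix
#'
#' An `omics_matrix` is a features-by-samples numeric matrix with a declared
#' data kind. The kind fixes value-range invariants: methylation beta values
#' must lie in \[0, 1\]; copy-number status calls must be integers in
#' \{-2, -1, 0, +1, +2\} (homozygous deletion through homozygous
#' amplification). Missing values (`NA`) are permitted in every kind and
#' survive a write/read round trip.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param feature_ids Character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of unique column identifiers; defaults
#'   to `colnames(values)`.
#' @param kind One of `"expression"`, `"methylation"`, `"rppa"`, `"auc"`,
#'   `"cnv"`.
#' @param units Free-text unit label, e.g. `"RPKM"` or `"beta"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values),
                         kind = c("expression", "methylation", "rppa", "auc", "cnv"),
                         units = "") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) {
    if (nrow(values) == 0) feature_ids <- character(0)
    else stop("feature_ids are required (set dimnames or pass explicitly)")
  }
  if (is.null(sample_ids)) {
    if (ncol(values) == 0) sample_ids <- character(0)
    else stop("sample_ids are required (set dimnames or pass explicitly)")
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("length(feature_ids) != nrow(values)")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) != ncol(values)")
  }
  check_unique_ids(feature_ids, "feature")
  check_unique_ids(sample_ids, "sample")
  dimnames(values) <- list(feature_ids, sample_ids)
  check_kind_range(values, kind)
  structure(list(values = values, kind = kind, units = units),
            class = "omics_matrix")
}

check_unique_ids <- function(ids, axis) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s ID(s): %s", axis,
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

check_kind_range <- function(values, kind) {
  if (kind == "methylation") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "methylation beta out of [0,1]: value %g at feature '%s', sample '%s'",
        values[bad[1, , drop = FALSE]],
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
    }
  } else if (kind == "cnv") {
    bad <- which(!is.na(values) & !(values %in% c(-2, -1, 0, 1, 2)),
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "CNV status not in {-2,-1,0,1,2}: value %g at feature '%s', sample '%s'",
        values[bad[1, , drop = FALSE]],
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
    }
  }
  invisible(TRUE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> kind=%s units='%s' %d features x %d samples (%d missing)\n",
              x$kind, x$units, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an omics matrix
#' @param x An `omics_matrix`.
#' @return Character vector of IDs.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an omics matrix from TSV
#'
#' The expected layout is a tab-separated file with feature IDs in the first
#' column and sample IDs in the header row. Empty cells, `NA` and `NaN` all
#' parse as missing. Kind-specific range invariants are enforced on read;
#' duplicate IDs and out-of-range values are hard errors naming the offender.
#'
#' @param path Path to a TSV file.
#' @inheritParams omics_matrix
#' @return An `omics_matrix`.
#' @export
read_matrix <- function(path, kind = c("expression", "methylation", "rppa", "auc", "cnv"),
                        units = "") {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN", ""), quote = "",
                          comment.char = "")
  if (ncol(df) < 2) stop(sprintf("'%s': expected feature column plus >=1 sample column", path))
  features <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  omics_matrix(vals, feature_ids = features, sample_ids = colnames(df)[-1],
               kind = kind, units = units)
}

#' Write an omics matrix to TSV
#'
#' Inverse of [read_matrix()]: values, IDs and missingness round-trip exactly.
#'
#' @param x An `omics_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. Missing p-values propagate as
#' missing and do not count toward the number of tests; output order matches
#' input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of BH-adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
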