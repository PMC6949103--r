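#' Fit a single-component cosinor model
#'
#' Least-squares fit of
#' \deqn{y = M + \beta_c \cos(\omega t) + \beta_s \sin(\omega t), \quad
#'       \omega = 2\pi/\mathrm{period}}
#' The mesor M is the rhythm-adjusted mean, the amplitude is
#' \eqn{\sqrt{\beta_c^2 + \beta_s^2}}, and the acrophase — the clock time at
#' which the fitted cosine peaks — is
#' \eqn{(\mathrm{period}/2\pi)\,\mathrm{atan2}(\beta_s, \beta_c)} wrapped to
#' \[0, period). Rhythmicity is tested with the F-test of the two rhythm
#' coefficients against the intercept-only model on (2, n-3) degrees of
#' freedom.
#'
#' @param values Numeric response vector (e.g. expression of one gene).
#' @param times_hours Sampling times in hours, same length as `values`.
#' @param period_hours Period of the fitted rhythm (default 24).
#' @return Object of class `cosinor_fit`: list with mesor, amplitude,
#'   acrophase_hours, p_value, r_squared, n, period_hours, beta_cos,
#'   beta_sin.
#' @export
fit_cosinor <- function(values, times_hours, period_hours = 24) {
  stopifnot(length(values) == length(times_hours), period_hours > 0)
  ok <- !is.na(values) & !is.na(times_hours)
  y <- as.numeric(values[ok])
  t <- as.numeric(times_hours[ok])
  n <- length(y)
  if (n < 4) stop("need >=4 non-missing observations")
  phase <- (t %% period_hours)
  if (length(unique(round(phase, 9))) < 3) stop("degenerate sampling")
  w <- 2 * pi / period_hours
  X <- cbind(1, cos(w * t), sin(w * t))
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  fitted <- X %*% beta
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  if (sst <= .Machine$double.eps * max(1, sum(y^2))) {
    # flat signal: no rhythm evidence at all
    r2 <- 0; p <- 1
  } else if (ssr <= 1e-12 * sst) {
    r2 <- 0; p <- 1
  } else if (sse <= 1e-12 * sst) {
    r2 <- 1; p <- 0
  } else {
    r2 <- ssr / sst
    f <- (ssr / 2) / (sse / (n - 3))
    p <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  }
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  acro <- if (amp == 0) 0 else
    ((period_hours / (2 * pi)) * atan2(beta[3], beta[2])) %% period_hours
  structure(list(mesor = unname(beta[1]), amplitude = unname(amp),
                 acrophase_hours = unname(acro), p_value = p,
                 r_squared = r2, n = n, period_hours = period_hours,
                 beta_cos = unname(beta[2]), beta_sin = unname(beta[3])),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(paste0("Cosinor fit (period %.4g h, n = %d)\n",
                     "  mesor     %.4g\n  amplitude %.4g\n",
                     "  acrophase %.4g h\n  R-squared %.3f\n  p-value   %.3g\n"),
              x$period_hours, x$n, x$mesor, x$amplitude, x$acrophase_hours,
              x$r_squared, x$p_value))
  invisible(x)
}

#' Cosinor rhythmicity across a gene panel
#'
#' Fits [fit_cosinor()] to every feature of a time-stamped expression matrix
#' and applies BH correction across the panel. Per-gene fit failures (e.g.
#' too few non-missing observations) downgrade to rows of missing values.
#'
#' @param timeseries `omics_matrix` (genes x timepoint samples).
#' @param times_hours Numeric vector of sampling times (hours), one per
#'   column of `timeseries`.
#' @param config An [analysis_config()]; `rhythm_period_hours` sets the
#'   fitted period.
#' @return data.frame with columns gene, mesor, amplitude, acrophase_hours,
#'   p_value, fdr, r_squared, n.
#' @export
rhythm_panel <- function(timeseries, times_hours, config = analysis_config()) {
  stopifnot(inherits(timeseries, "omics_matrix"),
            length(times_hours) == ncol(timeseries$values))
  genes <- rownames(timeseries$values)
  rows <- lapply(genes, function(g) {
    fit <- tryCatch(fit_cosinor(timeseries$values[g, ], times_hours,
                                config$rhythm_period_hours),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(gene = g, mesor = NA_real_, amplitude = NA_real_,
                        acrophase_hours = NA_real_, p_value = NA_real_,
                        r_squared = NA_real_, n = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    data.frame(gene = g, mesor = fit$mesor, amplitude = fit$amplitude,
               acrophase_hours = fit$acrophase_hours, p_value = fit$p_value,
               r_squared = fit$r_squared, n = fit$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(gene = character(), mesor = numeric(),
                      amplitude = numeric(), acrophase_hours = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      r_squared = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  res$fdr <- benjamini_hochberg(res$p_value)
  res[, c("gene", "mesor", "amplitude", "acrophase_hours", "p_value", "fdr",
          "r_squared", "n")]
}
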