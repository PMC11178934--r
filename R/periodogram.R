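#' Aggregate a binned recording into an activity series
#'
#' Counts `MOVING` bins per aggregation window — the activity metric fed
#' to the chi-square periodogram (default: counts per 30 min).
#'
#' @param binned A `binned_movement`.
#' @param agg_bin_s Aggregation window, seconds (multiple of the bin
#'   width).
#' @return Numeric vector of counts, one per window.
#' @export
activity_series <- function(binned, agg_bin_s = 1800) {
  if (agg_bin_s %% binned$bin_s != 0)
    stop("agg_bin_s must be a multiple of the recording bin width")
  per <- agg_bin_s %/% binned$bin_s
  n <- length(binned$symbols) %/% per
  moving <- as.integer(binned$symbols[seq_len(n * per)] == "MOVING")
  as.numeric(rowsum(moving, rep(seq_len(n), each = per)))
}

#' Chi-square periodogram
#'
#' For every candidate period of `P` bins the series is folded into `P`
#' phase columns with `K_h` entries each, and
#' `Q_P = sum_h K_h (M_h - Mbar)^2 / sigma2` with
#' `sigma2 = sum_i (x_i - Mbar)^2 / N`, referred to a chi-square
#' distribution with `P - 1` degrees of freedom. By default all data are
#' used (unequal column counts); `complete_cycles = TRUE` truncates the
#' series to whole cycles first. A noiseless periodic signal folded over
#' complete cycles gives `Q = N` exactly.
#'
#' @param activity Numeric per-bin activity series (e.g. from
#'   [activity_series()]).
#' @param bin_s Width of one bin of `activity`, in seconds.
#' @param p_min_h,p_max_h Candidate period range, hours; candidates lie
#'   on the bin grid.
#' @param alpha Significance level of the chi-square threshold.
#' @param correction Multiplicity handling for the significance threshold
#'   across the candidate-period grid: `"bonferroni"` (default) divides
#'   `alpha` by the number of candidate periods, so the family-wise rate
#'   of a spurious rhythmicity call stays near `alpha`; `"none"` applies
#'   `alpha` per period (appropriate when testing a single prespecified
#'   period).
#' @param complete_cycles Truncate to whole cycles per candidate period.
#' @return Object of class `periodogram_result`: `periods_h`, `Q`, `df`,
#'   `threshold`, `power` (`Q - threshold`), `alpha`, `peak_period_h`.
#' @export
chi_square_periodogram <- function(activity, bin_s = 1800, p_min_h = 16,
                                   p_max_h = 32, alpha = 0.05,
                                   correction = c("bonferroni", "none"),
                                   complete_cycles = FALSE) {
  correction <- match.arg(correction)
  x <- as.numeric(activity)
  N <- length(x)
  p_max_bins <- floor(p_max_h * 3600 / bin_s)
  p_min_bins <- ceiling(p_min_h * 3600 / bin_s)
  if (N < 2 * p_max_bins)
    stop("series too short: need at least 2 * p_max (", 2 * p_max_bins,
         " bins), got ", N)
  if (stats::var(x) == 0)
    stop("zero-variance activity series: no rhythm detectable")

  periods <- p_min_bins:p_max_bins
  Q <- vapply(periods, function(P) {
    xs <- if (complete_cycles) x[seq_len((N %/% P) * P)] else x
    n <- length(xs)
    h <- ((seq_len(n) - 1) %% P) + 1
    K <- tabulate(h, nbins = P)
    M <- as.numeric(rowsum(xs, h)) / K
    Mbar <- mean(xs)
    sigma2 <- sum((xs - Mbar)^2) / n
    sum(K * (M - Mbar)^2) / sigma2
  }, numeric(1))
  df <- periods - 1
  alpha_eff <- if (correction == "bonferroni") alpha / length(periods) else alpha
  threshold <- qchisq(1 - alpha_eff, df)
  power <- Q - threshold
  res <- structure(list(periods_h = periods * bin_s / 3600, Q = Q, df = df,
                        threshold = threshold, power = power, alpha = alpha),
                   class = "periodogram_result")
  res$peak_period_h <- peak_period(res)
  res
}

#' Peak period of a periodogram
#'
#' The period maximizing `power = Q - threshold` among significant
#' periods (`power > 0`); `NA` when no period is significant.
#'
#' @param result A `periodogram_result`.
#' @return Period in hours, or `NA`.
#' @export
peak_period <- function(result) {
  stopifnot(inherits(result, "periodogram_result"))
  sig <- result$power > 0
  if (!any(sig)) return(NA_real_)
  result$periods_h[sig][which.max(result$power[sig])]
}

#' Rhythmicity call
#'
#' `TRUE` when the periodogram has a significant peak (see
#' [peak_period()]).
#'
#' @param result A `periodogram_result`.
#' @return Logical.
#' @export
is_rhythmic <- function(result) {
  !is.na(peak_period(result))
}

#' @export
print.periodogram_result <- function(x, ...) {
  cat("<periodogram_result>", length(x$periods_h), "candidate periods in [",
      min(x$periods_h), ",", max(x$periods_h), "] h\n")
  if (is.na(x$peak_period_h)) cat("  no significant period at alpha =",
                                  x$alpha, "\n")
  else cat("  peak:", x$peak_period_h, "h (power",
           round(max(x$power), 1), ")\n")
  invisible(x)
}
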