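#' Sleep-deprivation efficiency
#'
#' Fraction of baseline sleep lost during the deprivation window:
#' `1 - sleep(SD) / sleep(baseline)`, with the two windows covering the
#' same zeitgeber span on different days. Negative values (more sleep
#' during deprivation than baseline) are clipped to 0 and flagged.
#'
#' @param binned A `binned_movement` covering both windows.
#' @param sd_window `c(start_h, end_h)` of the deprivation, hours from
#'   recording start.
#' @param baseline_window Matched baseline window, hours from start.
#' @return List: `efficiency` in `[0, 1]` (or `NA` when the fly slept
#'   nothing at baseline), `undefined`, `clipped`, and the two sleep
#'   amounts in minutes.
#' @export
sd_efficiency <- function(binned, sd_window, baseline_window) {
  stopifnot(diff(sd_window) == diff(baseline_window))
  scored <- score_sleep_5min(binned)
  abs_h <- (seq_along(scored$sleep) - 1) * binned$bin_s / 3600
  mins <- function(w) sum(scored$sleep[abs_h >= w[1] & abs_h < w[2]]) *
    binned$bin_s / 60
  base <- mins(baseline_window)
  sd <- mins(sd_window)
  if (base == 0)
    return(list(efficiency = NA_real_, undefined = TRUE, clipped = FALSE,
                sleep_sd_min = sd, sleep_baseline_min = base))
  eff <- 1 - sd / base
  list(efficiency = max(0, min(1, eff)), undefined = FALSE,
       clipped = eff < 0, sleep_sd_min = sd, sleep_baseline_min = base)
}

#' Exact Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with mid-rank ties and an exact permutation
#' p-value: the probability, over all equally likely assignments of the
#' pooled values to the two groups, of a rank sum at least as far from
#' its null expectation as observed. The distribution is obtained by full
#' enumeration when `choose(n + m, n) <= enum_limit`, by the
#' shift-algorithm convolution when the pooled sample is at most
#' `shift_limit`, and otherwise by seeded Monte-Carlo permutation.
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param enum_limit Enumeration cutoff on `choose(n + m, n)`.
#' @param shift_limit Pooled-size cutoff for the exact convolution.
#' @param n_mc Monte-Carlo permutations.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return List of class `drosleep_test`: `statistic` (rank sum of `x`),
#'   `p`, `method`, `n`, `tie_flag`.
#' @export
exact_wilcoxon <- function(x, y, alternative = c("two.sided", "greater", "less"),
                           enum_limit = 1e5, shift_limit = 200,
                           n_mc = 1e5, seed = 1) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  nx <- length(x); N <- length(pooled)
  r <- rank(pooled)  # mid-ranks
  W <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  tie_flag <- anyDuplicated(pooled) > 0
  eps <- 1e-9

  tail_prob <- function(ws, wt = NULL) {
    # ws: all achievable rank sums with weights wt (NULL = equally likely)
    if (is.null(wt)) wt <- rep(1, length(ws))
    tot <- sum(wt)
    switch(alternative,
      two.sided = sum(wt[abs(ws - mu) >= abs(W - mu) - eps]) / tot,
      greater = sum(wt[ws >= W - eps]) / tot,
      less = sum(wt[ws <= W + eps]) / tot)
  }

  if (choose(N, nx) <= enum_limit) {
    sums <- combn(N, nx, FUN = function(i) sum(r[i]))
    p <- tail_prob(sums)
    method <- "exact (enumeration)"
  } else if (N <= shift_limit) {
    r2 <- as.integer(round(2 * r))  # mid-ranks doubled are integers
    S <- sum(r2)
    f <- matrix(0, nrow = nx + 1, ncol = S + 1)
    f[1, 1] <- 1
    for (it in seq_len(N)) {
      v <- r2[it]
      kmax <- min(it, nx)
      for (k in kmax:1)
        f[k + 1, (v + 1):(S + 1)] <- f[k + 1, (v + 1):(S + 1)] +
          f[k, 1:(S + 1 - v)]
    }
    wt <- f[nx + 1, ]
    ws <- (0:S) / 2
    keep <- wt > 0
    p <- tail_prob(ws[keep], wt[keep])
    method <- "exact (shift algorithm)"
  } else {
    set.seed(seed)
    sums <- replicate(n_mc, sum(r[sample.int(N, nx)]))
    p <- tail_prob(c(W, sums))  # add the observed permutation
    method <- sprintf("Monte-Carlo (%d permutations)", as.integer(n_mc))
  }
  structure(list(statistic = W, p = min(1, p), method = method,
                 n = c(n_x = length(x), n_y = length(y)),
                 tie_flag = tie_flag),
            class = "drosleep_test")
}

#' @export
print.drosleep_test <- function(x, ...) {
  cat("<test>", x$method, "\n  statistic =", format(x$statistic),
      ", p =", format.pval(x$p), ", n =", paste(x$n, collapse = "/"), "\n")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone in the sorted order, capped at 1,
#' input order preserved.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Rebound sleep comparison in a recovery window
#'
#' Per-fly sleep minutes (five-minute rule) in a zeitgeber window of the
#' recovery day, compared between deprived and control flies with the
#' exact Wilcoxon rank-sum test. Apply quality control ([qc_cohort()])
#' before calling.
#'
#' @param deprived,control Lists of `binned_movement` objects.
#' @param window ZT window, default `c(0, 3)`.
#' @param recovery_day 1-based recording day of the recovery window.
#' @return List of class `rebound_result`: per-group minutes,
#'   `diff_medians` (deprived - control), `p_raw`, `p_adjusted` (`NA`
#'   until adjusted across comparisons), `n`, `method`.
#' @export
rebound_window_sleep <- function(deprived, control, window = c(0, 3),
                                 recovery_day = 3) {
  if (length(deprived) == 0 || length(control) == 0)
    stop("empty group in rebound comparison")
  mins <- function(b) sleep_amount(score_sleep_5min(b), window = window,
                                   day = recovery_day)
  dep <- vapply(deprived, mins, numeric(1))
  ctl <- vapply(control, mins, numeric(1))
  test <- exact_wilcoxon(dep, ctl)
  structure(list(
    deprived_min = dep, control_min = ctl,
    diff_medians = median(dep) - median(ctl),
    direction = if (median(dep) >= median(ctl)) "deprived > control"
                else "deprived < control",
    p_raw = test$p, p_adjusted = NA_real_, method = test$method,
    n = c(deprived = length(dep), control = length(ctl))
  ), class = "rebound_result")
}

#' @export
print.rebound_result <- function(x, ...) {
  cat("<rebound_result> n =", paste(x$n, collapse = "/"),
      "\n  median sleep (deprived/control):", median(x$deprived_min), "/",
      median(x$control_min), "min\n  p_raw =", format.pval(x$p_raw), "\n")
  invisible(x)
}

#' Bootstrapped confidence band for a cohort time course
#'
#' Resamples flies (rows) with replacement and reports the percentile
#' interval of the per-bin cohort mean.
#'
#' @param mat Numeric matrix, flies in rows, time bins in columns.
#' @param n_boot Bootstrap replicates.
#' @param level Confidence level (e.g. 0.95).
#' @param seed Seed.
#' @return data.table: `bin`, `mean`, `lo`, `hi`.
#' @export
bootstrap_timecourse_ci <- function(mat, n_boot = 1000, level = 0.95,
                                    seed = 1) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop("bootstrap over flies needs at least 2 flies")
  set.seed(seed)
  means <- matrix(0, n_boot, ncol(mat))
  for (b in seq_len(n_boot))
    means[b, ] <- colMeans(mat[sample.int(n, n, replace = TRUE), , drop = FALSE])
  a <- (1 - level) / 2
  data.table::data.table(
    bin = seq_len(ncol(mat)),
    mean = colMeans(mat),
    lo = apply(means, 2, quantile, probs = a),
    hi = apply(means, 2, quantile, probs = 1 - a))
}

#' Sleep-pressure trend over a chronic deprivation
#'
#' The number of delivered stimuli per day proxies sleep pressure. Each
#' fly contributes a Spearman rank correlation of its daily counts with
#' the day index (0 when its counts are constant); the cohort trend is a
#' Wilcoxon signed-rank test of the per-fly correlations against zero.
#'
#' @param counts Matrix of stimulus counts, flies in rows, days in
#'   columns (>= 3 days).
#' @return List of class `drosleep_test`: `statistic` (signed-rank V),
#'   `p`, `direction` (sign of the median correlation), `rho` (per fly),
#'   `method`, `n`.
#' @export
sleep_pressure_trend <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3) stop("need at least 3 days per fly")
  day <- seq_len(ncol(counts))
  rho <- apply(counts, 1, function(v) {
    if (stats::sd(v) == 0) 0 else suppressWarnings(cor(v, day, method = "spearman"))
  })
  if (all(rho == 0)) {
    p <- 1; V <- NA_real_
  } else {
    ht <- suppressWarnings(wilcox.test(rho, mu = 0))
    p <- ht$p.value; V <- unname(ht$statistic)
  }
  structure(list(statistic = V, p = p,
                 direction = sign(median(rho)), rho = rho,
                 method = "Spearman per fly + Wilcoxon signed-rank",
                 n = length(rho)),
            class = "drosleep_test")
}

#' Log-rank comparison of survival between groups
#'
#' Standard log-rank chi-square via [survival::survdiff()]; with more
#' than two groups, pairwise comparisons with FDR adjustment are added.
#'
#' @param time Event/censoring times.
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @param group Group labels.
#' @return List of class `logrank_result`: `statistic`, `df`, `p`,
#'   `no_events` flag, and `pairwise` (data.table, or `NULL` for two
#'   groups).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (sum(event) == 0)
    return(structure(list(statistic = 0, df = nlevels(group) - 1, p = 1,
                          no_events = TRUE, pairwise = NULL),
                     class = "logrank_result"))
  sd_all <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- pchisq(sd_all$chisq, df = nlevels(group) - 1, lower.tail = FALSE)
  pairwise <- NULL
  if (nlevels(group) > 2) {
    combos <- combn(levels(group), 2)
    rows <- lapply(seq_len(ncol(combos)), function(i) {
      sel <- group %in% combos[, i]
      g2 <- droplevels(group[sel])
      if (sum(event[sel]) == 0)
        return(data.table::data.table(group1 = combos[1, i],
                                      group2 = combos[2, i],
                                      chisq = 0, p_raw = 1))
      sd2 <- survival::survdiff(survival::Surv(time[sel], event[sel]) ~ g2)
      data.table::data.table(group1 = combos[1, i], group2 = combos[2, i],
                             chisq = sd2$chisq,
                             p_raw = pchisq(sd2$chisq, 1, lower.tail = FALSE))
    })
    pairwise <- data.table::rbindlist(rows)
    pairwise$p_adjusted <- fdr_adjust(pairwise$p_raw)
  }
  structure(list(statistic = sd_all$chisq, df = nlevels(group) - 1, p = p,
                 no_events = FALSE, pairwise = pairwise),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank_result> chisq =", format(x$statistic), "df =", x$df,
      "p =", format.pval(x$p), if (x$no_events) "(no events)" else "", "\n")
  invisible(x)
}
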