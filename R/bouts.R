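# maximal runs of a logical/character vector, as (start, end) indices
run_table <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.table::data.table(value = r$values, start = end - r$lengths + 1,
                         end = end, length = r$lengths)
}

#' Extract stage bouts from a decoded sequence
#'
#' Maximal runs of constant decoded stage. For every bout the maximum
#' consecutive non-moving (micro or immobile) time within the bout is
#' recorded, and bouts truncated by the recording boundaries are flagged
#' `censored` (their true duration is unknown).
#'
#' @param stage_seq A `stage_sequence` from [hmm_decode()].
#' @param binned The matching `binned_movement` (same length).
#' @return data.table: `fly_id`, `stage`, `start_zt`, `duration_s`,
#'   `max_consecutive_inactivity_s`, `censored`.
#' @export
extract_stage_bouts <- function(stage_seq, binned) {
  stopifnot(length(stage_seq$stages) == length(binned$symbols))
  bin_s <- binned$bin_s
  inactive <- binned$symbols != "MOVING"
  rt <- run_table(stage_seq$stages)
  n <- length(stage_seq$stages)
  max_inact <- vapply(seq_len(nrow(rt)), function(i) {
    seg <- inactive[rt$start[i]:rt$end[i]]
    r <- rle(seg)
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) else 0L
  }, integer(1))
  data.table::data.table(
    fly_id = stage_seq$fly_id,
    stage = rt$value,
    start_zt = binned$zt[rt$start],
    duration_s = rt$length * bin_s,
    max_consecutive_inactivity_s = max_inact * bin_s,
    censored = rt$start == 1 | rt$end == n
  )
}

#' Light-to-deep sleep time ratio
#'
#' Total time decoded as light sleep divided by total time decoded as deep
#' sleep.
#'
#' @param bouts Stage bout table from [extract_stage_bouts()] (possibly
#'   pooled over flies).
#' @return Ratio (scalar).
#' @export
light_deep_ratio <- function(bouts) {
  light <- sum(bouts$duration_s[bouts$stage == "LIGHT_SLEEP"])
  deep <- sum(bouts$duration_s[bouts$stage == "DEEP_SLEEP"])
  if (deep <= 0)
    stop("light:deep ratio undefined: no deep sleep in the bout table")
  light / deep
}

#' Mean stage-fraction time course over the day
#'
#' Pools decoded bins from all flies into ZT bins of width `bin_h` and
#' reports the fraction of time spent in each stage per ZT bin; fractions
#' sum to one within every bin.
#'
#' @param stage_seqs List of `stage_sequence` objects (with `zt`).
#' @param bin_h ZT bin width in hours.
#' @return data.table: `zt_bin` (bin start, hours), `stage`, `fraction`.
#' @export
stage_fraction_timecourse <- function(stage_seqs, bin_h = 1) {
  stopifnot(length(stage_seqs) >= 1)
  dt <- data.table::rbindlist(lapply(stage_seqs, function(s) {
    stopifnot(!is.null(s$zt))
    data.table::data.table(zt_bin = floor(s$zt / bin_h) * bin_h,
                           stage = s$stages)
  }))
  counts <- dt[, .N, by = c("zt_bin", "stage")]
  grid <- data.table::CJ(zt_bin = unique(counts$zt_bin), stage = STATES)
  counts <- counts[grid, on = c("zt_bin", "stage")]
  counts[is.na(N), N := 0L]
  counts[, fraction := N / sum(N), by = zt_bin]
  data.table::setorderv(counts, c("zt_bin", "stage"))
  counts[, list(zt_bin, stage, fraction)]
}

# maximal non-moving runs with bin indices; censored = touching a boundary
immobility_runs <- function(binned, min_s = 300) {
  rt <- run_table(binned$symbols != "MOVING")
  rt <- rt[rt$value & rt$length * binned$bin_s >= min_s, ]
  rt$censored <- rt$start == 1 | rt$end == length(binned$symbols)
  rt
}

#' Agreement of the five-minute rule with model staging
#'
#' Over all maximal non-moving runs of at least `min_s` seconds, the
#' percentage whose bins are all decoded as sleep (light or deep). Runs
#' truncated by the recording boundaries are excluded by default (their
#' decoded labels depend on the unobserved continuation).
#'
#' @param stage_seq A `stage_sequence`.
#' @param binned The matching `binned_movement`.
#' @param min_s Immobility threshold in seconds (default 300).
#' @param include_censored Include boundary-truncated runs.
#' @return Percentage in `[0, 100]`, or `NA` (with a message) when no
#'   qualifying run exists.
#' @export
fraction_long_immobility_bouts_as_sleep <- function(stage_seq, binned,
                                                    min_s = 300,
                                                    include_censored = FALSE) {
  stopifnot(length(stage_seq$stages) == length(binned$symbols))
  rt <- immobility_runs(binned, min_s)
  if (!include_censored) rt <- rt[!rt$censored, ]
  if (nrow(rt) == 0) {
    message("no immobility runs of at least ", min_s, " s: fraction undefined")
    return(NA_real_)
  }
  all_sleep <- vapply(seq_len(nrow(rt)), function(i)
    all(stage_seq$stages[rt$start[i]:rt$end[i]] %in% SLEEP_STATES),
    logical(1))
  100 * mean(all_sleep)
}

#' Consecutive inactivity within deep-sleep bouts
#'
#' Summary behind the claim that deep-sleep episodes feature at least
#' eight minutes of consecutive inactivity: the minimum over deep bouts of
#' the maximum consecutive non-moving time, and the percentage of deep
#' bouts reaching `min_s` seconds. Censored bouts are excluded by default.
#'
#' @param bouts Stage bout table from [extract_stage_bouts()].
#' @param min_s Inactivity floor in seconds (default 480 = 8 min).
#' @param include_censored Include boundary-truncated bouts.
#' @return List: `min_inactivity_s`, `pct_at_least`, `n_bouts`.
#' @export
min_inactivity_in_deep_bouts <- function(bouts, min_s = 480,
                                         include_censored = FALSE) {
  deep <- bouts[bouts$stage == "DEEP_SLEEP", ]
  if (!include_censored) deep <- deep[!deep$censored, ]
  if (nrow(deep) == 0) stop("no deep-sleep bouts in the bout table")
  x <- deep$max_consecutive_inactivity_s
  list(min_inactivity_s = min(x), pct_at_least = 100 * mean(x >= min_s),
       n_bouts = nrow(deep))
}
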