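#' Convert experiment time to zeitgeber time
#'
#' @param t Time in seconds from experiment start.
#' @param lights_on_offset Seconds at which lights came on (ZT 0).
#' @return Hours in `[0, 24)`.
#' @export
#' @examples
#' to_zt(27 * 3600, 0) # 3
to_zt <- function(t, lights_on_offset = 0) {
  ((t - lights_on_offset) / 3600) %% 24
}

#' Bin a recording into the movement alphabet
#'
#' Velocity recordings are reduced per bin by their maximum: `MOVING` if
#' the bin maximum reaches `moving_thresh`, `MICRO` if it lies in
#' `[micro_thresh, moving_thresh)`, `IMMOBILE` otherwise. Symbolic
#' recordings at the target bin width pass through unchanged; at finer
#' resolution the same maximum semantics apply on the symbol severity
#' (`MOVING > MICRO > IMMOBILE`). Bins are half-open `[t, t + bin_s)`,
#' left-aligned, 0-based from recording start; zeitgeber time is attached
#' after binning.
#'
#' @param rec An [activity_recording].
#' @param bin_s Bin width in seconds; must be a multiple of the recording
#'   step.
#' @param micro_thresh,moving_thresh Velocity thresholds,
#'   `moving_thresh > micro_thresh >= 0`. The tracker's native units are
#'   not standardized; the defaults (1 mm/s micro, 5 mm/s moving) are
#'   configurable.
#' @return Object of class `binned_movement`: `fly_id`, `bin_s`, `symbols`
#'   and per-bin `zt` (hours, bin start).
#' @export
bin_movement <- function(rec, bin_s = 10, micro_thresh = 1, moving_thresh = 5) {
  stopifnot(inherits(rec, "activity_recording"))
  if (moving_thresh <= micro_thresh || micro_thresh < 0)
    stop("thresholds must satisfy moving_thresh > micro_thresh >= 0")
  if (bin_s %% rec$step_s != 0)
    stop("bin_s (", bin_s, ") must be a multiple of the recording step (",
         rec$step_s, ")")
  per <- bin_s %/% rec$step_s
  n_bins <- length(rec$t) %/% per
  v <- rec$value[seq_len(n_bins * per)]

  if (per == 1 && is.character(v)) {
    symbols <- v  # already symbolized on the target grid
  } else {
    if (is.character(v)) {
      sev <- c(IMMOBILE = 0, MICRO = 1, MOVING = 2)[v]
    } else {
      sev <- findInterval(v, c(micro_thresh, moving_thresh))
    }
    # per-bin maximum via column-wise matrix reduction
    sm <- matrix(sev, nrow = per)
    bin_sev <- sm[1, ]
    if (per > 1) for (r in 2:per) bin_sev <- pmax(bin_sev, sm[r, ])
    symbols <- unname(c("IMMOBILE", "MICRO", "MOVING")[bin_sev + 1])
  }

  t0 <- rec$t[1] + (seq_len(n_bins) - 1) * bin_s
  structure(list(fly_id = rec$fly_id, bin_s = bin_s, symbols = symbols,
                 zt = to_zt(t0, rec$lights_on_offset)),
            class = "binned_movement")
}

#' @export
print.binned_movement <- function(x, ...) {
  cat("<binned_movement>", x$fly_id, ":", length(x$symbols), "bins @",
      x$bin_s, "s\n")
  invisible(x)
}

#' Dead-fly detection
#'
#' A fly is scored dead when the final `tail_h` hours of its binned
#' recording contain no `MOVING` or `MICRO` bin at all. Micro-movements
#' count as signs of life here even though they count as inactivity for
#' sleep scoring.
#'
#' @param binned A `binned_movement` object.
#' @param tail_h Length of the terminal window, hours.
#' @return Logical.
#' @export
detect_dead <- function(binned, tail_h = 12) {
  n_tail <- as.integer(tail_h * 3600 / binned$bin_s)
  if (length(binned$symbols) <= n_tail)
    stop("recording shorter than tail_h = ", tail_h, " h")
  tail_sym <- tail(binned$symbols, n_tail)
  all(tail_sym == "IMMOBILE")
}

#' Score sleep by the five-minute immobility rule
#'
#' Every maximal run of non-moving bins (`MICRO` or `IMMOBILE`) lasting at
#' least `min_s` seconds is scored asleep over its full extent; all other
#' bins are awake. Micro-movements count toward immobility, matching the
#' probing protocol's notion of total-or-partial inactivity.
#'
#' @param binned A `binned_movement` object; `bin_s` must divide `min_s`.
#' @param min_s Minimum immobility for sleep, seconds (default 300).
#' @return Object of class `sleep_series`: `fly_id`, `bin_s`, `zt`,
#'   logical `sleep` per bin, and `bouts` (data.table `fly_id`,
#'   `start_zt`, `duration_s`, `kind = "SLEEP_5MIN"`).
#' @export
score_sleep_5min <- function(binned, min_s = 300) {
  stopifnot(inherits(binned, "binned_movement"))
  if (min_s %% binned$bin_s != 0)
    stop("bin_s (", binned$bin_s, ") must divide the sleep threshold (",
         min_s, " s)")
  min_bins <- min_s %/% binned$bin_s
  inactive <- binned$symbols != "MOVING"
  r <- rle(inactive)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_bins
  sleep <- rep(FALSE, length(inactive))
  for (i in which(keep)) sleep[starts[i]:ends[i]] <- TRUE
  bouts <- data.table::data.table(
    fly_id = binned$fly_id,
    start_zt = binned$zt[starts[keep]],
    duration_s = r$lengths[keep] * binned$bin_s,
    kind = "SLEEP_5MIN")
  structure(list(fly_id = binned$fly_id, bin_s = binned$bin_s,
                 zt = binned$zt, sleep = sleep, bouts = bouts),
            class = "sleep_series")
}

# bins falling inside a ZT window; an inverted window wraps past midnight
zt_in_window <- function(zt, window) {
  lo <- window[1]; hi <- window[2]
  if (any(c(lo, hi) < 0) || any(c(lo, hi) > 24))
    stop("window bounds must lie in [0, 24]")
  if (lo <= hi) zt >= lo & zt < hi else zt >= lo | zt < hi
}

#' Sleep amount in a zeitgeber window
#'
#' Sums asleep time within a ZT window, in minutes. An inverted window
#' (`lo > hi`) wraps past midnight. With `day` set, only bins of that
#' recording day (1-based, counted in 24 h blocks from the start of the
#' series) are included.
#'
#' @param sleep A `sleep_series` (from [score_sleep_5min()]) or a logical
#'   vector accompanied by `zt` and `bin_s`.
#' @param window `c(lo, hi)` in ZT hours within `[0, 24]`.
#' @param day Optional 1-based recording day.
#' @param zt,bin_s Required when `sleep` is a bare logical vector.
#' @return Minutes asleep.
#' @export
sleep_amount <- function(sleep, window = c(0, 24), day = NULL,
                         zt = NULL, bin_s = NULL) {
  if (inherits(sleep, "sleep_series")) {
    zt <- sleep$zt; bin_s <- sleep$bin_s; sleep <- sleep$sleep
  }
  stopifnot(is.logical(sleep), length(zt) == length(sleep), !is.null(bin_s))
  sel <- zt_in_window(zt, window)
  if (!is.null(day)) {
    abs_day <- (seq_along(sleep) - 1) %/% as.integer(24 * 3600 / bin_s) + 1
    sel <- sel & abs_day == day
  }
  sum(sleep & sel) * bin_s / 60
}

#' Exclusion of ineffective sleep deprivation
#'
#' Flies asleep (five-minute rule) for more than `max_fraction` of the
#' deprivation window are excluded: the deprivation failed for them. The
#' boundary is strict: a fraction exactly equal to `max_fraction` is kept.
#'
#' @param binned A `binned_movement` object.
#' @param sd_window `c(start_h, end_h)` hours from recording start.
#' @param max_fraction Exclusion threshold (default 0.30).
#' @return List with `fraction_asleep_during_sd` and `sd_failure`.
#' @export
exclude_sd_failures <- function(binned, sd_window, max_fraction = 0.30) {
  scored <- score_sleep_5min(binned)
  abs_h <- (seq_along(scored$sleep) - 1) * binned$bin_s / 3600
  sel <- abs_h >= sd_window[1] & abs_h < sd_window[2]
  if (!any(sel)) stop("empty sleep-deprivation window")
  frac <- mean(scored$sleep[sel])
  list(fraction_asleep_during_sd = frac, sd_failure = frac > max_fraction)
}

#' Cohort quality control
#'
#' Applies [detect_dead()] and (when `sd_window` is given)
#' [exclude_sd_failures()] to every fly; a fly is included when it is
#' neither dead nor a deprivation failure.
#'
#' @param binned_list List of `binned_movement` objects.
#' @param sd_window Optional deprivation window (hours from start).
#' @param tail_h,max_fraction See the underlying checks.
#' @return data.table: `fly_id`, `dead`, `sd_failure`,
#'   `fraction_asleep_during_sd`, `included`.
#' @export
qc_cohort <- function(binned_list, sd_window = NULL, tail_h = 12,
                      max_fraction = 0.30) {
  rows <- lapply(binned_list, function(b) {
    dead <- detect_dead(b, tail_h = tail_h)
    if (is.null(sd_window)) {
      sdf <- FALSE; frac <- NA_real_
    } else {
      r <- exclude_sd_failures(b, sd_window, max_fraction)
      sdf <- r$sd_failure; frac <- r$fraction_asleep_during_sd
    }
    data.table::data.table(fly_id = b$fly_id, dead = dead, sd_failure = sdf,
                           fraction_asleep_during_sd = frac,
                           included = !dead && !sdf)
  })
  data.table::rbindlist(rows)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `metadata.csv` (columns `id`, `species`, `sex`, `treatment`,
#' `seed`, `lights_on_zt0_offset_s`), one `<id>.csv` per fly (columns
#' `t_s`, `symbol`), and, when latent traces carry stimulus logs,
#' `stimuli.csv` (columns `id`, `t_s`, `kind`, `protocol`, `responded`).
#'
#' @param cohort A `sim_cohort` (or list with `recordings` + `metadata`).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.csv"))
  for (rec in cohort$recordings) {
    data.table::fwrite(data.table::data.table(t_s = rec$t, symbol = rec$value),
                       file.path(dir, paste0(rec$fly_id, ".csv")))
  }
  if (!is.null(cohort$latents)) {
    logs <- data.table::rbindlist(lapply(cohort$latents, function(l)
      l$stimuli[, c("fly_id", "t_s", "kind", "protocol", "responded")]))
    if (nrow(logs)) {
      data.table::setnames(logs, "fly_id", "id")
      data.table::fwrite(logs, file.path(dir, "stimuli.csv"))
    }
  }
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' Reads the metadata table and the per-fly recording files it references,
#' validating timestamps and symbols. Malformed rows are reported with the
#' offending fly and row.
#'
#' @param metadata_path Path to the metadata CSV.
#' @param data_dir Directory containing `<id>.csv` recordings (defaults to
#'   the metadata's directory).
#' @return List with `recordings` (list of [activity_recording]) and
#'   `metadata` (data.table).
#' @export
read_cohort <- function(metadata_path, data_dir = dirname(metadata_path)) {
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  metadata <- data.table::fread(metadata_path)
  if (!all(c("id", "lights_on_zt0_offset_s") %in% names(metadata)))
    stop("metadata must have columns 'id' and 'lights_on_zt0_offset_s'")
  paths <- file.path(data_dir, paste0(metadata$id, ".csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing recording file(s): ", paste(missing, collapse = ", "))
  recordings <- lapply(seq_len(nrow(metadata)), function(i) {
    d <- data.table::fread(paths[i])
    if (!all(c("t_s", "symbol") %in% names(d)) &&
        !all(c("t_s", "velocity") %in% names(d)))
      stop("recording for fly '", metadata$id[i],
           "' must have columns t_s and symbol (or velocity)")
    value <- if ("symbol" %in% names(d)) as.character(d$symbol) else d$velocity
    activity_recording(metadata$id[i], d$t_s, value,
                       lights_on_offset = metadata$lights_on_zt0_offset_s[i])
  })
  list(recordings = recordings, metadata = metadata)
}
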