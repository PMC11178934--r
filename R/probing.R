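#' Arousal-probing configuration
#'
#' The two conditions used in the study are tau = 30 s with pi = 0.10 and
#' tau = 150 s with pi = 0.5; responses are scored in the 30 s following
#' each event.
#'
#' @param tau_s Immobility trigger, seconds (> 0).
#' @param pi Stimulus delivery probability in `[0, 1]`; failures are
#'   logged as mock events.
#' @param response_window_s Response scoring window, seconds.
#' @return Object of class `probe_config`.
#' @export
probe_config <- function(tau_s = 30, pi = 0.10, response_window_s = 30) {
  if (!is.numeric(tau_s) || tau_s <= 0) stop("tau_s must be > 0")
  if (pi < 0 || pi > 1) stop("pi must be a probability in [0, 1]")
  structure(list(tau_s = tau_s, pi = pi,
                 response_window_s = response_window_s),
            class = "probe_config")
}

#' Schedule stimulus events over a binned recording
#'
#' Replays the closed-loop trigger on a symbol stream: whenever continuous
#' non-moving time reaches `tau_s`, a Bernoulli(`pi`) draw decides between
#' a real and a mock event; the timer resets after every event and on
#' every moving bin. This is the ex-post counterpart of the trigger loop
#' embedded in [simulate_fly()]; applied to a baseline recording it yields
#' the events the hardware would have fired.
#'
#' @param binned A `binned_movement`; `bin_s` must not exceed `tau_s`.
#' @param config A [probe_config].
#' @param seed Optional seed for the delivery draws.
#' @return data.table of events: `fly_id`, `t_s` (end of the triggering
#'   bin), `kind` (`real`/`mock`), `preceding_inactivity_s`,
#'   `stage_at_delivery` (`"UNASSIGNED"` until [assign_stage()]),
#'   `responded` (`NA` until [score_response()]).
#' @export
schedule_events <- function(binned, config, seed = NULL) {
  stopifnot(inherits(binned, "binned_movement"), inherits(config, "probe_config"))
  if (config$tau_s < binned$bin_s)
    stop("tau (", config$tau_s, " s) is smaller than one bin (",
         binned$bin_s, " s)")
  if (!is.null(seed)) set.seed(seed)
  tau_bins <- as.integer(round(config$tau_s / binned$bin_s))
  inactive <- binned$symbols != "MOVING"
  n <- length(inactive)
  ev_bin <- integer(0); ev_pre <- integer(0)
  run <- 0L; since_moving <- 0L
  for (i in seq_len(n)) {
    if (inactive[i]) { run <- run + 1L; since_moving <- since_moving + 1L }
    else { run <- 0L; since_moving <- 0L }
    if (run >= tau_bins) {
      ev_bin <- c(ev_bin, i)
      ev_pre <- c(ev_pre, since_moving)
      run <- 0L
    }
  }
  kind <- ifelse(runif(length(ev_bin)) < config$pi, "real", "mock")
  data.table::data.table(
    fly_id = binned$fly_id,
    t_s = ev_bin * binned$bin_s,
    kind = kind,
    preceding_inactivity_s = ev_pre * binned$bin_s,
    stage_at_delivery = "UNASSIGNED",
    responded = NA)
}

#' Continuous non-moving time preceding given instants
#'
#' For each time in `t_s`, the continuous non-moving observation time
#' accumulated up to (and including) the bin ending at that instant.
#'
#' @param binned A `binned_movement`.
#' @param t_s Times in seconds (typically event times).
#' @return Seconds of preceding continuous inactivity.
#' @export
preceding_inactivity <- function(binned, t_s) {
  inactive <- binned$symbols != "MOVING"
  streak <- integer(length(inactive))
  run <- 0L
  for (i in seq_along(inactive)) {
    run <- if (inactive[i]) run + 1L else 0L
    streak[i] <- run
  }
  idx <- as.integer(ceiling(t_s / binned$bin_s))
  stopifnot(all(idx >= 1), all(idx <= length(streak)))
  streak[idx] * binned$bin_s
}

#' Score stimulus responses from the movement stream
#'
#' An event counts as an awakening when any moving bin occurs within
#' `(t, t + window_s]`; mock events are scored identically, measuring
#' spontaneous movement. Events too close to the recording end get
#' `responded = NA` and are excluded from summaries.
#'
#' @param binned A `binned_movement`.
#' @param events Event table (from [schedule_events()] or a simulator
#'   stimulus log with columns `t_s`, `kind`).
#' @param window_s Scoring window, seconds.
#' @return The event table with `responded` filled in.
#' @export
score_response <- function(binned, events, window_s = 30) {
  moving <- binned$symbols == "MOVING"
  n <- length(moving)
  b <- binned$bin_s
  w_bins <- as.integer(round(window_s / b))
  events <- data.table::as.data.table(events)
  responded <- vapply(events$t_s, function(t) {
    first <- as.integer(floor(t / b)) + 1L  # bin starting at/after t
    last <- first + w_bins - 1L
    if (last > n) return(NA)
    any(moving[first:last])
  }, logical(1))
  events$responded <- responded
  events
}

#' Assign decoded stages to stimulus events
#'
#' Each event takes the decoded stage of the bin containing its delivery
#' time; by the half-open bin convention an event at an exact boundary
#' belongs to the bin starting there. Times not covered by the stage
#' sequence yield `"UNASSIGNED"`.
#'
#' @param events Event table with `t_s`.
#' @param stage_seq A `stage_sequence`.
#' @return The event table with `stage_at_delivery` filled in.
#' @export
assign_stage <- function(events, stage_seq) {
  events <- data.table::as.data.table(events)
  b <- stage_seq$bin_s
  idx <- as.integer(floor(events$t_s / b)) + 1L
  ok <- idx >= 1 & idx <= length(stage_seq$stages)
  events$stage_at_delivery <- ifelse(ok, stage_seq$stages[pmin(pmax(idx, 1),
                                     length(stage_seq$stages))], "UNASSIGNED")
  events
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param level Confidence level.
#' @return Named vector `c(lo, hi)`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n == 0) return(c(lo = NA_real_, hi = NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Per-stage response probabilities
#'
#' Summarizes scored events by stage at delivery and event kind:
#' probability of movement in the response window with a Wilson 95%
#' confidence interval. Events with `NA` response are excluded and
#' counted.
#'
#' @param events Scored, stage-assigned event table.
#' @param level Confidence level for the Wilson interval.
#' @return data.table: `stage`, `kind`, `n`, `k`, `p`, `ci_lo`, `ci_hi`,
#'   `n_unscored`.
#' @export
response_by_stage <- function(events, level = 0.95) {
  events <- data.table::as.data.table(events)
  out <- events[, {
    n_unscored <- sum(is.na(responded))
    sc <- responded[!is.na(responded)]
    ci <- wilson_ci(sum(sc), length(sc), level)
    list(n = length(sc), k = sum(sc),
         p = if (length(sc)) mean(sc) else NA_real_,
         ci_lo = ci[["lo"]], ci_hi = ci[["hi"]], n_unscored = n_unscored)
  }, by = c("stage_at_delivery", "kind")]
  data.table::setnames(out, "stage_at_delivery", "stage")
  data.table::setorderv(out, c("stage", "kind"))
  out[]
}
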