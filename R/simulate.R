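#' Construct an activity recording
#'
#' One fly's time-stamped movement series. `value` is either a character
#' vector of movement symbols (see [movement_symbols()]) or a nonnegative
#' numeric velocity; [bin_movement()] reduces either to the symbolic
#' alphabet on a fixed bin grid.
#'
#' @param fly_id Fly identifier.
#' @param t Integer seconds from experiment start, strictly increasing and
#'   uniformly spaced.
#' @param value Symbol or velocity series, same length as `t`.
#' @param lights_on_offset Seconds mapping `t` to zeitgeber time
#'   (`t == lights_on_offset` is ZT 0).
#' @return An object of class `activity_recording`.
#' @export
activity_recording <- function(fly_id, t, value, lights_on_offset = 0) {
  stopifnot(length(t) == length(value), length(t) > 1)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("non-monotone timestamps in recording for fly '", fly_id, "'")
  if (length(unique(dt)) > 1)
    warning("gaps in recording for fly '", fly_id, "' (non-uniform step)")
  if (is.character(value) || is.factor(value)) {
    value <- as.character(value)
    bad <- which(!value %in% SYMBOLS)
    if (length(bad))
      stop("unknown symbol '", value[bad[1]], "' at row ", bad[1],
           " for fly '", fly_id, "'")
  } else if (any(value < 0)) {
    stop("negative velocity for fly '", fly_id, "'")
  }
  structure(list(fly_id = fly_id, t = as.integer(t), value = value,
                 step_s = as.integer(dt[1]),
                 lights_on_offset = lights_on_offset),
            class = "activity_recording")
}

#' @export
print.activity_recording <- function(x, ...) {
  cat("<activity_recording>", x$fly_id, ":", length(x$t), "samples @",
      x$step_s, "s,", if (is.character(x$value)) "symbolic" else "velocity", "\n")
  invisible(x)
}

# per-bin 4x4 transition matrices for a whole protocol, flattened to
# n x 16 (row-major within each bin) for the C++ stepping loop
protocol_transition_matrix <- function(params, protocol, n_bins, bin_s, sex) {
  zt <- ((seq_len(n_bins) - 1) * bin_s / 3600) %% 24
  abs_h <- (seq_len(n_bins) - 1) * bin_s / 3600
  supp <- NULL
  if (protocol$kind == "social_sd") {
    # intruder present ZT0-23 of the deprivation day(s)
    supp <- rep(1, n_bins)
    in_window <- abs_h >= protocol$sd_start_h & abs_h < protocol$sd_end_h &
      (abs_h - protocol$sd_start_h) %% 24 < 23
    supp[in_window] <- protocol$social_suppression
  }
  arr <- transition_array(params, zt_h = zt, sex = sex,
                          lighting = protocol$lighting,
                          social_suppress = supp)
  tm <- matrix(0, n_bins, 16)
  for (r in 1:4) for (s in 1:4) tm[, (r - 1) * 4 + s] <- arr[, r, s]
  tm
}

#' Simulate one fly under a protocol
#'
#' Steps a time-inhomogeneous four-state Markov chain at bin resolution.
#' Per-bin transition weights are the circadian-modulated base matrices
#' (see [transition_array()]); when the protocol engages a homeostasis
#' gain, wake-to-sleep weights are further multiplied by
#' `1 + gain * pressure` where pressure follows the linear homeostat of
#' [homeostat_step()]. One movement symbol is emitted per bin. Under
#' `mechanical_sd` and `probing` protocols the closed-loop trigger watches
#' the emitted symbol stream: whenever `trigger_tau_s` seconds of
#' continuous non-moving observation accumulate, a stimulus event fires
#' (real with probability pi, mock otherwise) and the timer resets.
#'
#' The protocol kind selects which homeostasis gain couples pressure to
#' behavior: `social_sd` engages `homeostasis_gain_social`, every other
#' kind the intrinsic `homeostasis_gain_mech`.
#'
#' @param params A [species_params] object (or preset name).
#' @param protocol A [protocol] object.
#' @param duration_h Recording length in hours (default: the protocol's).
#' @param bin_s Bin width in seconds; `duration_h * 3600` must be a
#'   multiple of `bin_s`.
#' @param seed Integer seed (optional; when given the run is reproducible).
#' @param sex `"male"` or `"female"`.
#' @param fly_id Identifier stored in the outputs.
#' @param .tm Precomputed per-bin transition matrix (internal; used by
#'   [simulate_cohort()] to share the circadian schedule across flies).
#' @return List with elements `recording` (an [activity_recording] of
#'   symbols) and `latent` (class `latent_trace`: true states, pressure
#'   series and the stimulus log).
#' @export
simulate_fly <- function(params, protocol, duration_h = protocol$duration_h,
                         bin_s = 10, seed = NULL, sex = "male",
                         fly_id = "fly_01", .tm = NULL) {
  if (is.character(params)) params <- build_species_preset(params)
  stopifnot(inherits(params, "species_params"), inherits(protocol, "protocol"))
  if ((duration_h * 3600) %% bin_s != 0)
    stop("duration (", duration_h, " h) is not a whole number of ",
         bin_s, " s bins")
  closed_loop <- protocol$kind %in% c("mechanical_sd", "probing")
  if (closed_loop && protocol$trigger_tau_s < bin_s)
    stop("immobility trigger tau (", protocol$trigger_tau_s,
         " s) is smaller than one bin (", bin_s, " s)")

  n <- as.integer(duration_h * 3600 / bin_s)
  tm <- .tm %||% protocol_transition_matrix(params, protocol, n, bin_s, sex)

  gain <- if (protocol$kind == "social_sd") params$homeostasis_gain_social
          else params$homeostasis_gain_mech
  trigger_bins <- if (closed_loop)
    as.integer(round(protocol$trigger_tau_s / bin_s)) else 0L
  win <- if (closed_loop)
    c(protocol$sd_start_h, protocol$sd_end_h) * 3600 / bin_s else c(0, 0)

  init <- c(0.85, 0.10, 0.04, 0.01)  # recordings start at lights-on
  if (!is.null(seed)) set.seed(seed)
  res <- sim_fly_cpp(tm, params$emission, init, bin_s,
                     params$pressure_rise, params$pressure_decay, gain,
                     trigger_bins, protocol$delivery_prob,
                     protocol$kind == "mechanical_sd",
                     protocol$strong_wake_prob, params$arousal_prob,
                     as.integer(win[1]), as.integer(win[2]))

  stimuli <- data.table::data.table(
    fly_id = fly_id,
    t_s = as.integer(res$ev_bin) * bin_s,
    kind = ifelse(res$ev_real == 1, "real", "mock"),
    protocol = protocol$kind,
    state_at_delivery = STATES[res$ev_state],
    responded = res$ev_responded
  )
  latent <- structure(list(
    fly_id = fly_id,
    states = STATES[res$states],
    pressure = res$pressure,
    bin_s = bin_s,
    stimuli = stimuli
  ), class = "latent_trace")
  rec <- activity_recording(fly_id, t = (seq_len(n) - 1L) * as.integer(bin_s),
                            value = SYMBOLS[res$symbols])
  list(recording = rec, latent = latent)
}

#' @export
print.latent_trace <- function(x, ...) {
  cat("<latent_trace>", x$fly_id, ":", length(x$states), "bins @", x$bin_s,
      "s,", nrow(x$stimuli), "stimulus events\n")
  invisible(x)
}

derive_fly_seed <- function(master_seed, i) {
  # documented counter scheme: distinct, reproducible, within 32-bit range
  as.integer((as.numeric(master_seed) * 10007 + i) %% 2147483647)
}

#' Simulate a cohort of flies
#'
#' Runs [simulate_fly()] for `n_flies` flies with per-fly seeds derived
#' from `seed` by the counter scheme `(seed * 10007 + i) mod (2^31 - 1)`.
#'
#' @param params A [species_params] object or preset name.
#' @param protocol A [protocol] object.
#' @param n_flies Number of flies (>= 1).
#' @param bin_s Bin width in seconds.
#' @param seed Master seed (integer).
#' @param sex `"male"` or `"female"` (recycled over flies).
#' @param treatment Label stored in the metadata (defaults to the
#'   protocol kind).
#' @param id_prefix Prefix for fly identifiers.
#' @return An object of class `sim_cohort`: list with `recordings`,
#'   `latents` and a `metadata` table (columns `id`, `species`, `sex`,
#'   `treatment`, `seed`, `lights_on_zt0_offset_s`).
#' @export
simulate_cohort <- function(params, protocol, n_flies, bin_s = 10, seed = 1,
                            sex = "male", treatment = NULL,
                            id_prefix = "fly") {
  if (is.character(params)) params <- build_species_preset(params)
  if (!is.numeric(n_flies) || n_flies < 1)
    stop("n_flies must be >= 1")
  n_flies <- as.integer(n_flies)
  treatment <- treatment %||% protocol$kind
  sex <- rep_len(sex, n_flies)
  ids <- sprintf("%s_%02d", id_prefix, seq_len(n_flies))
  seeds <- vapply(seq_len(n_flies), function(i) derive_fly_seed(seed, i), 1L)

  n_bins <- as.integer(protocol$duration_h * 3600 / bin_s)
  tms <- lapply(unique(sex), function(sx)
    protocol_transition_matrix(params, protocol, n_bins, bin_s, sx))
  names(tms) <- unique(sex)
  sims <- lapply(seq_len(n_flies), function(i)
    simulate_fly(params, protocol, bin_s = bin_s, seed = seeds[i],
                 sex = sex[i], fly_id = ids[i], .tm = tms[[sex[i]]]))

  metadata <- data.table::data.table(
    id = ids, species = params$name, sex = sex, treatment = treatment,
    seed = seeds, lights_on_zt0_offset_s = 0L)
  structure(list(
    recordings = lapply(sims, `[[`, "recording"),
    latents = lapply(sims, `[[`, "latent"),
    metadata = metadata
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", nrow(x$metadata), "flies,",
    unique(x$metadata$species), "(", unique(x$metadata$treatment), ")\n")
  invisible(x)
}
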