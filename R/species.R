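#' Species simulation parameters
#'
#' Bundle of generative parameters describing one species-like behavioral
#' phenotype: day and night base transition matrices over the four
#' behavioral states, circadian modulation amplitudes, the emission matrix
#' over the movement alphabet, state-specific arousal probabilities for
#' air-puff stimuli, and the sleep-pressure homeostat (linear rise
#' `pressure_rise` per hour awake, linear decay `pressure_decay` per hour
#' asleep, and the protocol-specific couplings `homeostasis_gain_mech` /
#' `homeostasis_gain_social` that multiply wake-to-sleep transition weights
#' by `1 + gain * pressure`).
#'
#' @param name Label for the parameter set.
#' @param base_transition_day,base_transition_night 4x4 row-stochastic
#'   matrices in canonical state order (see [sleep_states()]).
#' @param siesta_amplitude Named numeric `c(female = , male = )`: amplitude
#'   of the mid-day sleep bump (dimensionless multiplier weight).
#' @param crepuscular_amplitude Amplitude of the dawn/dusk activity bumps.
#' @param night_depth_amplitude Amplitude of the early-night (ZT 13.5)
#'   deep-sleep entry bump.
#' @param dd_rhythm_amplitude Scalar in `[0, 1]`; residual amplitude of the
#'   circadian modulation under constant darkness (0 = arrhythmic in DD).
#' @param emission 4x3 row-stochastic emission matrix over
#'   [movement_symbols()].
#' @param arousal_prob Named numeric over states: probability of waking in
#'   response to an air puff delivered in that state. Wake states always
#'   respond.
#' @param homeostasis_gain_mech,homeostasis_gain_social Nonnegative
#'   couplings of sleep pressure to wake-to-sleep transitions under the
#'   mechanical-deprivation and social-deprivation pathways.
#' @param pressure_rise,pressure_decay Nonnegative homeostat rates, in
#'   pressure units per hour awake / asleep.
#'
#' @return An object of class `species_params`.
#' @seealso [build_species_preset()] for ready-made presets.
#' @export
species_params <- function(name,
                           base_transition_day,
                           base_transition_night,
                           siesta_amplitude = c(female = 0.3, male = 1.2),
                           crepuscular_amplitude = 1,
                           night_depth_amplitude = 1.5,
                           dd_rhythm_amplitude = 0.9,
                           emission,
                           arousal_prob = c(ACTIVE_WAKE = 1, QUIET_WAKE = 1,
                                            LIGHT_SLEEP = 0.5, DEEP_SLEEP = 0.1),
                           homeostasis_gain_mech = 0,
                           homeostasis_gain_social = 0,
                           pressure_rise = 0.5,
                           pressure_decay = 1.2) {
  for (m in list(base_transition_day, base_transition_night))
    stopifnot(is.matrix(m), dim(m) == c(4, 4))
  stopifnot(is.matrix(emission), dim(emission) == c(4, 3))
  check_stochastic(base_transition_day, "base_transition_day")
  check_stochastic(base_transition_night, "base_transition_night")
  check_stochastic(emission, "emission")
  if (!all(names(siesta_amplitude) %in% c("female", "male")) ||
      length(siesta_amplitude) != 2)
    stop("siesta_amplitude must be a named pair c(female=, male=)")
  stopifnot(
    siesta_amplitude >= 0, crepuscular_amplitude >= 0,
    night_depth_amplitude >= 0,
    dd_rhythm_amplitude >= 0, dd_rhythm_amplitude <= 1,
    homeostasis_gain_mech >= 0, homeostasis_gain_social >= 0,
    pressure_rise >= 0, pressure_decay >= 0
  )
  ap <- arousal_prob[STATES]
  if (anyNA(ap) || any(ap < 0) || any(ap > 1))
    stop("arousal_prob must give a probability in [0,1] for every state")
  dimnames(base_transition_day) <- dimnames(base_transition_night) <-
    list(STATES, STATES)
  dimnames(emission) <- list(STATES, SYMBOLS)
  structure(list(
    name = name,
    base_transition_day = base_transition_day,
    base_transition_night = base_transition_night,
    siesta_amplitude = siesta_amplitude[c("female", "male")],
    crepuscular_amplitude = crepuscular_amplitude,
    night_depth_amplitude = night_depth_amplitude,
    dd_rhythm_amplitude = dd_rhythm_amplitude,
    emission = emission,
    arousal_prob = ap,
    homeostasis_gain_mech = homeostasis_gain_mech,
    homeostasis_gain_social = homeostasis_gain_social,
    pressure_rise = pressure_rise,
    pressure_decay = pressure_decay
  ), class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params>", x$name, "\n")
  cat("  dd_rhythm_amplitude:", x$dd_rhythm_amplitude, "\n")
  cat("  homeostasis gains (mech/social):", x$homeostasis_gain_mech, "/",
      x$homeostasis_gain_social, "\n")
  cat("  arousal_prob:", paste(sprintf("%s=%.2f", STATES, x$arousal_prob),
                               collapse = " "), "\n")
  invisible(x)
}

# Shared base matrices for the presets. The state order is
# ACTIVE_WAKE, QUIET_WAKE, LIGHT_SLEEP, DEEP_SLEEP. Deep sleep is only
# enterable from light sleep (or itself) and never exits directly to
# active wake, mirroring the structural constraints of the staging model.
base_day_matrix <- function(deep_entry_scale = 1, deep_exit_scale = 1) {
  m <- rbind(
    c(0.970, 0.020, 0.010, 0.000),
    c(0.150, 0.800, 0.050, 0.000),
    c(0.025, 0.040, 0.933, 0.002 * deep_entry_scale),
    c(0.000, 0.000, 0.008 * deep_exit_scale, 1 - 0.008 * deep_exit_scale)
  )
  renormalize_rows(m)
}

base_night_matrix <- function(deep_entry_scale = 1, deep_exit_scale = 1) {
  m <- rbind(
    c(0.900, 0.060, 0.040, 0.000),
    c(0.050, 0.750, 0.200, 0.000),
    c(0.004, 0.020, 0.972, 0.004 * deep_entry_scale),
    c(0.000, 0.000, 0.006 * deep_exit_scale, 1 - 0.006 * deep_exit_scale)
  )
  renormalize_rows(m)
}

base_emission_matrix <- function() {
  rbind(
    c(0.95, 0.04, 0.01),   # active wake: walking most bins
    c(0.62, 0.10, 0.28),   # quiet wake: grooming/feeding pauses
    c(0.00, 0.13, 0.87),   # light sleep: immobile with twitches
    c(0.00, 0.03, 0.97)    # deep sleep: near-total immobility
  )
}

#' Ready-made species-like parameter presets
#'
#' Seven presets encode the qualitative phenotypes of the seven Drosophila
#' species studied: all share the crepuscular/nocturnal-sleep architecture
#' and a male-biased siesta, and they differ in sleep-homeostasis couplings
#' (melanogaster-like rebounds after both mechanical and social
#' deprivation; simulans-, sechellia- and yakuba-like only after social
#' deprivation; erecta-, willistoni- and virilis-like after neither), in
#' the light:deep sleep balance (erecta-like has a much higher light:deep
#' ratio), and in free-running rhythmicity (virilis-like is arrhythmic in
#' constant darkness and shows a female-biased siesta).
#'
#' @param preset_name One of `"melanogaster_like"`, `"simulans_like"`,
#'   `"sechellia_like"`, `"yakuba_like"`, `"erecta_like"`,
#'   `"willistoni_like"`, `"virilis_like"`.
#' @return A [species_params] object.
#' @export
#' @examples
#' p <- build_species_preset("melanogaster_like")
#' p$homeostasis_gain_mech > 0
build_species_preset <- function(preset_name) {
  presets <- species_preset_names()
  if (length(preset_name) != 1 || !preset_name %in% presets)
    stop("unknown preset '", paste(preset_name, collapse = ","),
         "'; valid presets: ", paste(presets, collapse = ", "), call. = FALSE)

  B <- base_emission_matrix()
  args <- switch(preset_name,
    melanogaster_like = list(
      deep_scale = 1, dd = 0.90, siesta = c(female = 0.3, male = 1.2),
      gain_mech = 0.18, gain_social = 0.18),
    simulans_like = list(
      deep_scale = 1, dd = 0.90, siesta = c(female = 0.3, male = 1.1),
      gain_mech = 0, gain_social = 0.18),
    sechellia_like = list(
      deep_scale = 0.9, dd = 0.85, siesta = c(female = 0.3, male = 1.0),
      gain_mech = 0, gain_social = 0.18),
    yakuba_like = list(
      deep_scale = 0.9, dd = 0.85, siesta = c(female = 0.3, male = 1.0),
      gain_mech = 0, gain_social = 0.18),
    erecta_like = list(
      deep_scale = 0.5, exit_scale = 1.5, dd = 0.80,
      siesta = c(female = 0.2, male = 0.8),
      gain_mech = 0, gain_social = 0),
    willistoni_like = list(
      deep_scale = 0.8, dd = 0.80, siesta = c(female = 0.3, male = 0.9),
      gain_mech = 0, gain_social = 0),
    virilis_like = list(
      deep_scale = 0.8, dd = 0.00, siesta = c(female = 1.2, male = 0.3),
      gain_mech = 0, gain_social = 0)
  )

  exit_scale <- args$exit_scale %||% 1
  species_params(
    name = preset_name,
    base_transition_day = base_day_matrix(args$deep_scale, exit_scale),
    base_transition_night = base_night_matrix(args$deep_scale, exit_scale),
    siesta_amplitude = args$siesta,
    crepuscular_amplitude = if (preset_name == "virilis_like") 0.8 else 1,
    night_depth_amplitude = 1.5,
    dd_rhythm_amplitude = args$dd,
    emission = B,
    homeostasis_gain_mech = args$gain_mech,
    homeostasis_gain_social = args$gain_social
  )
}

#' @rdname build_species_preset
#' @export
species_preset_names <- function() {
  c("melanogaster_like", "simulans_like", "sechellia_like", "yakuba_like",
    "erecta_like", "willistoni_like", "virilis_like")
}

# circular gaussian bump on the 24 h clock face
zt_bump <- function(zt, center, sd) {
  d <- abs(zt - center)
  d <- pmin(d, 24 - d)
  exp(-d^2 / (2 * sd^2))
}

#' Circadian modulation of the behavioral transition matrix
#'
#' Blends the day and night base matrices with a smooth night weight,
#' applies crepuscular activity bumps at ZT 0 and ZT 12, a mid-day siesta
#' bump on wake-to-light-sleep entries (sex-specific amplitude) and an
#' early-night bump on deep-sleep entry, then renormalizes rows. Under
#' constant darkness every modulation amplitude is scaled by
#' `dd_rhythm_amplitude`; at amplitude 0 the output is constant in `zt`.
#'
#' @param zt Zeitgeber time in hours, in `[0, 24)`. Vectorized input is not
#'   supported; use [transition_array()] for whole recordings.
#' @param params A [species_params] object.
#' @param sex `"male"` or `"female"`.
#' @param lighting `"LD"` (12:12 entrained) or `"DD"` (constant darkness).
#' @return A 4x4 row-stochastic transition matrix.
#' @export
circadian_modulator <- function(zt, params, sex = "male", lighting = c("LD", "DD")) {
  lighting <- match.arg(lighting)
  stopifnot(length(zt) == 1, zt >= 0, zt < 24)
  transition_array(params, zt_h = zt, sex = sex, lighting = lighting)[1, , ]
}

#' Per-bin modulated transition matrices
#'
#' Vectorized form of [circadian_modulator()]: computes the modulated
#' transition matrix for every requested zeitgeber time at once.
#'
#' @param params A [species_params] object.
#' @param zt_h Numeric vector of zeitgeber times (hours; reduced mod 24).
#' @param sex,lighting See [circadian_modulator()].
#' @param social_suppress Optional numeric vector, same length as `zt_h`,
#'   of multipliers (< 1 suppresses) applied to wake-to-sleep entries;
#'   used to emulate forced wakefulness during social deprivation. Where
#'   suppression is active (< 1), sleep-exit weights are amplified by
#'   `social_arousal` (the intruder also interrupts ongoing sleep).
#' @param social_arousal Exit amplification during suppressed bins.
#' @return Array `length(zt_h) x 4 x 4`; each slice is row-stochastic.
#' @export
transition_array <- function(params, zt_h, sex = "male",
                             lighting = c("LD", "DD"),
                             social_suppress = NULL, social_arousal = 6) {
  lighting <- match.arg(lighting)
  stopifnot(inherits(params, "species_params"))
  sex <- match.arg(sex, c("male", "female"))
  zt <- zt_h %% 24
  n <- length(zt)

  amp <- if (lighting == "DD") params$dd_rhythm_amplitude else 1

  # smooth periodic night weight: ~0 during ZT0-12, ~1 during ZT12-24
  w <- plogis(8 * sin(pi * (zt - 12) / 12))
  w <- 0.5 + amp * (w - 0.5)

  crep <- 1 + amp * params$crepuscular_amplitude *
    (zt_bump(zt, 0, 0.75) + zt_bump(zt, 12, 0.75))
  siesta <- 1 + amp * params$siesta_amplitude[[sex]] * zt_bump(zt, 7.5, 1.5)
  depth <- 1 + amp * params$night_depth_amplitude * zt_bump(zt, 13.5, 1.5)
  supp <- if (is.null(social_suppress)) rep(1, n) else social_suppress
  stopifnot(length(supp) == n)

  D <- params$base_transition_day
  N <- params$base_transition_night
  out <- array(0, dim = c(n, 4, 4), dimnames = list(NULL, STATES, STATES))
  for (r in 1:4) for (s in 1:4)
    out[, r, s] <- (1 - w) * D[r, s] + w * N[r, s]

  # dawn/dusk bumps favor transitions into active wake
  for (r in 1:3) out[, r, 1] <- out[, r, 1] * crep
  # siesta favors wake -> light sleep at mid-day; social suppression acts
  # on the same entries in the opposite direction
  for (r in 1:2) out[, r, 3] <- out[, r, 3] * siesta * supp
  # early-night bump on deep-sleep entry
  out[, 3, 4] <- out[, 3, 4] * depth
  # an intruder also breaks up ongoing sleep
  intruder <- ifelse(supp < 1, social_arousal, 1)
  for (s in 1:2) out[, 3, s] <- out[, 3, s] * intruder
  out[, 4, 3] <- out[, 4, 3] * intruder

  tot <- out[, , 1] + out[, , 2] + out[, , 3] + out[, , 4]
  for (s in 1:4) out[, , s] <- out[, , s] / tot
  out
}

#' One step of the linear sleep-pressure homeostat
#'
#' Pressure rises linearly while awake (`pressure + rise * dt`) and decays
#' linearly while asleep, clamped at zero.
#'
#' @param pressure Current pressure (nonnegative scalar).
#' @param state State label occupied during the step.
#' @param dt Step duration in hours (> 0).
#' @param params A [species_params] object supplying the rates.
#' @return Updated pressure.
#' @export
homeostat_step <- function(pressure, state, dt, params) {
  stopifnot(pressure >= 0)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a positive duration in hours")
  state <- match.arg(state, STATES)
  if (state %in% WAKE_STATES) pressure + params$pressure_rise * dt
  else max(0, pressure - params$pressure_decay * dt)
}

#' Apply one arousal stimulus to a latent state
#'
#' With probability `arousal_prob[state]` the fly wakes (state becomes
#' `ACTIVE_WAKE`, responded `TRUE`); otherwise the state is unchanged.
#' Wake states always respond.
#'
#' @param state State label at delivery.
#' @param params A [species_params] object.
#' @return List with elements `state` and `responded`. Consumes one draw
#'   from R's random number stream.
#' @export
apply_stimulus <- function(state, params) {
  state <- match.arg(state, STATES)
  p <- if (state %in% WAKE_STATES) 1 else params$arousal_prob[[state]]
  responded <- runif(1) < p
  list(state = if (responded) "ACTIVE_WAKE" else state, responded = responded)
}
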