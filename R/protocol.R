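#' Experimental protocol description
#'
#' Describes the stimulus/lighting schedule a simulated fly experiences.
#' Four kinds are supported:
#' \describe{
#'   \item{`baseline`}{undisturbed recording.}
#'   \item{`mechanical_sd`}{closed-loop tube rotation after every
#'     `trigger_tau_s` seconds of observed immobility, within
#'     `[sd_start_h, sd_end_h)` hours from recording start. Delivery is
#'     certain (`delivery_prob = 1`) and the stimulus is strong
#'     (wakes sleeping flies with probability `strong_wake_prob`).}
#'   \item{`social_sd`}{forced elevated wakefulness (an intruder male):
#'     wake-to-sleep transition weights are multiplied by
#'     `social_suppression` during ZT 0--23 of the deprivation day; the
#'     social homeostasis gain is engaged for the whole protocol.}
#'   \item{`probing`}{air-puff arousal probing: after every
#'     `trigger_tau_s` seconds of observed immobility a stimulus is
#'     delivered with probability `delivery_prob` (otherwise a mock event
#'     is logged); response follows the species arousal map.}
#' }
#'
#' @param kind Protocol kind (see above).
#' @param duration_h Total recording duration in hours.
#' @param trigger_tau_s Immobility trigger tau in seconds (default 30, as
#'   used for both the rotation module and the standard puff condition).
#' @param delivery_prob Stimulus delivery probability pi (default 0.10 for
#'   probing; forced to 1 for mechanical deprivation).
#' @param stimulus_len_s Nominal stimulus length in seconds (metadata).
#' @param sd_start_h,sd_end_h Window (hours from recording start) during
#'   which the deprivation/probing loop is active. Defaults: whole
#'   recording for probing; second day (24--48 h) for deprivation.
#' @param strong_wake_prob Waking probability of the strong mechanical
#'   stimulus for sleeping flies.
#' @param social_suppression Multiplier (< 1) on wake-to-sleep weights
#'   during the social-deprivation window; the default leaves residual
#'   sleep.
#' @param lighting `"LD"` or `"DD"`.
#' @return An object of class `protocol`.
#' @export
protocol <- function(kind = c("baseline", "mechanical_sd", "social_sd", "probing"),
                     duration_h = 72,
                     trigger_tau_s = 30,
                     delivery_prob = 0.10,
                     stimulus_len_s = 3,
                     sd_start_h = NULL,
                     sd_end_h = NULL,
                     strong_wake_prob = 0.98,
                     social_suppression = 0.05,
                     lighting = c("LD", "DD")) {
  kind <- match.arg(kind)
  lighting <- match.arg(lighting)
  stopifnot(duration_h > 0)
  if (kind %in% c("mechanical_sd", "probing")) {
    if (!is.numeric(trigger_tau_s) || trigger_tau_s <= 0)
      stop("trigger_tau_s must be > 0 for ", kind)
  }
  if (delivery_prob < 0 || delivery_prob > 1)
    stop("delivery_prob must be a probability in [0, 1]")
  if (kind == "mechanical_sd") delivery_prob <- 1
  if (is.null(sd_start_h))
    sd_start_h <- switch(kind, probing = 0, baseline = 0, 24)
  if (is.null(sd_end_h))
    sd_end_h <- switch(kind, probing = duration_h, baseline = 0, 48)
  if (sd_end_h > duration_h)
    stop("deprivation window extends past the recording (sd_end_h > duration_h)")
  structure(list(
    kind = kind, duration_h = duration_h, trigger_tau_s = trigger_tau_s,
    delivery_prob = delivery_prob, stimulus_len_s = stimulus_len_s,
    sd_start_h = sd_start_h, sd_end_h = sd_end_h,
    strong_wake_prob = strong_wake_prob,
    social_suppression = social_suppression, lighting = lighting
  ), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol>", x$kind, sprintf("(%g h, %s)", x$duration_h, x$lighting), "\n")
  if (x$kind %in% c("mechanical_sd", "probing"))
    cat(sprintf("  tau = %g s, pi = %g, window = [%g, %g) h\n",
                x$trigger_tau_s, x$delivery_prob, x$sd_start_h, x$sd_end_h))
  if (x$kind == "social_sd")
    cat(sprintf("  suppression = %g, window = [%g, %g) h\n",
                x$social_suppression, x$sd_start_h, x$sd_end_h))
  invisible(x)
}
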