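#' Read a flat key-value simulation configuration
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a
#' comment. Recognized keys: `preset` (see [species_preset_names()]),
#' `protocol` (a [protocol()] kind), `n_flies`, `duration_h`, `bin_s`,
#' `seed`, `sex`, `lighting`, `trigger_tau_s`, `delivery_prob`.
#' Unrecognized keys are an error.
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=:]", fixed = FALSE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed config line ", which(bad)[1], ": '", lines[bad][1], "'")
  cfg <- setNames(trimws(vapply(kv, `[[`, "", 2)),
                  trimws(vapply(kv, `[[`, "", 1)))
  known <- c("preset", "protocol", "n_flies", "duration_h", "bin_s", "seed",
             "sex", "lighting", "trigger_tau_s", "delivery_prob")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- as.list(cfg)
  for (k in c("n_flies", "duration_h", "bin_s", "seed", "trigger_tau_s",
              "delivery_prob"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg
}

#' Simulate a cohort from a configuration file
#'
#' Convenience wrapper: [read_sim_config()] then [simulate_cohort()],
#' optionally writing the cohort CSVs.
#'
#' @param path Configuration file path.
#' @param out_dir Optional output directory for [write_cohort()].
#' @return The simulated `sim_cohort`.
#' @export
simulate_from_config <- function(path, out_dir = NULL) {
  cfg <- read_sim_config(path)
  proto_args <- list(kind = cfg$protocol %||% "baseline",
                     duration_h = cfg$duration_h %||% 72)
  if (!is.null(cfg$lighting)) proto_args$lighting <- cfg$lighting
  if (!is.null(cfg$trigger_tau_s)) proto_args$trigger_tau_s <- cfg$trigger_tau_s
  if (!is.null(cfg$delivery_prob)) proto_args$delivery_prob <- cfg$delivery_prob
  pr <- do.call(protocol, proto_args)
  co <- simulate_cohort(cfg$preset %||% "melanogaster_like", pr,
                        n_flies = cfg$n_flies %||% 1,
                        bin_s = cfg$bin_s %||% 10,
                        seed = cfg$seed %||% 1,
                        sex = cfg$sex %||% "male")
  if (!is.null(out_dir)) write_cohort(co, out_dir)
  co
}

#' Tabulate a decoded stage sequence
#'
#' Flat table form of a [hmm_decode()] result, suitable for CSV export.
#'
#' @param stage_seq A `stage_sequence`.
#' @return data.table: `fly_id`, `bin_index` (1-based), `zt`, `stage`.
#' @export
stage_table <- function(stage_seq) {
  stopifnot(inherits(stage_seq, "stage_sequence"))
  data.table::data.table(
    fly_id = stage_seq$fly_id,
    bin_index = seq_along(stage_seq$stages),
    zt = stage_seq$zt %||% NA_real_,
    stage = stage_seq$stages)
}

#' Delivered-stimulus counts per deprivation day
#'
#' Tabulates real stimulus events into 24 h days from the start of the
#' deprivation window — the sleep-pressure proxy series used for trend
#' analysis over chronic deprivation (see [sleep_pressure_trend()]).
#'
#' @param latents List of `latent_trace` objects (or a pooled stimulus
#'   log with columns `fly_id`, `t_s`, `kind`).
#' @param sd_start_h Start of the deprivation window, hours.
#' @param n_days Number of days to tabulate.
#' @return data.table: `fly_id`, `day` (1-based), `n_stimuli`; also a
#'   matrix form in attribute `"counts"` (flies x days) ready for
#'   [sleep_pressure_trend()].
#' @export
stimulus_counts_by_day <- function(latents, sd_start_h, n_days) {
  log_ <- if (data.table::is.data.table(latents) || is.data.frame(latents))
    data.table::as.data.table(latents)
  else data.table::rbindlist(lapply(latents, `[[`, "stimuli"))
  log_ <- log_[log_$kind == "real" & log_$t_s > sd_start_h * 3600, ]
  ids <- unique(log_$fly_id)
  counts <- t(vapply(ids, function(id) {
    d <- floor((log_$t_s[log_$fly_id == id] - sd_start_h * 3600) / 86400) + 1
    tabulate(d[d <= n_days], n_days)
  }, integer(n_days)))
  out <- data.table::data.table(
    fly_id = rep(ids, each = n_days),
    day = rep(seq_len(n_days), length(ids)),
    n_stimuli = as.integer(t(counts)))
  data.table::setattr(out, "counts", counts)
  out
}
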