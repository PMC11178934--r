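test_that("all presets are valid and encode the documented phenotypes", {
  for (nm in species_preset_names()) {
    p <- build_species_preset(nm)
    expect_s3_class(p, "species_params")
    for (m in list(p$base_transition_day, p$base_transition_night, p$emission))
      expect_lt(max(abs(rowSums(m) - 1)), 1e-9)
    expect_true(all(p$arousal_prob >= 0 & p$arousal_prob <= 1))
  }
  mel <- build_species_preset("melanogaster_like")
  ere <- build_species_preset("erecta_like")
  vir <- build_species_preset("virilis_like")
  # only the melanogaster-like homeostat couples to mechanical deprivation
  expect_gt(mel$homeostasis_gain_mech, 0)
  expect_identical(ere$homeostasis_gain_mech, 0)
  expect_gt(mel$homeostasis_gain_mech, ere$homeostasis_gain_mech)
  # virilis-like is arrhythmic in constant darkness, with a female siesta
  expect_identical(vir$dd_rhythm_amplitude, 0)
  expect_gt(vir$siesta_amplitude[["female"]], vir$siesta_amplitude[["male"]])
  # erecta-like enters deep sleep far more rarely than any other preset
  others <- setdiff(species_preset_names(), "erecta_like")
  min_entry <- min(vapply(others, function(nm)
    build_species_preset(nm)$base_transition_night["LIGHT_SLEEP", "DEEP_SLEEP"],
    numeric(1)))
  expect_lt(ere$base_transition_night["LIGHT_SLEEP", "DEEP_SLEEP"],
            min_entry / 1.5)
})

test_that("unknown preset errors and lists the valid names", {
  err <- tryCatch(build_species_preset("dmel"), error = identity)
  expect_s3_class(err, "error")
  for (nm in species_preset_names())
    expect_match(conditionMessage(err), nm, fixed = TRUE)
})

test_that("circadian modulation stays row-stochastic and follows the day", {
  p <- build_species_preset("melanogaster_like")
  for (zt in seq(0, 23.5, by = 0.5)) {
    for (lighting in c("LD", "DD")) {
      W <- circadian_modulator(zt, p, sex = "male", lighting = lighting)
      expect_lt(max(abs(rowSums(W) - 1)), 1e-9)
    }
  }
  # mid-night weights favor sleep over active wake relative to mid-day
  night <- circadian_modulator(18, p)
  day <- circadian_modulator(6, p)
  expect_gt(night["ACTIVE_WAKE", "LIGHT_SLEEP"], day["ACTIVE_WAKE", "LIGHT_SLEEP"])
  expect_lt(night["ACTIVE_WAKE", "ACTIVE_WAKE"], day["ACTIVE_WAKE", "ACTIVE_WAKE"])
})

test_that("zero DD amplitude makes the modulator constant over the day", {
  p <- build_species_preset("virilis_like")
  W0 <- circadian_modulator(0, p, lighting = "DD")
  for (zt in c(3, 7.5, 12, 13.5, 18, 23.5))
    expect_equal(circadian_modulator(zt, p, lighting = "DD"), W0,
                 tolerance = 1e-12)
  # the same preset is rhythmic under entrainment
  expect_false(isTRUE(all.equal(circadian_modulator(6, p, lighting = "LD"),
                                circadian_modulator(18, p, lighting = "LD"))))
})

test_that("active-wake occupancy matches a forward-simulation oracle", {
  p <- build_species_preset("simulans_like")
  bin_s <- 60
  n_day <- 24 * 3600 / bin_s
  zt <- ((seq_len(n_day) - 1) * bin_s / 3600) %% 24
  arr <- transition_array(p, zt, sex = "male", lighting = "LD")
  # oracle 1: exact marginal propagation to the periodic steady state
  v <- rep(0.25, 4)
  for (cycle in 1:30) for (i in seq_len(n_day)) v <- as.numeric(v %*% arr[i, , ])
  occ <- matrix(0, n_day, 4)
  for (i in seq_len(n_day)) { v <- as.numeric(v %*% arr[i, , ]); occ[i, ] <- v }
  exact_active <- mean(occ[, 1])
  # oracle 2: brute-force chain simulation, 1e5 steps
  set.seed(42)
  n_steps <- 1e5
  s <- 1L; hits <- 0L
  for (t in seq_len(n_steps)) {
    s <- sample.int(4, 1, prob = arr[((t - 1) %% n_day) + 1, s, ])
    hits <- hits + (s == 1L)
  }
  mc_active <- hits / n_steps
  se <- sqrt(exact_active * (1 - exact_active) / n_steps)
  # Monte-Carlo error allowance; autocorrelation inflates the iid se
  expect_lt(abs(mc_active - exact_active), 30 * se)
})

test_that("homeostat pressure follows the linear rise/decay with clamping", {
  p <- build_species_preset("melanogaster_like")
  expect_identical(homeostat_step(0, "LIGHT_SLEEP", 5, p), 0)
  p2 <- p; p2$pressure_rise <- 0.5
  expect_equal(homeostat_step(1.0, "ACTIVE_WAKE", 2, p2), 2.0)
  expect_error(homeostat_step(1, "ACTIVE_WAKE", -1, p), "positive")
  # long-run time-average against an independent event-driven oracle
  set.seed(7)
  states <- sample(sleep_states(), 5000, replace = TRUE,
                   prob = c(0.4, 0.1, 0.3, 0.2))
  dt <- 1 / 60
  pr <- numeric(5000); x <- 0
  for (i in seq_along(states)) {
    x <- homeostat_step(x, states[i], dt, p)
    pr[i] <- x
  }
  # oracle: direct cumulative integration with reflection at zero
  drift <- ifelse(states %in% c("ACTIVE_WAKE", "QUIET_WAKE"),
                  p$pressure_rise, -p$pressure_decay) * dt
  y <- numeric(5000); acc <- 0
  for (i in seq_along(drift)) { acc <- max(0, acc + drift[i]); y[i] <- acc }
  expect_lt(abs(mean(pr) - mean(y)) / max(mean(y), 1e-12), 0.02)
})

test_that("stimulus response follows the state-specific arousal map", {
  p <- build_species_preset("melanogaster_like")
  set.seed(1)
  for (i in 1:20)
    expect_true(apply_stimulus("ACTIVE_WAKE", p)$responded)
  p0 <- p; p0$arousal_prob[["DEEP_SLEEP"]] <- 0
  for (i in 1:20) {
    r <- apply_stimulus("DEEP_SLEEP", p0)
    expect_false(r$responded)
    expect_identical(r$state, "DEEP_SLEEP")
  }
  # empirical frequency within the binomial CI of the set probability
  set.seed(11)
  n <- 1e4
  hits <- sum(vapply(seq_len(n), function(i)
    apply_stimulus("LIGHT_SLEEP", p)$responded, logical(1)))
  ci <- qbinom(c(0.0005, 0.9995), n, p$arousal_prob[["LIGHT_SLEEP"]])
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})
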