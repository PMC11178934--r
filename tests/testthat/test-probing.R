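test_that("probe configuration validates its fields", {
  expect_error(probe_config(tau_s = 0), "tau")
  expect_error(probe_config(pi = 1.2), "probability")
  cfg <- probe_config(150, 0.5)
  expect_equal(cfg$tau_s, 150)
})

test_that("delivery probability splits events into real and mock", {
  b <- make_binned(rep("IMMOBILE", 1000))
  all_real <- schedule_events(b, probe_config(30, pi = 1), seed = 1)
  expect_true(all(all_real$kind == "real"))
  all_mock <- schedule_events(b, probe_config(30, pi = 0), seed = 1)
  expect_true(all(all_mock$kind == "mock"))
  expect_error(schedule_events(make_binned(rep("IMMOBILE", 10), bin_s = 60),
                               probe_config(30)), "smaller than one bin")
})

test_that("the trigger fires on tau of inactivity and resets afterwards", {
  # a fully immobile stream triggers every tau exactly
  b <- make_binned(rep("IMMOBILE", 100))
  ev <- schedule_events(b, probe_config(30, 0.1), seed = 2)
  expect_equal(ev$t_s, seq(30, 990, by = 30))
  expect_equal(ev$preceding_inactivity_s, seq(30, 990, by = 30))
  # random symbols: no event ever has < tau of preceding inactivity
  set.seed(3)
  for (rep in 1:5) {
    b2 <- make_binned(sample(movement_symbols(), 3000, TRUE, c(0.25, 0.15, 0.6)))
    ev2 <- schedule_events(b2, probe_config(30, 0.3), seed = rep)
    expect_true(all(ev2$preceding_inactivity_s >= 30))
    expect_true(all(preceding_inactivity(b2, ev2$t_s) >= 30))
  }
})

test_that("real and mock events sample the same inactivity distribution", {
  p <- build_species_preset("melanogaster_like")
  ok <- 0L
  for (seed in 1:10) {
    sim <- simulate_fly(p, protocol("probing", duration_h = 48), seed = seed)
    b <- bin_movement(sim$recording, 10)
    ev <- sim$latent$stimuli
    pre <- preceding_inactivity(b, ev$t_s)
    ks <- suppressWarnings(ks.test(pre[ev$kind == "real"],
                                   pre[ev$kind == "mock"]))
    ok <- ok + (ks$p.value > 0.01)
  }
  expect_gte(ok, 9)
})

test_that("responses are scored by movement in the following window", {
  syms <- rep("IMMOBILE", 100)
  syms[8] <- "MOVING"  # 70-80 s
  b <- make_binned(syms)
  ev <- data.table::data.table(fly_id = "f", t_s = c(60, 300, 985),
                               kind = "real")
  scored <- score_response(b, ev, window_s = 30)
  expect_identical(scored$responded, c(TRUE, FALSE, NA))
  # brute-force window oracle on random data
  set.seed(5)
  for (rep in 1:5) {
    b2 <- make_binned(sample(movement_symbols(), 500, TRUE))
    t_ev <- sort(sample(seq(10, 4800, by = 10), 40))
    got <- score_response(b2, data.table::data.table(t_s = t_ev), 30)$responded
    oracle <- vapply(t_ev, function(t) {
      bins <- (t / 10 + 1):(t / 10 + 3)
      if (max(bins) > 500) return(NA)
      any(b2$symbols[bins] == "MOVING")
    }, logical(1))
    expect_identical(got, oracle)
  }
})

test_that("stage assignment uses the half-open bin convention", {
  b <- make_binned(rep("IMMOBILE", 20))
  stages <- rep(c("LIGHT_SLEEP", "DEEP_SLEEP"), each = 10)
  ss <- make_stages(stages, b)
  ev <- data.table::data.table(t_s = c(95, 100, 105, 200, 350))
  out <- assign_stage(ev, ss)
  # 100 s is the boundary: it belongs to the bin starting there (bin 11)
  expect_identical(out$stage_at_delivery,
                   c("LIGHT_SLEEP", "DEEP_SLEEP", "DEEP_SLEEP",
                     "UNASSIGNED", "UNASSIGNED"))
  # index-arithmetic oracle on random event sets
  set.seed(6)
  t_ev <- sample(seq(5, 195, by = 5), 20)
  out2 <- assign_stage(data.table::data.table(t_s = t_ev), ss)
  expect_identical(out2$stage_at_delivery, stages[floor(t_ev / 10) + 1])
})

test_that("Wilson intervals match the standard score interval", {
  for (kn in list(c(5, 10), c(0, 20), c(20, 20), c(3, 200))) {
    ci <- wilson_ci(kn[1], kn[2])
    ref <- prop.test(kn[1], kn[2], correct = FALSE)$conf.int
    expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-10)
  }
  expect_true(all(is.na(wilson_ci(0, 0))))
})

test_that("per-stage summaries count, estimate and bound the response rate", {
  ev <- data.table::data.table(
    stage_at_delivery = rep(c("LIGHT_SLEEP", "DEEP_SLEEP"), each = 10),
    kind = "real",
    responded = c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)))
  out <- response_by_stage(ev)
  light <- out[out$stage == "LIGHT_SLEEP", ]
  expect_equal(light$p, 1)
  expect_equal(light$ci_hi, 1)
  deep <- out[out$stage == "DEEP_SLEEP", ]
  expect_equal(deep$p, 0.5)
  expect_true(deep$ci_lo > 0 && deep$ci_hi < 1)
  # NA responses are excluded and reported
  ev$responded[1] <- NA
  out2 <- response_by_stage(ev)
  expect_identical(out2[out2$stage == "LIGHT_SLEEP", ]$n_unscored, 1L)
  expect_identical(out2[out2$stage == "LIGHT_SLEEP", ]$n, 9L)
})

test_that("probing a simulated fly recovers the arousal ordering", {
  p <- build_species_preset("sechellia_like")
  evs <- lapply(1:6, function(s) {
    sim <- simulate_fly(p, protocol("probing", duration_h = 48), seed = 400 + s)
    b <- bin_movement(sim$recording, 10)
    ev <- score_response(b, sim$latent$stimuli, 30)
    ev$stage_at_delivery <- ev$state_at_delivery
    ev
  })
  out <- response_by_stage(data.table::rbindlist(evs))
  real <- out[out$kind == "real", ]
  p_of <- function(st) real$p[real$stage == st]
  expect_gte(p_of("QUIET_WAKE"), p_of("LIGHT_SLEEP"))
  expect_gt(p_of("LIGHT_SLEEP"), p_of("DEEP_SLEEP"))
  mock <- out[out$kind == "mock", ]
  for (st in c("LIGHT_SLEEP", "DEEP_SLEEP"))
    expect_gt(p_of(st), mock$p[mock$stage == st])
})
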