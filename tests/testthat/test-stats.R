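test_that("the exact rank-sum p-value matches enumeration on the textbook case", {
  r <- exact_wilcoxon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)  # 2 of the C(6,3) = 20 assignments are as extreme
  expect_match(r$method, "enumeration")
  # identical multisets are maximally unremarkable
  expect_equal(exact_wilcoxon(c(1, 2, 3), c(3, 1, 2))$p, 1)
  r_tied <- exact_wilcoxon(rep(2, 4), rep(2, 5))
  expect_equal(r_tied$p, 1)
  expect_true(r_tied$tie_flag)
})

test_that("small-sample p-values agree with an independent enumeration oracle", {
  set.seed(50)
  for (i in 1:50) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- round(rnorm(n), 1); y <- round(rnorm(m, 0.5), 1)
    got <- exact_wilcoxon(x, y)
    ranks <- rank(c(x, y))
    W <- sum(ranks[seq_len(n)])
    mu <- n * (n + m + 1) / 2
    sets <- combn(n + m, n)
    ws <- colSums(matrix(ranks[sets], nrow = n))
    p_oracle <- mean(abs(ws - mu) >= abs(W - mu) - 1e-9)
    expect_lt(abs(got$p - p_oracle), 1e-12)
  }
})

test_that("the shift-algorithm branch reproduces enumeration with ties", {
  set.seed(51)
  x <- sample(1:6, 9, replace = TRUE)
  y <- sample(2:7, 9, replace = TRUE)
  by_enum <- exact_wilcoxon(x, y)                  # C(18,9) = 48620 <= 1e5
  by_shift <- exact_wilcoxon(x, y, enum_limit = 1) # force the DP branch
  expect_match(by_shift$method, "shift")
  expect_lt(abs(by_enum$p - by_shift$p), 1e-12)
  # and without ties, against the classical exact distribution
  x2 <- rnorm(8); y2 <- rnorm(8)
  ref <- wilcox.test(x2, y2, exact = TRUE)$p.value
  got <- exact_wilcoxon(x2, y2, enum_limit = 1)
  expect_equal(got$p, ref, tolerance = 1e-12)
})

test_that("rank-sum p is invariant to group swap and location shift", {
  set.seed(52)
  x <- rnorm(7); y <- rnorm(5, 1)
  a <- exact_wilcoxon(x, y)$p
  expect_equal(exact_wilcoxon(y, x)$p, a, tolerance = 1e-12)
  expect_equal(exact_wilcoxon(x + 10, y + 10)$p, a, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(53)
  p <- runif(20)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))                       # never decreases
  expect_true(all(diff(adj[order(p)]) >= 0))       # monotone in sorted order
  # hand-computed step-up (with monotonicity enforcement) on a fixed vector
  p2 <- c(0.005, 0.04, 0.03, 0.9)
  expect_equal(fdr_adjust(p2), c(0.02, 4 * 0.04 / 3, 4 * 0.04 / 3, 0.9))
})

test_that("bootstrap bands collapse for identical flies and contain the mean", {
  mat <- matrix(rep(1:10, each = 6), nrow = 6)
  ci <- bootstrap_timecourse_ci(mat, n_boot = 100, seed = 1)
  expect_equal(ci$lo, ci$mean)
  expect_equal(ci$hi, ci$mean)
  set.seed(54)
  mat2 <- matrix(rnorm(20 * 12), nrow = 20)
  ci2 <- bootstrap_timecourse_ci(mat2, n_boot = 500, seed = 2)
  expect_true(all(ci2$lo <= ci2$mean & ci2$mean <= ci2$hi))
  expect_error(bootstrap_timecourse_ci(mat2[1, , drop = FALSE]), "2 flies")
})

test_that("bootstrap bands cover the true mean at roughly the nominal rate", {
  set.seed(55)
  n_rep <- 200
  covered <- matrix(FALSE, n_rep, 5)
  for (r in seq_len(n_rep)) {
    mat <- matrix(rnorm(40 * 5), nrow = 40)  # true mean 0 everywhere
    ci <- bootstrap_timecourse_ci(mat, n_boot = 1000, seed = r)
    covered[r, ] <- ci$lo <= 0 & 0 <= ci$hi
  }
  cov <- mean(covered)
  expect_gte(cov, 0.92)
  expect_lte(cov, 0.98)
})

test_that("pressure trends detect monotone stimulus counts and not noise", {
  rising <- t(sapply(1:6, function(i) (1:7) * 10 + i))
  r <- sleep_pressure_trend(rising)
  expect_identical(r$direction, 1)
  expect_lt(r$p, 0.05)
  flat <- matrix(5, 6, 7)
  rf <- sleep_pressure_trend(flat)
  expect_equal(rf$p, 1)
  expect_true(all(rf$rho == 0))
  expect_error(sleep_pressure_trend(matrix(1, 3, 2)), "3 days")
  # null rejection rate near alpha on shuffled counts
  set.seed(56)
  rej <- vapply(1:500, function(i) {
    counts <- matrix(sample(rep(1:7, 8)), nrow = 8)
    sleep_pressure_trend(counts)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.025 / 2)
  expect_lte(mean(rej), 0.1)
})

test_that("log-rank matches the O-E/V hand calculation on a toy dataset", {
  time <- c(2, 4, 6, 1, 3, 5)
  event <- rep(1, 6)
  group <- rep(c("a", "b"), each = 3)
  got <- logrank_test(time, event, group)
  # hand calculation of the standard statistic
  O <- E <- V <- 0
  for (t in sort(unique(time))) {
    at_risk <- time >= t
    d <- sum(time == t & event == 1)
    n <- sum(at_risk); n1 <- sum(at_risk & group == "a")
    d1 <- sum(time == t & event == 1 & group == "a")
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq_hand <- (O - E)^2 / V
  expect_lt(abs(got$statistic - chisq_hand), 1e-12)
  expect_equal(got$p, pchisq(chisq_hand, 1, lower.tail = FALSE))
  # identical curves give a zero statistic
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), group)
  expect_lt(same$statistic, 1e-12)
  # all-censored data: flagged p = 1
  cens <- logrank_test(time, rep(0, 6), group)
  expect_true(cens$no_events)
  expect_equal(cens$p, 1)
  # more than two groups: pairwise table with FDR adjustment
  g3 <- logrank_test(c(time, 7, 8), c(event, 1, 1), c(group, "c", "c"))
  expect_identical(nrow(g3$pairwise), 3L)
  expect_true(all(g3$pairwise$p_adjusted >= g3$pairwise$p_raw))
})

test_that("deprivation efficiency is the fraction of baseline sleep lost", {
  sleepy_day <- rep("IMMOBILE", 8640)
  awake_day <- rep("MOVING", 8640)
  b <- make_binned(c(sleepy_day, awake_day))
  r <- sd_efficiency(b, sd_window = c(24, 48), baseline_window = c(0, 24))
  expect_equal(r$efficiency, 1)
  b2 <- make_binned(c(sleepy_day, sleepy_day))
  expect_equal(sd_efficiency(b2, c(24, 48), c(0, 24))$efficiency, 0)
  b3 <- make_binned(c(awake_day, sleepy_day))
  r3 <- sd_efficiency(b3, c(24, 48), c(0, 24))
  expect_true(r3$undefined)
})

test_that("rebound comparison returns p = 1 for identical groups", {
  co <- simulate_cohort("yakuba_like", protocol("baseline", duration_h = 72),
                        n_flies = 8, seed = 70)
  binned <- lapply(co$recordings, bin_movement, 10)
  r <- rebound_window_sleep(binned, binned, window = c(0, 3), recovery_day = 3)
  expect_equal(r$p_raw, 1)
  expect_equal(r$diff_medians, 0)
  expect_error(rebound_window_sleep(list(), binned), "empty group")
})
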