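test_that("initialization honors the structural constraints and the seed", {
  m <- hmm_init(seed = 1)
  expect_identical(m$A["DEEP_SLEEP", "ACTIVE_WAKE"], 0)
  expect_identical(m$A["ACTIVE_WAKE", "DEEP_SLEEP"], 0)
  expect_identical(m$A["QUIET_WAKE", "DEEP_SLEEP"], 0)
  expect_lt(max(abs(rowSums(m$A) - 1)), 1e-12)
  expect_identical(hmm_init(seed = 1)$A, m$A)
  expect_false(identical(hmm_init(seed = 2)$A, m$A))
  bad <- default_structural_zeros()
  bad["DEEP_SLEEP", ] <- TRUE
  expect_error(hmm_init(constraints = bad), "forbids every transition")
  unreachable <- matrix(FALSE, 4, 4)
  unreachable[, 4] <- TRUE  # nothing may enter deep sleep, including itself
  expect_error(hmm_init(constraints = unreachable), "reducible")
})

test_that("forward likelihood equals the brute-force sum over all paths", {
  tr <- canonical_truth()
  set.seed(14)
  for (rep in 1:3) {
    obs <- sample(1:3, 10, replace = TRUE)
    m <- drosleep:::new_hmm(tr$A, tr$B, tr$rho)
    ll <- hmm_loglik(m, obs)
    bf <- brute_force_loglik(tr$A, tr$B, tr$rho, obs)
    expect_lt(abs(ll - bf) / abs(bf), 1e-10)
  }
})

test_that("Viterbi equals exhaustive search over all length-8 paths", {
  set.seed(15)
  for (rep in 1:3) {
    # arbitrary small random model
    A <- matrix(rexp(16), 4); A <- A / rowSums(A)
    B <- matrix(rexp(12), 4); B <- B / rowSums(B)
    rho <- rexp(4); rho <- rho / sum(rho)
    obs <- sample(1:3, 8, replace = TRUE)
    m <- drosleep:::new_hmm(A, B, rho)
    m$fitted <- TRUE
    path <- match(hmm_decode(m, obs)$stages, sleep_states())
    expect_identical(path, unname(brute_force_viterbi(A, B, rho, obs)))
  }
})

test_that("EM log-likelihood is monotone nondecreasing", {
  set.seed(16)
  tr <- canonical_truth()
  seqs <- lapply(1:3, function(i) sample_hmm(tr$A, tr$B, tr$rho, 2000)$symbols)
  fit <- hmm_fit(hmm_init(3), seqs, restarts = 2, seed = 5)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("a 2-state identity-emission chain is recovered within 0.02", {
  A <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  B <- diag(2)
  rho <- c(0.5, 0.5)
  set.seed(17)
  seqs <- lapply(1:50, function(i) sample_hmm(A, B, rho, 2000)$symbols)
  m0 <- drosleep:::new_hmm(matrix(0.5, 2, 2), rbind(c(0.6, 0.4), c(0.4, 0.6)),
                           rho)
  fit <- hmm_fit(m0, seqs, restarts = 2, seed = 18)
  # align states by their dominant emission before comparing
  perm <- apply(fit$B, 1, which.max)
  expect_identical(sort(perm), 1:2)
  expect_lt(max(abs(fit$A[order(perm), order(perm)] - A)), 0.02)
})

test_that("a constrained 4-state model is recovered from simulated flies", {
  tr <- canonical_truth()
  set.seed(19)
  seqs <- lapply(1:10, function(i) sample_hmm(tr$A, tr$B, tr$rho, 8640)$symbols)
  fit <- label_states(hmm_fit(hmm_init(4), seqs, restarts = 3, seed = 20))
  expect_lt(max(abs(fit$A - tr$A)), 0.05)
  expect_lt(max(abs(fit$B - tr$B)), 0.05)
  # structural zeros survive fitting exactly
  expect_identical(unname(fit$A[default_structural_zeros()]), rep(0, 3))
})

test_that("canonical labeling is a self-inverse permutation of the model", {
  tr <- canonical_truth()
  m <- drosleep:::new_hmm(tr$A, tr$B, tr$rho,
                          structural_zeros = default_structural_zeros())
  dimnames(m$A) <- list(sleep_states(), sleep_states())
  dimnames(m$B) <- list(sleep_states(), movement_symbols())
  m$fitted <- TRUE
  canon <- label_states(m)
  expect_identical(canon$label_permutation, 1:4)  # already canonical
  expect_equal(unname(canon$A), unname(tr$A))
  # a permuted copy is mapped back to the original
  perm <- c(3, 1, 4, 2)
  mp <- m
  mp$A <- m$A[perm, perm]; mp$B <- m$B[perm, ]; mp$rho <- m$rho[perm]
  mp$structural_zeros <- m$structural_zeros[perm, perm]
  back <- label_states(mp)
  expect_equal(unname(back$A), unname(tr$A))
  expect_equal(unname(back$B), unname(tr$B))
})

test_that("labels recover the generating identities across seeded fits", {
  tr <- canonical_truth()
  ok <- 0L
  for (seed in 1:20) {
    set.seed(seed + 300)
    seqs <- lapply(1:5, function(i) sample_hmm(tr$A, tr$B, tr$rho, 5000)$symbols)
    fit <- label_states(hmm_fit(hmm_init(seed), seqs, restarts = 2,
                                seed = seed + 600))
    # labels match when each labeled state's emission row is closest to the
    # generating row of the same name
    match_ok <- all(vapply(1:4, function(s)
      which.min(colSums((t(tr$B) - fit$B[s, ])^2)) == s, logical(1)))
    ok <- ok + match_ok
  }
  expect_gte(ok, 19)
})

test_that("decoding maps symbols through an identity-emission model", {
  A <- matrix(0.25, 4, 4)
  B <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  B[4, ] <- c(1/3, 1/3, 1/3)
  m <- drosleep:::new_hmm(A, B, c(0.3, 0.3, 0.3, 0.1))
  m$fitted <- TRUE
  obs <- c(1, 2, 3, 1, 1, 2)
  path <- match(hmm_decode(m, obs)$stages, sleep_states())
  expect_identical(path, as.integer(obs))
  err <- tryCatch(hmm_decode(m, c("MOVING", "JUMPING")), error = identity)
  expect_match(conditionMessage(err), "position 2")
})

test_that("decoding is invariant to emission scaling with renormalization", {
  tr <- canonical_truth()
  m <- drosleep:::new_hmm(tr$A, tr$B, tr$rho); m$fitted <- TRUE
  set.seed(21)
  obs <- sample(1:3, 500, replace = TRUE, prob = c(0.4, 0.2, 0.4))
  m2 <- m
  m2$B <- (tr$B * 7) / rowSums(tr$B * 7)
  expect_identical(hmm_decode(m, obs)$stages, hmm_decode(m2, obs)$stages)
})

test_that("decoding commutes with relabeling", {
  tr <- canonical_truth()
  perm <- c(2, 4, 1, 3)
  scrambled <- drosleep:::new_hmm(tr$A[perm, perm], tr$B[perm, ],
                                  tr$rho[perm])
  scrambled$fitted <- TRUE
  dimnames(scrambled$A) <- list(sleep_states(), sleep_states())
  dimnames(scrambled$B) <- list(sleep_states(), movement_symbols())
  scrambled$structural_zeros <- matrix(FALSE, 4, 4,
                                       dimnames = dimnames(scrambled$A))
  set.seed(22)
  obs <- sample(1:3, 400, replace = TRUE)
  canon <- label_states(scrambled)
  path_after <- hmm_decode(canon, obs)$stages
  # decode with the scrambled model, then rename its states canonically
  raw <- hmm_decode(scrambled, obs)$stages
  inv <- canon$label_permutation
  renamed <- sleep_states()[match(match(raw, sleep_states()), inv)]
  expect_identical(path_after, renamed)
})

test_that("degenerate single-symbol data fit with a warning and a flag", {
  seqs <- list(rep("IMMOBILE", 200), rep("IMMOBILE", 300))
  expect_warning(fit <- hmm_fit(hmm_init(5), seqs, restarts = 1,
                                max_iter = 10, min_iter = 1),
                 "degenerate")
  expect_true(fit$degenerate)
})

test_that("model serialization round-trips exactly", {
  tr <- canonical_truth()
  set.seed(23)
  seqs <- lapply(1:2, function(i) sample_hmm(tr$A, tr$B, tr$rho, 1500)$symbols)
  m <- label_states(hmm_fit(hmm_init(6), seqs, restarts = 1, max_iter = 60))
  path <- tempfile(fileext = ".hmm")
  write_hmm(m, path)
  back <- read_hmm(path)
  expect_identical(back$A, m$A)
  expect_identical(back$B, m$B)
  expect_identical(back$rho, m$rho)
  expect_identical(back$structural_zeros, m$structural_zeros)
  expect_identical(back$train_loglik, m$train_loglik)
  expect_identical(back$bin_s, m$bin_s)
  expect_error(read_hmm(system.file("DESCRIPTION", package = "drosleep")),
               "not a drosleep model")
  unlink(path)
})

test_that("training sequences must be long enough", {
  expect_error(hmm_fit(hmm_init(1), list(rep("MOVING", 50))), "100 bins")
})
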