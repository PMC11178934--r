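# shared fixture builders; everything is generated in code

# a binned_movement object built directly from a symbol vector
make_binned <- function(symbols, bin_s = 10, fly_id = "test_fly",
                        t0_s = 0) {
  structure(list(
    fly_id = fly_id, bin_s = bin_s, symbols = symbols,
    zt = drosleep::to_zt(t0_s + (seq_along(symbols) - 1) * bin_s)),
    class = "binned_movement")
}

# a stage_sequence aligned with a binned_movement
make_stages <- function(stages, binned) {
  structure(list(fly_id = binned$fly_id, stages = stages, zt = binned$zt,
                 bin_s = binned$bin_s, source_model = NA_real_),
            class = "stage_sequence")
}

# sample a sequence of latent states + symbols from a homogeneous HMM
sample_hmm <- function(A, B, rho, n) {
  k <- nrow(A); m <- ncol(B)
  s <- integer(n); o <- integer(n)
  s[1] <- sample.int(k, 1, prob = rho)
  o[1] <- sample.int(m, 1, prob = B[s[1], ])
  for (i in 2:n) {
    s[i] <- sample.int(k, 1, prob = A[s[i - 1], ])
    o[i] <- sample.int(m, 1, prob = B[s[i], ])
  }
  list(states = s, symbols = o)
}

# a well-separated canonical 4-state generating model (homogeneous),
# mirroring the structural constraints of the staging model
canonical_truth <- function() {
  A <- rbind(c(0.955, 0.025, 0.020, 0.000),
             c(0.100, 0.800, 0.100, 0.000),
             c(0.015, 0.025, 0.952, 0.008),
             c(0.000, 0.000, 0.006, 0.994))
  B <- rbind(c(0.95, 0.04, 0.01),
             c(0.62, 0.10, 0.28),
             c(0.01, 0.13, 0.86),
             c(0.01, 0.03, 0.96))
  rho <- c(0.7, 0.1, 0.15, 0.05)
  list(A = A, B = B, rho = rho)
}

# brute-force likelihood: sum over every state path (small inputs only)
brute_force_loglik <- function(A, B, rho, obs) {
  k <- nrow(A); n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  p <- rho[paths[, 1]] * B[cbind(paths[, 1], obs[1])]
  for (t in 2:n)
    p <- p * A[cbind(paths[, t - 1], paths[, t])] * B[cbind(paths[, t], obs[t])]
  log(sum(p))
}

# brute-force most-probable path (small inputs only)
brute_force_viterbi <- function(A, B, rho, obs) {
  k <- nrow(A); n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  p <- rho[paths[, 1]] * B[cbind(paths[, 1], obs[1])]
  for (t in 2:n)
    p <- p * A[cbind(paths[, t - 1], paths[, t])] * B[cbind(paths[, t], obs[t])]
  paths[which.max(p), ]
}
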