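#' Default structural constraints of the staging model
#'
#' Deep sleep can only be entered from light sleep (or maintained), and a
#' fly never jumps from deep sleep directly to active wake. Entries are
#' `TRUE` where a transition is forbidden.
#'
#' @return 4x4 logical matrix in canonical state order.
#' @export
default_structural_zeros <- function() {
  m <- matrix(FALSE, 4, 4, dimnames = list(STATES, STATES))
  m["ACTIVE_WAKE", "DEEP_SLEEP"] <- TRUE
  m["QUIET_WAKE", "DEEP_SLEEP"] <- TRUE
  m["DEEP_SLEEP", "ACTIVE_WAKE"] <- TRUE
  m
}

check_constraints <- function(mask) {
  stopifnot(is.logical(mask), nrow(mask) == ncol(mask))
  k <- nrow(mask)
  allowed <- !mask
  if (any(rowSums(allowed) == 0))
    stop("constraint mask forbids every transition out of state ",
         which(rowSums(allowed) == 0)[1])
  # irreducibility over allowed edges: every state reachable from every other
  reach <- allowed | diag(k) > 0
  for (i in seq_len(k)) reach <- (reach %*% reach) > 0
  if (!all(reach))
    stop("constraint mask makes the chain reducible (some state unreachable)")
  invisible(TRUE)
}

# bare constructor (also used with non-default dimensions in tests of the
# generic fitting machinery)
new_hmm <- function(A, B, rho, structural_zeros = NULL, bin_s = 10) {
  if (is.null(structural_zeros))
    structural_zeros <- matrix(FALSE, nrow(A), ncol(A))
  structure(list(states = rownames(A) %||% paste0("S", seq_len(nrow(A))),
                 A = A, B = B, rho = rho,
                 structural_zeros = structural_zeros,
                 train_loglik = NA_real_, bin_s = bin_s, fitted = FALSE,
                 degenerate = FALSE, loglik_trace = numeric(0)),
            class = "hmm_model")
}

#' Initialize a staging model
#'
#' Draws a random valid model (Dirichlet rows) respecting the structural
#' constraint mask.
#'
#' @param seed Integer seed.
#' @param constraints Logical 4x4 mask of forbidden transitions.
#' @param bin_s Bin width the model operates at, seconds.
#' @return An object of class `hmm_model` with fields `states`, `A`, `B`,
#'   `rho`, `structural_zeros`, `train_loglik`, `bin_s`.
#' @export
hmm_init <- function(seed = 1, constraints = default_structural_zeros(),
                     bin_s = 10) {
  check_constraints(constraints)
  set.seed(seed)
  # Dirichlet rows centered on the behavioral roles the constraint mask
  # encodes (wake states mobile, sleep states immobile, deep stickiest),
  # so the positional constraints keep their intended meaning during EM.
  rdir <- function(center, conc = 10) {
    g <- stats::rgamma(length(center), shape = center * conc)
    g / sum(g)
  }
  a_center <- rbind(c(0.90, 0.04, 0.04, 0.02),
                    c(0.20, 0.60, 0.15, 0.05),
                    c(0.05, 0.05, 0.80, 0.10),
                    c(0.01, 0.01, 0.08, 0.90))
  b_center <- rbind(c(0.80, 0.10, 0.10),
                    c(0.40, 0.30, 0.30),
                    c(0.10, 0.20, 0.70),
                    c(0.05, 0.10, 0.85))
  A <- t(vapply(1:4, function(r) {
    w <- rdir(a_center[r, ])
    w[constraints[r, ]] <- 0
    w / sum(w)
  }, numeric(4)))
  B <- t(vapply(1:4, function(r) rdir(b_center[r, ]), numeric(3)))
  rho <- rdir(c(0.4, 0.2, 0.2, 0.2))
  dimnames(A) <- list(STATES, STATES)
  dimnames(B) <- list(STATES, SYMBOLS)
  names(rho) <- STATES
  structure(list(states = STATES, A = A, B = B, rho = rho,
                 structural_zeros = constraints, train_loglik = NA_real_,
                 bin_s = bin_s, fitted = FALSE, degenerate = FALSE,
                 loglik_trace = numeric(0)),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, digits = 3, ...) {
  cat("<hmm_model>", if (x$fitted) "fitted" else "unfitted",
      sprintf("(bin_s = %g s)", x$bin_s), "\n")
  if (x$fitted) cat("  train loglik:", format(x$train_loglik), "\n")
  cat("  transition matrix:\n")
  print(round(x$A, digits))
  cat("  emission matrix:\n")
  print(round(x$B, digits))
  invisible(x)
}

as_symbol_int <- function(symbols) {
  if (inherits(symbols, "binned_movement")) symbols <- symbols$symbols
  if (is.character(symbols)) {
    idx <- match(symbols, SYMBOLS)
    if (anyNA(idx))
      stop("symbol outside alphabet at position ", which(is.na(idx))[1],
           ": '", symbols[which(is.na(idx))[1]], "'")
    return(idx - 1L)
  }
  stopifnot(is.numeric(symbols), all(symbols %in% 1:3))
  as.integer(symbols) - 1L
}

#' Fit a staging model by Baum-Welch expectation-maximization
#'
#' Runs EM from `restarts` random initializations (the supplied model is
#' the first) and returns the restart with the best final log-likelihood.
#' Structural zeros are preserved exactly; the log-likelihood trace is
#' monotone nondecreasing within each restart.
#'
#' @param model An `hmm_model` (from [hmm_init()]).
#' @param sequences List of symbol sequences (character vectors over
#'   [movement_symbols()] or `binned_movement` objects), each at least
#'   100 bins.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Stop when the log-likelihood improvement drops below `tol`.
#' @param restarts Number of random restarts.
#' @param min_iter Minimum EM iterations before the tolerance stop is
#'   honored; rare emissions decay geometrically toward zero and need a
#'   few dozen iterations to collapse even after the log-likelihood has
#'   plateaued.
#' @param seed Seed controlling the restart initializations.
#' @return The fitted `hmm_model`, with `train_loglik` and
#'   `loglik_trace` filled in.
#' @export
hmm_fit <- function(model, sequences, max_iter = 500, tol = 1e-4,
                    restarts = 5, min_iter = 30, seed = 1) {
  stopifnot(inherits(model, "hmm_model"), length(sequences) >= 1)
  obs <- lapply(sequences, as_symbol_int)
  if (any(lengths(obs) < 100))
    stop("every training sequence must be at least 100 bins long")
  degenerate <- length(unique(unlist(lapply(obs, unique)))) == 1
  if (degenerate)
    warning("degenerate training data (single symbol throughout); ",
            "best-effort fit flagged")
  mask <- model$structural_zeros

  canonical <- nrow(model$A) == 4 && ncol(model$B) == 3
  run_em <- function(m) {
    fit <- hmm_em_cpp(m$A, m$B, m$rho, obs, mask, max_iter, tol, min_iter)
    A <- fit$A; B <- fit$B; rho <- as.numeric(fit$rho)
    if (canonical) {
      dimnames(A) <- list(STATES, STATES)
      dimnames(B) <- list(STATES, SYMBOLS)
      names(rho) <- STATES
    }
    list(A = A, B = B, rho = rho, loglik = fit$loglik, trace = fit$trace)
  }

  fits <- vector("list", restarts)
  fits[[1]] <- run_em(model)
  if (restarts > 1) {
    for (r in 2:restarts)
      fits[[r]] <- run_em(if (canonical)
        hmm_init(seed + r, constraints = mask, bin_s = model$bin_s)
      else perturb_model(model, seed + r))
  }
  lls <- vapply(fits, `[[`, 0, "loglik")
  if (canonical && any(mask) && !degenerate) {
    # A restart is label-consistent when, after canonical relabeling, the
    # transitions the mask forbids are still (numerically) zero; scrambled
    # local optima that repurpose the constrained state are rejected.
    consistent <- vapply(fits, function(f) {
      tmp <- model
      tmp$A <- f$A; tmp$B <- f$B; tmp$rho <- f$rho; tmp$fitted <- TRUE
      rl <- label_states(tmp)
      max(rl$A[mask]) < 1e-6
    }, logical(1))
    if (any(consistent)) {
      lls[!consistent] <- -Inf
    } else {
      warning("no restart produced a label-consistent fit; ",
              "returning the best-likelihood model")
    }
  }
  best <- fits[[which.max(lls)]]
  model$A <- best$A; model$B <- best$B; model$rho <- best$rho
  model$train_loglik <- best$loglik
  model$loglik_trace <- best$trace
  model$fitted <- TRUE
  model$degenerate <- degenerate
  model
}

# random restart for non-canonical model dimensions: jitter rows with a
# Dirichlet perturbation, preserving structural zeros
perturb_model <- function(model, seed) {
  set.seed(seed)
  jitter_rows <- function(m, mask = NULL) {
    for (r in seq_len(nrow(m))) {
      g <- stats::rgamma(ncol(m), shape = 1)
      w <- m[r, ] * 0.2 + 0.8 * g / sum(g)
      if (!is.null(mask)) w[mask[r, ]] <- 0
      m[r, ] <- w / sum(w)
    }
    m
  }
  model$A <- jitter_rows(model$A, model$structural_zeros)
  model$B <- jitter_rows(model$B)
  model
}

#' Canonical state labeling of a fitted model
#'
#' Assigns the canonical labels by behavioral signature: `ACTIVE_WAKE` is
#' the state with the highest probability of emitting `MOVING`; among the
#' rest, the two with the highest immobile-emission probability are the
#' sleep states, of which `DEEP_SLEEP` is the one with the longer expected
#' dwell time `1 / (1 - A[s, s])` (ties broken by immobile-emission
#' probability); `LIGHT_SLEEP` is the other; `QUIET_WAKE` is the
#' remainder. The relabeling is a pure permutation of `A`, `B`, `rho` and
#' the constraint mask.
#'
#' @param model A fitted `hmm_model`.
#' @return The relabeled model, with attribute field `label_permutation`
#'   (index such that new state i is old state `label_permutation[i]`).
#' @export
label_states <- function(model) {
  stopifnot(inherits(model, "hmm_model"))
  B <- model$B; A <- model$A
  active <- which.max(B[, "MOVING"])
  rest <- setdiff(1:4, active)
  imm <- B[rest, "IMMOBILE"]
  sleepers <- rest[order(-imm)][1:2]
  quiet <- setdiff(rest, sleepers)
  dwell <- 1 / (1 - diag(A)[sleepers])
  # longer-dwelling sleep state is deep; tie-break on immobility emission
  ord <- order(-dwell, -B[sleepers, "IMMOBILE"])
  deep <- sleepers[ord[1]]; light <- sleepers[ord[2]]
  perm <- unname(c(active, quiet, light, deep))
  model$A <- model$A[perm, perm, drop = FALSE]
  model$B <- model$B[perm, , drop = FALSE]
  model$rho <- model$rho[perm]
  model$structural_zeros <- model$structural_zeros[perm, perm, drop = FALSE]
  dimnames(model$A) <- list(STATES, STATES)
  dimnames(model$B) <- list(STATES, SYMBOLS)
  names(model$rho) <- STATES
  dimnames(model$structural_zeros) <- list(STATES, STATES)
  model$label_permutation <- perm
  model
}

#' Log-likelihood of a symbol sequence under a model
#'
#' Scaled forward-algorithm likelihood.
#'
#' @param model An `hmm_model`.
#' @param symbols Symbol sequence (character or `binned_movement`).
#' @return Log-likelihood.
#' @export
hmm_loglik <- function(model, symbols) {
  hmm_forward_loglik_cpp(model$A, model$B, model$rho, as_symbol_int(symbols))
}

#' Viterbi decoding of a symbol sequence
#'
#' Most-probable state path under the model; deterministic given inputs.
#'
#' @param model A fitted `hmm_model`.
#' @param binned A `binned_movement` object (or bare symbol vector).
#' @return Object of class `stage_sequence`: `fly_id`, per-bin `stages`,
#'   `zt`, `bin_s` and `source_model`.
#' @export
hmm_decode <- function(model, binned) {
  stopifnot(inherits(model, "hmm_model"))
  if (!model$fitted)
    warning("decoding with an unfitted model")
  obs <- as_symbol_int(binned)
  path <- hmm_viterbi_cpp(model$A, model$B, model$rho, obs)
  structure(list(
    fly_id = if (inherits(binned, "binned_movement")) binned$fly_id else NA_character_,
    stages = STATES[path],
    zt = if (inherits(binned, "binned_movement")) binned$zt else NULL,
    bin_s = if (inherits(binned, "binned_movement")) binned$bin_s else model$bin_s,
    source_model = model$train_loglik
  ), class = "stage_sequence")
}

#' @export
print.stage_sequence <- function(x, ...) {
  cat("<stage_sequence>", x$fly_id, ":", length(x$stages), "bins\n")
  print(round(table(x$stages) / length(x$stages), 3))
  invisible(x)
}

#' Write / read a staging model as plain text
#'
#' Key-value plus matrix blocks at full double precision; the round trip
#' is exact to better than 1e-15.
#'
#' @param model An `hmm_model`.
#' @param path File path.
#' @return `write_hmm`: `path` invisibly. `read_hmm`: the model.
#' @export
write_hmm <- function(model, path) {
  fm <- function(x) sprintf("%.17g", x)
  lines <- c(
    "drosleep_hmm 1",
    paste("bin_s", fm(model$bin_s)),
    paste("train_loglik", fm(model$train_loglik)),
    paste("fitted", as.integer(model$fitted)),
    paste("states", paste(model$states, collapse = " ")),
    "A", vapply(1:4, function(r) paste(fm(model$A[r, ]), collapse = " "), ""),
    "B", vapply(1:4, function(r) paste(fm(model$B[r, ]), collapse = " "), ""),
    paste("rho", paste(fm(model$rho), collapse = " ")),
    "structural_zeros",
    vapply(1:4, function(r)
      paste(as.integer(model$structural_zeros[r, ]), collapse = " "), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "drosleep_hmm"))
    stop("not a drosleep model file: ", path)
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    strsplit(sub(paste0("^", key, " "), "", ln), " ")[[1]]
  }
  block <- function(key, nrow) {
    i <- which(lines == key)[1]
    t(vapply(lines[(i + 1):(i + nrow)],
             function(l) as.numeric(strsplit(l, " ")[[1]]),
             numeric(length(strsplit(lines[i + 1], " ")[[1]])),
             USE.NAMES = FALSE))
  }
  A <- block("A", 4); B <- block("B", 4)
  rho <- as.numeric(kv("rho"))
  sz <- block("structural_zeros", 4) > 0
  dimnames(A) <- list(STATES, STATES)
  dimnames(B) <- list(STATES, SYMBOLS)
  names(rho) <- STATES
  dimnames(sz) <- list(STATES, STATES)
  structure(list(states = kv("states"), A = A, B = B, rho = rho,
                 structural_zeros = sz,
                 train_loglik = as.numeric(kv("train_loglik")),
                 bin_s = as.numeric(kv("bin_s")),
                 fitted = as.integer(kv("fitted")) == 1,
                 degenerate = FALSE, loglik_trace = numeric(0)),
            class = "hmm_model")
}
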