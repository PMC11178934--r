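#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass. obs is 0-based symbol index.
// Returns log-likelihood only.
// [[Rcpp::export]]
double hmm_forward_loglik_cpp(NumericMatrix A, NumericMatrix B,
                              NumericVector rho, IntegerVector obs) {
  const int S = A.nrow();
  const int T = obs.size();
  std::vector<double> alpha(S), alpha_new(S);
  double ll = 0.0;

  double c = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha[s] = rho[s] * B(s, obs[0]);
    c += alpha[s];
  }
  if (c <= 0.0) return R_NegInf;
  for (int s = 0; s < S; ++s) alpha[s] /= c;
  ll += std::log(c);

  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int r = 0; r < S; ++r) acc += alpha[r] * A(r, s);
      alpha_new[s] = acc * B(s, obs[t]);
      c += alpha_new[s];
    }
    if (c <= 0.0) return R_NegInf;
    for (int s = 0; s < S; ++s) alpha[s] = alpha_new[s] / c;
    ll += std::log(c);
  }
  return ll;
}

// One E-step over a single sequence (scaled forward-backward).
// Returns expected transition counts, expected emission counts,
// gamma at t=0 and the sequence log-likelihood.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericMatrix A, NumericMatrix B,
                   NumericVector rho, IntegerVector obs) {
  const int S = A.nrow();
  const int M = B.ncol();
  const int T = obs.size();

  NumericMatrix alpha(T, S);
  NumericVector scale(T);
  double ll = 0.0;

  // forward
  double c = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha(0, s) = rho[s] * B(s, obs[0]);
    c += alpha(0, s);
  }
  if (c <= 0.0) stop("zero forward probability at t=1 (symbol impossible under model)");
  for (int s = 0; s < S; ++s) alpha(0, s) /= c;
  scale[0] = c;
  ll += std::log(c);

  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int r = 0; r < S; ++r) acc += alpha(t - 1, r) * A(r, s);
      alpha(t, s) = acc * B(s, obs[t]);
      c += alpha(t, s);
    }
    if (c <= 0.0) stop("zero forward probability at t=%d", t + 1);
    for (int s = 0; s < S; ++s) alpha(t, s) /= c;
    scale[t] = c;
    ll += std::log(c);
  }

  // backward + accumulation
  NumericMatrix trans(S, S);
  NumericMatrix emit(S, M);
  NumericVector gamma0(S);

  std::vector<double> beta(S, 1.0), beta_new(S);
  for (int s = 0; s < S; ++s) emit(s, obs[T - 1]) += alpha(T - 1, s);

  for (int t = T - 2; t >= 0; --t) {
    // xi_t(r,s) proportional to alpha(t,r) A(r,s) B(s,obs[t+1]) beta_{t+1}(s)
    for (int r = 0; r < S; ++r) {
      double acc = 0.0;
      for (int s = 0; s < S; ++s) {
        double x = alpha(t, r) * A(r, s) * B(s, obs[t + 1]) * beta[s] / scale[t + 1];
        trans(r, s) += x;
        acc += A(r, s) * B(s, obs[t + 1]) * beta[s];
      }
      beta_new[r] = acc / scale[t + 1];
    }
    for (int r = 0; r < S; ++r) beta[r] = beta_new[r];
    for (int s = 0; s < S; ++s) {
      double g = alpha(t, s) * beta[s];
      emit(s, obs[t]) += g;
      if (t == 0) gamma0[s] = g;
    }
  }
  if (T == 1) for (int s = 0; s < S; ++s) gamma0[s] = alpha(0, s);

  return List::create(_["loglik"] = ll, _["trans"] = trans,
                      _["emit"] = emit, _["gamma0"] = gamma0);
}

// Full Baum-Welch EM over a list of sequences, entirely in C++.
// mask: true where a transition is structurally forbidden.
// Returns final parameters and the (monotone) log-likelihood trace.
// The trace entry at iteration k is the log-likelihood of the parameters
// *entering* iteration k; iteration stops when the improvement drops
// below tol (but not before min_iter iterations) or at max_iter.
//
// The kernel is templated on the state/symbol counts so the canonical
// 4-state / 3-symbol staging model compiles fully unrolled; other
// dimensions fall back to a generic (slower) instantiation.

template <int S, int M>
static List em_run(NumericMatrix A0, NumericMatrix B0, NumericVector rho0,
                   const std::vector<std::vector<int> >& seqs,
                   LogicalMatrix mask, int max_iter, double tol,
                   int min_iter) {
  double A[S * S], B[S * M], rho[S];
  for (int r = 0; r < S; ++r) {
    for (int s = 0; s < S; ++s) A[r * S + s] = A0(r, s);
    for (int m = 0; m < M; ++m) B[r * M + m] = B0(r, m);
    rho[r] = rho0[r];
  }
  size_t tmax = 0;
  for (size_t i = 0; i < seqs.size(); ++i)
    tmax = std::max(tmax, seqs[i].size());
  std::vector<double> alpha(tmax * S), scale(tmax);
  double trans[S * S], emit[S * M], gamma0[S];
  std::vector<double> trace;
  double prev = -std::numeric_limits<double>::infinity();

  for (int it = 0; it < max_iter; ++it) {
    std::fill(trans, trans + S * S, 0.0);
    std::fill(emit, emit + S * M, 0.0);
    std::fill(gamma0, gamma0 + S, 0.0);
    double ll = 0.0;

    for (size_t q = 0; q < seqs.size(); ++q) {
      const std::vector<int>& obs = seqs[q];
      const int T = (int)obs.size();
      // forward (scaled)
      double c = 0.0;
      for (int s = 0; s < S; ++s) {
        alpha[s] = rho[s] * B[s * M + obs[0]];
        c += alpha[s];
      }
      if (c <= 0.0) stop("zero forward probability during EM");
      for (int s = 0; s < S; ++s) alpha[s] /= c;
      scale[0] = c; ll += std::log(c);
      for (int t = 1; t < T; ++t) {
        double* at = &alpha[(size_t)t * S];
        const double* ap = &alpha[(size_t)(t - 1) * S];
        c = 0.0;
        const int o = obs[t];
        for (int s = 0; s < S; ++s) {
          double acc = 0.0;
          for (int r = 0; r < S; ++r) acc += ap[r] * A[r * S + s];
          at[s] = acc * B[s * M + o];
          c += at[s];
        }
        if (c <= 0.0) stop("zero forward probability during EM");
        for (int s = 0; s < S; ++s) at[s] /= c;
        scale[t] = c; ll += std::log(c);
      }
      // backward + accumulate
      double beta[S], beta_new[S], bb[S];
      for (int s = 0; s < S; ++s) beta[s] = 1.0;
      {
        const double* at = &alpha[(size_t)(T - 1) * S];
        for (int s = 0; s < S; ++s) emit[s * M + obs[T - 1]] += at[s];
      }
      for (int t = T - 2; t >= 0; --t) {
        const double* at = &alpha[(size_t)t * S];
        const int o1 = obs[t + 1];
        const double sc = scale[t + 1];
        for (int s = 0; s < S; ++s) bb[s] = B[s * M + o1] * beta[s] / sc;
        for (int r = 0; r < S; ++r) {
          double acc = 0.0;
          const double* Ar = &A[r * S];
          for (int s = 0; s < S; ++s) {
            const double x = Ar[s] * bb[s];
            trans[r * S + s] += at[r] * x;
            acc += x;
          }
          beta_new[r] = acc;
        }
        for (int r = 0; r < S; ++r) beta[r] = beta_new[r];
        const int o = obs[t];
        for (int s = 0; s < S; ++s) {
          const double g = at[s] * beta[s];
          emit[s * M + o] += g;
          if (t == 0) gamma0[s] += g;
        }
      }
      if (T == 1) for (int s = 0; s < S; ++s) gamma0[s] += alpha[s];
    }

    trace.push_back(ll);
    const double improved = ll - prev;
    prev = ll;

    // M-step with structural zeros
    for (int r = 0; r < S; ++r) {
      double tot = 0.0;
      for (int s = 0; s < S; ++s) {
        if (mask(r, s)) trans[r * S + s] = 0.0;
        tot += trans[r * S + s];
      }
      if (tot > 0) for (int s = 0; s < S; ++s) A[r * S + s] = trans[r * S + s] / tot;
      double te = 0.0;
      for (int m = 0; m < M; ++m) te += emit[r * M + m];
      if (te > 0) for (int m = 0; m < M; ++m) B[r * M + m] = emit[r * M + m] / te;
    }
    double tg = 0.0;
    for (int s = 0; s < S; ++s) tg += gamma0[s];
    for (int s = 0; s < S; ++s) rho[s] = gamma0[s] / tg;

    if (it + 1 >= min_iter && improved < tol) break;
  }

  NumericMatrix Aout(S, S), Bout(S, M);
  NumericVector rhoout(S);
  for (int r = 0; r < S; ++r) {
    for (int s = 0; s < S; ++s) Aout(r, s) = A[r * S + s];
    for (int m = 0; m < M; ++m) Bout(r, m) = B[r * M + m];
    rhoout[r] = rho[r];
  }
  return List::create(_["A"] = Aout, _["B"] = Bout, _["rho"] = rhoout,
                      _["loglik"] = prev, _["trace"] = wrap(trace));
}

// [[Rcpp::export]]
List hmm_em_cpp(NumericMatrix A0, NumericMatrix B0, NumericVector rho0,
                List obs_list, LogicalMatrix mask,
                int max_iter, double tol, int min_iter) {
  const int S = A0.nrow(), M = B0.ncol();
  std::vector<std::vector<int> > seqs(obs_list.size());
  for (int i = 0; i < obs_list.size(); ++i) {
    IntegerVector o = obs_list[i];
    seqs[i].assign(o.begin(), o.end());
  }
  if (S == 4 && M == 3)
    return em_run<4, 3>(A0, B0, rho0, seqs, mask, max_iter, tol, min_iter);
  if (S == 2 && M == 2)
    return em_run<2, 2>(A0, B0, rho0, seqs, mask, max_iter, tol, min_iter);
  if (S == 2 && M == 3)
    return em_run<2, 3>(A0, B0, rho0, seqs, mask, max_iter, tol, min_iter);
  if (S == 3 && M == 3)
    return em_run<3, 3>(A0, B0, rho0, seqs, mask, max_iter, tol, min_iter);
  stop("unsupported model dimensions (%d states, %d symbols)", S, M);
}

// Viterbi decoding in log space; returns 1-based state path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix A, NumericMatrix B,
                              NumericVector rho, IntegerVector obs) {
  const int S = A.nrow();
  const int T = obs.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  NumericMatrix logA(S, S), logB(B.nrow(), B.ncol());
  for (int r = 0; r < S; ++r)
    for (int s = 0; s < S; ++s)
      logA(r, s) = A(r, s) > 0 ? std::log(A(r, s)) : NEG;
  for (int s = 0; s < S; ++s)
    for (int m = 0; m < B.ncol(); ++m)
      logB(s, m) = B(s, m) > 0 ? std::log(B(s, m)) : NEG;

  std::vector<double> delta(S), delta_new(S);
  IntegerMatrix psi(T, S);
  for (int s = 0; s < S; ++s)
    delta[s] = (rho[s] > 0 ? std::log(rho[s]) : NEG) + logB(s, obs[0]);

  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = NEG;
      int arg = 0;
      for (int r = 0; r < S; ++r) {
        double v = delta[r] + logA(r, s);
        if (v > best) { best = v; arg = r; }
      }
      delta_new[s] = best + logB(s, obs[t]);
      psi(t, s) = arg;
    }
    for (int s = 0; s < S; ++s) delta[s] = delta_new[s];
  }

  IntegerVector path(T);
  int best = 0;
  for (int s = 1; s < S; ++s) if (delta[s] > delta[best]) best = s;
  if (delta[best] == NEG) stop("observation sequence impossible under model");
  path[T - 1] = best;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
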