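#include <Rcpp.h>
using namespace Rcpp;

static inline int sample_discrete(const double* p, int n, double u) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += p[i];
    if (u <= acc) return i;
  }
  return n - 1; // numerical slack
}

// Core stepping loop for one fly.
//
// trans:  n_bins x 16 matrix, bin-specific 4x4 transition matrix stored
//         row-major (entry r->s in column r*4 + s), already circadian-
//         modulated and (for social deprivation) window-suppressed.
// B:      4 x 3 emission matrix (MOVING, MICRO, IMMOBILE).
// init:   initial state distribution (length 4).
// gain:   homeostat coupling applied to wake->sleep entries (A->L, Q->L)
//         as a (1 + gain * pressure) multiplier with row renormalization.
// trigger_bins: closed-loop immobility trigger in bins (0 = no closed loop).
// pi:     stimulus delivery probability (real vs mock).
// strong: if true the stimulus uses strong_wake_prob for sleep states
//         (tube rotation); otherwise the state-specific arousal map.
// Wake states (ACTIVE=0, QUIET=1) always respond.
// States are returned 1-based, symbols 1-based.
// [[Rcpp::export]]
List sim_fly_cpp(NumericMatrix trans, NumericMatrix B, NumericVector init,
                 double bin_s, double p_rise, double p_decay, double gain,
                 int trigger_bins, double pi_deliver, bool strong,
                 double strong_wake_prob, NumericVector arousal,
                 int window_start_bin, int window_end_bin) {
  const int T = trans.nrow();
  const double dt_h = bin_s / 3600.0;

  IntegerVector states(T), symbols(T);
  NumericVector pressure(T);

  std::vector<int> ev_bin, ev_kind, ev_state, ev_resp;

  double P = 0.0;
  int run = 0;
  bool wake_pending = false;
  int state = sample_discrete(&init[0], 4, R::runif(0, 1));

  double row[4];
  for (int t = 0; t < T; ++t) {
    if (wake_pending) {
      state = 0; // woken by the stimulus: active from this bin
      wake_pending = false;
    } else if (t > 0) {
      const int off = state * 4;
      double tot = 0.0;
      for (int s = 0; s < 4; ++s) { row[s] = trans(t, off + s); tot += row[s]; }
      if (gain > 0.0 && P > 0.0) {
        const double mult = 1.0 + gain * P;
        if (state <= 1) {
          // pressure promotes falling asleep ...
          row[2] *= mult;
          row[3] *= mult;
        } else if (state == 2) {
          // ... and consolidates it (light-sleep exits dampened)
          row[0] /= mult;
          row[1] /= mult;
        }
        tot = row[0] + row[1] + row[2] + row[3];
      }
      for (int s = 0; s < 4; ++s) row[s] /= tot;
      state = sample_discrete(row, 4, R::runif(0, 1));
    }

    // emission
    double brow[3];
    for (int m = 0; m < 3; ++m) brow[m] = B(state, m);
    int sym = sample_discrete(brow, 3, R::runif(0, 1));

    // closed-loop trigger on the observable stream
    if (trigger_bins > 0 && t >= window_start_bin && t < window_end_bin) {
      if (sym != 0) run += 1; else run = 0;
      if (run >= trigger_bins) {
        const bool real = R::runif(0, 1) < pi_deliver;
        int responded = 0;
        const int state_at = state;
        if (real) {
          double wp;
          if (state <= 1) wp = 1.0;
          else wp = strong ? strong_wake_prob : arousal[state];
          responded = (R::runif(0, 1) < wp) ? 1 : 0;
          if (responded) wake_pending = true; // active from the next bin
        }
        ev_bin.push_back(t + 1);
        ev_kind.push_back(real ? 1 : 0);
        ev_state.push_back(state_at + 1);
        ev_resp.push_back(real ? responded : NA_INTEGER);
        run = 0; // timer resets after every event, real or mock
      }
    } else {
      if (sym != 0) run += 1; else run = 0;
    }

    // homeostat update (state occupied during this bin)
    if (state <= 1) P += p_rise * dt_h;
    else P = std::max(0.0, P - p_decay * dt_h);

    states[t] = state + 1;
    symbols[t] = sym + 1;
    pressure[t] = P;
  }

  return List::create(
    _["states"] = states, _["symbols"] = symbols, _["pressure"] = pressure,
    _["ev_bin"] = wrap(ev_bin), _["ev_real"] = wrap(ev_kind),
    _["ev_state"] = wrap(ev_state), _["ev_responded"] = wrap(ev_resp));
}
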