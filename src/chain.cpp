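#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Metropolis-Hastings chain over domain architectures.
//
// States are integer token vectors (0-based indices into the alphabet; the
// NULL terminus is index nd in the logp matrix). Moves are single-domain
// gains and losses; acceptance uses the cancelled three-factor probability
// ratios of the first-order model. R's RNG is used so that set.seed() makes
// runs reproducible, and the draw sequence per iteration is fixed
// (event-type, site, [token], accept) so the pure-R reference engine can
// replay it exactly: a vetoed deletion draws event-type and site only.
//
// mode: 0 = "paper" (gain iff u > 1/N_D), 1 = "symmetric" (gain odds N_D:1),
// 2 = "exact-hastings" (symmetric proposal + proposal-ratio correction).
// tally_max_len > 0 additionally tallies, after every iteration, the visited
// state whenever its length is <= tally_max_len (used by stationarity
// checks); states are ranked lexicographically within each length.

static inline int short_state_key(const std::vector<int> &st, int nd,
                                  int max_len) {
  int n = (int)st.size();
  if (n > max_len) return -1;
  int offset = 0, p = 1;
  for (int l = 1; l < n; ++l) { p *= nd; offset += p; }
  // offset = nd + nd^2 + ... + nd^(n-1); rank within length n:
  int rank = 0;
  for (int i = 0; i < n; ++i) rank = rank * nd + st[i];
  return offset + rank;
}

// emit_events: 0 = none, 1 = every iteration, 2 = accepted moves only.
// [[Rcpp::export]]
List cpp_run_chain(NumericMatrix logp, IntegerVector start0, int T, int nd,
                   int mode, double bias, int trace_every, int emit_events,
                   bool veto_consumes, int tally_max_len) {
  std::vector<int> st(start0.begin(), start0.end());
  const int NUL = nd;

  double odds = (mode == 0 ? (double)(nd - 1) : (double)nd) * bias;
  double g = odds / (1.0 + odds);      // gain probability
  double p_loss = 1.0 - g;
  double lcorr_gain = 0.0, lcorr_loss = 0.0;
  if (mode == 2 && g > 0.0) {
    lcorr_gain = std::log((1.0 - g) * (double)nd / g);
    lcorr_loss = -lcorr_gain;
  }

  long prop_gain = 0, prop_loss = 0, acc_gain = 0, acc_loss = 0, vetoed = 0;

  int n_samples = (trace_every > 0) ? T / trace_every : 0;
  IntegerVector samp_iter(n_samples), samp_len(n_samples);
  int si = 0;

  std::vector<int> ev_iter, ev_kind, ev_site, ev_tok, ev_pre, ev_acc;
  std::vector<double> ev_lr;
  if (emit_events) {
    ev_iter.reserve(T); ev_kind.reserve(T); ev_site.reserve(T);
    ev_tok.reserve(T); ev_pre.reserve(T); ev_acc.reserve(T);
    ev_lr.reserve(T);
  }

  int tally_size = 0;
  if (tally_max_len > 0) {
    int p = 1;
    for (int l = 1; l <= tally_max_len; ++l) { p *= nd; tally_size += p; }
  }
  std::vector<double> tally(tally_size, 0.0);

  RNGScope scope;
  int t = 0;
  while (t < T) {
    ++t;
    int n = (int)st.size();
    double u1 = unif_rand();
    bool is_gain = (u1 > p_loss);
    int kind, site, tok = -1, acc = 0, pre = n;
    double lr = NA_REAL;

    if (is_gain) {
      ++prop_gain;
      kind = 0;
      double u2 = unif_rand();
      site = (int)(u2 * (n + 1)); if (site > n) site = n;
      double u3 = unif_rand();
      tok = (int)(u3 * nd); if (tok >= nd) tok = nd - 1;
      int left = (site == 0) ? NUL : st[site - 1];
      int right = (site == n) ? NUL : st[site];
      double num = logp(left, tok) + logp(tok, right);
      double den = logp(left, right);
      if (num == R_NegInf) lr = R_NegInf;
      else if (den == R_NegInf) lr = R_PosInf;
      else lr = num - den;
      if (mode == 2 && R_finite(lr)) lr += lcorr_gain;
      double u4 = unif_rand();
      if (lr >= 0.0 || u4 < std::exp(lr)) {
        st.insert(st.begin() + site, tok);
        acc = 1; ++acc_gain;
      }
    } else {
      kind = 1;
      double u2 = unif_rand();
      site = (int)(u2 * n); if (site >= n) site = n - 1;
      if (n == 1) {
        // deletion would empty the architecture: veto (Prevent extinction)
        ++vetoed;
        if (emit_events == 1) {
          ev_iter.push_back(t); ev_kind.push_back(2); ev_site.push_back(site);
          ev_tok.push_back(NA_INTEGER); ev_pre.push_back(pre);
          ev_acc.push_back(0); ev_lr.push_back(NA_REAL);
        }
        if (!veto_consumes) { --t; continue; }
        if (trace_every > 0 && t % trace_every == 0 && si < n_samples) {
          samp_iter[si] = t; samp_len[si] = (int)st.size(); ++si;
        }
        if (tally_max_len > 0) {
          int key = short_state_key(st, nd, tally_max_len);
          if (key >= 0) tally[key] += 1.0;
        }
        continue;
      }
      ++prop_loss;
      int d = st[site];
      int left = (site == 0) ? NUL : st[site - 1];
      int right = (site == n - 1) ? NUL : st[site + 1];
      double num = logp(left, right);
      double den = logp(left, d) + logp(d, right);
      if (num == R_NegInf) lr = R_NegInf;
      else if (den == R_NegInf) lr = R_PosInf;
      else lr = num - den;
      if (mode == 2 && R_finite(lr)) lr += lcorr_loss;
      double u4 = unif_rand();
      if (lr >= 0.0 || u4 < std::exp(lr)) {
        st.erase(st.begin() + site);
        acc = 1; ++acc_loss;
      }
    }

    if (emit_events == 1 || (emit_events == 2 && acc)) {
      ev_iter.push_back(t); ev_kind.push_back(kind); ev_site.push_back(site);
      ev_tok.push_back(tok); ev_pre.push_back(pre); ev_acc.push_back(acc);
      ev_lr.push_back(lr);
    }
    if (trace_every > 0 && t % trace_every == 0 && si < n_samples) {
      samp_iter[si] = t; samp_len[si] = (int)st.size(); ++si;
    }
    if (tally_max_len > 0) {
      int key = short_state_key(st, nd, tally_max_len);
      if (key >= 0) tally[key] += 1.0;
    }
  }

  List events = R_NilValue;
  if (emit_events) {
    events = List::create(
      _["iteration"] = wrap(ev_iter), _["kind"] = wrap(ev_kind),
      _["site"] = wrap(ev_site), _["token"] = wrap(ev_tok),
      _["pre_length"] = wrap(ev_pre), _["log_ratio"] = wrap(ev_lr),
      _["accepted"] = wrap(ev_acc));
  }
  return List::create(
    _["final"] = wrap(st),
    _["sample_iteration"] = samp_iter, _["sample_length"] = samp_len,
    _["proposed_gain"] = (double)prop_gain,
    _["proposed_loss"] = (double)prop_loss,
    _["accepted_gain"] = (double)acc_gain,
    _["accepted_loss"] = (double)acc_loss,
    _["vetoed_loss"] = (double)vetoed,
    _["events"] = events,
    _["tally"] = wrap(tally));
}
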