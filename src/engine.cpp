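// Compiled event-stream engine for the avoidance simulation.
//
// Arithmetic-identical to the pure-R reference engine in R/task_env.R:
// identical operation order (column-wise action-value accumulation,
// long-double sums matching R's sum()/cumsum()), identical uniform-draw
// consumption (one draw per timestep), so the two engines produce bitwise
// equal trajectories from the same seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// magnitudes that decay below this are snapped to exact zero (see the
// reference implementation's WEIGHT_FLOOR): keeps multi-week inter-session
// periods out of the denormal range without affecting behavior
constexpr double WEIGHT_FLOOR = 1e-250;

struct Engine {
  // model parameters
  double alpha, eps, temp, persev, gamma_, r_shock, r_press, m_init, decay;
  int A;
  bool gated;
  // schedule
  int warning_len, shock_len, iti_len, pre_len, trials_per_session;
  int n_acq, n_ext, inter_len;
  bool rtc, lever_between;

  // agent state; m column-major A x 5
  std::vector<double> m;
  double v[5];
  double v_prev;
  // lazy perseveration trace: step index of last refresh (-1 = never);
  // value when computing action values at step t is decay^(t - last - 1)
  std::vector<long long> last;
  long long t;
  std::vector<double> powtab;

  // scratch
  std::vector<double> M, z, probs;

  void init() {
    m.assign((size_t)A * 5, m_init);
    for (int i = 0; i < 5; ++i) v[i] = 0.0;
    v_prev = 0.0;
    last.assign(gated ? (size_t)A * 5 : (size_t)A, -1LL);
    t = 0;
    M.resize(A); z.resize(A); probs.resize(A);
    // iterated product table: matches the reference engine's repeated
    // multiplication exactly, down to hard underflow
    // iterated product, truncated at the underflow floor (traces below it
    // are snapped to exact zero, exactly as in the reference engine)
    powtab.clear();
    double p = 1.0;
    powtab.push_back(p);
    while (powtab.size() < 20000000u) {
      p *= decay;
      if (p < WEIGHT_FLOOR) break;
      powtab.push_back(p);
    }
  }

  inline double trace_at(int a, int i) const {
    long long l = gated ? last[(size_t)a + (size_t)i * A] : last[(size_t)a];
    if (l < 0) return 0.0;
    long long k = t - l - 1;
    if (k >= (long long)powtab.size()) return 0.0;
    return powtab[(size_t)k];
  }

  // softmax action selection over actions [allowed_from, A); consumes one
  // uniform draw; returns 0-based action index. Inactive inputs contribute
  // exact zeros to every accumulation, so they are skipped; the executed
  // sequence of rounded operations is otherwise identical to the reference
  // engine's action_values().
  int select(const double* I, int allowed_from) {
    for (int a = 0; a < A; ++a) M[a] = 0.0;
    for (int i = 0; i < 5; ++i) {
      if (I[i] == 0.0) continue;
      const double Ii = I[i];
      const double* mi = &m[(size_t)i * A];
      for (int a = 0; a < A; ++a) M[a] = M[a] + mi[a] * Ii;
    }
    if (persev != 0.0) {
      if (!gated) {
        for (int a = 0; a < A; ++a) {
          const double cv = trace_at(a, 0);
          if (cv == 0.0) continue;
          const double pc = persev * cv;
          double acc = M[a];
          for (int i = 0; i < 5; ++i) acc = acc + pc;
          M[a] = acc;
        }
      } else {
        for (int i = 0; i < 5; ++i)
          for (int a = 0; a < A; ++a) M[a] = M[a] + persev * trace_at(a, i);
      }
    }
    const int n_allowed = A - allowed_from;
    double mx = M[allowed_from];
    for (int a = allowed_from + 1; a < A; ++a) if (M[a] > mx) mx = M[a];
    long double S = 0.0L;
    for (int k = 0; k < n_allowed; ++k) {
      double zz = std::exp((M[allowed_from + k] - mx) / temp);
      z[k] = zz;
      S += zz;
    }
    const double Sd = (double)S;
    for (int k = 0; k < n_allowed; ++k) probs[k] = z[k] / Sd;
    const double u = unif_rand();
    long double cacc = 0.0L;
    int sel = n_allowed - 1;  // guard against rounding at the tail
    for (int k = 0; k < n_allowed; ++k) {
      cacc += probs[k];
      if (u <= (double)cacc) { sel = k; break; }
    }
    return sel + allowed_from;
  }

  // one TD(0) learning step for executed `action` (0-based; 0 = lever)
  void learn(const double* I, const double* In, bool shock_next, int action) {
    const bool pressed = (action == 0);
    const double R = shock_next ? r_shock : (pressed ? r_press : 0.0);
    long double vacc = 0.0L;
    for (int i = 0; i < 5; ++i) { double prod = v[i] * In[i]; vacc += prod; }
    const double Vn = (double)vacc;
    const double PE = R + gamma_ * Vn - v_prev;
    const double d = alpha * PE;
    const double bound = std::fabs(r_shock);
    for (int i = 0; i < 5; ++i) {
      double nv = v[i] + d * I[i];
      if (std::fabs(nv) < WEIGHT_FLOOR) nv = 0.0;
      if (nv < -bound) nv = -bound;
      if (nv > bound) nv = bound;
      v[i] = nv;
    }
    for (int i = 0; i < 5; ++i) {
      double cur = m[(size_t)action + (size_t)i * A];
      double t1 = eps * (PE - cur);
      double nm = cur + t1 * I[i];
      if (std::fabs(nm) < WEIGHT_FLOOR) nm = 0.0;
      if (nm < 0.0) nm = 0.0;
      m[(size_t)action + (size_t)i * A] = nm;
    }
    if (gated) {
      for (int i = 0; i < 5; ++i)
        if (I[i] > 0) last[(size_t)action + (size_t)i * A] = t;
    } else {
      last[(size_t)action] = t;
    }
    v_prev = Vn;
    ++t;
  }
};

} // namespace

// [[Rcpp::export]]
List engine_run(List params, List config, bool keep_state) {
  Engine e;
  e.alpha = as<double>(params["alpha"]);
  e.eps = as<double>(params["epsilon"]);
  e.temp = as<double>(params["temperature"]);
  e.persev = as<double>(params["persev"]);
  e.gamma_ = as<double>(params["gamma"]);
  e.r_shock = as<double>(params["r_shock"]);
  e.r_press = as<double>(params["r_press"]);
  e.A = as<int>(params["n_actions"]);
  e.m_init = as<double>(params["m_init"]);
  e.decay = as<double>(params["trace_decay"]);
  e.gated = as<bool>(params["trace_gated"]);
  e.warning_len = as<int>(config["warning_len"]);
  e.shock_len = as<int>(config["shock_len"]);
  e.iti_len = as<int>(config["iti_len"]);
  e.pre_len = as<int>(config["pre_len"]);
  e.trials_per_session = as<int>(config["trials_per_session"]);
  e.n_acq = as<int>(config["n_acq_sessions"]);
  e.n_ext = as<int>(config["n_ext_sessions"]);
  e.inter_len = as<int>(config["intersession_len"]);
  e.rtc = as<bool>(config["round_the_clock"]);
  e.lever_between = as<bool>(config["lever_available_between"]);
  e.init();

  static const double PRE[5]  = {0, 0, 0, 1, 0};
  static const double WARN[5] = {1, 0, 0, 1, 0};
  static const double SHK[5]  = {1, 0, 1, 1, 0};
  static const double ITI[5]  = {0, 1, 0, 1, 0};
  static const double HOME[5] = {0, 0, 0, 0, 1};
  const double* INTER = e.rtc ? PRE : HOME;
  const double* first_inputs =
      e.pre_len > 0 ? PRE : (e.trials_per_session > 0 ? WARN : INTER);

  const int n_sessions = e.n_acq + e.n_ext;
  const int n_trials_total = n_sessions * e.trials_per_session;
  const int trial_max = e.warning_len + e.shock_len + e.iti_len;
  IntegerVector r_session(n_trials_total), r_trial(n_trials_total),
      r_phase(n_trials_total), r_outcome(n_trials_total),
      r_latency(n_trials_total), r_npress(n_trials_total),
      r_length(n_trials_total), r_antic(n_sessions);
  int rec = 0;

  for (int s = 0; s < n_sessions; ++s) {
    const bool acq = s < e.n_acq;
    const bool last_session = (s == n_sessions - 1);
    const double* session_next =
        (last_session || e.inter_len > 0) ? INTER : first_inputs;
    const double* after_pre =
        e.trials_per_session > 0 ? WARN : session_next;
    int antic = 0;
    for (int k = 1; k <= e.pre_len; ++k) {
      const double* In = (k < e.pre_len) ? PRE : after_pre;
      int a = e.select(PRE, 0);
      e.learn(PRE, In, false, a);
      if (a == 0) ++antic;
    }
    r_antic[s] = antic;

    const double* segI[3] = {WARN, acq ? SHK : WARN, ITI};
    const int seglen[3] = {e.warning_len, e.shock_len, e.iti_len};
    for (int j = 1; j <= e.trials_per_session; ++j) {
      const double* trial_next =
          (j < e.trials_per_session) ? WARN : session_next;
      int seg = 0, seg_step = 0, t_in = 0;
      int first_press = -1, first_seg = -1, npress = 0;
      for (;;) {
        const double* I = segI[seg];
        int a = e.select(I, 0);
        const bool pressed = (a == 0);
        int nseg, nstep;
        if (pressed && seg <= 1) { nseg = 2; nstep = 0; }
        else { nseg = seg; nstep = seg_step + 1; }
        while (nseg != 3 && nstep >= seglen[nseg]) { nstep = 0; ++nseg; }
        const bool done = (nseg == 3);
        const double* In = done ? trial_next : segI[nseg];
        const bool shock_next = !done && nseg == 1 && acq;
        e.learn(I, In, shock_next, a);
        if (pressed) {
          ++npress;
          if (first_press < 0) { first_press = t_in; first_seg = seg; }
        }
        ++t_in;
        if (done) break;
        seg = nseg; seg_step = nstep;
      }
      r_session[rec] = s + 1;
      r_trial[rec] = j;
      r_phase[rec] = acq ? 1 : 2;
      r_outcome[rec] = first_press < 0 ? 3
                       : (first_seg == 0 ? 1 : (first_seg == 1 ? 2 : 3));
      r_latency[rec] = first_press < 0 ? trial_max : first_press;
      r_npress[rec] = npress;
      r_length[rec] = t_in;
      ++rec;
    }

    if (!last_session && e.inter_len > 0) {
      const int allowed_from = e.lever_between ? 0 : 1;
      for (int k = 1; k <= e.inter_len; ++k) {
        const double* In = (k < e.inter_len) ? INTER : first_inputs;
        int a = e.select(INTER, allowed_from);
        e.learn(INTER, In, false, a);
      }
    }
    if (s % 4 == 3) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["session"] = r_session, _["trial"] = r_trial, _["phase"] = r_phase,
      _["outcome"] = r_outcome, _["latency"] = r_latency,
      _["n_presses"] = r_npress, _["trial_length"] = r_length,
      _["anticipatory"] = r_antic);
  if (keep_state) {
    NumericMatrix mm(e.A, 5), cm(e.A, 5);
    for (int i = 0; i < 5; ++i)
      for (int a = 0; a < e.A; ++a) {
        mm(a, i) = e.m[(size_t)a + (size_t)i * e.A];
        long long l = e.gated ? e.last[(size_t)a + (size_t)i * e.A]
                              : e.last[(size_t)a];
        double cv = 0.0;
        if (l >= 0) {
          long long k = (e.t - 1) - l;  // decays applied since refresh
          if (k < (long long)e.powtab.size()) cv = e.powtab[(size_t)k];
        }
        cm(a, i) = cv;
      }
    out["m"] = mm;
    out["c"] = cm;
    out["v"] = NumericVector(e.v, e.v + 5);
    out["v_prev"] = e.v_prev;
  }
  return out;
}
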