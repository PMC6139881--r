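// Event-driven (Gillespie) simulation of the dimeric lattice gas with
// Langmuir kinetics, facilitated detachment and optional inactive states.
// All randomness comes from R's RNG, so set.seed() on the R side gives
// bit-identical event sequences.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// set with O(1) insert/erase/uniform-sample, keyed by lattice site
struct ISet {
  std::vector<int> items, pos;
  void init(int cap) { items.clear(); pos.assign(cap, -1); }
  inline bool has(int x) const { return pos[x] >= 0; }
  inline void ins(int x) {
    if (pos[x] < 0) { pos[x] = (int)items.size(); items.push_back(x); }
  }
  inline void del(int x) {
    int p = pos[x];
    if (p >= 0) {
      int last = items.back();
      items[p] = last; pos[last] = p;
      items.pop_back(); pos[x] = -1;
    }
  }
  inline int size() const { return (int)items.size(); }
  inline int sample() const {
    int k = (int)(unif_rand() * items.size());
    if (k >= (int)items.size()) k = (int)items.size() - 1;
    return items[k];
  }
};

struct Sim {
  int L;
  double nu, omega_A, omega_D, theta, r_in, r_act;
  bool kick_off;
  // occupancy: 0 empty, 1 front head, 2 back head; mot = motor id at site
  std::vector<int> occ, mot;
  // per-motor registry
  std::vector<int> front, steps, attach_site;
  std::vector<char> active, bound, tracked;
  std::vector<double> attach_t;
  // channel sets (keyed by front site; pairS keyed by right site of pair)
  ISet hopS, thetaS, motorS, activeS, inactiveS, pairS;

  inline int nxt(int i) const { return i + 1 < L ? i + 1 : 0; }
  inline int prv(int i) const { return i > 0 ? i - 1 : L - 1; }

  void refresh_motor(int f) {
    int m = mot[f];
    if (active[m] && occ[nxt(f)] == 0) hopS.ins(f); else hopS.del(f);
    bool th = kick_off ? (occ[prv(prv(f))] == 1) : (occ[nxt(f)] == 2);
    if (th) thetaS.ins(f); else thetaS.del(f);
  }
  void refresh_pair(int i) {  // pair = sites (i-1, i)
    if (occ[i] == 0 && occ[prv(i)] == 0) pairS.ins(i); else pairS.del(i);
  }
  void refresh_site(int s) {
    if (occ[s] == 1) refresh_motor(s); else { hopS.del(s); thetaS.del(s); }
    int a = prv(s);
    if (occ[a] == 1) refresh_motor(a);
    int b = nxt(nxt(s));
    if (occ[b] == 1) refresh_motor(b);
    refresh_pair(s); refresh_pair(nxt(s));
  }

  int new_motor(int f, double t, double tracer_fraction) {
    front.push_back(f); steps.push_back(0); attach_site.push_back(f);
    active.push_back(1); bound.push_back(1);
    tracked.push_back(unif_rand() < tracer_fraction ? 1 : 0);
    attach_t.push_back(t);
    return (int)front.size() - 1;
  }

  void place(int f, double t, double tracer_fraction) {
    int m = new_motor(f, t, tracer_fraction);
    occ[f] = 1; occ[prv(f)] = 2;
    mot[f] = m; mot[prv(f)] = m;
    motorS.ins(f); activeS.ins(f);
    refresh_site(f); refresh_site(prv(f));
  }
};

template <class CloseRun>
void do_detach(Sim& S, int f, bool fac, double t, CloseRun& close_run) {
  int m = S.mot[f], b = S.prv(f);
  close_run(m, t, fac ? 1 : 0);
  S.occ[f] = 0; S.occ[b] = 0; S.mot[f] = -1; S.mot[b] = -1;
  S.bound[m] = 0;
  S.motorS.del(f); S.activeS.del(f); S.inactiveS.del(f);
  S.hopS.del(f); S.thetaS.del(f);
  S.refresh_site(b); S.refresh_site(f);
}

}  // namespace

// [[Rcpp::export(name = ".sim_gillespie_cpp")]]
List sim_gillespie_cpp(int L, double nu, double omega_A, double omega_D,
                       double theta, bool kick_off, double r_in, double r_act,
                       double t_end, double burn_in, double frame_interval,
                       double tracer_fraction, bool record_frames,
                       bool record_runs, int n_init) {
  if (L < 4) stop("L must be at least 4");
  if (burn_in >= t_end) stop("burn_in must be below t_end");
  Sim S;
  S.L = L; S.nu = nu; S.omega_A = omega_A; S.omega_D = omega_D;
  S.theta = theta; S.kick_off = kick_off; S.r_in = r_in; S.r_act = r_act;
  S.occ.assign(L, 0); S.mot.assign(L, -1);
  S.hopS.init(L); S.thetaS.init(L); S.motorS.init(L);
  S.activeS.init(L); S.inactiveS.init(L); S.pairS.init(L);
  for (int i = 0; i < L; ++i) S.refresh_pair(i);

  if (n_init > 0) {
    if (2 * n_init > L) stop("n_init motors do not fit on the ring");
    int stride = L / n_init;
    if (stride < 2) stride = 2;
    for (int k = 0; k < n_init; ++k)
      S.place((k * stride + 1) % L, 0.0, tracer_fraction);
  }

  // frame buffers
  std::vector<double> f_t, f_pos;
  std::vector<int> f_motor, f_site, f_active;
  // run records
  std::vector<int> r_motor, r_attach_site, r_detach_site, r_steps, r_cause,
      r_tracked;
  std::vector<double> r_attach_t, r_detach_t;
  auto close_run = [&](int m, double t, int cause) {
    if (!record_runs || S.attach_t[m] < burn_in) return;
    r_motor.push_back(m);
    r_tracked.push_back(S.tracked[m]);
    r_attach_t.push_back(S.attach_t[m]); r_detach_t.push_back(t);
    r_attach_site.push_back(S.attach_site[m]);
    r_detach_site.push_back(S.front[m]);
    r_steps.push_back(S.steps[m]); r_cause.push_back(cause);
  };

  // time-weighted accumulators and event counters (measurement window);
  // block-resolved copies give Monte-Carlo standard errors for the
  // collective observables
  const int n_blocks = 20;
  double int_n = 0, int_pairs = 0;
  std::vector<double> int_n_b(n_blocks, 0.0), int_pairs_b(n_blocks, 0.0),
      hops_b(n_blocks, 0.0);
  double block_len = (t_end - burn_in) / n_blocks;
  long long hops = 0, attaches = 0, det_spont = 0, det_fac = 0,
            inact_ev = 0, act_ev = 0;

  long long kf = (long long)std::ceil(burn_in / frame_interval - 1e-9);
  if (kf < 0) kf = 0;

  double t = 0;
  while (true) {
    double R_hop = nu * S.hopS.size();
    double R_att = omega_A * S.pairS.size();
    double R_det = omega_D * S.motorS.size();
    double R_fac = theta * S.thetaS.size();
    double R_in = r_in * S.activeS.size();
    double R_ac = r_act * S.inactiveS.size();
    double total = R_hop + R_att + R_det + R_fac + R_in + R_ac;

    double t_new = (total > 0) ? t + exp_rand() / total : t_end + 1.0;

    // time-weighted state statistics over the measurement window
    double lo = t > burn_in ? t : burn_in;
    double hi = t_new < t_end ? t_new : t_end;
    if (hi > lo) {
      int_n += (hi - lo) * S.motorS.size();
      int_pairs += (hi - lo) * S.pairS.size();
      int blk = (int)((0.5 * (lo + hi) - burn_in) / block_len);
      if (blk >= n_blocks) blk = n_blocks - 1;
      if (blk >= 0) {
        int_n_b[blk] += (hi - lo) * S.motorS.size();
        int_pairs_b[blk] += (hi - lo) * S.pairS.size();
      }
    }
    // frames falling before the next event (state is constant in between)
    if (record_frames) {
      while (kf * frame_interval <= (t_new < t_end ? t_new : t_end) + 1e-12 &&
             kf * frame_interval <= t_end + 1e-12) {
        double ft = kf * frame_interval;
        for (int idx = 0; idx < S.motorS.size(); ++idx) {
          int f = S.motorS.items[idx];
          int m = S.mot[f];
          if (!S.tracked[m]) continue;
          f_t.push_back(ft); f_motor.push_back(m);
          f_pos.push_back((double)S.attach_site[m] + S.steps[m]);
          f_site.push_back(f); f_active.push_back(S.active[m]);
        }
        ++kf;
      }
    }
    if (t_new >= t_end) { t = t_end; break; }
    t = t_new;
    bool measuring = t >= burn_in;

    double u = unif_rand() * total;
    if ((u -= R_hop) < 0) {
      int f = S.hopS.sample();
      int m = S.mot[f], f1 = S.nxt(f), b = S.prv(f);
      S.occ[b] = 0; S.mot[b] = -1;
      S.occ[f] = 2;
      S.occ[f1] = 1; S.mot[f1] = m;
      S.front[m] = f1; S.steps[m]++;
      S.motorS.del(f); S.motorS.ins(f1);
      S.activeS.del(f); S.activeS.ins(f1);
      S.refresh_site(b); S.refresh_site(f); S.refresh_site(f1);
      if (measuring) {
        ++hops;
        int blk = (int)((t - burn_in) / block_len);
        if (blk >= n_blocks) blk = n_blocks - 1;
        hops_b[blk] += 1.0;
      }
    } else if ((u -= R_att) < 0) {
      int i = S.pairS.sample();
      S.place(i, t, tracer_fraction);
      if (measuring) ++attaches;
    } else if ((u -= R_det) < 0) {
      do_detach(S, S.motorS.sample(), false, t, close_run);
      if (measuring) ++det_spont;
    } else if ((u -= R_fac) < 0) {
      do_detach(S, S.thetaS.sample(), true, t, close_run);
      if (measuring) ++det_fac;
    } else if ((u -= R_in) < 0) {
      int f = S.activeS.sample();
      S.active[S.mot[f]] = 0;
      S.activeS.del(f); S.inactiveS.ins(f);
      S.refresh_motor(f);
      if (measuring) ++inact_ev;
    } else {
      int f = S.inactiveS.sample();
      S.active[S.mot[f]] = 1;
      S.inactiveS.del(f); S.activeS.ins(f);
      S.refresh_motor(f);
      if (measuring) ++act_ev;
    }
  }

  // truncated runs for motors still bound at t_end
  for (int idx = 0; idx < S.motorS.size(); ++idx) {
    int m = S.mot[S.motorS.items[idx]];
    close_run(m, t_end, 2);
  }

  double T_meas = t_end - burn_in;
  return List::create(
    _["frames"] = List::create(
      _["t"] = f_t, _["motor_id"] = f_motor, _["position"] = f_pos,
      _["site"] = f_site, _["active"] = f_active),
    _["runs"] = List::create(
      _["motor_id"] = r_motor, _["attach_time"] = r_attach_t,
      _["detach_time"] = r_detach_t, _["attach_site"] = r_attach_site,
      _["detach_site"] = r_detach_site, _["steps"] = r_steps,
      _["cause"] = r_cause, _["tracked"] = r_tracked),
    _["stats"] = List::create(
      _["T_measure"] = T_meas, _["int_n"] = int_n,
      _["int_pairs"] = int_pairs,
      _["int_n_blocks"] = int_n_b, _["int_pairs_blocks"] = int_pairs_b,
      _["hops_blocks"] = hops_b,
      _["hops"] = (double)hops,
      _["attaches"] = (double)attaches, _["det_spont"] = (double)det_spont,
      _["det_fac"] = (double)det_fac, _["inactivations"] = (double)inact_ev,
      _["activations"] = (double)act_ev,
      _["n_bound_final"] = S.motorS.size()));
}

// Frame-based detector of periods of no or slow motion. Input rows must
// be sorted by motor then time; positions in lattice sites. A displacement
// below d_c counts as small (backward motion included); a period starts at
// the frame preceding the first of onset_run consecutive small
// displacements and ends at the frame preceding the first of
// termination_run consecutive large ones (single large displacements
// inside a period are thereby tolerated for termination_run = 2).
// [[Rcpp::export(name = ".detect_periods_cpp")]]
List detect_periods_cpp(IntegerVector motor, NumericVector t,
                        NumericVector pos, double d_c, int onset_run,
                        int termination_run, double cutoff) {
  int n = motor.size();
  std::vector<int> p_motor; std::vector<double> p_start, p_end, p_prog;
  std::vector<int> p_trunc;
  int g0 = 0;
  while (g0 < n) {
    int g1 = g0;
    while (g1 + 1 < n && motor[g1 + 1] == motor[g0]) ++g1;
    int m = g1 - g0 + 1;  // frames in this trajectory
    if (m >= onset_run + 1) {
      // displacement k spans frames k, k+1 (local indexing)
      auto small = [&](int k) {
        return pos[g0 + k + 1] - pos[g0 + k] < d_c;
      };
      int k = 0;
      while (k <= m - 1 - onset_run) {
        // onset: onset_run consecutive small displacements starting at k
        bool onset = true;
        for (int r = 0; r < onset_run; ++r)
          if (!small(k + r)) { onset = false; break; }
        if (!onset) { ++k; continue; }
        int s = k;  // period start frame
        // termination: first j with termination_run consecutive larges
        int endf = -1;
        for (int j = s + onset_run; j <= m - 1 - termination_run; ++j) {
          bool term = true;
          for (int r = 0; r < termination_run; ++r)
            if (small(j + r)) { term = false; break; }
          if (term) { endf = j; break; }
        }
        bool trunc = endf < 0;
        if (trunc) endf = m - 1;
        double dur = t[g0 + endf] - t[g0 + s];
        // progression is measured to the frame where normal motion is
        // confirmed again (after the termination pair); the duration
        // counts only the slow frames so that the onset-run cutoff
        // identity and the censoring correction stay exact
        int resume = trunc ? endf : std::min(endf + termination_run, m - 1);
        if (dur >= cutoff - 1e-9) {
          p_motor.push_back(motor[g0]);
          p_start.push_back(t[g0 + s]); p_end.push_back(t[g0 + endf]);
          p_prog.push_back(pos[g0 + resume] - pos[g0 + s]);
          p_trunc.push_back(trunc);
        }
        k = trunc ? m : endf + termination_run;
      }
    }
    g0 = g1 + 1;
  }
  return List::create(
    _["motor_id"] = p_motor, _["start_time"] = p_start,
    _["end_time"] = p_end, _["progression"] = p_prog,
    _["truncated"] = p_trunc);
}

// Jam membership per frame: a motor is in-state iff it is inactive or its
// front head sits exactly one site behind the back head of an in-state
// motor (front site + 2 carries the leader's front head), following the
// chain towards the plus end. Cycles with no inactive member (a fully
// closed ring of active motors) are not in-state. Rows must be grouped by
// frame; `site` is the ring front site.
// [[Rcpp::export(name = ".jam_state_cpp")]]
LogicalVector jam_state_cpp(IntegerVector frame, IntegerVector site,
                            LogicalVector active, int L) {
  int n = frame.size();
  LogicalVector out(n);
  std::vector<int> at(L, -1);     // site -> row in current frame
  std::vector<signed char> st(L); // 0 unknown, 1 in, 2 out, 3 visiting
  int g0 = 0;
  while (g0 < n) {
    int g1 = g0;
    while (g1 + 1 < n && frame[g1 + 1] == frame[g0]) ++g1;
    for (int i = g0; i <= g1; ++i) { at[site[i]] = i; st[site[i]] = 0; }
    for (int i = g0; i <= g1; ++i) {
      int s = site[i];
      if (st[s]) continue;
      // walk the chain ahead until resolved
      std::vector<int> path;
      int cur = s; signed char res = 2;
      while (true) {
        if (st[cur] == 1 || st[cur] == 2) { res = st[cur]; break; }
        if (st[cur] == 3) { res = 2; break; }  // active cycle
        if (!active[at[cur]]) { st[cur] = 1; res = 1; break; }
        st[cur] = 3; path.push_back(cur);
        int ahead = (cur + 2) % L;
        if (at[ahead] < 0) { res = 2; break; }
        cur = ahead;
      }
      for (size_t k = 0; k < path.size(); ++k) st[path[k]] = res;
    }
    for (int i = g0; i <= g1; ++i) {
      out[i] = st[site[i]] == 1;
      at[site[i]] = -1;  // reset for next frame
    }
    g0 = g1 + 1;
  }
  return out;
}
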