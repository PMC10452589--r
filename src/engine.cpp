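#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Health-state and event codes shared with the R side (see R/microsim.R).
enum State { NED = 1, UNDET = 2, CUR = 3, PALL_S = 4, PALL_A = 5, DEAD = 6 };
enum Event {
  EV_VISIT = 1, EV_COLONO = 2, EV_DETECT = 4, EV_SYMPT = 8,
  EV_SURG = 16, EV_OPDEATH = 32, EV_FP = 64, EV_DEATH = 128
};

// Counter-based RNG: a splitmix64 hash of (seed, patient, cycle, purpose).
// Every stochastic decision in the model has a fixed (cycle, purpose) address,
// so two strategies simulated with the same seed and patient id share all
// draws that both models consume (common random numbers), and results are
// reproducible without any global RNG state.
static inline uint64_t sm64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double u01(uint64_t seed, uint64_t patient, uint64_t cycle,
                         uint64_t purpose) {
  uint64_t h = sm64(seed);
  h = sm64(h ^ patient);
  h = sm64(h ^ cycle);
  h = sm64(h ^ purpose);
  return (h >> 11) * (1.0 / 9007199254740992.0); // 53-bit mantissa in [0, 1)
}

// Draw purposes (addresses within a cycle).
enum Purpose {
  PUR_DEATH = 1, PUR_RECUR = 2, PUR_CONVERT = 3, PUR_DETECT = 4,
  PUR_RESECT = 5, PUR_OPDEATH = 6, PUR_FP = 7
};

//' @noRd
// [[Rcpp::export(name = ".cpp_u01")]]
double cpp_u01(double seed, double patient, double cycle, double purpose) {
  return u01((uint64_t)seed, (uint64_t)patient, (uint64_t)cycle,
             (uint64_t)purpose);
}

struct Pars {
  double p_recur, p_sympt, p_bg, p_postrec, p_opdeath, p_res_a, p_res_s;
  double u_state[7]; // indexed by State
  double c_visit, c_colono, c_fp_workup, c_surgery, c_cur_chemo, c_pall_chemo;
  int cur_dur, pall_dur;
  double sens, sens_colono, fp, fp_colono;
  double annual_rate;
  int horizon;
  bool charge_fp;
  IntegerVector visit; // length horizon; 0 none, 1 visit, 2 visit + colonoscopy
};

static Pars parse_pars(const List& par) {
  Pars P;
  P.p_recur = par["p_recur"]; P.p_sympt = par["p_sympt"];
  P.p_bg = par["p_bg"]; P.p_postrec = par["p_postrec"];
  P.p_opdeath = par["p_opdeath"];
  P.p_res_a = par["p_res_a"]; P.p_res_s = par["p_res_s"];
  NumericVector u = par["utilities"]; // NED, UNDET, CUR, PALL_S, PALL_A
  P.u_state[NED] = u[0]; P.u_state[UNDET] = u[1]; P.u_state[CUR] = u[2];
  P.u_state[PALL_S] = u[3]; P.u_state[PALL_A] = u[4]; P.u_state[DEAD] = 0.0;
  P.c_visit = par["c_visit"]; P.c_colono = par["c_colono"];
  P.c_fp_workup = par["c_fp_workup"]; P.c_surgery = par["c_surgery"];
  P.c_cur_chemo = par["c_cur_chemo"]; P.c_pall_chemo = par["c_pall_chemo"];
  P.cur_dur = par["cur_dur"]; P.pall_dur = par["pall_dur"];
  P.sens = par["sens"]; P.sens_colono = par["sens_colono"];
  P.fp = par["fp"]; P.fp_colono = par["fp_colono"];
  P.annual_rate = par["annual_rate"];
  P.horizon = par["horizon"];
  P.charge_fp = par["charge_fp"];
  P.visit = as<IntegerVector>(par["visit"]);
  return P;
}

// One monthly transition. `state` is the state occupied during `cycle`;
// the returned `next` is occupied from `cycle + 1`. Draw order within the
// cycle: (1) death in current state, (2) NED recurrence, (3) undetected ->
// symptomatic conversion, (4) scheduled-visit detection, (5) resection,
// (6) operative death, false positives at disease-free visits.
static inline void do_step(const Pars& P, uint64_t seed, uint64_t pid,
                           int cycle, int state, int& m_cur, int& m_pall,
                           int& next, int& events, double& event_cost) {
  events = 0; event_cost = 0.0; next = state;
  double p_die = (state == NED || state == CUR) ? P.p_bg : P.p_postrec;
  if (u01(seed, pid, cycle, PUR_DEATH) < p_die) {
    events |= EV_DEATH; next = DEAD; return; // dies before any visit this cycle
  }
  int vf = P.visit[cycle - 1];
  if (state == NED) {
    bool recurred = u01(seed, pid, cycle, PUR_RECUR) < P.p_recur;
    if (vf > 0) {
      events |= EV_VISIT; event_cost += P.c_visit;
      if (vf == 2) { events |= EV_COLONO; event_cost += P.c_colono; }
      if (!recurred) {
        double fpp = (vf == 2) ? P.fp_colono : P.fp;
        if (u01(seed, pid, cycle, PUR_FP) < fpp) {
          events |= EV_FP;
          if (P.charge_fp) event_cost += P.c_fp_workup;
        }
      }
    }
    next = recurred ? UNDET : NED;
  } else if (state == UNDET) {
    if (u01(seed, pid, cycle, PUR_CONVERT) < P.p_sympt) {
      events |= EV_SYMPT; // symptoms prompt presentation regardless of schedule
      if (u01(seed, pid, cycle, PUR_RESECT) < P.p_res_s) {
        events |= EV_SURG; event_cost += P.c_surgery;
        if (u01(seed, pid, cycle, PUR_OPDEATH) < P.p_opdeath) {
          events |= EV_OPDEATH | EV_DEATH; next = DEAD;
        } else { next = CUR; m_cur = 0; }
      } else { next = PALL_S; m_pall = 0; }
    } else if (vf > 0) {
      events |= EV_VISIT; event_cost += P.c_visit;
      if (vf == 2) { events |= EV_COLONO; event_cost += P.c_colono; }
      double sens = (vf == 2) ? P.sens_colono : P.sens;
      if (u01(seed, pid, cycle, PUR_DETECT) < sens) {
        events |= EV_DETECT;
        if (u01(seed, pid, cycle, PUR_RESECT) < P.p_res_a) {
          events |= EV_SURG; event_cost += P.c_surgery;
          if (u01(seed, pid, cycle, PUR_OPDEATH) < P.p_opdeath) {
            events |= EV_OPDEATH | EV_DEATH; next = DEAD;
          } else { next = CUR; m_cur = 0; }
        } else { next = PALL_A; m_pall = 0; }
      }
    }
  } else if (state == CUR) {
    m_cur += 1;
    if (m_cur >= P.cur_dur) next = NED; // renewed recurrence risk from next cycle
  }
  // Palliative states: no exits other than the death draw above.
}

// Per-cycle accounting. Continuous (state-occupancy) costs, utility and
// life-years take weight 1/2 in the cycle of transition into DEAD (half-cycle
// correction); one-off event costs keep full weight at their event cycle.
static inline void accrue_cycle(const Pars& P, int state, int next,
                                int m_pall, double event_cost,
                                double& cost, double& util, double& ly) {
  double w = (next == DEAD) ? 0.5 : 1.0;
  double occ = 0.0;
  if (state == CUR) occ = P.c_cur_chemo;
  else if (state == PALL_S || state == PALL_A)
    occ = (m_pall < P.pall_dur) ? P.c_pall_chemo : 0.0;
  cost = event_cost + w * occ;
  util = w * P.u_state[state] / 12.0;
  ly = w / 12.0;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_trajectory")]]
NumericMatrix cpp_trajectory(double seed, double patient, List par) {
  Pars P = parse_pars(par);
  uint64_t sd = (uint64_t)seed, pid = (uint64_t)patient;
  NumericMatrix out(P.horizon, 6);
  colnames(out) = CharacterVector::create("cycle", "state", "events",
                                          "cost", "utility", "ly");
  int state = NED, m_cur = 0, m_pall = 0, nrow = 0;
  for (int c = 1; c <= P.horizon; ++c) {
    int next, events; double event_cost, cost, util, ly;
    do_step(P, sd, pid, c, state, m_cur, m_pall, next, events, event_cost);
    accrue_cycle(P, state, next, m_pall, event_cost, cost, util, ly);
    if (state == PALL_S || state == PALL_A) m_pall += 1;
    out(nrow, 0) = c; out(nrow, 1) = state; out(nrow, 2) = events;
    out(nrow, 3) = cost; out(nrow, 4) = util; out(nrow, 5) = ly;
    ++nrow;
    if (next == DEAD) break;
    state = next;
  }
  return out(Range(0, nrow - 1), Range(0, 5));
}

//' @noRd
// [[Rcpp::export(name = ".cpp_run_patients")]]
NumericMatrix cpp_run_patients(int n, double seed, List par) {
  Pars P = parse_pars(par);
  uint64_t sd = (uint64_t)seed;
  NumericMatrix out(n, 10);
  colnames(out) = CharacterVector::create(
      "cost", "qaly", "ly", "n_colonoscopy", "n_metastasectomy",
      "detected_asymptomatic", "recurred", "death_cycle", "n_false_positive",
      "n_visits");
  double log1r = log1p(P.annual_rate);
  for (int i = 0; i < n; ++i) {
    uint64_t pid = (uint64_t)(i + 1);
    int state = NED, m_cur = 0, m_pall = 0;
    double dcost = 0, dqaly = 0, dly = 0;
    int n_col = 0, n_surg = 0, n_fp = 0, n_vis = 0, death_cycle = 0;
    bool det_asym = false, recurred = false;
    for (int c = 1; c <= P.horizon; ++c) {
      int next, events; double event_cost, cost, util, ly;
      do_step(P, sd, pid, c, state, m_cur, m_pall, next, events, event_cost);
      accrue_cycle(P, state, next, m_pall, event_cost, cost, util, ly);
      if (state == PALL_S || state == PALL_A) m_pall += 1;
      double df = exp(-log1r * (c - 0.5) / 12.0);
      dcost += df * cost; dqaly += df * util; dly += df * ly;
      if (events & EV_COLONO) ++n_col;
      if (events & EV_SURG) ++n_surg;
      if (events & EV_FP) ++n_fp;
      if (events & EV_VISIT) ++n_vis;
      if (events & EV_DETECT) det_asym = true;
      if (next == UNDET) recurred = true;
      if (next == DEAD) { death_cycle = c; break; }
      state = next;
    }
    out(i, 0) = dcost; out(i, 1) = dqaly; out(i, 2) = dly;
    out(i, 3) = n_col; out(i, 4) = n_surg; out(i, 5) = det_asym ? 1 : 0;
    out(i, 6) = recurred ? 1 : 0; out(i, 7) = death_cycle;
    out(i, 8) = n_fp; out(i, 9) = n_vis;
  }
  return out;
}
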