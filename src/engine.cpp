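#include <Rcpp.h>
#include "core.h"
#include "rng.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// helpers: parse R lists into core structs
// ---------------------------------------------------------------------------

static double gd(const List &l, const char *n) { return as<double>(l[n]); }
static int gi(const List &l, const char *n) { return as<int>(l[n]); }
static bool gb(const List &l, const char *n) { return as<bool>(l[n]); }

static RewardParams parse_reward(const List &l) {
  RewardParams r;
  r.kg = gd(l, "k_g");
  r.kdv = gd(l, "k_dv");
  r.kda = gd(l, "k_da");
  r.vfree = gd(l, "v_free");
  return r;
}

static ValCfg parse_valcfg(const List &l) {
  ValCfg c;
  c.scheme = gi(l, "scheme");
  c.sigmoid = gi(l, "sigmoid");
  c.TP = gd(l, "T_P");
  c.Td = gd(l, "discount_T");
  c.ccost = gd(l, "collision_cost");
  c.pcost = gd(l, "priority_cost");
  c.loomw = gd(l, "looming_weight");
  c.squash = gd(l, "squash_scale");
  c.dt_int = gd(l, "dt_int");
  c.a_comf = gd(l, "a_comf");
  c.a_max = gd(l, "a_max");
  c.a_dec_max = gd(l, "a_dec_max");
  c.zone_ego = gd(l, "zone_ego");
  c.zone_oth = gd(l, "zone_oth");
  c.margin_ego = gd(l, "margin_ego");
  c.margin_oth = gd(l, "margin_oth");
  c.oth_has_priority = gb(l, "oth_has_priority");
  c.block_first = gb(l, "block_first");
  return c;
}

static OtherProj parse_proj(const List &l) {
  OtherProj p;
  p.assert_accel = gd(l, "assert_accel");
  p.vfree = gd(l, "v_free");
  p.a_stop_max = gd(l, "a_stop_max");
  return p;
}

static EgoState parse_ego(const List &l) {
  EgoState e;
  e.role = gi(l, "role");
  e.d = gd(l, "d");
  e.v = gd(l, "v");
  e.ctrl_now = gd(l, "ctrl_now");
  e.ramp_rem = as<std::vector<double> >(l["ramp_rem"]);
  e.ramp_amp = as<std::vector<double> >(l["ramp_amp"]);
  e.ramp_dur = gd(l, "ramp_dur");
  return e;
}

// ---------------------------------------------------------------------------
// exported core operations (module surface used by the R wrappers)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_rng_normals(double seed, int agent, int subsystem, int n) {
  StreamRNG r(crossim_stream_seed((uint64_t)seed, agent, subsystem));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = r.norm();
  return out;
}

// [[Rcpp::export]]
List cpp_predict_state(List ego, double action_amp, double other_d, double other_v,
                       double other_accel, double horizon) {
  EgoState es = parse_ego(ego);
  std::vector<Seg> segs = pred_segments(es.role, es.ctrl_now, es.ramp_rem,
                                        es.ramp_amp, es.ramp_dur, action_amp, horizon);
  Profile p;
  p.d0 = es.d;
  p.v0 = std::max(es.v, 0.0);
  p.segs = segs;
  Walker w;
  w.init(p);
  w.step(horizon);
  double aP;
  if (es.role == 0) {
    aP = (w.v - std::max(es.v, 0.0)) / horizon;
  } else {
    aP = es.ctrl_now + action_amp * std::min(horizon, es.ramp_dur) / es.ramp_dur;
    for (size_t i = 0; i < es.ramp_rem.size(); ++i)
      aP += es.ramp_amp[i] * std::min(horizon, es.ramp_rem[i]) / es.ramp_dur;
  }
  Profile po;
  po.d0 = other_d;
  po.v0 = std::max(other_v, 0.0);
  if (std::fabs(other_accel) > 1e-15) {
    Seg s;
    if (other_accel < 0.0) {
      s.dur = po.v0 / (-other_accel);
    } else {
      s.dur = horizon;
    }
    s.a0 = other_accel;
    s.j = 0.0;
    po.segs.push_back(s);
  }
  Walker wo;
  wo.init(po);
  wo.step(horizon);
  return List::create(_["ego_d"] = w.d, _["ego_v"] = w.v, _["ego_a"] = aP,
                      _["other_d"] = wo.d, _["other_v"] = wo.v);
}

// [[Rcpp::export]]
double cpp_short_term_value(List ego, double action_amp, double other_d,
                            double other_v, int behavior, List reward, List valcfg,
                            List proj) {
  EgoState es = parse_ego(ego);
  RewardParams rp = parse_reward(reward);
  ValCfg c = parse_valcfg(valcfg);
  OtherProj op = parse_proj(proj);
  c.scheme = 0;
  return eval_u_ego(es, action_amp, other_d, other_v, behavior, rp, c, op);
}

// [[Rcpp::export]]
List cpp_affordance_value(List ego, double action_amp, double other_d,
                          double other_v, int behavior, List reward, List valcfg,
                          List proj) {
  EgoState es = parse_ego(ego);
  RewardParams rp = parse_reward(reward);
  ValCfg c = parse_valcfg(valcfg);
  OtherProj op = parse_proj(proj);
  c.scheme = 1;
  double uf, us;
  double u = eval_u_ego(es, action_amp, other_d, other_v, behavior, rp, c, op, &uf, &us);
  return List::create(_["u"] = u, _["u_pass_first"] = uf, _["u_pass_second"] = us);
}

// [[Rcpp::export]]
List cpp_plan_access_order(List ego, double action_amp, double other_d,
                           double other_v, int behavior, int order, List reward,
                           List valcfg, List proj) {
  EgoState es = parse_ego(ego);
  RewardParams rp = parse_reward(reward);
  ValCfg c = parse_valcfg(valcfg);
  OtherProj op = parse_proj(proj);
  std::vector<Seg> segs = pred_segments(es.role, es.ctrl_now, es.ramp_rem,
                                        es.ramp_amp, es.ramp_dur, action_amp, c.TP);
  Profile tmp;
  tmp.d0 = es.d;
  tmp.v0 = std::max(es.v, 0.0);
  tmp.segs = segs;
  Walker w;
  w.init(tmp);
  w.step(c.TP);
  double fa;
  Profile othp = behavior_profile_cpp(other_d, other_v, behavior, op, &fa);
  double te_o, tx_o;
  entry_exit_times(othp, c.zone_oth, &te_o, &tx_o);
  PlanResult pr = plan_order_cpp(order, es.d, es.v, segs, w.d, w.v, c.TP, rp, c,
                                 te_o, tx_o);
  NumericMatrix sm(pr.prof.segs.size(), 3);
  for (size_t i = 0; i < pr.prof.segs.size(); ++i) {
    sm(i, 0) = pr.prof.segs[i].dur;
    sm(i, 1) = pr.prof.segs[i].a0;
    sm(i, 2) = pr.prof.segs[i].j;
  }
  colnames(sm) = CharacterVector::create("dur", "accel", "jerk");
  return List::create(_["feasible"] = pr.feasible, _["t_entry"] = pr.t_entry,
                      _["t_exit"] = pr.t_exit, _["other_t_entry"] = te_o,
                      _["other_t_exit"] = tx_o, _["segments"] = sm);
}

// [[Rcpp::export]]
double cpp_value_other(List ego, double cond_amp, double other_d, double other_v,
                       int behavior, List reward_oth, List valcfg_oth, List proj_oth) {
  EgoState es = parse_ego(ego);
  RewardParams rp = parse_reward(reward_oth);
  ValCfg c = parse_valcfg(valcfg_oth);
  OtherProj op = parse_proj(proj_oth);
  return eval_u_oth(es, cond_amp, other_d, other_v, behavior, rp, c, op);
}

// [[Rcpp::export]]
double cpp_behavior_accel(double d, double v, int behavior, List proj) {
  OtherProj op = parse_proj(proj);
  double fa;
  behavior_profile_cpp(d, v, behavior, op, &fa);
  return fa;
}

// ---------------------------------------------------------------------------
// simulation engine
// ---------------------------------------------------------------------------

struct AgentSim {
  bool modeled;
  int role;
  double zone;
  double d, v, a, ctrl;
  std::vector<double> sd, sv; // scripted trajectory
  // control machinery
  double baseline, ramp_dur;
  std::vector<double> ramp_t0, ramp_g;
  std::vector<double> amps;
  int null_idx;
  RewardParams rp, rp_oth;
  ValCfg vc, vc_oth;
  OtherProj proj_oth;
  bool obs_est, val_est, act_sens, val_noise, kalman, accum, reset;
  int sens_mode;
  double T, sigV, dVth, betaV, sigO, TOf, TO1, sigs, sigth, eyeh, floor_d, procn,
      prior_vm, prior_vsd;
  // internal state
  bool kal_init;
  double km0, km1, kp00, kp01, kp11;
  bool have_prev;
  double prev_pp, prev_pv;
  std::vector<double> obs_hist; // raw observations (no-filter speed estimate)
  double speed_window;
  std::vector<double> AO;  // 2
  std::vector<double> Vba; // 2 * ncond
  bool Vba_init;
  std::vector<double> Vhat;
  bool Vhat_init;
  bool frozen;
  double Pfroz0, Pfroz1;
  StreamRNG *rng_sens, *rng_kal, *rng_val, *rng_bval;
  // trace outputs of the current decision
  double out_Pf, out_Ps, out_pp, out_pv, out_kvp, out_kvs, out_act, out_Vn, out_Vb;
};

static void kal_step_sim(AgentSim &A, double obs, double sx, double dt) {
  if (!A.kal_init) {
    A.km0 = obs;
    A.km1 = A.prior_vm;
    A.kp00 = sx * sx;
    A.kp01 = 0.0;
    A.kp11 = A.prior_vsd * A.prior_vsd;
    A.kal_init = true;
    return;
  }
  double q = A.procn * A.procn;
  double p00 = A.kp00 - 2.0 * dt * A.kp01 + dt * dt * A.kp11 + q * dt * dt * dt * dt / 4.0;
  double p01 = A.kp01 - dt * A.kp11 - q * dt * dt * dt / 2.0;
  double p11 = A.kp11 + q * dt * dt;
  double m0 = A.km0 - A.km1 * dt, m1 = A.km1;
  if (R_finite(obs)) {
    double S = p00 + sx * sx;
    double Kp = p00 / S, Ks = p01 / S;
    double innov = obs - m0;
    m0 += Kp * innov;
    m1 += Ks * innov;
    double p00n = (1.0 - Kp) * p00;
    double p01n = (1.0 - Kp) * p01;
    double p11n = p11 - Ks * p01;
    p00 = p00n;
    p01 = p01n;
    p11 = p11n;
  }
  A.km0 = m0;
  A.km1 = m1;
  A.kp00 = p00;
  A.kp01 = p01;
  A.kp11 = p11;
}

static void decide(AgentSim &A, double od, double ov, bool block_first, double t,
                   double dt) {
  int na = (int)A.amps.size();
  int nc = A.act_sens ? na : 1;

  // --- perception ---------------------------------------------------------
  double pp, pv;
  if (A.sens_mode == 0) {
    pp = od;
    pv = ov;
  } else {
    double D = std::max(od, A.floor_d);
    double sx = (A.sens_mode == 1) ? A.sigs
                                   : A.sigth * (D * D + A.eyeh * A.eyeh) / A.eyeh;
    double obs = od + sx * A.rng_sens->norm();
    if (!A.kalman) A.obs_hist.push_back(obs);
    if (A.kalman) {
      kal_step_sim(A, obs, sx, dt);
      // joint draw from the posterior (Cholesky)
      double l00 = std::sqrt(std::max(A.kp00, 0.0));
      double l10 = (l00 > 1e-12) ? A.kp01 / l00 : 0.0;
      double l11 = std::sqrt(std::max(A.kp11 - l10 * l10, 0.0));
      double z1 = A.rng_kal->norm(), z2 = A.rng_kal->norm();
      pp = A.km0 + l00 * z1;
      pv = A.km1 + l10 * z1 + l11 * z2;
      A.out_kvp = A.kp00;
      A.out_kvs = A.kp11;
    } else {
      pp = obs;
      // windowed finite-difference speed estimate: humans judge approach
      // speed from position samples over a perceptual window, not per frame
      int k = (int)A.obs_hist.size() - 1;
      int m = (int)(A.speed_window / dt + 0.5);
      if (m < 1) m = 1;
      if (m > k) m = k;
      pv = (m >= 1) ? (A.obs_hist[k - m] - obs) / (m * dt) : A.prior_vm;
    }
  }
  A.out_pp = pp;
  A.out_pv = pv;

  // --- freeze once the other is past its conflict exit ---------------------
  bool resolved = (pp <= -A.vc.zone_oth);

  EgoState es;
  es.role = A.role;
  es.d = A.d;
  es.v = A.v;
  es.ctrl_now = A.ctrl;
  es.ramp_dur = A.ramp_dur;
  for (size_t i = 0; i < A.ramp_t0.size(); ++i) {
    es.ramp_rem.push_back(A.ramp_dur - (t - A.ramp_t0[i]));
    es.ramp_amp.push_back(A.ramp_g[i]);
  }

  // --- value-based behavior evidence (initialize on first contact) ---------
  std::vector<double> Vba_new(2 * nc, 0.0);
  bool upd_val = A.val_est && !A.frozen && !resolved;
  if (upd_val) {
    for (int ci = 0; ci < nc; ++ci) {
      double camp = A.act_sens ? A.amps[ci] : 0.0;
      for (int b = 0; b < 2; ++b) {
        double u = eval_u_oth(es, camp, pp, pv, b, A.rp_oth, A.vc_oth, A.proj_oth);
        Vba_new[b * nc + ci] = squash_cpp(u, A.vc_oth.squash, A.vc_oth.sigmoid);
      }
    }
    if (!A.Vba_init) {
      A.Vba = Vba_new;
      A.Vba_init = true;
      upd_val = false; // initialization counts as this step's update
    }
  }

  // --- behavior probabilities from previous-step evidence -------------------
  std::vector<double> Pf(nc), Ps(nc);
  if (A.frozen || resolved) {
    for (int ci = 0; ci < nc; ++ci) {
      Pf[ci] = A.Pfroz0;
      Ps[ci] = A.Pfroz1;
    }
    A.frozen = true;
  } else {
    for (int ci = 0; ci < nc; ++ci) {
      double Af = 0.0, As = 0.0;
      if (A.val_est && A.Vba_init) {
        Af += A.betaV * A.Vba[0 * nc + ci];
        As += A.betaV * A.Vba[1 * nc + ci];
      }
      if (A.obs_est) {
        Af += A.AO[0];
        As += A.AO[1];
      }
      double m = std::max(Af, As);
      double ef = std::exp(Af - m), esx = std::exp(As - m);
      Pf[ci] = ef / (ef + esx);
      Ps[ci] = esx / (ef + esx);
    }
    A.Pfroz0 = Pf[0];
    A.Pfroz1 = Ps[0];
  }
  int ci_null = A.act_sens ? A.null_idx : 0;
  A.out_Pf = Pf[ci_null];
  A.out_Ps = Ps[ci_null];

  // --- update stored evidence to current step -------------------------------
  if (upd_val) {
    double Teff = A.accum ? A.T : dt;
    for (int i = 0; i < 2 * nc; ++i) {
      double noise = A.val_noise ? A.sigV * std::sqrt(dt) * A.rng_bval->norm() : 0.0;
      A.Vba[i] = (1.0 - dt / Teff) * A.Vba[i] + (dt / Teff) * Vba_new[i] + noise;
    }
  }
  if (A.obs_est && !A.frozen && A.have_prev) {
    for (int b = 0; b < 2; ++b) {
      double fa;
      behavior_profile_cpp(A.prev_pp, std::max(A.prev_pv, 0.0), b, A.proj_oth, &fa);
      double pred = A.prev_pp - std::max(A.prev_pv, 0.0) * dt - 0.5 * fa * dt * dt;
      double z = (pp - pred) / A.sigO;
      double ll = -0.5 * std::log(2.0 * M_PI * A.sigO * A.sigO) - 0.5 * z * z;
      A.AO[b] = (1.0 - dt / A.TOf) * A.AO[b] + (dt / A.TO1) * ll;
    }
  }
  A.prev_pp = pp;
  A.prev_pv = pv;
  A.have_prev = true;

  // --- ego action values: behavior-weighted squashed values ------------------
  ValCfg vc = A.vc;
  vc.block_first = block_first;
  std::vector<double> Vt(na);
  for (int ai = 0; ai < na; ++ai) {
    int ci = A.act_sens ? ai : 0;
    double v = 0.0;
    for (int b = 0; b < 2; ++b) {
      double u = eval_u_ego(es, A.amps[ai], pp, pv, b, A.rp, vc, A.proj_oth);
      double Vab = squash_cpp(u, vc.squash, vc.sigmoid);
      v += (b == 0 ? Pf[ci] : Ps[ci]) * Vab;
    }
    Vt[ai] = v;
  }

  // --- evidence accumulation -------------------------------------------------
  for (int ai = 0; ai < na; ++ai) {
    double noise = A.val_noise ? A.sigV * std::sqrt(dt) * A.rng_val->norm() : 0.0;
    if (!A.Vhat_init) {
      A.Vhat[ai] = Vt[ai] + noise;
    } else if (A.accum) {
      A.Vhat[ai] = (1.0 - dt / A.T) * A.Vhat[ai] + (dt / A.T) * Vt[ai] + noise;
    } else {
      A.Vhat[ai] = Vt[ai] + noise;
    }
  }
  A.Vhat_init = true;

  // --- threshold-gated selection ----------------------------------------------
  int best = A.null_idx;
  for (int ai = 0; ai < na; ++ai) {
    if (ai == A.null_idx) continue;
    double diff = A.Vhat[ai] - A.Vhat[best];
    if (diff > 1e-15) {
      best = ai;
    } else if (std::fabs(diff) <= 1e-15 && best != A.null_idx) {
      if (std::fabs(A.amps[ai]) < std::fabs(A.amps[best])) best = ai;
    }
  }
  A.out_Vn = A.Vhat[A.null_idx];
  A.out_Vb = A.Vhat[best];
  int chosen = A.null_idx;
  if (best != A.null_idx && A.Vhat[best] - A.Vhat[A.null_idx] > A.dVth) chosen = best;
  A.out_act = A.amps[chosen];
  if (chosen != A.null_idx) {
    A.ramp_t0.push_back(t);
    A.ramp_g.push_back(A.amps[chosen]);
    if (A.reset) {
      double v0 = A.Vhat[A.null_idx];
      for (int ai = 0; ai < na; ++ai) A.Vhat[ai] = v0;
    }
  }
}

static void apply_control(AgentSim &A, double t_next, double dt) {
  // fold completed ramps into the baseline
  double ctrl_new = A.baseline;
  std::vector<double> t0s, gs;
  for (size_t i = 0; i < A.ramp_t0.size(); ++i) {
    double el = t_next - A.ramp_t0[i];
    if (el >= A.ramp_dur - 1e-12) {
      A.baseline += A.ramp_g[i];
      ctrl_new += A.ramp_g[i];
    } else {
      ctrl_new += A.ramp_g[i] * std::max(0.0, el) / A.ramp_dur;
      t0s.push_back(A.ramp_t0[i]);
      gs.push_back(A.ramp_g[i]);
    }
  }
  A.ramp_t0 = t0s;
  A.ramp_g = gs;
  double v_new;
  if (A.role == 0) {
    v_new = std::max(0.0, ctrl_new);
  } else {
    v_new = std::max(0.0, A.v + dt * ctrl_new);
  }
  A.d -= dt * 0.5 * (A.v + v_new);
  A.a = (v_new - A.v) / dt;
  A.v = v_new;
  A.ctrl = ctrl_new;
}

static void setup_agent(AgentSim &A, const List &ag, double ped_priority, int idx,
                        double other_zone, uint64_t seed) {
  A.modeled = gb(ag, "modeled");
  A.role = gi(ag, "role");
  A.zone = gd(ag, "zone");
  A.d = gd(ag, "d0");
  A.v = gd(ag, "v0");
  A.a = 0.0;
  A.kal_init = false;
  A.have_prev = false;
  A.Vba_init = false;
  A.Vhat_init = false;
  A.frozen = false;
  A.Pfroz0 = A.Pfroz1 = 0.5;
  A.AO.assign(2, 0.0);
  A.out_Pf = A.out_Ps = NA_REAL;
  if (!A.modeled) {
    A.sd = as<std::vector<double> >(ag["d"]);
    A.sv = as<std::vector<double> >(ag["v"]);
    A.ctrl = NA_REAL;
    return;
  }
  A.baseline = gd(ag, "baseline");
  A.ctrl = A.baseline;
  A.amps = as<std::vector<double> >(ag["amps"]);
  A.null_idx = -1;
  for (size_t i = 0; i < A.amps.size(); ++i)
    if (std::fabs(A.amps[i]) < 1e-15) A.null_idx = (int)i;
  if (A.null_idx < 0) stop("action set must contain the null action");
  A.rp = parse_reward(ag["reward"]);
  A.rp_oth = parse_reward(ag["other_reward"]);
  A.vc = parse_valcfg(ag["valcfg"]);
  A.vc_oth = parse_valcfg(ag["valcfg_oth"]);
  A.proj_oth = parse_proj(ag["proj_other"]);
  List fl = ag["flags"];
  A.obs_est = gb(fl, "obs_estimation");
  A.val_est = gb(fl, "value_estimation");
  A.act_sens = gb(fl, "action_sensitive");
  A.val_noise = gb(fl, "value_noise");
  A.sens_mode = gi(fl, "sensory_mode");
  A.kalman = gb(fl, "kalman");
  A.accum = gb(fl, "accumulation");
  List pm = ag["params"];
  A.T = gd(pm, "T");
  A.sigV = gd(pm, "sigma_V");
  A.dVth = gd(pm, "delta_V_th");
  A.betaV = gd(pm, "beta_V");
  A.sigO = gd(pm, "sigma_O");
  A.TOf = gd(pm, "T_Of");
  A.TO1 = gd(pm, "T_O1");
  A.sigs = gd(pm, "sigma_s");
  A.sigth = gd(pm, "sigma_theta");
  A.eyeh = gd(pm, "eye_height");
  A.floor_d = gd(pm, "noise_floor_dist");
  A.procn = gd(pm, "process_noise_accel");
  A.prior_vm = gd(pm, "prior_speed_mean");
  A.prior_vsd = gd(pm, "prior_speed_sd");
  A.ramp_dur = gd(pm, "ramp_dur");
  A.speed_window = gd(pm, "speed_est_window");
  A.reset = gb(pm, "reset_on_action");
  A.Vhat.assign(A.amps.size(), 0.0);
  int nc = A.act_sens ? (int)A.amps.size() : 1;
  A.Vba.assign(2 * nc, 0.0);
  A.rng_sens = new StreamRNG(crossim_stream_seed(seed, idx, 0));
  A.rng_kal = new StreamRNG(crossim_stream_seed(seed, idx, 1));
  A.rng_val = new StreamRNG(crossim_stream_seed(seed, idx, 2));
  A.rng_bval = new StreamRNG(crossim_stream_seed(seed, idx, 3));
}

// [[Rcpp::export]]
List cpp_run_sim(List cfg) {
  double dt = gd(cfg, "dt");
  int n_steps = gi(cfg, "n_steps");
  double seedd = gd(cfg, "seed");
  uint64_t seed = (uint64_t)seedd;
  bool has_lead = cfg.containsElementNamed("lead_d") &&
                  !Rf_isNull(cfg["lead_d"]);
  std::vector<double> lead_d;
  double lead_zone = 0.0;
  if (has_lead) {
    lead_d = as<std::vector<double> >(cfg["lead_d"]);
    lead_zone = gd(cfg, "lead_zone");
  }
  List agl = cfg["agents"];
  if (agl.size() != 2) stop("engine expects exactly two interaction agents");
  double ped_priority = gb(cfg, "ped_priority") ? 1.0 : 0.0;

  AgentSim A[2];
  List ag0 = agl[0], ag1 = agl[1];
  setup_agent(A[0], ag0, ped_priority, 0, gd(ag1, "zone"), seed);
  setup_agent(A[1], ag1, ped_priority, 1, gd(ag0, "zone"), seed);

  const int NC = 17;
  NumericMatrix tr[2] = {NumericMatrix(n_steps + 1, NC),
                         NumericMatrix(n_steps + 1, NC)};
  CharacterVector cn = CharacterVector::create(
      "t", "d", "v", "a", "control", "action", "P_first", "P_second", "Vhat_null",
      "Vhat_best", "percept_pos", "percept_speed", "kal_pos_var", "kal_speed_var",
      "AO_first", "AO_second", "in_conflict");
  colnames(tr[0]) = cn;
  colnames(tr[1]) = cn;

  for (int k = 0; k <= n_steps; ++k) {
    double t = k * dt;
    // record state
    for (int i = 0; i < 2; ++i) {
      tr[i](k, 0) = t;
      tr[i](k, 1) = A[i].d;
      tr[i](k, 2) = A[i].v;
      tr[i](k, 3) = A[i].a;
      tr[i](k, 4) = A[i].modeled ? A[i].ctrl : NA_REAL;
      for (int c = 5; c <= 15; ++c) tr[i](k, c) = NA_REAL;
      tr[i](k, 16) = (A[i].d <= -0.05 && A[i].d > -A[i].zone) ? 1.0 : 0.0;
    }
    if (k == n_steps) break;

    bool block = has_lead && lead_d[k] > -lead_zone;

    // decisions from the synchronous state at step k
    for (int i = 0; i < 2; ++i) {
      if (!A[i].modeled) continue;
      int j = 1 - i;
      decide(A[i], A[j].d, A[j].v, block && A[i].role == 0, t, dt);
      tr[i](k, 5) = A[i].out_act;
      tr[i](k, 6) = A[i].out_Pf;
      tr[i](k, 7) = A[i].out_Ps;
      tr[i](k, 8) = A[i].out_Vn;
      tr[i](k, 9) = A[i].out_Vb;
      tr[i](k, 10) = A[i].out_pp;
      tr[i](k, 11) = A[i].out_pv;
      tr[i](k, 12) = A[i].kal_init ? A[i].kp00 : NA_REAL;
      tr[i](k, 13) = A[i].kal_init ? A[i].kp11 : NA_REAL;
      tr[i](k, 14) = A[i].AO[0];
      tr[i](k, 15) = A[i].AO[1];
    }

    // synchronous state update
    for (int i = 0; i < 2; ++i) {
      if (A[i].modeled) {
        apply_control(A[i], t + dt, dt);
        // the lead-vehicle instruction is a hard constraint: the pedestrian
        // stays at the curb until the first vehicle has fully passed
        if (block && A[i].role == 0 && A[i].d < 0.02) {
          A[i].d = 0.02;
          A[i].v = 0.0;
          A[i].a = 0.0;
        }
        if (!R_finite(A[i].d) || !R_finite(A[i].v))
          stop("non-finite state at step %d for agent %d", k, i + 1);
      } else {
        double vn = A[i].sv[k + 1];
        A[i].a = (vn - A[i].v) / dt;
        A[i].v = vn;
        A[i].d = A[i].sd[k + 1];
      }
    }
  }

  for (int i = 0; i < 2; ++i) {
    if (A[i].modeled) {
      delete A[i].rng_sens;
      delete A[i].rng_kal;
      delete A[i].rng_val;
      delete A[i].rng_bval;
    }
  }
  return List::create(_["agent1"] = tr[0], _["agent2"] = tr[1]);
}
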