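#include "core.h"
#include <algorithm>

// ---------------------------------------------------------------------------
// segment kinematics
// ---------------------------------------------------------------------------

void seg_state(double v0, double a0, double j, double tau, double *x, double *v) {
  double X = 0.0, V = v0, t = 0.0, A = a0;
  for (int guard = 0; guard < 8 && t < tau - 1e-15; ++guard) {
    double rem = tau - t;
    if (V <= 1e-15 && A <= 0.0) {
      // stopped and pushed backwards: stationary until accel turns positive
      if (j <= 0.0) {
        t = tau;
        break;
      }
      double tp = -A / j;
      if (tp >= rem) {
        t = tau;
        break;
      }
      t += tp;
      A = 0.0;
      V = 0.0;
      continue;
    }
    double ve = V + A * rem + 0.5 * j * rem * rem;
    bool dip = false;
    if (ve < 0.0) {
      dip = true;
    } else if (j > 0.0 && A < 0.0) {
      double tv = -A / j; // location of the speed minimum
      if (tv > 0.0 && tv < rem) {
        double vmin = V + A * tv + 0.5 * j * tv * tv;
        if (vmin < 0.0) dip = true;
      }
    }
    if (dip) {
      // first root of V + A s + (j/2) s^2 in (0, rem]
      double lo = 0.0, hi = rem;
      if (ve >= 0.0 && j > 0.0) hi = -A / j;
      for (int it = 0; it < 60; ++it) {
        double mid = 0.5 * (lo + hi);
        double f = V + A * mid + 0.5 * j * mid * mid;
        if (f > 0.0) lo = mid; else hi = mid;
      }
      double tz = hi;
      X += V * tz + 0.5 * A * tz * tz + (j / 6.0) * tz * tz * tz;
      t += tz;
      A = A + j * tz;
      V = 0.0;
      continue;
    }
    X += V * rem + 0.5 * A * rem * rem + (j / 6.0) * rem * rem * rem;
    V = ve;
    t = tau;
    break;
  }
  *x = X;
  *v = std::max(V, 0.0);
}

void Walker::init(const Profile &pr) {
  p = &pr;
  i = 0;
  tin = 0.0;
  d = pr.d0;
  v = pr.v0 < 0.0 ? 0.0 : pr.v0;
  t = 0.0;
}

double Walker::cur_accel() const {
  if (i >= p->segs.size()) return 0.0;
  const Seg &s = p->segs[i];
  double a = s.a0 + s.j * tin;
  if (v <= 1e-12 && a < 0.0) return 0.0;
  return a;
}

void Walker::step(double h) {
  while (h > 1e-15) {
    if (i >= p->segs.size()) { // hold terminal speed
      d -= v * h;
      t += h;
      return;
    }
    const Seg &s = p->segs[i];
    double rem = s.dur - tin;
    double hh = std::min(h, rem);
    double x, vn;
    seg_state(v, s.a0 + s.j * tin, s.j, hh, &x, &vn);
    d -= x;
    v = vn;
    t += hh;
    tin += hh;
    h -= hh;
    if (tin >= s.dur - 1e-12) {
      ++i;
      tin = 0.0;
    }
  }
}

double time_to_advance(const Profile &p, double target) {
  if (target <= 0.0) return 0.0;
  double X = 0.0, V = p.v0 < 0.0 ? 0.0 : p.v0, T = 0.0;
  for (size_t i = 0; i < p.segs.size(); ++i) {
    const Seg &s = p.segs[i];
    double xe, ve;
    seg_state(V, s.a0, s.j, s.dur, &xe, &ve);
    if (X + xe >= target - 1e-12) {
      double lo = 0.0, hi = s.dur;
      for (int it = 0; it < 60; ++it) {
        double mid = 0.5 * (lo + hi), xm, vm;
        seg_state(V, s.a0, s.j, mid, &xm, &vm);
        if (X + xm < target) lo = mid; else hi = mid;
      }
      return T + hi;
    }
    X += xe;
    V = ve;
    T += s.dur;
  }
  if (V > 1e-12) return T + (target - X) / V;
  return CS_INF;
}

void entry_exit_times(const Profile &p, double L, double *t_entry, double *t_exit,
                      double margin) {
  if (p.d0 <= -L) { // already past its exit: no longer a constraint
    *t_entry = CS_INF;
    *t_exit = 0.0;
    return;
  }
  *t_entry = (p.d0 <= margin) ? 0.0 : time_to_advance(p, p.d0 - margin);
  *t_exit = time_to_advance(p, p.d0 + L);
}

// ---------------------------------------------------------------------------
// projections and prediction
// ---------------------------------------------------------------------------

Profile behavior_profile_cpp(double d, double v, int behavior, const OtherProj &op,
                             double *first_accel) {
  Profile p;
  p.d0 = d;
  p.v0 = std::max(v, 0.0);
  double a = 0.0;
  if (behavior == 0) { // pass first: head for (at least) free speed
    if (p.v0 < op.vfree - 1e-9 && op.assert_accel > 0.0) {
      a = op.assert_accel;
      Seg s = {(op.vfree - p.v0) / a, a, 0.0};
      p.segs.push_back(s);
    }
  } else { // pass second: stop at own conflict entry
    if (p.v0 > 1e-9) {
      double areq = (d > 0.05) ? p.v0 * p.v0 / (2.0 * d) : op.a_stop_max;
      double amag = std::min(areq, op.a_stop_max);
      a = -amag;
      Seg s = {p.v0 / amag, a, 0.0};
      p.segs.push_back(s);
    }
  }
  if (first_accel) *first_accel = a;
  return p;
}

std::vector<Seg> pred_segments(int role, double ctrl_now,
                               const std::vector<double> &rem,
                               const std::vector<double> &amp, double ramp_dur,
                               double action_amp, double horizon) {
  std::vector<double> r, g;
  for (size_t i = 0; i < rem.size(); ++i) {
    if (rem[i] > 1e-12 && std::fabs(amp[i]) > 1e-15) {
      r.push_back(rem[i]);
      g.push_back(amp[i]);
    }
  }
  if (std::fabs(action_amp) > 1e-15) {
    r.push_back(ramp_dur);
    g.push_back(action_amp);
  }
  std::vector<double> brk;
  brk.push_back(0.0);
  for (size_t i = 0; i < r.size(); ++i)
    if (r[i] < horizon - 1e-12) brk.push_back(r[i]);
  brk.push_back(horizon);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end(),
                        [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
            brk.end());

  std::vector<Seg> out;
  for (size_t k = 0; k + 1 < brk.size(); ++k) {
    double ta = brk[k], tb = brk[k + 1];
    double slope = 0.0, level = ctrl_now;
    for (size_t i = 0; i < r.size(); ++i) {
      if (r[i] > ta + 1e-12) slope += g[i] / ramp_dur;
      level += g[i] * std::min(ta, r[i]) / ramp_dur;
    }
    Seg s;
    s.dur = tb - ta;
    if (role == 0) { // pedestrian: control is speed; accel = slope of command
      s.a0 = slope;
      s.j = 0.0;
    } else { // driver: control is acceleration, linear within the interval
      s.a0 = level;
      s.j = slope;
    }
    out.push_back(s);
  }
  return out;
}

static std::vector<Seg> truncate_segs(const std::vector<Seg> &in, double T) {
  std::vector<Seg> out;
  double t = 0.0;
  for (size_t i = 0; i < in.size(); ++i) {
    if (t >= T - 1e-12) break;
    Seg s = in[i];
    s.dur = std::min(s.dur, T - t);
    out.push_back(s);
    t += s.dur;
  }
  if (t < T - 1e-12) {
    Seg s = {T - t, 0.0, 0.0};
    out.push_back(s);
  }
  return out;
}

static void append_goto(std::vector<Seg> &s, double vfrom, double vto, double amag) {
  if (amag <= 0.0 || std::fabs(vto - vfrom) < 1e-9) return;
  Seg seg;
  seg.a0 = (vto > vfrom) ? amag : -amag;
  seg.j = 0.0;
  seg.dur = std::fabs(vto - vfrom) / amag;
  s.push_back(seg);
}

// ---------------------------------------------------------------------------
// access-order plans
// ---------------------------------------------------------------------------

PlanResult plan_order_cpp(int order, double d_now, double v_now,
                          const std::vector<Seg> &pred, double d_TP, double v_TP,
                          double TP, const RewardParams &rp, const ValCfg &c,
                          double t_entry_o, double t_exit_o) {
  std::vector<Seg> pred_t = truncate_segs(pred, TP);
  auto make_profile = [&](const std::vector<Seg> &plan) {
    Profile p;
    p.d0 = d_now;
    p.v0 = std::max(v_now, 0.0);
    p.segs = pred_t;
    p.segs.insert(p.segs.end(), plan.begin(), plan.end());
    return p;
  };

  PlanResult r;
  r.feasible = true;
  // hold the post-horizon speed until own exit, regain free speed after
  auto hold_plan = [&]() {
    Profile ph = make_profile(std::vector<Seg>());
    double teh, txh;
    entry_exit_times(ph, c.zone_ego, &teh, &txh);
    std::vector<Seg> s;
    if (txh < CS_INF) {
      double hold = std::max(0.0, txh - TP);
      if (hold > 1e-9) {
        Seg h = {hold, 0.0, 0.0};
        s.push_back(h);
      }
      append_goto(s, v_TP, rp.vfree, c.a_comf);
    }
    return s;
  };

  if (order == 0) { // pass first: exit before the other's entry
    // the pass-first affordance is what the current (post-action) speed
    // affords: hold it until the exit, regain the free speed after
    // clearing; raising speed further is the action channel's job, so an
    // exit later than the other's entry makes this order infeasible (the
    // hold profile is then the least-violating boundary plan)
    Profile ph = make_profile(std::vector<Seg>());
    double teh, txh;
    entry_exit_times(ph, c.zone_ego, &teh, &txh);
    bool unconstrained = !(t_entry_o < CS_INF) || d_now <= -c.zone_ego;
    if (!(unconstrained || txh <= t_entry_o + 1e-9)) r.feasible = false;
    r.prof = make_profile(hold_plan());
  } else { // pass second: enter no earlier than the other's exit
    double d_stop = d_TP - c.margin_ego; // yielding plans leave the clearance
    if (!(t_exit_o < CS_INF)) {
      // other never clears: stop (or stay) short of the entry and hold
      std::vector<Seg> s;
      if (v_TP > 1e-9) {
        double amag = (d_stop > 0.05) ? std::min(v_TP * v_TP / (2.0 * d_stop), c.a_dec_max)
                                      : c.a_dec_max;
        Seg seg = {v_TP / amag, -amag, 0.0};
        s.push_back(seg);
        if (d_stop <= 0.05 || v_TP * v_TP / (2.0 * d_stop) > c.a_dec_max + 1e-9)
          r.feasible = false;
      }
      r.prof = make_profile(s);
    } else if (t_exit_o <= TP + 1e-9) {
      r.prof = make_profile(hold_plan());
    } else {
      Profile pd = make_profile(std::vector<Seg>());
      double ted, txd;
      entry_exit_times(pd, c.zone_ego, &ted, &txd);
      if (ted >= t_exit_o - 1e-9) {
        // natural arrival is already late enough
        r.prof = make_profile(hold_plan());
      } else if (d_TP <= 0.0) {
        // already inside the conflict space: cannot cede the space
        r.feasible = false;
        std::vector<Seg> s;
        if (v_TP > 1e-9) {
          Seg seg = {v_TP / c.a_dec_max, -c.a_dec_max, 0.0};
          s.push_back(seg);
        }
        double wait = std::max(0.0, t_exit_o - TP - (v_TP > 1e-9 ? v_TP / c.a_dec_max : 0.0));
        if (wait > 1e-9) {
          Seg w = {wait, 0.0, 0.0};
          s.push_back(w);
        }
        append_goto(s, 0.0, rp.vfree, c.a_comf);
        r.prof = make_profile(s);
      } else if (v_TP < 1e-9) {
        // stationary: wait out the other, then go
        std::vector<Seg> s;
        Seg w = {t_exit_o - TP, 0.0, 0.0};
        s.push_back(w);
        append_goto(s, 0.0, rp.vfree, c.a_comf);
        r.prof = make_profile(s);
      } else {
        double tau = t_exit_o - TP;
        double a2 = 2.0 * (v_TP * tau - d_TP) / (tau * tau);
        double vend = v_TP - a2 * tau;
        std::vector<Seg> s;
        if (a2 > 0.0 && vend >= -1e-9 && a2 <= c.a_dec_max + 1e-12) {
          // single sustained deceleration, arriving exactly at the other's exit
          Seg seg = {tau, -a2, 0.0};
          s.push_back(seg);
          append_goto(s, std::max(vend, 0.0), rp.vfree, c.a_comf);
        } else {
          double as = (d_stop > 0.05) ? v_TP * v_TP / (2.0 * d_stop)
                                      : c.a_dec_max + 1.0;
          if (as <= c.a_dec_max + 1e-12) {
            // stop short of the entry, wait, then go
            double tstop = v_TP / std::max(as, 1e-9);
            if (as > 1e-9) {
              Seg seg = {tstop, -as, 0.0};
              s.push_back(seg);
            } else {
              tstop = 0.0;
            }
            double wait = std::max(0.0, tau - tstop);
            if (wait > 1e-9) {
              Seg w = {wait, 0.0, 0.0};
              s.push_back(w);
            }
            append_goto(s, 0.0, rp.vfree, c.a_comf);
          } else {
            // cannot stop before the entry: boundary (hard-braking) plan
            r.feasible = false;
            double tstop = v_TP / c.a_dec_max;
            Seg seg = {tstop, -c.a_dec_max, 0.0};
            s.push_back(seg);
            double wait = std::max(0.0, tau - tstop);
            if (wait > 1e-9) {
              Seg w = {wait, 0.0, 0.0};
              s.push_back(w);
            }
            append_goto(s, 0.0, rp.vfree, c.a_comf);
          }
        }
        r.prof = make_profile(s);
      }
    }
  }
  entry_exit_times(r.prof, c.zone_ego, &r.t_entry, &r.t_exit);
  return r;
}

// ---------------------------------------------------------------------------
// value computation
// ---------------------------------------------------------------------------

double kinematic_reward_cpp(double v, double a, const RewardParams &rp) {
  return rp.kg * v - rp.kdv * v * v - rp.kda * a * a;
}

double squash_cpp(double u, double scale, int sigmoid) {
  if (u == -CS_INF) return -1.0;
  if (u == CS_INF) return 1.0;
  if (sigmoid == 1) return (2.0 / M_PI) * std::atan(scale * u * M_PI / 2.0);
  return std::tanh(scale * u);
}

double integrate_u(const Profile &ego, const Profile &oth, const RewardParams &rp,
                   const ValCfg &c, bool feasible) {
  double te_o, tx_o;
  entry_exit_times(oth, c.zone_oth, &te_o, &tx_o);
  bool oth_never = !(te_o < CS_INF);
  Walker we, wo;
  we.init(ego);
  wo.init(oth);
  double u = 0.0, t = 0.0;
  bool collided = false;
  const double tcap = 60.0;
  double dfac = std::exp(-c.dt_int / c.Td);
  double disc = std::exp(-0.5 * c.dt_int / c.Td); // midpoint discount weight
  while (t < tcap) {
    double v0 = we.v;
    we.step(c.dt_int);
    wo.step(c.dt_int);
    double v = 0.5 * (v0 + we.v), a = we.cur_accel();
    double K = kinematic_reward_cpp(v, a, rp);
    double L = 0.0;
    if (c.loomw > 0.0 && wo.d > 0.0 && wo.v > 0.0) {
      double D = std::max(wo.d, 0.5);
      L = c.loomw * 1.8 * wo.v / (D * D);
    }
    // an infeasible boundary plan pays the collision cost once, at the
    // first predicted simultaneous occupancy
    if (!feasible && !collided) {
      bool ein = we.d <= c.margin_ego && we.d > -c.zone_ego;
      bool oin = wo.d <= c.margin_oth && wo.d > -c.zone_oth;
      if (ein && oin) {
        u -= c.ccost * disc;
        collided = true;
      }
    }
    u += (K - L) * disc * c.dt_int;
    disc *= dfac;
    t += c.dt_int;
    // once both profiles are in their terminal hold states (constant
    // speeds, all costs resolved) the remaining discounted reward has the
    // closed form K(v_hold) * Td * exp(-t/Td)
    bool steady = we.i >= ego.segs.size() && wo.i >= oth.segs.size();
    bool costs_resolved = (feasible || collided) &&
      (c.loomw == 0.0 || wo.d <= 0.0 || wo.v <= 1e-9);
    if ((steady && costs_resolved) || disc < 1e-4) {
      u += kinematic_reward_cpp(we.v, 0.0, rp) * c.Td * std::exp(-t / c.Td);
      return u;
    }
  }
  u += kinematic_reward_cpp(we.v, 0.0, rp) * c.Td * std::exp(-t / c.Td);
  return u;
}

double short_term_u_cpp(bool ego_is_driver, double dP, double vP, double aP,
                        double dPo, double vPo, const RewardParams &rp,
                        const ValCfg &c) {
  double K = kinematic_reward_cpp(vP, aP, rp);
  // collision cost: constant-velocity occupancy overlap from the predicted state
  auto interval = [](double d, double v, double L, double *te, double *tx) {
    if (d <= -L) { // already past: empty interval
      *te = 1.0;
      *tx = 0.0;
      return;
    }
    *te = (d <= 0.0) ? 0.0 : (v > 1e-9 ? d / v : CS_INF);
    *tx = (v > 1e-9) ? (d + L) / v : CS_INF;
  };
  double te1, tx1, te2, tx2;
  interval(dP, vP, c.zone_ego, &te1, &tx1);
  interval(dPo - c.margin_oth, vPo, c.zone_oth + c.margin_oth, &te2, &tx2);
  double C = (std::max(te1, te2) < std::min(tx1, tx2)) ? c.ccost : 0.0;
  // priority cost: deceleration insufficient to stop before the crossing
  double R = 0.0;
  if (ego_is_driver && c.oth_has_priority && dPo > -c.zone_oth && dP > 0.1 &&
      vP > 1e-6) {
    double dreq = vP * vP / (2.0 * dP);
    double dcur = std::max(0.0, -aP);
    if (dreq > 1e-9) R = c.pcost * std::max(0.0, dreq - dcur) / dreq;
  }
  return K - C - R;
}

// commanded acceleration of a driver at the end of the prediction horizon
static double drv_accel_at(const EgoState &es, double action_amp, double TP) {
  double a = es.ctrl_now + action_amp * std::min(TP, es.ramp_dur) / es.ramp_dur;
  for (size_t i = 0; i < es.ramp_rem.size(); ++i)
    a += es.ramp_amp[i] * std::min(TP, es.ramp_rem[i]) / es.ramp_dur;
  return a;
}

// a plan cannot drop a committed acceleration instantly: ramp it to zero
// over one primitive duration before the plan phases take over
static void append_relax(std::vector<Seg> &segs, double a_end, double dur) {
  if (std::fabs(a_end) > 1e-9 && dur > 1e-9) {
    Seg s = {dur, a_end, -a_end / dur};
    segs.push_back(s);
  }
}

double eval_u_ego(const EgoState &es, double action_amp, double d_oth, double v_oth,
                  int behavior, const RewardParams &rp, const ValCfg &c,
                  const OtherProj &op, double *u_first, double *u_second) {
  std::vector<Seg> segs = pred_segments(es.role, es.ctrl_now, es.ramp_rem,
                                        es.ramp_amp, es.ramp_dur, action_amp, c.TP);
  Profile tmp;
  tmp.d0 = es.d;
  tmp.v0 = std::max(es.v, 0.0);
  tmp.segs = segs;
  Walker w;
  w.init(tmp);
  w.step(c.TP);
  double d_TP = w.d, v_TP = w.v;
  double fa;
  Profile othp = behavior_profile_cpp(d_oth, v_oth, behavior, op, &fa);

  if (c.scheme == 0) {
    double aP;
    if (es.role == 0) {
      aP = (v_TP - std::max(es.v, 0.0)) / c.TP;
    } else {
      aP = drv_accel_at(es, action_amp, c.TP);
    }
    Walker wo;
    wo.init(othp);
    wo.step(c.TP);
    double u = short_term_u_cpp(es.role == 1, d_TP, v_TP, aP, wo.d, wo.v, rp, c);
    if (u_first) *u_first = u;
    if (u_second) *u_second = u;
    return u;
  }

  double TP_eff = c.TP;
  if (es.role == 1) {
    double aTP = drv_accel_at(es, action_amp, c.TP);
    if (std::fabs(aTP) > 1e-9) {
      append_relax(segs, aTP, es.ramp_dur);
      TP_eff = c.TP + es.ramp_dur;
      Profile tmp2;
      tmp2.d0 = es.d;
      tmp2.v0 = std::max(es.v, 0.0);
      tmp2.segs = segs;
      Walker w2;
      w2.init(tmp2);
      w2.step(TP_eff);
      d_TP = w2.d;
      v_TP = w2.v;
    }
  }

  double te_o, tx_o;
  entry_exit_times(othp, c.zone_oth, &te_o, &tx_o, c.margin_oth);
  double best = -CS_INF;
  for (int ord = 0; ord < 2; ++ord) {
    double uo;
    if (ord == 0 && c.block_first) {
      uo = -CS_INF;
    } else {
      PlanResult pr = plan_order_cpp(ord, es.d, es.v, segs, d_TP, v_TP, TP_eff,
                                     rp, c, te_o, tx_o);
      uo = integrate_u(pr.prof, othp, rp, c, pr.feasible);
      if (ord == 0 && c.oth_has_priority) uo -= c.pcost;
    }
    if (ord == 0 && u_first) *u_first = uo;
    if (ord == 1 && u_second) *u_second = uo;
    if (uo > best) best = uo;
  }
  return best;
}

double eval_u_oth(const EgoState &es, double cond_amp, double d_oth, double v_oth,
                  int behavior, const RewardParams &rp_oth, const ValCfg &c_oth,
                  const OtherProj &op_oth) {
  // the other agent's own movement under behavior b
  double fa;
  Profile othp = behavior_profile_cpp(d_oth, std::max(v_oth, 0.0), behavior, op_oth, &fa);
  // the ego, as seen from the other's perspective: pending ramps plus the
  // conditioning action over the horizon, then the commanded control read
  // as committed -- a braking driver is projected to brake to a stop, an
  // accelerating one to keep accelerating over a short commitment horizon
  std::vector<Seg> esegs = pred_segments(es.role, es.ctrl_now, es.ramp_rem,
                                         es.ramp_amp, es.ramp_dur, cond_amp, c_oth.TP);
  if (es.role == 1) {
    double aTP = drv_accel_at(es, cond_amp, c_oth.TP);
    if (aTP < -1e-9) {
      // a braking driver reads as intending to stop, and no later than its
      // own conflict entry: steepen the read to the stopping requirement
      Profile pp;
      pp.d0 = es.d;
      pp.v0 = std::max(es.v, 0.0);
      pp.segs = esegs;
      Walker w;
      w.init(pp);
      w.step(c_oth.TP);
      double amag = -aTP;
      if (w.v > 1e-9) {
        if (w.d > 0.05) amag = std::max(amag, w.v * w.v / (2.0 * w.d));
        Seg s = {w.v / amag, -amag, 0.0};
        esegs.push_back(s);
      }
    } else if (aTP > 1e-9) {
      Seg s = {2.0, aTP, 0.0};
      esegs.push_back(s);
    }
  }
  Profile egop;
  egop.d0 = es.d;
  egop.v0 = std::max(es.v, 0.0);
  egop.segs = esegs;

  if (c_oth.scheme == 0) {
    Walker wo, we;
    wo.init(othp);
    wo.step(c_oth.TP);
    we.init(egop);
    we.step(c_oth.TP);
    bool oth_is_driver = (es.role == 0);
    return short_term_u_cpp(oth_is_driver, wo.d, wo.v, fa, we.d, we.v, rp_oth, c_oth);
  }

  double te_e, tx_e;
  entry_exit_times(egop, c_oth.zone_oth, &te_e, &tx_e, c_oth.margin_oth);
  // the behavior is itself a complete maneuver (accelerate up to free speed,
  // or decelerate to a stop): let the order plan take over where the
  // behavior profile naturally completes, not at the ego action horizon
  double tdur = 0.0;
  for (size_t i = 0; i < othp.segs.size(); ++i) tdur += othp.segs[i].dur;
  double TPo = std::max(tdur, c_oth.TP);
  Walker wo;
  wo.init(othp);
  wo.step(TPo);
  PlanResult pr = plan_order_cpp(behavior, d_oth, std::max(v_oth, 0.0), othp.segs,
                                 wo.d, wo.v, TPo, rp_oth, c_oth, te_e, tx_e);
  double u = integrate_u(pr.prof, egop, rp_oth, c_oth, pr.feasible);
  if (behavior == 0 && c_oth.oth_has_priority) u -= c_oth.pcost;
  return u;
}
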