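#pragma once
#include <vector>
#include <cmath>
#include <limits>

// ---------------------------------------------------------------------------
// Kinematic profiles
//
// Every agent moves on its own 1-D path coordinate, expressed as signed
// distance d to its own conflict-space entry (positive before entry,
// decreasing while approaching).  A Profile is the agent's (actual or
// hypothetical) future trajectory: piecewise segments with acceleration
// linear in time, a(tau) = a0 + j * tau, with speed clamped at zero (no
// reversing; a stopped agent stays stopped until its acceleration becomes
// positive).  After the last explicit segment the speed is held constant.
// ---------------------------------------------------------------------------

const double CS_INF = std::numeric_limits<double>::infinity();

struct Seg {
  double dur, a0, j;
};

struct Profile {
  double d0 = 0.0, v0 = 0.0;
  std::vector<Seg> segs;
};

// state advance within one segment, with v >= 0 clamping
void seg_state(double v0, double a0, double j, double tau, double *x, double *v);

// sequential sampler over a profile
struct Walker {
  const Profile *p = nullptr;
  size_t i = 0;
  double tin = 0.0, d = 0.0, v = 0.0, t = 0.0;
  void init(const Profile &pr);
  double cur_accel() const;
  void step(double h);
};

// time at which cumulated forward advance reaches `target` metres (INF if never)
double time_to_advance(const Profile &p, double target);

// entry/exit times of the conflict space (zone length L); 0 if already
// inside/past; `margin` moves the entry line outward (an opponent is read
// as entering once within `margin` of its entry)
void entry_exit_times(const Profile &p, double L, double *t_entry, double *t_exit,
                      double margin = 0.0);

// ---------------------------------------------------------------------------
// Valuation
// ---------------------------------------------------------------------------

struct RewardParams {
  double kg, kdv, kda, vfree;
};

struct ValCfg {
  int scheme;      // 0 short-term payoff, 1 affordance
  int sigmoid;     // 0 tanh, 1 arctan
  double TP;       // prediction horizon [s]
  double Td;       // discount time constant [s]
  double ccost;    // collision cost
  double pcost;    // priority violation cost
  double loomw;    // looming cost weight (0 disables)
  double squash;   // squash scale [1/reward]
  double dt_int;   // integration step for the affordance integral [s]
  double a_comf;   // comfortable accel magnitude for plans [m/s^2]
  double a_max;    // maximum accel for boosted pass-first plans [m/s^2]
  double a_dec_max; // maximum comfortable deceleration [m/s^2]
  double zone_ego, zone_oth; // conflict-zone lengths along each path [m]
  // safety clearance applies to vehicle positions only: pedestrians demand
  // it from cars, cars do not need it from a waiting pedestrian
  double margin_ego, margin_oth;
  bool oth_has_priority;     // passing first violates the other's priority
  bool block_first;          // forbid the pass-first order (lead-vehicle rule)
};

struct OtherProj {
  double assert_accel; // accel toward free speed under pass-first [m/s^2]
  double vfree;        // role-typical free speed assumed for the other [m/s]
  double a_stop_max;   // cap on the stopping deceleration [m/s^2]
};

// projection of the other agent under behavior b (0 = pass first, 1 = pass
// second); *first_accel receives the signed acceleration of the initial phase
Profile behavior_profile_cpp(double d, double v, int behavior, const OtherProj &op,
                             double *first_accel);

// prediction-phase segments of the ego agent from its pending motor-primitive
// ramps plus one candidate action; covers [0, horizon]
// role: 0 pedestrian (speed control), 1 driver (acceleration control)
std::vector<Seg> pred_segments(int role, double ctrl_now,
                               const std::vector<double> &rem,
                               const std::vector<double> &amp, double ramp_dur,
                               double action_amp, double horizon);

struct PlanResult {
  bool feasible;
  Profile prof;          // full ego profile from now (prediction + plan)
  double t_entry, t_exit; // ego conflict entry/exit under the plan, from now
};

// construct the ego plan achieving access order `order` (0 pass first,
// 1 pass second) against the other's projected entry/exit times
PlanResult plan_order_cpp(int order, double d_now, double v_now,
                          const std::vector<Seg> &pred, double d_TP, double v_TP,
                          double TP, const RewardParams &rp, const ValCfg &c,
                          double t_entry_o, double t_exit_o);

// discounted long-term reward integral along the ego profile, against the
// other's projection (looming, and the overlap penalty for infeasible plans)
double integrate_u(const Profile &ego, const Profile &oth, const RewardParams &rp,
                   const ValCfg &c, bool feasible);

double kinematic_reward_cpp(double v, double a, const RewardParams &rp);
double squash_cpp(double u, double scale, int sigmoid);

// short-term payoff value from the predicted joint state
double short_term_u_cpp(bool ego_is_driver, double dP, double vP, double aP,
                        double dPo, double vPo, const RewardParams &rp,
                        const ValCfg &c);

struct EgoState {
  int role; // 0 ped, 1 driver
  double d, v;
  double ctrl_now;                 // current commanded control
  std::vector<double> ramp_rem;    // remaining ramp times of pending primitives
  std::vector<double> ramp_amp;    // their amplitudes
  double ramp_dur;
};

// unconstrained ego value of (action, other-behavior); for the affordance
// scheme the max over access orders, honoring block_first
double eval_u_ego(const EgoState &es, double action_amp, double d_oth, double v_oth,
                  int behavior, const RewardParams &rp, const ValCfg &c,
                  const OtherProj &op, double *u_first = nullptr,
                  double *u_second = nullptr);

// unconstrained value, for the other agent, of behavior b given the ego's
// conditioning action (roles swapped; "calculated completely analogously")
double eval_u_oth(const EgoState &es, double cond_amp, double d_oth, double v_oth,
                  int behavior, const RewardParams &rp_oth, const ValCfg &c_oth,
                  const OtherProj &op_oth);
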