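---
title: "Model and methods behind crossim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind crossim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossim)
```

# Overview

`crossim` simulates a road-crossing interaction between a driver and a
pedestrian as two cognitive agents approaching a shared *conflict space* —
the stretch of road both must traverse — each on its own one-dimensional
path.  An agent's state is its signed distance to its conflict-space entry
(positive before entry), speed, and acceleration.  Simultaneous occupancy of
the conflict space constitutes a collision; the two collision-free outcomes
are the two *access orders*: the agent passes first or second.

Each simulated agent runs the same perceive–estimate–value–decide loop at
every time step:

1. **Perception.** The agent knows its own state exactly and observes the
   other agent's position with Gaussian noise, either of constant standard
   deviation or growing with distance through the visual angle under the
   horizon (constant retinal angular noise).  Optionally a two-state Kalman
   filter (position and approach speed, white-acceleration process noise,
   position-only measurements) integrates the observations; the percept is
   then a joint random draw from the posterior, so downstream values span
   the currently plausible world states rather than tracking the point
   estimate.
2. **Behavior estimation (theory of mind).**  The agent estimates the
   probability that the other intends to pass first or second.  Two
   evidence sources combine additively: *observation-based* evidence — a
   leaky accumulator of the Gaussian log-likelihood of the current percept
   under each behavior's predicted motion — and *value-based* evidence —
   the accumulated squashed value, for the other agent, of each behavior,
   computed with the same valuation machinery with roles swapped, and
   optionally conditioned on the ego agent's own candidate action
   (action-sensitive estimation).  A softmax over the combined evidence
   (from the previous step) gives `P(b|a)`.
3. **Valuation.**  Each candidate motor primitive (a stepwise speed
   adjustment for the pedestrian, a stepwise acceleration adjustment for
   the driver, ramping linearly over 0.4 s and then holding) is valued
   under each assumed behavior of the other.  Two schemes are provided:
   a *short-term payoff* (predict 0.5 s ahead; reward the kinematics
   `K(v, a) = k_g v − k_dv v² − k_da a²`, subtract a collision-course
   indicator cost and, for a driver facing pedestrian priority, a
   deceleration-deficit cost), and an *affordance-based* long-term value
   (apply the action over the horizon, follow a kinematically bounded plan
   achieving each access order, integrate the discounted kinematics reward,
   and take the best order).  Values pass through a `tanh` sigmoid onto
   `[-1, 1]`.
4. **Decision.**  Expected action values mix the per-behavior values with
   `P(b|a)`.  They feed per-action accumulators (a first-order low-pass
   filter with optional additive Gaussian value noise).  The agent takes
   the best action only when its accumulated value exceeds the
   no-adjustment action's by more than a threshold; otherwise it does
   nothing.  After a non-null action all accumulators reset to the null
   action's level, preventing immediate retriggering from stale evidence.

Every assumption — valuation scheme, observation/value-based estimation,
action sensitivity, sensory noise, Kalman filtering, value noise, evidence
accumulation, looming — can be switched off individually
(`model_variant()`), producing the lattice of model variants that the
selection screens compare.

# Free parameters

| Parameter | Unit | Default | Role |
|---|---|---|---|
| `delta_V_th` | squashed value | 0.005 | action-selection threshold |
| `T` | s | 0.4 | evidence accumulation time constant |
| `sigma_V` | value/√s | 0.1 | value noise scale |
| `beta_V` | – | 2 | weight of value-based behavior evidence |
| `sigma_O` | m | 0.5 | observation-likelihood standard deviation |
| `T_Of`, `T_O1` | s | 2, 0.2 | observation-evidence forgetting / update time |
| `sigma_s` | m | 0.5 | constant sensory noise |
| `sigma_theta` | rad | 0.005 | retinal angular noise |
| `process_noise_accel` | m/s² | 1 | Kalman process noise |
| `discount_T` | s | 10 | exponential temporal discount constant |
| `collision_cost` | reward | 5 / 30 | collision (course) cost, by scheme |
| `priority_cost` | reward | 2 | cost of passing first against priority |
| `entry_margin` | m | 1.5 | safety clearance demanded from vehicles |

The kinematic reward coefficients are not free: they are calibrated
(`calibrate_kinematic_rewards()`) so that the reward rate peaks at the free
speed with unit maximum (`k_g = 2 k_dv v_free`, `k_dv = 1/v_free²`).  The
pedestrian free speed defaults to 1.5 m/s — a brisk walk, and a speed
reachable from standstill through the 0.5 m/s action lattice, which the
steady-state calibration requires; the driver free speed is 13.4 m/s, the
30 mph urban limit.  The grid screens draw log-spaced values inside
`default_parameter_ranges()`; the constant-noise range extends to 10 m
because human distance estimates at the 70–80 m scenario ranges err by
roughly 10–15%, and because the model's 40 Hz independent sampling means
the effective post-filtering uncertainty is far below the per-sample value.

# Design choices in the valuation core

Several pieces of the valuation machinery are deliberate design decisions
where more than one construction was defensible; the chosen forms and their
reasons:

**Hold-until-exit plans.**  The pass-first plan holds the post-horizon
speed until the conflict-space exit and regains the free speed only
afterwards; it does not accelerate on the agent's behalf.  An earlier
construction that let plans accelerate toward the free speed (or sprint to
beat the other agent) made action values insensitive to the actions
themselves — the hypothetical plan absorbed every consequence, so the
threshold gate never saw a reason to act.  Under hold-until-exit semantics,
raising or lowering speed is exclusively the action channel's job, and the
value landscape rewards exactly the action being evaluated.  The pass-second
plan uses a single sustained deceleration to arrive no earlier than the
other's exit when that suffices, and otherwise stops short of the entry and
waits; kinematically impossible orders return the least-violating boundary
plan flagged infeasible.

**Comfortable deceleration bounds.**  Plans never brake harder than a
comfortable deceleration (0.5 m/s² for walking, 3.5 m/s² for driving).
This bound defines a point of no return: past it, ceding the space is no
longer part of the agent's envisioned options, which is what makes an
uncertain percept genuinely risky for the keep-going action and produces
hesitation.  With physically maximal braking in the plans, yielding is
always trivially available and uncertainty never differentiates actions.

**Safety margin on vehicle positions.**  Agents read a vehicle as entering
the conflict space once it is within `entry_margin` (1.5 m) of its entry
line, and a driver plans its yielding stop that far short of the line.  A
car stopping exactly at the line therefore still blocks a pedestrian, while
one stopping clearly short reads as a completed yield — the gradient behind
short-stopping as implicit communication.  Pedestrian positions carry no
margin: a person waiting at the curb does not block a car.

**Committed-control reading of the other.**  When the other agent values
its behaviors (roles swapped), the ego agent's commanded control is read as
committed: a braking driver is projected to continue braking to a stop —
and, as intention-reading, to stop no later than its own entry line — while
an accelerating one is projected to keep accelerating over a short
commitment horizon (2 s).  The ego's own plans, in contrast, relax a
commanded acceleration back to zero over one ramp duration, reflecting that
the agent knows it will keep re-deciding.  This asymmetry is what lets
graded braking function as a signal.

**Collision cost as a lump.**  Under an infeasible boundary plan the
collision cost is charged once, at the first predicted simultaneous
occupancy, rather than per unit of overlap time.  A duration-proportional
charge perversely favored speeding through a conflict over half-hearted
braking.  In the affordance scheme the cost defaults to 30 — roughly half a
minute of maximal progress reward — making a predicted collision worse than
any reasonable waiting time.

**Behavior projections.**  The pass-second behavior of the other agent maps
to the constant deceleration stopping at its entry (capped at a maximal
stopping rate); pass-first maps to accelerating toward the role-typical
free speed when below it (0.6 m/s² walking, 1.5 m/s² driving).  Without
the acceleration component a standing agent would project as never crossing
and could never be yielded to.  A behavior is treated as a complete
maneuver: the order plan continues from where the behavior profile ends,
not from the ego's action horizon.

**Squash scale.**  The affordance values of realistic futures scale with
the discount constant, so the sigmoid scale defaults to `1/discount_T`,
which places typical values near the sigmoid's sensitive range; the
short-term scheme uses scale 1.  The arctan sigmoid is available as a
configuration alternative.

**Raw speed percepts.**  Without Kalman filtering the percept carries a
finite-difference speed estimate over a 0.5 s window of stored
observations, not over a single 25 ms step: speed-from-position judgments
integrate over a perceptual window, and one-step differences at high
sampling rates are numerically meaningless.

# Scenarios

The phenomenon screens use five one-agent scenarios in three kinematic
variants each (vehicle initial time-to-arrival offset by −0.5, 0, +0.5 s):

* **Priority assertion** and **short-stopping**: the modeled driver
  approaches (TTA 3 s at 13.4 m/s) a scripted pedestrian with crossing
  priority standing 1.5 m from its entry.  The scripted pedestrian steps
  off at t = 8 s, giving the episode closure: a genuinely yielding driver
  resumes and passes afterwards, whereas a parameterization that freezes at
  standstill never progresses and is excluded — the operational meaning of
  "getting stuck".
* **Yield acceptance hesitation** and **early yield acceptance**: the
  modeled pedestrian walks at its equilibrium speed, 3 s from entry, toward
  a car yielding with constant deceleration between 38.5 m and 2.5 m from
  the crossing.
* **Gap acceptance hesitation**: the same pedestrian faces a constant-speed
  car at a base TTA of 5.5 s.  The pedestrian needs about 5.3 s to clear,
  so the gap is objectively acceptable — a deterministic agent crosses at
  full speed — but marginal enough that perceptual uncertainty of realistic
  magnitude makes the keep-walking action risky.  Hesitation in this model
  is therefore risk aversion under uncertainty, not a physically forced
  yield; at larger gaps the phenomenon disappears into certainty, at
  smaller ones into rational yielding by every variant.

The interactive set holds the two-agent version of the gap scenario plus
two encounters with both agents at equilibrium speed 3 s from entry, with
and without pedestrian priority.  The experiment replications place the
pedestrian at standstill 1 m (two-vehicle design: 3 speeds × 4 gaps ×
constant/yielding second vehicle, the lead vehicle 3 s from fully passing)
or 1.95 m (interactive design: gaps 3–7 s minus one second of reaction
delay, 4.5 m lane, zebra present or absent) from the conflict space.
During the two-vehicle trials the instruction not to cross before the first
car is enforced two ways: the pass-first order carries value −∞ while the
lead has not fully passed, and the pedestrian is kinematically held at the
curb for that period (instructed participants do not step into a stream in
front of a passing car).  The crossing initiation time is measured from the
lead vehicle's rear passing the crossing to the onset of the movement
episode that leads into the conflict space, so stepping up to the curb and
waiting does not count as crossing.

# Model selection

The deterministic screen runs every grid parameterization over all fifteen
phenomenon scenario variants and flags each phenomenon when its defining
inequality holds in any variant: pedestrian mean-speed ratio below 0.98
(hesitations), vehicle speed above zero at the pedestrian's crossing onset
(early yield), vehicle mean-speed ratio above 1.02 (assertion), and
positive mean excess deceleration together with a final stopping distance
above 1 m (short-stopping).  Parameterizations with collisions or
non-progression are ineligible; retention requires three of five phenomena,
deliberately inclusive.

The stochastic screen simulates five repetitions of the base gap-acceptance
scenario and the three interactive scenarios.  Gap acceptance hesitation is
retained when the median speed ratio lies below one — a bias toward
slowing, which separates genuine hesitation from symmetric decision jitter
that value noise alone produces — with at least one clear episode below the
0.98 threshold, and when all interactive repetitions are collision-free.
Retained deterministic and stochastic parameterizations are then paired
exhaustively and sampled (at most 5,000 per combined variant) into the
populations used for the experiment predictions; when a stochastic variant
retains no parameterization of its own, the combination stage borrows the
retained sets of the other sensory-noise variants so that the more complex
combined variant can still be evaluated.

# Numerical choices

The simulation step is 0.1 s for deterministic runs and 0.025 s for
stochastic ones.  The affordance integral is evaluated at a fixed 0.1 s
step regardless of the simulation step — the integrand is piecewise
polynomial under piecewise-constant-acceleration plans and gains nothing
from a finer mesh — with midpoint discount weights, and terminates with a
closed-form tail `K(v_hold) · discount_T · e^{−t/discount_T}` as soon as
both trajectories reach their terminal hold states with all costs resolved
(hard caps: 60 s, or a discount weight below 10⁻⁴).  Trajectory segments
are integrated in closed form, including zero-speed clamping; conflict
entry and exit times are solved by bisection on the exact profiles.  Agents
update synchronously from the previous step's states, so the update order
cannot matter.  Each (seed, agent, subsystem) triple owns an independent
xorshift64* random stream, so enabling one noise source never perturbs the
draws of another and runs are bit-reproducible.  An agent is counted inside
the conflict space once 5 cm past its entry line, so waiting exactly at the
line does not register as entering.  Selection ties break toward the null
action, then the smaller amplitude.

The acceptance checks run deliberately reduced problem sizes: deterministic
screens at 3 grid values per parameter, stochastic screens over 100 sampled
parameterizations per variant, encounter outcomes over 100 seeds, the
interactive-experiment table over 20 parameterization draws, and the
crossing-time contrast over 50 draws × 6 repetitions of the four yielding
scenarios at 30 mph.

# What the generators do and do not emulate

The scenario factories reproduce the designed kinematics of the two
controlled experiments (initial distances, speeds, gaps, yielding profiles,
priority conditions) and the screening scenarios' geometry.  They do not
emulate reaction-time delays, occlusions, lateral movement, eHMI signals,
more than two (plus one lead) road users, or any demographic heterogeneity
beyond the parameterization populations.  Passing the screens therefore
shows that the cognitive mechanisms can generate the targeted interaction
phenomena under idealized kinematics; it does not certify quantitative
agreement with human trajectories.

# Known limitations

Some retained parameterizations still deadlock at standstill in symmetric
encounters (both agents waiting), a known consequence of this evidence-
accumulation formulation; the non-progression rules exclude them from the
experiment predictions.  The Kalman-filtered pedestrian expresses gap
uncertainty mostly as crossing speed-up rather than slowing, so its simple
stochastic variant retains few parameterizations; the unfiltered
sensory-noise variants carry most of the gap-hesitation retention.  The
priority assertion the model produces is modest (mean-speed ratios a few
percent above one).  Behavior estimation is first-order only: agents do not
model the other agent's model of themselves.
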