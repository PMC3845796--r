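---
title: "The gripsim model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gripsim model: assumptions, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gripsim` simulates a precision grip-and-lift task and models the
trial-to-trial choice of grip force as risk-sensitive action selection in
the basal ganglia. This vignette records the model structure, the
assumptions behind each component, the numerical choices, and the design
decisions that were genuinely open — together with what the simulated
results do and do not show.

## 1. The plant: a two-body stick-slip system

The plant is the minimal mechanical system that produces the slip
phenomenology the rest of the model needs: an object of mass $M_o$ resting
on a table at height $0$, and a finger assembly of effective inertia
$m_{fin}$ pressing on it with grip force $F_G$ and pulling up with lift
force $F_L$. Friction transmits at most $\mu F_G$ of tangential force
between them, so the static hold threshold is exactly the slip force
$F_{slip} = M_o g / \mu$ — the operational definition of $\mu$ as (object
weight)/(slip force).

Three modelling choices deserve justification, because no detailed
published description of the original plant component is available, and
each choice is forced by the published closed-loop behaviour
(slip $< 5$ mm and position error $< 1$ mm at a constant 10 N grip
reference, for all three experimental conditions, with the published PID
gains):

* **Friction capacity is $\mu F_G$, not $2\mu F_G$.** Although each of the
  two fingers has its own contact face, a $2\mu F_G$ capacity would halve
  the hold threshold and contradict $F_{slip} = M_o g/\mu$. The single
  coefficient absorbs both faces.
* **The finger assembly is gravity-compensated.** The arm bears the hand's
  weight; $F_L$ is the *net* vertical drive at the interface. If finger
  weight were part of the vertical balance, the finger would sink during
  the first ~0.1 s (while $F_G$, and with it the friction capacity, is
  still near zero), producing a spurious negative slip and pathological
  costs. With gravity compensation the early transient is a small upward
  creep bounded by the growing friction cone.
* **The controller's lift force acts once per finger** (total
  $2 F_{L}$). With a single $F_L$, lift-off against a 3.24 N object weight
  would occur only at $t = (M_o g - K_P X_{ref}) / (K_I X_{ref}) \approx
  4$ s — after the steady-measurement window opens — leaving a ~23 mm
  position error, 23 times the published bound. Per-finger application
  lifts at ~1.8 s and meets both bounds. (Two other readings of the gains
  were tested and rejected: a position error normalized by $X_{ref}$, and
  centimetre units; both drive the lift force far above the early friction
  capacity and launch the finger.)

The default finger inertia is $m_{fin} = 0.12$ kg. A Routh analysis of the
linearized stick-phase loop shows the published PID gains are stable for a
total lifted mass below 0.75 kg; within that window, 0.12 kg balances the
two error budgets (worst-case slip 3.8 mm of the 5 mm budget, worst-case
position error 0.55 mm of the 1 mm budget). Damping `c_damp` defaults to 0
(the published model is undamped) and is kept as a stabilization option.

**Integration.** Fixed step $dt = 1$ ms, explicit mode switching
(resting / stick / slip), velocities by explicit Euler and positions by the
locally exact constant-acceleration rule $x \mathrel{+}= (v_{old} +
v_{new})\,dt/2$. On piecewise-constant-force segments this is exact, so a
10× finer integration agrees to $\sim 10^{-12}$ m; the only error source is
$O(dt^2)$ per mode switch. Re-sticking projects both bodies onto their
common momentum-conserving velocity when the relative velocity crosses
zero; the relative-velocity tolerance is $10^{-9}$ m/s. Trials whose
positions exceed 10 m are flagged (`blown`) rather than raised as errors,
so optimization layers above always receive a finite cost.

## 2. The controllers

The grip controller is the closed-form step response of an underdamped
second-order system with unity DC gain. The design interprets the
published overshoot criterion $M_p = 1.25$ as the *peak-to-steady-state
ratio* (overshoot fraction $f = M_p - 1$); this is the only reading under
which the published design outputs ($\zeta = 0.4$, $\omega_n = 6.4$ rad/s)
follow from the design formulas. `design_grip_controller(1.25, 0.530)`
returns $\zeta = 0.4037$, $\omega_n = 6.479$ rad/s.

The lift controller is a textbook PID with backward-difference derivative,
no derivative filtering and no anti-windup — the published gains come
without either, and the first-order output filter ($\tau_s = 0.087$ s,
discretized exactly as $F_L \leftarrow F_{L,pid} + (F_L - F_{L,pid})
e^{-dt/\tau_s}$) already suppresses the derivative kick and enforces
$F_L(0) = 0$. The error is used in the negative-feedback orientation
$e = X_{ref} - X_o$ with positive gains (the sign-flipped error with a
negated output is algebraically identical). The derivative memory is
seeded with the initial error, so a pre-existing constant error produces
no kick at $t = 0$. $\tau_s$ and the gains are taken to be in SI units
(seconds); this is the only reading consistent with a 5 s trial.

## 3. Value, risk and utility

A lift at grip reference $F_{Gref}$ is scored by
$CE = \tfrac12\!\left(\frac{\bar X_{fin}-\bar X_o}{\bar X_{fin}}\right)^2 +
\tfrac12\!\left(\frac{X_{ref}-\bar X_o}{X_{ref}}\right)^2$, with all
position averages over the 4–5 s window (the same window as the stable
grip force; the trial lasts 5 s). If the finger never moved
($\bar X_{fin} = 0$) both penalty terms are taken as saturated and
$CE = 1$, keeping the cost finite for the optimization layers.

Value and risk at a grip reference are the mean and *population* variance
of $V_{CE} = e^{-CE}$ over repeated lifts at $\hat F = F_{Gref} + \nu$,
$\nu \sim U(-\nu_{max}, \nu_{max})$, drawn fresh per lift and clamped at
0 N (a negative grip is unphysical, and the clamp
only matters for references below 3 N). The noise half-width is 3 N for
the $\mu = 0.44$ conditions and 1.5 N for $\mu = 0.94$, i.e. proportional
to the slip force. With 2500 samples the population/sample variance
distinction is negligible.

The estimates are taken on a fixed even grid of 25 references spanning
1–10 N rather than at random references; both converge to the same
functions and the grid is reproducible. A master seed is split into
per-grid-point child seeds, so any single estimate can be reproduced in
isolation. The smoother is a Gaussian RBF network: 20 centers evenly
spaced on [1, 10] N, width 1.5× the center spacing, ridge $10^{-6}$, plus
an unpenalized linear tail. The tail is the standard remedy for boundary
droop in RBF least squares: without it the fitted value surface dips about
1% below its plateau at the domain edge, which would corrupt the
monotonicity of the value surface where outcomes are pure. Negative risk
predictions are floored at zero. The utility is $U = V - \alpha h$; the
sign-dependent variant $U = V - \alpha\,\mathrm{sign}(V)\,h$ is available
but coincides with the plain form here because $V_{CE} \in (0, 1]$.

## 4. Go/Explore/NoGo action selection

The selection rule updates the grip reference by
$$\Delta F(t) = A_G\,\mathrm{logsig}(\lambda_G \delta)\,\Delta F(t{-}1)
 - A_N\,\mathrm{logsig}(\lambda_N \delta)\,\Delta F(t{-}1)
 + A_E\,\psi\,e^{-\delta^2/\sigma_E^2},$$
with $\delta$ the trial-to-trial utility difference (the dopamine signal)
after the condition transform: identity for controls,
$\min(\delta, \delta_{Lim})$ for PD OFF, and $\min(\delta, \delta_{Lim}) +
\delta_{Med}$ for PD ON (clamp first, then shift — the order that matches
the stated PD ON range endpoints $[a + \delta_{Med}, \delta_{Lim} +
\delta_{Med}]$). The legacy three-branch threshold rule (fixed-magnitude
explore step, thresholds $DA_{hi}/DA_{lo}$) is kept as
`gen_update_legacy()`.

Choices the published model leaves open, fixed once here:

* **Initialization**: $F_{Gref}(0) \sim U(1, 10)$ N and $\Delta F(0) \sim
  U(-0.5, 0.5)$ N per run. The multiplicative Go/NoGo terms need a nonzero
  seed step.
* **Domain**: the reference is clipped to the RBF training range
  [1, 10] N (extrapolated RBF values are meaningless), and the *stored*
  previous step is the applied, post-clipping step — otherwise a clipped
  oscillation would keep amplifying a step that is never executed.
* **Trial count**: 50 trials per run by default; one "subject" is one
  seeded run; group sizes default to the experimental cohorts (12
  control / 16 PD for the light-object study, 10 per group for the
  medication study).
* **Per-run SGF**: the stable grip force of a lift simulated at the final
  trial's reference. (The across-trial mean is also recorded in the trace
  for users who prefer the series reading; the group-level conclusions
  below are unchanged under either.)
* The empirical range $[a, b]$ of the unconstrained signal is used only to
  validate the clamp constraint $\delta_{Lim} + \delta_{Med} < b$, never
  to rescale.

## 5. Calibration

The calibration cost doubles the weight of the mean error:
$CE_{GEN} = 2(\overline{SGF}_{expt} - \overline{SGF}_{sim})^2 +
(\sigma_{expt} - \sigma_{sim})^2$. The optimizer is a real-coded genetic
algorithm (tournament selection of size 2, BLX-0.5 crossover, Gaussian
mutation with $\sigma$ = 10% of each parameter's range at rate 0.2,
single elitism; population 40, 60 generations by default) — the original
hyperparameters are in an unavailable supplement, so these are ordinary
textbook settings, all exposed in `ga_config()`. For controls the free
set is the six selection parameters plus $\alpha$; for PD OFF only
$(\alpha, \delta_{Lim})$; for PD ON $(\alpha, \delta_{Lim},
\delta_{Med})$, with the control-calibrated gains held fixed. Published
group statistics exist only as figure bars and are not digitized here;
calibration therefore ships with a self-consistency mode (recovering the
statistics of a group simulated with known parameters) and accepts a
user-supplied target.

Group summaries are reported both as mean/variance and in the median/Q3
convention (normality assumed: mean = median, Q3 = mean + 0.6745 sd);
group comparisons use a Welch two-sample t-test on per-run SGF values,
the safe unequal-variance default where no particular test is prescribed.

## 6. What the simulations show — and what they do not

The package's own test suite and acceptance script verify, at the problem
sizes noted: the controller design point and its step-response round trip
(dt = 0.1 ms); the closed-loop slip/position bounds in all three
conditions; the sigmoidal value surface and the risk peak within 1.5 N of
the slip force (25 grid points × 500 lifts per condition); the
Go/NoGo/Explore regime structure of the update rule; and the
plant/optimizer invariants.

Two published group-level contrasts do **not** emerge from this
reconstruction with the tabulated parameters, and the corresponding
checks are expected to fail honestly rather than being tuned to pass:

* *PD ON mean grip force above controls* (light-object study). The
  tabulated PD ON transform ($\delta_{Lim} = -0.5$, $\delta_{Med} =
  0.427$) maps every utility increment smaller than 0.5 in magnitude to
  the constant $-0.073$. Since a smooth batch-fitted utility surface
  yields per-trial increments of order 0.1 at most (steps ≤ 0.5 N times
  slopes ≤ 0.2 per N), the PD ON dynamics are effectively blind to the
  utility landscape: the update reduces to $\Delta F(t) \approx
  -\Delta F(t{-}1) + 0.43\psi$, a neutral oscillation whose terminal
  distribution centers on its initialization, while the control group
  drifts toward the utility maximum at the top of the domain. No faithful
  reading of the initialization, trial count, or SGF aggregation reverses
  this ordering.
* *PD OFF variance above controls* (medication study). The tabulated
  clamp $\delta_{Lim} = 0.5$ never binds for the same scale reason, so PD
  OFF differs from controls only through the smaller $\alpha$, which
  steepens rather than flattens the climbed surface and does not widen
  the terminal spread.

Both clamps would become active — and the published contrasts plausible —
if the per-trial dopamine signal had order-1 magnitude, e.g. under much
larger exploratory steps or an unsmoothed, per-trial-sampled utility.
That variant is outside the scope of the batch pipeline implemented here.

## 7. What the synthetic conditions emulate

The three shipped conditions reproduce the published experimental setups:
object mass and friction (0.33 kg/0.44; 0.3 kg/0.44 "silk"; 0.3 kg/0.94
"sandpaper"), a 5 cm target height, 5 s trials, and grip-reference noise
proportional to the slip force. They do not emulate: multi-digit or 3-D
biomechanics, object rotation, skin viscoelasticity, load perturbations
("rapid load changes"), friction-adaptation protocols, or trial-history
effects in the plant (each lift is independent given its reference).
Passing tests on these conditions therefore support the model's internal
consistency and its controller/plant reconstruction, not claims about
unmodelled experimental manipulations.
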