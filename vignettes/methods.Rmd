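---
title: "Closed-loop DBS control of a thalamocortical absence-epilepsy model: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop DBS control of a thalamocortical absence-epilepsy model: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
three-neuron conductance-based model of childhood absence epilepsy (CAE), the
adaptive fuzzy terminal sliding-mode controller (AFTSMC) that shapes
deep-brain-stimulation (DBS) currents in closed loop, the generators that
define the experimental conditions, and every numerical decision that shapes
the results.

## The plant: a three-neuron corticothalamic motif

Absence seizures arise from aberrant interplay in the loop formed by
thalamic relay (TC), cortical (CT) and reticular thalamic (RT) neurons.  The
package models one neuron of each class as a Hodgkin–Huxley-type
conductance-based cell:

$$C\,\dot V = -\textstyle\sum I_{\text{ionic}} - I_{\text{syn}} + I_{\text{ext}} + u + d,$$

with $C = 1\ \mu F\,cm^{-2}$ per cell, control current $u$ (the DBS input)
and disturbance current $d$ entering additively.  Channel complements: the
TC cell carries leak, transient Na, delayed-rectifier K, low-threshold Ca
($I_T$), hyperpolarization-activated mixed cation ($I_h$) and slow K
($I_{K2}$) currents; the CT cell adds a muscarinic K current ($I_M$) to the
spike triad; the RT cell carries its own low-threshold Ca current
($I_{TS}$).  Spike currents use Traub–Miles rate kinetics with per-cell
threshold offsets; the Ca, h-type and slow K currents use Destexhe-family
voltage-dependent steady states and time constants (the transcription is in
`src/plant.h`, one named function per gate so errors localize).  Maximal
conductances were chosen so that three stated behaviors hold, and the test
suite asserts all three:

* uncoupled cells with zero external drive settle to a quiescent rest
  ($|\dot V| < 10^{-6}$ mV/ms);
* the `normal` preset ($I^{TC}_{\text{ext}} = 5\ \mu A\,cm^{-2}$,
  $\bar g_{GABA_A}(RT{\to}TC) = 0.65\ mS\,cm^{-2}$) produces a slower
  single-spiking rhythm;
* the `cae` preset ($6\ \mu A\,cm^{-2}$, $0.32\ mS\,cm^{-2}$) produces
  faster tonic spiking.

The two presets differ *only* in those two values.  One tuning note: the RT
low-threshold Ca conductance is 1.5 $mS\,cm^{-2}$; at values typical for
isolated reticular-cell models (≥ 2) the uncoupled RT cell becomes a
spontaneous oscillator through its $I_{TS}$ window current, contradicting
the rest requirement.

Synapses follow first-order transmitter-gated kinetics
$\dot s = \alpha T (1-s) - \beta s$ with the sigmoidal release function
$T(V_{\text{pre}}) = 2.84 / (1 + e^{(2 - V_{\text{pre}})/5})$.  The RT→TC
pathway adds a slow GABA$_B$ branch: receptor activation
$\dot r = 0.5\,T(1-r) - 0.0012\,r$ drives a G-protein pool
$\dot s = 0.18\,r - 0.034\,s$ that opens the channel with fourth-power
cooperativity $s^4/(s^4 + K_d)$, $K_d = 100$.  Note that this $s$ is a
concentration, not a fraction: its equilibrium is $(0.18/0.034)\,r \approx
5.3\,r$, so the unit-interval invariant applies to the first-order gates and
to $r$, not to the G-protein pool.

Two conduction delays close the loop: the corticothalamic delay $\tau_1$
(default 10 ms, configurable within 2–10 ms) acts on the transmitter of the
CT→TC AMPA pathway, the thalamocortical delay $\tau_2 = 2.8$ ms on the
TC→CT pathway.  Both presets share the delays, so the desired and actual
plants differ only in the two preset-defining parameters.

### The canonical control-oriented decomposition

For controller analysis the voltage dynamics are written as the
three-input/three-output state-delay system
$\dot x = f(x) + f_\tau(x_\tau) + G\,u + d$ with $x$ the voltage triple.
In this plant the delayed voltages enter only through the presynaptic
transmitter in the gate ODEs, never the voltage equation directly, so the
split assigns the synaptic currents of the two *delayed pathways* to
$f_\tau$ (CT→TC AMPA on the TC channel, TC→CT AMPA on the CT channel, zero
for RT) and everything else to $f$.  $G = \mathrm{diag}(1/C)$ is constant,
positive definite, and bounded below by $\chi_0 = 1/\max C$.  The identity
$f + f_\tau + G u + d = \dot V$ holds to machine precision and is asserted
at 1000 random states; it makes `true_dynamics_split()` the ground-truth
oracle for controller tests.  The delayed-state input of the $f_\tau$
estimators is $(V_{TC}(t-\tau_2), V_{CT}(t-\tau_1), V_{RT}(t))$ — the model
has no delayed RT pathway.

## The controller

The tracking error $e = x_d - x$ (desired minus actual voltage) feeds the
nonsingular terminal sliding surface

$$s_i = \int_0^t e_i\,dt + \sigma |e_i|^{\eta}\,\mathrm{sign}(e_i),
\qquad \sigma > 0,\ 1 < \eta < 2,$$

with the fast reaching law $\dot s = -K_1 s - K_2 |s|^{\rho}\mathrm{sign}(s)$,
$0 < \rho < 1$.  The fractional powers give finite-time convergence with a
*continuous* control input; the analytic reaching-time, settling-time and
boundary-layer bounds are exposed by `time_bounds()` and exercised against
an ideal-knowledge controller on a known scalar plant
(`simulate_ideal_tsm()`), including a numerical check of the Lyapunov
decrease inequality along the reaching phase.

Deployment replaces the unknown dynamics by fuzzy estimates and the exact
gain inverse by the regularized form
$u_c = \hat G^{\mathsf T}(\varepsilon_0 I + \hat G \hat G^{\mathsf T})^{-1}(\cdot)$,
which is finite for every estimate including $\hat G = 0$.  The residual of
the regularization, $u_0$, and online upper-bound estimates of the fuzzy
approximation errors ($\hat\varepsilon_f$, $\hat\varepsilon_{f_\tau}$,
$\hat\varepsilon_g$) and of the disturbance ($\hat d$) feed a continuous
robustifying term

$$u_r = \frac{s\,|s^{\mathsf T}|\,(\hat\varepsilon_f +
\hat\varepsilon_{f_\tau} + \hat\varepsilon_g |u_c| + \hat d + |u_0|)}
{\sigma_0 \lVert s\rVert^2 + \Upsilon},$$

whose adaptive denominator parameter $\Upsilon$ only decreases (floored at
$\Upsilon_{\min}$) while the bound estimates only grow.  The total input is
$u = u_c + u_r$, optionally saturated (off by default and in all benchmark
runs).

### The fuzzy estimators

Fifteen fuzzy logic systems approximate the unknowns: three for $f$, three
for $f_\tau$, nine for the entries of $G$.  Each uses five Gaussian
memberships per input voltage with centers $(-60,-40,0,40,60)$ mV and width
$\delta$, a $5^3$ product-inference rule base, center-average
defuzzification, and adaptive output weights updated by terminal-gradient
laws whose step scales with $\sigma\eta|e|^{\eta-1}|s|$.

The published width $\delta = 1$ mV with centers 40 mV apart makes the
Gaussians near-disjoint: between centers all raw rule products underflow
double precision.  The basis is therefore evaluated in the log domain
(softmax form), which keeps it an exact simplex everywhere — the package
asserts normalization to $10^{-12}$ at $10^4$ random points.  With
$\delta = 1$ the basis is effectively one-hot, so each estimator is
piecewise constant over 40 mV cells; the approximation residual this leaves
is precisely what the robustifying term and the adaptive bounds absorb.
`membership_spec(delta = 20)` is the better-conditioned alternative if a
genuinely interpolating approximator is wanted; all shipped defaults and
all benchmark runs use the published $\delta = 1$.

### Baseline controllers

Two reconstructions serve as comparison arms (their exact published
formulations are not available):

* **AFSMC** — linear surface $s = e + \lambda\int e$, exponential reaching
  law $k_{1,\text{lin}} s + k_{sw}\,\mathrm{sign}(s)$, the same fuzzy
  estimators for $f$ and $f_\tau$, and the input gain taken as known
  ($G = I$, which is the true gain here) in the classical manner.  We found
  that additionally estimating $G$ with uniformly initialised, near-one-hot
  fuzzy cells and no robustifying term reverses the control sign in freshly
  visited cells and destabilises the loop for every gain setting tried —
  consistent with the classical literature's preference for a known input
  gain.  The discontinuous switching term makes this baseline the
  chattering reference.
* **STSMC** — per-channel super-twisting law
  $u = a|s|^{1/2}\mathrm{sign}(s) + w$, $\dot w = b\,\mathrm{sign}(s)$ on
  the same linear surface; continuous by construction, no model knowledge.

### Tuned gains

The reference study selected controller gains by trial and error and did
not print them, so the package ships its own tuning, frozen after
calibration on the nominal scenario and then used unchanged for the
disturbance and uncertainty studies (the same protocol the study
describes).  Defaults: $\sigma = 0.03$, $\eta = 1.5$, $\rho = 0.6$,
$K_1 = 400 I$, $K_2 = 200 I$, $\varepsilon_0 = 0.01$, $\sigma_0 = 10$,
$\kappa_f = \kappa_{f_\tau} = 10$, $\kappa_g = 0.1$,
$\kappa_0 = \gamma_0 = \dots = \gamma_3 = 0.1$, $\Upsilon(0) = 1$,
$\Upsilon_{\min} = 10^{-6}$.  Three choices deserve explanation:

* **Small $\kappa_g$.**  At the first control step the bracket term is
  large (initial voltage mismatch up to 40 mV), and a fast gain-weight
  update overshoots $\hat G$ by orders of magnitude, after which the
  regularized inverse collapses the control and recovery is slow.  A slow
  gain adaptation ($\kappa_g = 0.1$) lets the robustifying term carry the
  startup while $\hat G$ converges gently.
* **$\sigma_0 = 10$ and the projection bound on $\hat\varepsilon_g$.**  In
  the robustifying numerator the term $\hat\varepsilon_g |u_c|$ scales with
  the control magnitude, so $u_r$ acts as a gain of roughly
  $\hat\varepsilon_g/\sigma_0$ on $u_c$ when $\lVert s\rVert$ is large.
  $\hat\varepsilon_g$ is non-decreasing by construction; in long runs under
  heavy parameter drift it would grow until the discrete-time loop rings
  and diverges.  The continuous-time theory keeps it bounded via the
  Lyapunov argument; the discrete safeguard is a projection bound
  (`eps_g_max = 50`, same spirit as the $\pm 10^6$ weight projection).
  Shrinking $\gamma_2$ instead starves the robust term and forfeits the
  nominal tracking accuracy.
* **Small $\sigma$.**  On the sliding surface the error decays at rate
  $\propto 1/(\eta\sigma)|e|^{2-\eta}$, so a smaller $\sigma$ shortens the
  startup transient, which dominates the 2000 ms RMSE; the steady-state
  boundary layer $(\delta/\sigma)^{1/\eta}$ grows only mildly.

Baseline gains: $\lambda = 1$, $k_{1,\text{lin}} = 10$, $k_{sw} = 20$,
$a = 20$, $b = 50$.

## Experimental conditions

`run_trial()` co-simulates the desired (normal) and actual (CAE) plants;
the desired-trajectory derivative $\dot x_d$ is the desired plant's exact
instantaneous derivative (no finite differencing).  Every random quantity
derives from the trial seed, so `(config, seed)` replays byte-identically.

* **Initial conditions** — both plants' voltages uniform on
  $[-60, -20]$ mV with all gating at steady state; estimator weights
  uniform on $[0, 1]$.
* **Disturbance** — rectangular current pulses (width 1 ms, amplitudes
  1.25–2 $\mu A\,cm^{-2}$) on the CT neuron, onset intervals i.i.d. gamma
  with mean rate 14 Hz.  The gamma shape is not specified in the source
  protocol; shape 2 is used (a renewal process with coefficient of
  variation $1/\sqrt 2$ — irregular but not Poisson-bursty), configurable.
* **Parameter uncertainty** — each ionic maximal conductance and reversal
  potential (28 parameters) is multiplied by $1 + y(t)$ where $y$ is an
  independent uniform sequence on $[-p, +p]$, resampled every 2 s, passed
  through a critically damped second-order low-pass filter with natural
  frequency 0.05 Hz.  The filter is a convex smoother, so
  $|y| \le p$ holds for all time by construction.  Two deliberate choices:
  the filter state starts at the first raw draw (a stationary start) —
  warming up from zero would leave a 0.05 Hz filter essentially at nominal
  for an entire 2000 ms trial, making the uncertainty scenario vacuous —
  and the 2 s resampling (rather than 1 s) is what keeps ≥ 95 % of the
  drift power below 0.1 Hz after this filter, a property the test suite
  checks by periodogram on a 200 s sample.

Metrics: per-channel tracking RMSE
$\sqrt{N^{-1}\sum_i |x_j(i) - x_{j,d}(i)|^2}$ over all integration samples,
and a chattering index (mean absolute step-to-step control difference
normalized by step and range) that quantifies the switching-activity
contrast between the terminal design and the AFSMC baseline.  Batches
re-randomize everything per trial and report mean ± population standard
deviation.

## Numerical choices

* **Integrator** — classical RK4 at a fixed step, default
  $dt = 10^{-3}$ ms (the reference sampling period, shared by plant,
  controller and all adaptation laws, which advance by forward Euler at the
  same step).  A $10^{-2}$ ms profile is used for open-loop plant tests
  after the convergence check; the closed-loop adaptive laws need the fine
  step.
* **Delays** — ring buffers at grid resolution; delays are validated as
  integer grid multiples at configuration time; pre-history is the constant
  initial voltage.  RK4 stage values of the delayed voltages use the stored
  grid samples directly at whole steps and a four-point (cubic) stencil at
  half steps, preserving the integrator's fourth order (the observed order
  is asserted to be $4 \pm 0.5$); a zero delay substitutes the stage's own
  instantaneous voltage.
* **Degenerate inputs and guards** — $\mathrm{sign}(0) = 0$ everywhere;
  $|V| > 150$ mV or any non-finite state flags divergence with a timestamp
  (a flagged result, not a crash, in `run_trial()`); the fuzzy basis
  denominator is floored via the log-domain max-subtraction; weights are
  projected to $\pm 10^6$; $\Upsilon$ is floored at $10^{-6}$.
* **Problem sizes in the test suite** — property tests run the plant at
  $dt = 10^{-2}$ ms over 1–8 s horizons; the closed-loop benchmark tests
  run the full 2000 ms protocol at $dt = 10^{-3}$ ms, with batches of five
  trials per condition.

## What the generators do and do not emulate

The synthetic conditions reproduce the study protocol: random operating
points, non-regular pulse disturbances, slow parameter drift.  They do not
emulate several features of real closed-loop DBS: there is no channel or
measurement noise (voltages are read exactly), no electrode geometry or
field spread, no charge-balancing constraint on the stimulation waveform,
and the plant is a three-neuron motif rather than a population — so passing
benchmarks here demonstrates the control design's properties on the stated
model, not clinical performance.  Tracking intracellular membrane voltage
directly also presumes an observation channel that long-term clinical
recordings cannot provide; feature-level tracking (e.g. local-field
synchrony) is out of scope.

## Known limitations

* The supplementary channel-kinetics tables of the reference study were not
  available; the ionic kinetics are standard Destexhe-family formulations
  tuned to reproduce the stated qualitative regimes, so trajectory-level
  agreement with the original figures is not expected — tracking-error
  benchmarks are computed against this package's own plant.
* The AFSMC and STSMC baselines are textbook reconstructions (the source
  figures cite no equations); their absolute RMSE values are indicative
  only, though the chattering contrast is structural.
* The delay is assumed known to the controller (it reads its own delayed
  measurements); online delay estimation is not implemented.
* Gains are tuned for the shipped plant at $dt = 10^{-3}$ ms; re-tuning is
  expected after substantial plant edits, and the closed-loop adaptive laws
  are not stable at the coarse $10^{-2}$ ms test step.
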