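---
title: "Reverse engineering chemotaxis controllers: models, filters and the run-and-tumble simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse engineering chemotaxis controllers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactaxis)
```

## The control problem

A swimming *E. coli* cell alternates between straight **runs**
(counter-clockwise flagellar rotation) and reorienting **tumbles**
(clockwise rotation). The only actuator the chemotaxis pathway has is the
phosphorylation level of CheY: CheY-P binds the motor and raises the
clockwise (tumble) bias. Seen through control theory, the pathway is a
controller that maps receptor occupancy

$$u = \frac{[L]}{[L] + K_L}$$

to [CheY-P], and the motor plus cell kinematics are a discrete, stochastic
plant that cannot itself be written as a transfer function. `bactaxis`
implements this picture end to end: pathway ODE models and their
linearization into transfer functions $H(s)$, canonical controller filters,
a Hill-type motor with a two-state Markov chain, static 2-D ligand fields,
and an agent-based population simulator that evaluates any controller by the
**chemotactic effect** — the population mean of each agent's local ligand
concentration averaged over the last 50 s of a 1000 s run.

## Controller filters

Two canonical controllers cover the two pathway classes found in nature:

* **Low-pass (non-adaptive)**: $H(s) = A\,\omega_0/(s + \omega_0)$.
  Steady-state CheY-P tracks the occupancy level; the cell is sensitive to
  slow changes but its motility depends on where it sits in the field.
* **Band-pass (adaptive), rank 2**:
  $H(s) = K s / ((s+\omega_1)(s+\omega_2))$ with $K = A(\omega_1+\omega_2)$,
  and a rank-4 variant $K_4 s^2/((s+\omega_1)^2(s+\omega_2)^2)$ with
  $K_4 = A(\omega_1+\omega_2)^2$. The differentiator numerator makes
  $H(0)=0$: constant stimuli produce no steady response, which is exactly
  perfect adaptation, and the sign of the output reports whether occupancy
  is rising or falling along the current run.

The gains are normalised so that the *peak* Bode magnitude equals $A$
exactly (the maximum of $|H(i\omega)|$ sits at $\omega=\sqrt{\omega_1\omega_2}$),
so "max amplification" is literally the peak of the Bode plot. Parameters
and defaults:

| parameter | meaning | default | units |
|---|---|---|---|
| $A$ | peak amplification (CheY-P deviation per unit occupancy) | 16 | µM |
| $\omega_1$ | down cut-off: adaptation rate, sets the "memory" $\sim 1/\omega_1$ | 0.02 | s⁻¹ |
| $\omega_2$ | up cut-off: response rate | 5 | s⁻¹ |
| baseline | CheY-P with no stimulus (20 % CW bias) | 2.71 | µM |
| $K_L$ | receptor half-saturation | 1 | µM |

All frequencies in the package are angular (s⁻¹); the slow cut-off is
sometimes quoted in Hz in the chemotaxis literature with the same numeric
value, and we do not attempt to reconcile that unit looseness — every
$\omega$ here is in radians per second.

With the attractant sign convention the controller output is *subtracted*
from the baseline: rising occupancy lowers CheY-P and extends runs. CheY-P
is clipped below at 0 µM; large excursions on either side land in the
motor's saturated or dead zone anyway, which is why a linear controller
between occupancy and CheY-P is an acceptable approximation even when the
deviations are not small.

Step responses are computed by **exact zero-order-hold discretization** of
the controllable-canonical realization (`Matrix::expm` of the augmented
$[A\,B;0\,0]$ block): for piecewise-constant input the discrete update
reproduces the continuous-time response at every sample with no integration
error, which the tests verify at $10^{-10}$ against the closed-form
double-exponential. Timing of a step response is summarised by the
**response time** $\tau_2$ (stimulus to half-peak on the rise) and the
**adaptation time** $\tau_1$ (stimulus to half-peak on the decay), both
located by linear interpolation between samples. The half-rise convention
for $\tau_2$ is a package choice; conventions based on $1/e$ or on the peak
time would shift $\tau_2$ by tens of percent, which is why downstream
comparisons treat it with a wide band. For the reference band-pass filter
($A=16$, $\omega_1=0.02$, $\omega_2=5$):

```{r timing}
traj <- step_response(controller_filter("band_pass", A = 16, omega1 = 0.02,
                                        omega2 = 5),
                      step = -0.1, T = 400, dt = 0.005)
timing_summary(traj)
```

## The designed three-molecule pathway

The minimal biochemical realization of a band-pass controller needs no
feedback loop. In the positive wiring, occupied receptor $u$ drives two
arms that converge on CheY: a fast arm (direct dephosphorylation of CheY-P
by $u$) and a slow arm (production of an intermediate $v$ that
phosphorylates CheY):

$$\dot v = c_v u - d_v v, \qquad
  \dot y = k_{\mathrm{phos}}\, v\,(Y_T - y) - k_{\mathrm{dephos}}\, u\, y.$$

At steady state $v^* = c_v u / d_v$, so the phosphorylation and
dephosphorylation fluxes are both proportional to $u$ and the equilibrium

$$y^* = \frac{Y_T\, k_{\mathrm{phos}} c_v / d_v}
             {k_{\mathrm{phos}} c_v / d_v + k_{\mathrm{dephos}}}$$

is independent of the input — an "asymmetric clamp" whose two low-pass arms
cancel at DC. This is *robust* perfect adaptation: it survives any change
of the rate constants, because the cancellation is structural, not tuned.
Equivalently, the linearization

$$H(s) = \frac{-k_{\mathrm{dephos}}\, y^*\, s}
             {(s + d_v)(s + k_{\mathrm{phos}} v^* + k_{\mathrm{dephos}} u^*)}$$

has $H(0) = 0$, with down cut-off $d_v$ and up cut-off
$k_{\mathrm{phos}} v^* + k_{\mathrm{dephos}} u^*$. Swapping which arm
phosphorylates gives the repellent (negative) wiring; replacing the fast
arm by a constant autophosphorylation $k_{\mathrm{auto}}(Y_T - y)$ gives
the non-adaptive pseudo variant, a low-pass controller.

The printed literature this design descends from does not fix a complete
rate table, so the package defaults are calibrated to the stated targets:
$d_v = 0.02\ \mathrm{s^{-1}}$ (the optimal memory), $y^* = 2.71$ µM, and an
up cut-off of $5\ \mathrm{s^{-1}}$ at the reference occupancy $u^* = 0.5$,
with $Y_T = 6$ µM and $K_L = 1$ µM. The free choice $c_v = 0.1$ µM/s then
fixes $k_{\mathrm{phos}} = 27.1/30$ and $k_{\mathrm{dephos}} = 32.9/6$;
$k_{\mathrm{auto}} = 1.86\ \mathrm{s^{-1}}$ places the pseudo variant's
CheY-P near the same baseline at $u = 0.5$. The resulting peak gain of the
designed pathway is only $\approx 3$, which is why its chemotactic effect
is real but weaker than the $A = 16$ abstract filter.

```{r design}
pos <- designed_pathway("positive")
tf <- transfer_function(linearize_model(as_pathway_model(pos), 0.5))
tf
classify_filter(tf)
tf_dcgain(tf)
```

The general workhorse behind systematic design is the universal
activation/deactivation network: $n$ molecules with totals $y_{it}$, where
active molecule $j$ activates/deactivates molecule $i$ at rates
$C_{ij}/D_{ij}$, plus receptor-driven and self rates. One structural
caveat is worth knowing: receptor-driven activation enters as
$(y_{it}-y_i) C_i u$, so the designed pathway's *linear* production
$c_v u$ corresponds to the large-pool limit
$y_{1t} \to \infty,\ y_{1t} C_1 = c_v$. The tests exercise that embedding
at $y_{1t} = 10^{14}$, where the two right-hand sides agree to $10^{-12}$.
Saturating production ($y_{1t}$ finite) would break the exact flux
proportionality and hence the perfect adaptation, which is precisely why
the designed model keeps it linear.

## Linearization machinery and numerical choices

`find_equilibrium()` uses damped Newton iteration (step halving on the
residual norm, at most 100 iterations, tolerance
$\lVert F \rVert \le 10^{-10}(1+\lVert x\rVert)$). Jacobians are central
finite differences with steps relative $10^{-6}$ to each variable's scale;
for the designed pathways the analytic Jacobians serve as test oracles.
`transfer_function()` expands $H(s) = C(sI-A)^{-1}B + D$ through the
determinant identity
$\det(sI-A+BC) = \det(sI-A)\,(1 + C(sI-A)^{-1}B)$, using characteristic
polynomials, so no symbolic algebra is required. Filter classification
calls $H$ band-pass when $|H(0)| \le 10^{-9}$ of the peak gain with a
decaying high-frequency tail, and low-pass when the peak sits at DC (within
$10^{-6}$ relative) and the magnitude is non-increasing; a pure gain is
"other". Bode tables default to 200 log-spaced points on
$[10^{-4}, 10^3]\ \mathrm{s^{-1}}$ with unwrapped phase in degrees.

## The motor

The motor state is held constant over 0.5 s intervals. The stationary CW
bias is a Hill function of CheY-P with half-point $K_{1/2} = 3.1$ µM and
coefficient $h = 10.3$ (the classic single-motor dose-response
calibration); this places the 2.71 µM baseline at a 20.0 % CW bias, runs
essentially certain below ~2.3 µM (dead zone) and tumbles essentially
certain above ~4 µM (saturation). The chain is memoryless per interval —
the next state is a Bernoulli draw with $p = \mathrm{bias}$ — which is the
simplest chain with the correct stationary law given that state persistence
is already expressed by the 0.5 s interval itself. An optional
`persistence` parameter scales both transition probabilities equally,
lengthening runs and tumbles without changing the stationary bias.

## The population simulator and what it does (not) emulate

`simulate_swarm()` advances all agents in lock step at
$\Delta t = 0.5\ \mathrm{s}$. Per interval each agent (1) runs
$0.02\ \mathrm{mm/s} \times \Delta t$ along its heading, or reorients in
place if tumbling; (2) reads the ligand at its new position (the input is
piecewise constant at the motor time scale); (3) advances its controller —
exact zero-order-hold for LTI filters, classical Runge–Kutta with 10
substeps for the nonlinear pathways (integration error far below the motor
stochasticity) — giving the CheY-P at the end of the interval; (4) draws
the next motor state from that CheY-P. Computing CheY-P *after* the
interval's displacement matters: sampling the field before moving would add
a spurious half-second of sensory latency, which measurably degrades
chemotaxis at these run speeds. All agents start at the configured point
with uniform random headings, controller states at equilibrium for the
local input, and motor states drawn from the baseline bias. Every random
draw flows from the single configuration seed, so records are bit-identical
across repeated runs.

Default study conditions: mountain field
$L = L_0 e^{-(x/r)^2}$ with $L_0 = 2$ µM, $r = 2$ mm; start at
$(1.4, 0)$ mm (local $L = 1.2253$ µM, occupancy 0.551); 1000 s duration;
1000 agents for population portraits and 100 agents per cell for parameter
scans (3 seed replicates with common random numbers, reported as the mean).

Features of real chemotaxis deliberately not emulated: rotational Brownian
drift during runs, the measured tumble-angle distribution (the default
reorientation is uniform on $[0, 2\pi)$; a wrapped-normal deflection is
configurable, and in our checks a persistent deflection with
$\mathbb{E}[\cos\Delta] \approx 0.33$ changes the headline statistics by
less than 0.01 µM), tumble durations shorter than the 0.5 s interval,
CheY-P shot noise, multi-motor voting, cell–cell interactions and ligand
consumption. Passing tests therefore validate the control-theoretic
comparisons between controllers under a common, simplified plant — not a
quantitative prediction of any single cell's trajectory.

For non-adaptive (low-pass) controllers the input is the occupancy
*deviation from the start position's occupancy*, where the controller is at
rest. Some reference is unavoidable for a controller with $H(0) \ne 0$;
anchoring it at the initial position reproduces the characteristic
low-pass phenomenology (hyperactive cells at high ligand that overshoot the
crest, trapped tumbling cells at low ligand). For adaptive controllers the
reference is immaterial because $H(0) = 0$.

## Known limitations

* The chemotactic-effect landscape is nearly flat between
  $\omega_1 = 0.02$ and $0.05\ \mathrm{s^{-1}}$ under the default plant:
  at 100 agents and 3 seed replicates the two cells differ by less than
  their standard errors, so the location of the scan argmax between those
  two values is not reproducible at that replication level (the $\omega_2$
  structure — rising to $5\ \mathrm{s^{-1}}$, then a plateau — is robust).
* $\tau_1$ and $\tau_2$ are measured from the stimulus time; for band-pass
  filters with a slow up cut-off the peak time itself contributes
  noticeably to $\tau_1$, so $\tau_1$ is only approximately a function of
  $\omega_1$ alone (within ~15 % across $\omega_2 \in [1, 100]$).
* The designed pathways are simulated on their deterministic rate
  equations; stochastic chemical kinetics at low copy number are out of
  scope, as are time-evolving fields and 3-D swimming.
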