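---
title: "Modelling and optimally steering collective electrotaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimally steering collective electrotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltaxis)
```

## The model

Epithelial monolayers migrate along an applied DC electric field
(electrotaxis), but the response is transient: under a constant field the
collective speeds up within the first hour and then slows down again even
though the field never changes. `voltaxis` models the bulk velocity $v$ of
the monolayer centre (the spatial average over the central tissue region,
away from edge effects) with a three-variable linear excitation–adaptation
system driven by the normalized field strength $s(t)$ (1 unit $\equiv$
3 V/cm):

$$
\dot v = -\gamma v + \alpha\,\max(s_{\rm eff}, 0), \qquad
\dot s_{\rm eff} = \frac{s - (s_{\rm eff} + I)}{\tau_e}, \qquad
\dot I = \frac{s - I}{\tau_a},
$$

from rest, $v(0)=s_{\rm eff}(0)=I(0)=0$. The *effective signal*
$s_{\rm eff}$ is the transduced internal representation of the field that
drives active force production; the *inhibitor* $I$ is the slow pathway
that adapts the cell to a sustained stimulus. With
$\tau_e \ll \tau_a$ a step input produces the characteristic
excite-then-adapt response

$$
s_{\rm eff}(t) = \frac{\tau_a}{\tau_a - \tau_e}
  \left(e^{-t/\tau_a} - e^{-t/\tau_e}\right), \qquad
I(t) = 1 - e^{-t/\tau_a},
$$

which is nonnegative, peaks at
$\tau_{\max} = (\log\tau_a - \log\tau_e)/(\tau_e^{-1}-\tau_a^{-1})$
(`tau_max()`), and wanes to zero: the only steady state under constant
stimulation is $(v,s_{\rm eff},I)=(0,0,s)$, stable with eigenvalues
$\{-\gamma,-\tau_e^{-1},-\tau_a^{-1}\}$, so sustained speed cannot be
obtained from a sustained field. The clamp $\max(s_{\rm eff},0)$ encodes
that monolayers are not observed to reverse when the field is switched off
and the raw linear system would briefly drive $s_{\rm eff}$ negative.

Parameters, with the calibrated defaults exposed as `calibrated_params()`:

| parameter | meaning | units | default |
|---|---|---|---|
| $\gamma$ | friction / velocity decay rate | 1/h | 1.765 |
| $\alpha$ | force responsiveness | µm/h² | 149.92 |
| $\tau_e$ | excitation timescale | h | 0.260 |
| $\tau_a$ | adaptation timescale | h | 2.038 |

All field strengths are normalized internally (1 = 3 V/cm); conversion
happens only at I/O boundaries (`field_to_physical()`).

## Numerical choices

The system is linear and non-stiff at realistic parameters; `simulate_model()`
uses an adaptive-step integrator at relative tolerance $10^{-8}$ and
absolute tolerance $10^{-10}$, so quadratures of the solution are
grid-independent at the accuracy the package reports. Two closed-form paths
bypass the integrator where exactness and speed matter: the step response
above (tested against the integrator at $10^{-6}$ sup-norm), and a
piecewise exponential-sum solution for single-pulse protocols, including
the clamped coasting phase after switch-off whose onset (the zero crossing
of $s_{\rm eff}$) is located analytically. The pulse path makes a full
likelihood evaluation cost microseconds, which is what keeps the MCMC
budget (4 chains × 20 000 iterations) in seconds. Near-degenerate
exponential rates ($|\gamma - 1/\tau|<10^{-8}$) switch to a series limit;
exactly resonant adjoint rates raise an error rather than silently losing
precision.

## Calibration

Calibration is staged the way the experiment dictates:

1. **Friction from free decay.** After switch-off the model coasts,
   $v(t) = C e^{-\gamma (t-t_{\rm end})}$ with $C = v(t_{\rm end})$ pinned
   to the observed switch-off sample. `fit_gamma_decay()` does the
   one-dimensional least-squares fit over a 2.5 h window. On pure-decay
   data the estimator is exact without noise and unbiased to well under 2%
   at σ = 2 µm/h (Monte-Carlo property in the test suite). Fitting γ from
   the tail of a *pulse* trace instead is biased low, because the force
   term keeps pushing for the few minutes until $s_{\rm eff}$ crosses zero
   while $C$ is pinned to a noisy sample; γ should come from a dedicated
   decay experiment, and `run_mcmc()` therefore takes it as a fixed input.

2. **Remaining parameters by MCMC.** `run_mcmc()` samples
   $(\alpha, \tau_e, \tau_a, \sigma)$ under an iid Gaussian observation
   model with an adaptive-covariance random-walk Metropolis sampler
   (Haario–Bardenet flavour: running-covariance proposal with a global
   scale adapted towards 23.4% acceptance). Priors are independent
   uniforms — $\alpha \in [0,1000]$ µm/h², $\tau_e \in [0.01,2]$ h,
   $\tau_a \in [0.1,20]$ h, $\sigma \in [0.1,50]$ µm/h — restricted to
   $\tau_e < \tau_a$; they are deliberately wide and carry no information
   beyond positivity, ordering and physical plausibility. Chains start
   from a multi-start maximum-likelihood point with 5% multiplicative
   jitter, which buys convergence well inside the iteration cap; the first
   half of each chain is discarded. Convergence is summarised by the
   classic Gelman–Rubin $\hat R$ (between/within-chain variance ratio;
   threshold 1.05, split variant available); note a run can only be
   declared converged, never proven — with common-region starts $\hat R$
   is a mixing diagnostic more than a multi-modality probe. Observation
   noise σ is a sampled nuisance parameter rather than a plug-in.

## What the synthetic generator does and does not emulate

`generate_trace()` produces the data the calibration assumes: the model
solution under a protocol (default: 3 h pulse at 3 V/cm plus a 2.5 h
field-off tail), sampled every 10 min like the imaging pipeline, with iid
Gaussian noise (default σ = 3 µm/h, chosen so that recovery is nontrivial
but typically reliable at this cadence). `generate_decay_trace()` is the
pure-exponential analogue for the friction fit. Real bulk-velocity traces
differ in ways the generator deliberately ignores: noise is averaged over
many PIV windows and tissues (so replicate-to-replicate variability and
temporal autocorrelation exist), and the tissue is not a perfect
excitation–adaptation device. Passing recovery tests on synthetic data
therefore demonstrates the *estimator* is correct and calibrated, not that
the model is true.

Under these study conditions the posterior is informative but carries a
genuine soft ridge: α trades off against $\tau_a$ (and $\tau_e$), since a
10-min cadence barely resolves a 15.6-min excitation timescale. Across
noise realizations the posterior means scatter with standard deviation of
roughly 10% for α, 15% for $\tau_a$ and 20% for $\tau_e$, and single
realizations can sit 2σ out while fitting their own data better than the
generating values do. That is a property of the design (one trace, 34
samples, σ = 3), not of the sampler.

## The control problems

All five problems steer the same linear model; they differ in objective
and constraint, and the package solves each with the technique its
structure rewards.

**Isoperimetric problems** (`solve_max_distance()`,
`solve_max_terminal_velocity()`): maximise total distance
$\int_0^T v\,dt$ or terminal velocity $v(T)$ subject to the charge budget
$\int_0^T s^2 dt = s_{\rm budget}$ (default 3 normalized = 27 V²h/cm²,
what a constant 3 V/cm pulse spends in $T=3$ h). The Hamiltonian is
quadratic in $s$ through the budget multiplier, and Pontryagin's principle
gives $s^\ast = \psi/(2\mu^\ast)$ with switching function
$\psi = \tau_e^{-1}\lambda_{s_{\rm eff}} + \tau_a^{-1}\lambda_I$. The
adjoints solve a constant-coefficient linear system backwards from zero
terminal conditions; the package derives them *from the adjoint ODEs* in
closed form as exponential sums (the forms one finds quoted for such
systems are prone to sign slips, so the test suite checks every closed
form against independent backward integration at $10^{-6}$), and
normalises by the budget in closed form,
$\mu^\ast = \tfrac12\sqrt{\smallint\psi^2 dt / s_{\rm budget}}$, taking
the positive root so the stationary point is the maximiser. Two structural
facts are worth internalising: $\psi(t)$ *is* the sensitivity kernel of
the objective to the field (the package verifies
$\smallint \psi\,dt$ = constant-field distance, and a finite-difference
oracle confirms first-order optimality on the budget sphere), and the
terminal-velocity kernel vanishes at $t=T$ — field applied in the last
instants cannot propagate through the $\tau_e$ transduction lag into
velocity — so the optimal ramp returns to zero at the horizon. The
adjoints are derived for the *unclamped* system; each solution is
post-checked for $s_{\rm eff} \ge 0$ and a feasibility flag records
violations (the max-distance optimum does undershoot briefly near $T$,
where the physical clamp slightly *helps* the objective).

**Cruise problems** (`solve_cruise_bvp()`, `solve_cruise_window()`): hold
the velocity at a target $v^\ast$, globally (with terminal constraint
$v(T)=v^\ast$) or inside a window $[t_1, T-t_1]$ weighted by the smooth
bump `bump()` with transition scale ε (default 1/50 h). Here the
Hamiltonian is *linear* in the unbounded control, and the tracking
functional $\int \Phi\,(v-v^\ast)^2 dt$ does not penalise the field at
all, so the continuum problem is ill-posed in an instructive way: the
infimum concentrates an impulsive field at the onset (the velocity is
asked to appear instantly), and any mesh-based solver returns a spike
whose height grows as the inverse square of its time resolution — a
numerical artifact wearing the costume of a prediction. The package makes
the regularisation explicit and physical instead: the control is
piecewise-linear on knots at the 10-min acquisition cadence for the
global cruise problem (the timescale on which the stimulation hardware is
programmed; `knot_dt` exposes it) and at the bump scale ε for the
windowed problem (so the objective weight is resolved), the linear
dynamics are discretised *exactly* via augmented matrix exponentials
(Van Loan blocks), and the resulting convex quadratic problem is solved
through its KKT system, with a numerically negligible Tikhonov term
(`penalty`) selecting the minimum-field solution among ties. Reported
adjoints are recovered by backward integration of the tracking costate
system and satisfy the transversality conditions
($\lambda_{s_{\rm eff}}(T)=\lambda_I(T)=0$; $\lambda_v(T)$ is the
terminal-constraint multiplier in the constrained problem and zero in the
windowed one). The headline qualitative results are mesh-independent even
though the peak height is not: the cruise field must be enormous at onset
relative to anything tolerable in vitro (tens of V/cm at the 10-min
cadence against a ~9 V/cm tolerability ceiling, growing without bound at
finer cadences); capping the field (`s_max`, applied as
$\min(s^\ast, s_{\max})$ with the state re-simulated) trades a terminal
velocity error that decreases monotonically as the cap rises; and the
windowed problem switches regime exactly at $\tau_{\max}$ — waiting
times $t_1 > \tau_{\max}$ allow a gentle ramp with near-zero initial
field and no overshoot, $t_1 < \tau_{\max}$ force a large initial field
and an overshoot before the plateau — with peak field exactly linear in
$v^\ast$ (the whole pipeline is linear-quadratic).

**Bang-bang** (`bang_bang_policy()`): replacing the budget by a bound
$0 \le s \le s_{\max}$ makes the Hamiltonian linear in $s$ with
coefficient $\psi$, so the optimum takes extreme values: $s^\ast =
s_{\max}$ where $\psi > 0$. At the calibrated parameters $\psi > 0$ on
all of $[0,T)$ — the plain constant pulse, the protocol experimentalists
converged on by iteration, is the bang-bang optimum. A random-search
oracle over bounded piecewise-constant protocols backs this up in the
test suite.

## Design decisions that were genuinely open

* **Cruise functional.** "Keep the velocity constant" admits both a
  squared-acceleration reading $\int \dot v^2 dt$ and a tracking reading
  $\int (v - v^\ast)^2 dt$. They are not the same problem: with only the
  terminal velocity pinned, minimising $\int \dot v^2$ is solved by the
  straight ramp $v = v^\ast t/T$ (constant acceleration, peak field a few
  V/cm, no plateau), which is not cruise behaviour at all. The package
  implements the tracking functional for both cruise kinds — it is the
  one whose optimum actually holds the velocity — and treats the global
  problem as the windowed problem with $\Phi \equiv 1$ plus a terminal
  constraint.
* **Control parameterisation as regularisation.** Because the continuum
  cruise problem has no optimum, *some* regularisation is unavoidable;
  the package uses the control cadence, states it, and exposes it, rather
  than letting a solver mesh choose silently. Peak-field numbers from any
  cruise solver are only meaningful together with that cadence.
* **γ fixed, not sampled.** Estimating γ separately from decay data and
  conditioning on it reduces the MCMC dimension and mirrors the staged
  experimental design; the cost is that γ's uncertainty is not propagated
  into the posterior (it is small: the decay fit has percent-level noise
  at realistic σ).
* **Reporting grid.** Control solutions are reported on 301 uniform
  points over the horizon, dense enough that trapezoid quadratures of
  smooth solutions are accurate to ~$10^{-5}$ relative; budget integrals
  are checked with spline quadrature at $10^{-6}$ relative tolerance.

## Known limitations

Uniaxial fields only; no spatial structure, edge dynamics, or
tissue-to-tissue variability; iid Gaussian noise; the cruise peak field is
cadence-relative by construction; and the calibration posterior's soft
ridge means single-trace posterior means should be quoted with their
credible intervals, not alone.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full study conditions:
4 × 20 000 MCMC iterations on a 34-sample trace (seconds, thanks to the
closed-form pulse likelihood), 200 Monte-Carlo replicates of the decay
fit, 301-point reporting grids, 60-point finite-difference oracles, and
100 random protocols for the bang-bang search oracle.
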