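---
title: "Methods: adaptive trapezoidal solution and dynamic sensitivities of DDE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive trapezoidal solution and dynamic sensitivities of DDE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddesens)
```

# The problem

Many models of gene expression, signal transduction and physiological control
involve explicit time delays and are written as delay differential equations
(DDEs) with fixed discrete delays,

$$\frac{dx}{dt} = f\bigl(x(t),\, x(t-\tau_1), \dots, x(t-\tau_r);\,\theta\bigr),
\qquad x(t) = x(0) \ \text{for } t \le 0,$$

with states $x \in \mathbb{R}^n$, parameters $\theta \in \mathbb{R}^p$, and
positive delays $\tau_i$.  Local (first-order) *dynamic sensitivities*
$s(x_i, \theta_j)(t) = \partial x_i(t;\theta)/\partial\theta_j$ quantify how
strongly each parameter and each initial condition shapes each trajectory,
and their time-averaged magnitudes rank the parameters that control the
system.  Computing them by the direct method requires the Jacobians of $f$
at every step — tedious and error-prone to derive by hand for models with
Hill terms, products and trigonometric forcing.  This package removes that
step: models are supplied as plain-text equations at run time, and all
Jacobians are evaluated by forward-mode automatic differentiation (AD),
exactly to round-off.

# State propagation

Within each sampling interval $[t_{i-1}, t_i]$ the state is advanced by the
implicit trapezoidal (collocation) rule

$$x(t_j) = x(t_{j-1}) + \tfrac{1}{2}\eta_j\,
\bigl\{ f(x(t_j), y(t_j);\theta) + f(x(t_{j-1}), y(t_{j-1});\theta) \bigr\},$$

where $y_k(t) = x_{j_k}(t - \tau_k)$ are the delayed terms.  The implicit
equation is solved by fixed-point iteration from an explicit Euler
predictor; "converged" means every component update satisfies the mixed
tolerance $|\Delta x_i| \le \mathrm{atol} + \mathrm{rtol}\,|x_i|$ (defaults
$10^{-12}$ and $10^{-8}$; the mixed form is scale-free for states spanning
$\sim 100$ mmHg down to small concentrations).  If the update has not
converged within `iteration_limit` corrector sweeps (default 20 — a choice;
the fixed-point map contracts fast whenever the step-size control below has
accepted the step, so the limit only triggers on genuinely non-contractive
steps) the run aborts with a classed non-convergence error rather than
silently continuing.

Delayed values are looked up in an append-only history of accepted nodes
with linear interpolation between the two bracketing nodes; for $t \le t_0$
the constant initial history $x_0$ is returned.  When a lookup lands
exactly on a node the stored value is returned, which breaks floating-point
ties deterministically.  Bracketing is found by binary search; nodes are
never pruned within a run (runs are short; simplicity over memory).

## Step-size control and stiffness

Before each step the Jacobian $A = [\partial f/\partial x,\ \partial
f/\partial y]$ is evaluated by AD at the step start and the bound

$$\mu = n\,(m+n)\,\max_{i,j} |a_{ij}| \;\ge\; \lVert A \rVert_2$$

is formed over the state and delayed-state columns only (the parameter
Jacobian plays no role in step control).  Three branches follow:

* $\mu\,\varepsilon \ge 1$: the system is declared stiff for the requested
  tolerance $\varepsilon$ (default $10^{-3}$) and the run aborts with a
  stiffness error — this solver is deliberately not an implicit-Newton
  stiff solver.
* $\mu\,\eta > 1$: the step is clipped to $\eta = 0.9/\mu$, keeping the
  trapezoidal fixed-point iteration contractive.
* When delays are present, $\eta$ is additionally capped at the smallest
  delay, the standard method-of-steps constraint: it guarantees that the
  delayed lookup at the step's right endpoint never runs ahead of accepted
  history.

Each sampling interval starts with $\eta$ equal to the interval width and
re-clips after every accepted substep; the final substep is exactly the
remaining width, so sampling points are hit exactly and outputs never
interpolate.

# Forward-mode automatic differentiation

Equations are parsed into expression graphs over five operators
(`+ - * / ^`), unary minus, and eight intrinsics (`sin, cos, tan, exp, log,
sqrt, abs, tanh`).  The intrinsic set is a design choice wide enough for
both kinetic rate laws and trigonometric forcing; extending it means adding
one value rule and one derivative rule to the tape evaluator.  Delayed
references use the explicit label syntax `x2@d1` so the grammar stays
context-free and multiple delays are unambiguous; the model file maps
labels to durations.

Each graph is flattened once into a topologically ordered tape.  A single
bottom-up pass evaluates values, and the same pass optionally carries a
gradient vector per node, combining child gradients by the chain rule of
the elementary operation — forward-mode AD, exact up to round-off.  One
pass per equation system yields $f$, $A = \partial f/\partial x$,
$B = \partial f/\partial y$ and $C = \partial f/\partial\theta$
simultaneously, which is also what the evaluation counter counts.

Numerical edge cases are resolved as follows: `u^v` with constant
integer-valued `v` uses the power rule, valid for any sign of `u` (a Hill
exponent of 8 must survive transiently negative bases); non-integer `v`
with `u <= 0`, division by zero, `log` of a non-positive value and `sqrt`
of a negative value raise classed domain errors naming the offending
subexpression; `abs` at zero uses subgradient 0 with a warning.  Constant
folding is not performed, so the value channel is identical whether or not
gradients are requested.

# Sensitivity propagation (direct-decoupled)

Differentiating the model through $\theta$ gives the linear delayed
variational system

$$\dot\Phi(t) = A(t)\,\Phi(t) + B(t)\,\Phi(t-\tau) + [\,C(t)\mid 0\,],$$

for the $n \times q$ matrix $\Phi$ with $q = p + n$ columns: parameters
first, then initial conditions, initialized to $[\,0 \mid I\,]$.  The
initial-condition block of the forcing is zero because $f$ has no explicit
$x_0$ dependence; sensitivities w.r.t. a delay *duration* are out of scope
(they are supported only when the duration also appears algebraically as a
parameter, as in the cardiovascular model below, because the variational
system contains no $\dot x(t-\tau)$ term).

The method is *direct-decoupled*: at each accepted step the state is
advanced first, then $\Phi$ is advanced over the same $\eta$ by the same
trapezoidal corrector.  Step control uses $A$ and $B$ only, so the state
trajectory is bit-identical whether or not sensitivities are propagated.
Left-endpoint Jacobians are computed once per step (shared with step
control); right-endpoint Jacobians are computed once after the state step
and reused across corrector sweeps.  Delayed sensitivity rows are
interpolated linearly from stored nodes — the same interpolation order as
the state, chosen for consistency — and any lookup at or before $t_0$
returns $\Phi_0$, applied per lookup time so intervals straddling
$t_0+\tau$ are handled correctly.

One deliberate refinement: the fixed-point map decouples over the columns
of $\Phi$, so each column is iterated until its own entries meet the mixed
tolerance and is then frozen.  This realizes the entrywise convergence
criterion and keeps the initial-condition columns in exact arithmetic
lockstep with the state corrector (their recursion *is* the state's
variational recursion), so the discrete identity
$s(x, x_0) \equiv x(t)/x_0$ for linear problems holds to machine precision
rather than drifting with iteration-count mismatches.

# Sensitivity measures and ranking

From absolute sensitivities the package derives the dimensionless relative
form $S = (\theta_j/x_i)\,s$, the semi-relative form $\tilde S =
\theta_j\,s$ (the remedy when a state passes through zero; the relative
conversion refuses such states unless overridden), and the time-averaged
magnitude

$$\bar S_{ij} = \frac{1}{t_f}\int_0^{t_f} |S(x_i,\theta_j)|\,dt,$$

computed by trapezoidal quadrature on the sampling grid (the grid is
user-controlled, hence so is quadrature accuracy).  The averaging window
defaults to the full run — no burn-in is discarded — but an optional window
exists precisely because time-averaged rankings of oscillatory systems can
depend strongly on the horizon (see limitations).  Ranking tables hold one
row per column with percentages taken against the total over *all* $q$
columns (printed subsets therefore need not reach 100%), ties broken by
declaration order; stacked fractions renormalize each state's column to 1
for 100%-stacked-column charts.

# The cardiovascular fixture

The shipped worked model is a two-state baroreflex model of heart rate
$x_1$ and arterial pressure $x_2$ in dimensionless time (real time divided
by the sympathetic delay $\tau$, so the discrete delay is 1): delayed
sympathetic drive enters through a Hill function $g_1$ of
$x_2(t-1)/p_0$ (exponent $n = 8$), instantaneous vagal feedback through
$g_2$ of $x_2(t)/p_0$, a small sinusoid of amplitude $A_2$ mimics
respiration, and the pressure equation balances cardiac input
$\mu p_0 x_1 / (\varepsilon_p h_0)$ against a Windkessel-type decay
$x_2 / \bigl(\varepsilon_p (1+\alpha g_1)\bigr)$ whose rate is slowed by
the sympathetically controlled peripheral resistance $1+\alpha g_1$ — with
this structure the nominal parameter set places the equilibrium at a
physiological $x_1 \approx 65$ bpm, $x_2 \approx 100$ mmHg.  Because time
is dimensionless, $\tau$ and the breathing rate $f_r$ enter the equations
only through their product in the respiration phase, which forces the
structural identity $S(x_i, f_r) \equiv S(x_i, \tau)$ — a sharp test of
the whole pipeline.  The parameter $\mu$ is stored at its tabulated value
0.18 even though it is nominally $3/(2+\alpha) = 3/17 \approx 0.176$;
a fixture test checks the two-decimal consistency but the printed value is
used.

Two quantities are assumptions, not published values, and are flagged in
the fixture notes: the initial conditions ($x_1(0) = h_0 = 100$,
$x_2(0) = p_0 = 100$) and the simulation horizon ($t^* \in [0, 200]$,
sampling step 0.02).  Under these conditions the model sustains a
large-amplitude heart-rate oscillation (the package's trajectory agrees
with an independent `deSolve::dede` solution to within 0.06 absolute over
the full horizon), and time-averaged sensitivities of an oscillatory
system grow with the horizon for every parameter that shifts the
oscillation frequency.  Ranking tables for this fixture should therefore
be read with the window sensitivity in mind; the optional averaging window
of `rank_table()` exists to explore exactly this.

# Oracles, fixtures and what passing tests show

* **Closed-form DDE**: $\dot x = -\theta x(t-\tau)$ with constant history
  has the method-of-steps piecewise polynomial attached; the solver is
  exact on its first two segments (piecewise-linear right-hand side) and
  second-order beyond, which the convergence-order test measures.
* **Independent integrator**: `reference_trajectory()` wraps
  `deSolve::dede` (lsoda with its own history interpolation) — a fully
  independent implementation used for cross-checks and as the solver under
  finite differences; the trapezoidal solver is never validated against
  itself.
* **Finite differences**: `finite_difference_sensitivities()` implements
  the forward-difference approximation with relative spacing; it is a
  *biased* oracle (bias linear in the spacing) whose disagreement with the
  AD-propagated sensitivities must shrink as the spacing ratio decreases —
  the tests assert that direction as well as closeness.  Near zeros of an
  oscillating sensitivity the pointwise *relative* deviation of a forward
  difference is unbounded even for an exact solver, so strict pointwise
  relative bounds are meaningful only away from crossings.
* **Expression fuzzing**: `random_expression_generator()` draws random
  graphs over the full operator set with bindings rejected until every
  intermediate value stays clear of domain boundaries (log/sqrt arguments
  and |denominators| at least 0.1, bounded magnitudes), then AD is checked
  against central differences.

The synthetic problems emulate smooth, well-scaled kinetic systems with
constant history.  They do not emulate state-dependent or distributed
delays, non-constant initial history, discontinuous forcing, or stiffness
(the solver aborts on stiffness by design), so green tests say nothing
about those regimes.

Problem sizes used by the default test run are the package's own choices:
grids of step 0.01 on the analytic problems, horizons of 10–30
dimensionless units for the cardiovascular structural checks and
finite-difference comparisons (about five oscillation periods), and the
full $[0, 200]$ horizon for the ranking reproduction and the acceptance
script.

# Known limitations

* No discontinuity tracking: derivative kinks at $t_0 + k\tau$ are not
  stepped on exactly (beyond what the delay cap provides), so sparse
  sampling grids whose adaptive steps straddle a kink lose accuracy there;
  dense or kink-aligned grids recover second order.
* Failed steps abort (stiffness, non-convergence) rather than retrying
  with a smaller step; the error carries the last accepted time.
* Adjoint/backward sensitivities, second-order sensitivities and
  sensitivities w.r.t. the delay argument of the history lookup are out of
  scope.
* Time-averaged rankings of systems on oscillatory attractors depend on
  the averaging horizon (secular sensitivity growth); compare windows
  before trusting a ranking.
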