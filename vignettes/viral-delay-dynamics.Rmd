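---
title: "Delayed viral dynamics with CTL and antibody responses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed viral dynamics with CTL and antibody responses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viraldelay)
```

## The model

`viraldelay` analyses a five-compartment in-host infection model: uninfected
target cells $x$, infected cells $y$, free virus $v$, cytotoxic T
lymphocytes $z$ and antibodies $w$,

$$
\begin{aligned}
x' &= s(x) - f(x, v),\\
y' &= e^{-m_1\tau_1} f(x_{\tau_1}, v_{\tau_1}) - a\,g_1(y) - p\,g_1(y)g_4(z),\\
v' &= k e^{-m_2\tau_2} g_1(y_{\tau_2}) - u\,g_2(v) - q\,g_2(v)g_3(w),\\
z' &= c\,g_1(y_{\tau_3})g_4(z_{\tau_3}) - b\,g_4(z),\\
w' &= r\,g_2(v)g_3(w) - h\,g_3(w),
\end{aligned}
$$

where $x_\tau$ denotes $x(t-\tau)$.  $\tau_1$ is the intracellular
(eclipse) delay, $\tau_2$ the virus maturation delay and $\tau_3$ the lag
in antigenic stimulation of the CTL response; $e^{-m_i\tau_i}$ are the
corresponding survival probabilities.  Time and concentration units are
deliberately abstract: the theory is scale-free, and the benchmark
parameter sets define their own (day-like) scale.  All rates are strictly
positive; delays are nonnegative.

The functional ingredients are interchangeable, subject to four structural
assumptions:

* **H1** — the growth law $s$ has a unique carrying state $\bar x > 0$
  with $s(\bar x) = 0$, $s'(\bar x) < 0$.
* **H2** — the incidence $f$ vanishes iff $x = 0$ or $v = 0$, is positive
  and nondecreasing in both arguments, and its slope
  $\partial f(x, 0)/\partial v$ is nondecreasing in $x$.
* **H3** — each removal law $g_i$ is strictly increasing, normalised
  ($g_i(0) = 0$, $g_i'(0) = 1$) and bounded below by a linear function.
* **H4** — $f(x, v)/g_2(v)$ is nonincreasing in $v$ (saturation of the
  per-virion infection efficiency).

`validate_assumptions()` checks these on a dense grid
($(0, 2\bar x] \times (0, v_{\max}]$, at least 100 points per axis,
default 120) rather than symbolically: the inequalities are transcendental
in general, and a grid with violation reporting is a testable contract.
The derivative normalisation $g_i'(0) = 1$ is enforced at machine
precision — a form violating it is rejected, never silently rescaled.  A
pass certifies the assumptions on the sampled box only; the default
$v_{\max} = 100$ covers the benchmark dynamics with a wide margin (the
exponential-shift incidence, for example, has a decreasing slope beyond
$v = 1/c_1 + b_1$, which is $100.01$ at the benchmark parameters — the
box is chosen to end where that form's monotone range ends).

## Thresholds and equilibria

Five reproduction numbers gate the equilibrium structure.  With
$\varepsilon = e^{-m_1\tau_1 - m_2\tau_2}$:

* $R_0 = k\varepsilon\, \partial f(\bar x, 0)/\partial v\,/(au)$ — basic
  reproduction number; $R_0 > 1$ admits the immune-free equilibrium
  $E_1 = (x_1, y_1, v_1, 0, 0)$.
* $R_1 = k\varepsilon f(x_2, v_2)/(a u\, g_2(v_2))$ with
  $v_2 = g_2^{-1}(h/r)$ — antibody establishment; gates
  $E_2 = (x_2, y_2, v_2, 0, w_2)$.
* $R_2 = k\varepsilon f(x_3, v_3)/(a u\, g_2(v_3))$ with
  $v_3 = g_2^{-1}(bk e^{-m_2\tau_2}/(cu))$ — CTL establishment; gates
  $E_3 = (x_3, y_3, v_3, z_3, 0)$.
* $R_3 = c e^{-m_1\tau_1} f(x_4, v_4)/(ab)$ and
  $R_4 = k e^{-m_2\tau_2} g_1(y_4)/(u\,g_2(v_4))$ — competition numbers
  gating the coexistence equilibrium $E_4$ (both must exceed 1).

Two derivation notes.  First, the $R_1$ implemented here carries the
infected-cell death rate $a$ in its denominator: the identity
$w_2 = g_3^{-1}(u(R_1 - 1)/q)$, i.e. positivity of the antibody component
exactly when $R_1 > 1$, forces it (and makes $R_1$ the exact analogue of
$R_2$).  The package treats that identity — which it verifies through the
stationarity residual of $E_2$ — as definitive.  Second, $R_4$ is
implemented from its defining identity
$w_4 = g_3^{-1}(u(R_4-1)/q)$ as $k e^{-m_2\tau_2} g_1(y_4)/(u\,g_2(v_4))$,
which reduces to $kbr e^{-m_2\tau_2}/(uch)$ for identity removals.

Each equilibrium is constructed, not solved as a 5-dimensional system: the
immune components are pinned by inverse removal functions
($y_3 = g_1^{-1}(b/c)$, $v_4 = g_2^{-1}(h/r)$, ...), and the remaining
cell component is the unique root of a scalar function on $(0, \bar x)$
(for $E_2, E_3, E_4$ the decreasing function $s(x) - f(x, v_e)$; for
$E_1$ the function $f(x, \varphi(x)) - s(x)$ with
$\varphi(x) = g_2^{-1}(k s(x)\varepsilon/(au))$, which is negative at $0$
and positive just below $\bar x$ when $R_0 > 1$).  Roots are found by
bracketed Brent iteration (`stats::uniroot`) at $10^{-12}$ relative
tolerance on brackets $(10^{-9}\bar x,\ \bar x)$; the theory guarantees a
unique sign change, which the test suite confirms by $10^4$-point dense
scans.  Nonlinear removal inverses use closed forms where available and
monotone bisection on an adaptively doubled bracket otherwise.  Every
returned equilibrium carries its stationarity residual (max norm of the
right-hand side); the suite requires residual
$< 10^{-8}(1 + \lVert E\rVert)$.

Threshold equalities ($R_i$ exactly 1) are classified as "$\le 1$"
(nonexistence of the gated component), matching the weak inequalities of
the stability theory.  `classify_regime()` returns the regime label only
when exactly one set of threshold conditions selects it, and
`"indeterminate"` (with the satisfied conditions listed) otherwise — in
particular whenever $\tau_3 > 0$ puts the CTL-involved corners outside the
proven theory.

### Benchmark discrepancies

Three printed components of the benchmark tuples are internally
inconsistent and are flagged rather than matched: the CTL component of
the first benchmark's $E_3$ (printed 15.3959, but
$g_4^{-1}(a(R_2-1)/p) = 16.71$ at the printed $R_2$ itself), and the
virus and antibody components of the second benchmark's $E_4$ (printed
0.6667 and 5.3039, but $v_4 = h/r = 0.0667$ — a decimal shift — and
$w_4 = u(R_4-1)/q = 5.308$).  The package reports the
construction-identity values, which is what makes its equilibrium
residuals vanish.

## Local stability

At an equilibrium the linearisation gives the characteristic matrix
$M(\lambda) = \lambda I - J_0 - J_1 e^{-\lambda\tau_1}
- J_2 e^{-\lambda\tau_2} - J_3 e^{-\lambda\tau_3}$, with $J_0$ the
current-state Jacobian block and $J_1..J_3$ the delayed-argument blocks;
$\Delta(\lambda) = \det M(\lambda)$.  At $E_0..E_3$ the determinant
factors into scalar immune-mode factors (e.g. $\lambda + h - r g_2(v_1)$,
$\lambda + b - c g_1(y)e^{-\lambda\tau_3}$) times a reduced determinant;
the package implements both the factored forms and the generic $5\times 5$
determinant (the only option at $E_4$) and tests their agreement at random
complex points.  The determinant is evaluated by complex LU with partial
pivoting (base R's `det` is real-only).

`rightmost_root()` combines two mechanisms:

* an **argument-principle count** of roots with positive real part, by
  summed phase increments of $\Delta$ along the boundary of the right
  sub-rectangle, with recursive segment bisection until each phase step is
  below $\pi/3$ (large steps risk phase aliasing — a change near $2\pi$
  reading as a small one — which showed up in practice near the
  characteristic function's near-zero at the origin for $E_4$); a
  non-integer total triggers a perturbed-contour retry and, after three
  failures, the verdict `inconclusive`;
* **Newton refinement** from a coarse grid of starting points, with the
  derivative by central differences of the holomorphic $\Delta$, roots
  deduplicated at $10^{-6}$.

The default search rectangle,
$\mathrm{Re} \in [-2\max(a,u,b,h),\ 1+\max\text{rate}]$,
$\mathrm{Im} \in [0, 50/\min(1, \tau_{\max})]$, covers the dominant roots
at the benchmark scales (delay equations have root chains receding
leftwards); it is an exposed parameter.  Roots within $10^{-7}$ of the
imaginary axis yield the verdict `marginal` — the numerical Hopf
candidate handed to the delay sweep.  `analytic_unstable_roots()`
additionally returns the closed-form positive roots that the instability
clauses exhibit ($\lambda^* = r g_2(v_e) - h$ at $E_1$/$E_3$, the root of
$\lambda + b - c g_1(y_e)e^{-\lambda\tau_3}$ at $E_1$/$E_2$, and the real
root of the viral quadratic factor at $E_0$).

## Integration

The integrator is the classical method of steps: fixed-step RK4 where
delayed values are read from a cubic Hermite dense interpolant built
segment by segment from node states and node derivatives; delayed times
$\le 0$ read the history function directly.  The step must satisfy
$h \le \min_i \tau_i/4$ over positive delays (so all delayed lookups fall
in completed segments), defaults to $\min(\tau_i)/20$ capped at $0.05$,
and ideally divides the delays so the derivative discontinuities
propagating from $t = 0$ land on nodes.  With exact endpoint data the
Hermite interpolant is locally $O(h^4)$, so the scheme retains fourth
order globally; the suite verifies an empirical order slope $\ge 3.5$ on
the scalar reference problem $y'(t) = -y(t-1)$ against its exact
piecewise-polynomial solution.  A deliberately simple design — no
adaptivity, no event detection — keeps runs bit-reproducible; stiffness
is not expected at the benchmark parameter scales, and where strong
immune activation makes a step locally stiff the positivity guard below
absorbs it.

Solutions of the model are provably positive and ultimately bounded.
Numerically, a grid step driving a component below $-10^{-6}$ is retried
as two internal half steps, recursively (to 12 levels), with a warning;
residual negatives smaller than $10^{-6}$ in magnitude are projected to
zero.  Models built from the registered form library run on a compiled
(Rcpp) core; custom plug-in forms fall back to the plain-R reference
integrator with identical semantics, and the two paths are tested to
agree to $10^{-9}$.  An independent adaptive DDE solver (`deSolve::dede`)
serves as a cross-check oracle in the test suite, never as the
implementation.

## Delay sweeps and oscillation detection

`detect_oscillation()` operationalises the stable/oscillatory dichotomy:
on the post-transient window (default: the last 30% of the run) it
computes each compartment's relative amplitude
$(\max-\min)/\text{scale}$, the scale being the window mean floored at
$10^{-6}$ of the largest compartment mean (so compartments decaying to
zero report amplitude $0$, not $0/0$ noise).  Classification thresholds:
`converged` when all amplitudes are below $\varepsilon_{\text{conv}} =
10^{-3}$; `oscillatory` when the virus amplitude is at least
$\varepsilon_{\text{osc}} = 10^{-2}$ *and* non-decaying (last quarter
amplitude $\ge 0.8\times$ the preceding quarter's); `undecided` otherwise.
The benchmarks' damped and sustained cases sit orders of magnitude on
either side of these thresholds, which are exposed as arguments.  The
dominant period is the median spacing of successive virus peaks — a
dependency-light estimator that is exact for clean limit cycles.  No
printed amplitudes or periods exist for the benchmark figures, so the
sweep checks are qualitative by construction: pattern of classifications,
not trajectory matching.

`scan_tau3()` integrates once per grid value of $\tau_3$ with everything
else held fixed (default horizon $T = 3000$, step $h = 0.01$, history =
the $\tau_3 = 0$ regime equilibrium perturbed by $+10\%$ with a small
positive floor — the benchmark figures' actual histories are not
recorded, so convergence claims are asserted as limits, not paths) and
reports the classification-change intervals: the numerically observed
stability switches.  Hopf certification is numerical only — a
classification flip, corroborated by a `marginal` rightmost root where
available; no normal-form analysis is attempted, matching the open state
of the $\tau_3 > 0$ theory.

## Lyapunov functionals

The global-stability results rest on five Volterra-type functionals, built
from $H(\xi) = \xi - 1 - \ln\xi \ge 0$ and brackets
$\int_{u_e}^{u}(1 - K(u_e)/K(\theta))\,d\theta$ (for kernels
$K = f(\cdot, v_e), g_1, \dots$), plus delay-window integrals such as
$f(x_e,v_e)\int_{-\tau_1}^0 H\!\big(f(x(t+s), v(t+s))/f(x_e,v_e)\big)ds$.
`lyapunov_functional()` evaluates them along a simulated trajectory:
bracket integrals by adaptive quadrature of the closed-form integrand,
delay windows by composite Simpson on the dense interpolant at node
spacing $\le h$ (the integrands are smooth along trajectories).  Two
reconstruction choices were made where the printed forms are garbled:
the brackets are implemented in the subtracted (Goh–Volterra) form, which
vanishes at the reference equilibrium and is nonnegative — the properties
the theory uses — and the antibody-bracket coefficient in the coexistence
functional carries the factor $1/r$ present in all four other
functionals, which the cancellation of the $w$–$v$ cross terms in
$dV/dt$ requires.  Neither choice affects the decay statement, which is
what the tests check: in each regime (with $\tau_3 = 0$ where the theory
requires it) the corresponding $V$ is nonincreasing along simulated
trajectories within $10^{-6}(1+V)$, and in the subthreshold regime
$dV_1/dt$ respects the proof's explicit bound
$(au\,e^{m_1\tau_1+m_2\tau_2}/k)\,g_2(v)(R_0-1)$.

## Random admissible models

Property checks draw random models via `random_viral_model()`: rates
uniform on ranges bracketing the benchmark scales, incidence form drawn
from the registered library (the exponential-shift form is excluded from
random draws because its monotone range is bounded), positive delays
floored at $0.5$ (shorter delays are dynamically indistinguishable at
these time scales but force tiny integrator steps).  Regime targeting
exploits monotonicity of the thresholds in single rates ($R_0 \propto
\beta$, $R_3 \propto c$; raising $r$ raises $R_1, R_4$; raising $c$
raises $R_2$) and pushes each gated threshold to $\le 0.8$ or
$\ge 1.25$, so sampled models sit away from bifurcation boundaries;
draws are rejected unless `classify_regime()` confirms the target.  All
randomness flows through R's RNG.

## Problem sizes and limitations

The shipped tests run at desk scale: 100 random models for the threshold
order property, 8–15 for trajectory properties, horizons $T \le 3000$ at
steps $0.01$–$0.05$, five random histories per regime for convergence
checks.  Passing them certifies the implementation on the benchmark
parameter ranges, not on arbitrary stiff or extreme-parameter corners.
Known limitations, by design: no distributed delays, no stochastic
forcing, no adaptive error control; no analytic Hopf theory (first
Lyapunov coefficient, bifurcation direction); assumption checking is
grid-based, not a proof; and trajectory matching of the published figures
is out of reach because their initial histories are unstated — the
package asserts the limits and patterns the theory predicts instead.
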