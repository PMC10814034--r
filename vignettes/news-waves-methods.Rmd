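---
title: "Analytic news waves: model, closed forms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic news waves: model, closed forms, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(newswaves)
```

## The model

A piece of news spreading through a population of `N` individuals is
modeled with the SIR compartmental system. `S(t)` counts potential
spreaders (susceptible to the news), `I(t)` active spreaders, and `R(t)`
individuals who have lost interest (removed):

$$
\frac{dS}{dt} = -\frac{\tau}{N} S I, \qquad
\frac{dI}{dt} = \frac{\tau}{N} S I - \rho I, \qquad
\frac{dR}{dt} = \rho I .
$$

The transmission rate $\tau$ and recovery rate $\rho$ are constants (per
abstract time unit; the model itself fixes no calendar scale), and
$S + I + R = N$ is conserved. Two derived quantities summarize a wave: the
logarithmic growth rate $\sigma = (1/I)\, dI/dt$ and the time-varying
effective reproduction number $R_n = 1 + \sigma/\rho$, which crosses 1
exactly at the wave peak. A wave's *amplitude* $I_m$ is its peak number of
active spreaders, and its *time horizon* $t_m$ the time of that peak.

Eliminating $S = S(0) e^{-\tau (R - R(0))/(\rho N)}$ (an exact first
integral) reduces the whole system to a single equation for the removed
count,

$$
\frac{dR}{dt} = \rho\left[ N - R - S(0)\, e^{-\tau R/(\rho N)} \right],
$$

after a nonzero initial removed pool is absorbed into the effective
coefficient $S(0)^* = S(0)\, e^{\tau R(0)/(\rho N)}$ (see "Degenerate and
shifted inputs" below).

## Truncation to a polynomial chain

For waves that touch a modest fraction of the population the exponent
$x = \tau R / (\rho N)$ stays small: with $N = 10^7$, a wave reaching
$R = 10^5$ and $\tau \approx \rho$ has $x = 0.01$, where
$e^x = 1.010050\ldots$ differs from 1 by one percent. Truncating the
exponential at polynomial order $M$ yields the chain

$$
\frac{dR}{dt} = \sum_{j=0}^{M} \alpha_j R^j, \qquad
\alpha_0 = \rho [N - S(0)],\quad
\alpha_1 = \frac{\tau S(0)}{N} - \rho,\quad
\alpha_j = -(-1)^j \frac{\tau^j S(0)}{j!\, \rho^{j-1} N^j},
$$

with even coefficients ($j \ge 2$) negative and odd ones positive. The
truncation is controlled by the Lagrange-remainder estimate
$\frac{e}{(M+1)!} x^{M+1}$, exposed by `validity_bound()` together with the
raw ratio `x`. "Small" is operationalized as a default threshold of 0.1 —
a warning level, not a hard error, because the cubic family legitimately
attains $e/4! \approx 0.113$ at the end of its wave and that is still
small compared to 1.

## Closed forms

**Quadratic order (`solve_m2`).** At $M = 2$ the chain is a Riccati
equation. Its general solution is a hyperbolic-tangent front plus a
two-constant correction term parameterized by $D$ and $E$; the family
depends only on the ratio $G = D/E$, so `E = 0` (a formal limiting branch
that the theory never uses) is rejected. The composite rate

$$
\theta = \left[ \left( \frac{\tau S(0)}{N} - \rho \right)^2
  + \frac{2 \tau^2 S(0) [N - S(0)]}{N^2} \right]^{1/2}
  = \sqrt{\alpha_1^2 - 4 \alpha_0 \alpha_2}
$$

is the discriminant of the quadratic right-hand side (always the positive
root). The canonical news wave is the $D = 0$ branch, for which the active
count is a symmetric pulse
$I(t) = I_m\, \mathrm{sech}^2[\theta (t - t_m)/2]$ with closed-form peak

$$
t_m = \frac{2}{\theta} \operatorname{atanh}\frac{\alpha_1}{\theta},
\qquad
I_m = \frac{\theta^2 N^2}{2 \tau^2 S(0)} .
$$

The time-shift constant $C$ is fixed by the initial removed count; its
`atanh` argument must lie in $(-1, 1)$, otherwise the requested constants
cannot represent a wave through the initial condition and construction
fails (`constants-infeasible`). For $D \ne 0$ the admissible ratio is
bounded by $D/E < \theta/(-2\alpha_2)$; at the characteristic time
$t = -C$ the solution takes the value $-\alpha_1/(2\alpha_2) + D/E$,
pinned between the $D = 0$ reference and the upper bound
$-\alpha_1/(2\alpha_2) - \theta/(2\alpha_2)$ (`correction_at_minus_C()`).

**Cubic order (`solve_m3`).** At $M = 3$ a closed form exists only on a
constraint surface. Shifting $R$ to the cubic's inflection point
$-\alpha_2/(3\alpha_3) = \rho N / \tau$ and requiring that point to be a
root of the right-hand side removes the constant and quadratic terms,
leaving a Bernoulli equation $\dot z = \beta_1 z + \alpha_3 z^3$ that
integrates in elementary functions. The root condition pins the recovery
rate:

$$
\rho = \tau \left( 1 - \frac{S(0)}{3N} \right),
$$

so `rho` is *not* a free input of `solve_m3()`. With $A = 6N - 5S(0)$ the
wave is

$$
R(t) = \left( N - \frac{S(0)}{3} \right)
  \left\{ 1 - \left[ \frac{A}{S(0) + 6[N - S(0)]\, e^{A \tau t/(3N)}}
  \right]^{1/2} \right\},
$$

which starts at $R(0) = 0$ with $I(0) = N - S(0)$ and saturates at
$R_\infty = N - S(0)/3$ — exactly the point where $x = \tau R/(\rho N)$
reaches 1, hence the $e/4!$ bound above. We note the superficially
plausible alternative reading $\rho = \tau[N - S(0)]/(3N)$ with plateau
$[N - S(0)]/3$: it satisfies the *definitional* identity
$I = (1/\rho)\,dR/dt$ equally well (both readings produce the same printed
$I(t)$), but it does **not** solve the order-3 chain — its residual
against $\sum_j \alpha_j R^j$ is order one, while the adopted form's is at
machine precision. The residual check is the discriminating instrument;
this is why the package ships one.

These cubic waves are strongly dissipative. The active count
$I(t) \propto \sqrt{w} / [S(0) w + 6(N - S(0))]^{3/2}$ with
$w = e^{-A\tau t/(3N)}$ has an interior maximum only when
$S(0) > 3N/4$, i.e. when fewer than a quarter of the population starts as
spreaders; the peak is then modest (about 24% above $I(0)$ for the
canonical cubic scenario) and the horizon is
$t_m = \frac{3N}{A\tau} \log \frac{S(0)}{3[N - S(0)]}$. For
$I(0) \ge N/4$ the count decays monotonically and the horizon is exactly
0, which is the regime meant by calling these waves dissipative: they
need a large organized seed and fade fast.

## Verification strategy: two oracles and a residual

Every closed form is cross-validated three ways, and `run_scenario()`
certifies all of them per run:

1. **Chain oracle.** `integrate_chain()` solves the same truncated
   polynomial ODE numerically (`deSolve::lsoda`, relative tolerance
   $10^{-9}$, absolute tolerance $10^{-9} N$). Closed form and chain solve
   the identical equation, so they must agree to integrator tolerance;
   observed sup-norm relative differences are below $10^{-8}$ on the
   canonical scenarios, asserted below $10^{-6}$.
2. **Full-SIR oracle.** `integrate_sir()` solves the untruncated system
   with the same tolerances. Here the difference *is* the truncation
   error, so agreement is asserted at the 2% level at the wave peak
   (evaluating both trajectories at the closed-form peak time) whenever
   the validity bound stays below threshold; for gentle waves
   ($x \le 0.02$) the observed peak discrepancy is about 0.1%.
3. **Residual certification.** `residual_m2()` / `residual_m3()`
   differentiate the closed form by fourth-order central finite
   differences — deliberately *not* the explicit derivative formula used
   inside the solvers — and normalize the worst violation of the chain
   equation by $\alpha_0$. Certified means below $10^{-5}$; the
   off-constraint negative control (recovery rate inflated 10% off the
   cubic constraint) scores above $10^{-3}$, confirming the check has
   teeth. The step $h = 0.002/\theta$ (or $0.002 \times 3N/(A\tau)$)
   balances $O(h^4)$ truncation against $O(\varepsilon/h)$ roundoff for
   the magnitudes involved.

## Numerical choices

* $\sigma$ from gridded trajectories uses central differences of
  $\log I$, which is exact for exponential segments, with one-sided
  differences at the endpoints; grid points with $I < 10^{-12} N$ are
  reported as undefined rather than amplifying 0/0 noise at wave tails.
* Polynomial right-hand sides are evaluated in nested (Horner) order —
  the $\alpha_j$ span ten or more orders of magnitude.
* $\mathrm{sech}^2$ is computed as $4 e^{-2|u|}/(1 + e^{-2|u|})^2$ and the
  cubic wave via $w = e^{-kt}$, so large times cannot overflow.
* `compute_metrics()` refines the grid argmax by golden-section search
  (`stats::optimize`) and finds the $R_n = 1$ crossing by bisection on
  $\sigma$; when a closed-form peak is available it is used directly and
  cross-checked numerically at $10^{-6}$ relative. Windows that end while
  the wave is still rising are doubled, up to $2^{10}$ times, before a
  horizon-not-reached error — slow waves with small transmission rates
  have very long horizons. A wave already decaying at $t = 0$ reports
  `tm = 0` (not missing) with `Im = I(0)`, and no crossing time.
* Nonzero initial removed counts are absorbed into $S(0)^*$ above, with
  the chain written in the actual (unshifted) $R$ and the constant $C$
  fitted to $R(0)$; this is supported on the canonical $D = 0$ branch.
  Note the absorption can be infeasible when $\tau R(0)/(\rho N)$ is
  large enough that $S(0)^* $ exceeds $N$; construction then fails with
  the domain error rather than returning a non-wave.

## Wave typology and sweeps

The A-E typology quarters the $(\tau, \rho)$ plane: A (high transmission,
low recovery: big, fast waves), B (both high), C (low transmission, high
recovery: small, slow waves), D (both low), E (intermediate band). The
theory is qualitative about "large" and "small", so the cut-offs are
configuration (`wave_type_thresholds()`); the shipped defaults
(0.004/0.012 for both rates) bracket the canonical scenario rates so the
classifier is immediately usable, and boundary values resolve away from E
toward the adjacent corner (ties in the order A, B, C, D) to keep the map
total and deterministic.

`sensitivity_sweep()` recomputes metrics along one-parameter grids. On the
shipped scenario grids it exposes the directional laws: amplitude grows
with initial spreaders, population size and transmission rate, and falls
with recovery rate; the horizon falls with initial spreaders and
transmission and grows with population. The sweep function reports the
metrics table; the package's tests (not the sweep itself) assert the
directional laws, so a user sweeping an unusual corner of parameter space
is shown what happens rather than stopped by an assertion.

## Wavetrains

A wavetrain chains waves of similar-but-different pieces of news: at a
splice time the next wave starts with the currently active spreaders,
$I_{n+1}(0) = I_n(t_{\text{splice}})$, while its removed pool resets to 0
and its susceptible pool to $N - I_{n+1}(0)$ — the new piece of news is
new to everyone, so previous recovery does not carry over. This
initialization is what allows indefinitely increasing trains; carrying $R$
across splices would cap growth. $I$ is therefore continuous at splices
while $S$ and $R$ jump, which is documented behavior, not a conservation
bug. Because the canonical quadratic pulse is symmetric about its peak,
splicing at twice the peak time restarts a wave at exactly its own
$I(0)$: amplitudes are invariant, and the splice-at-fraction policy
(`peak_fraction` below/above 2) cleanly selects increasing or decreasing
trains. Per-segment horizons are reported on each segment's own clock,
with global-clock peak times alongside. Trains are classified by strict
amplitude ordering: increasing, decreasing, or mixed.

## Problem sizes and scope of the test evidence

The shipped scenarios integrate 1001-point grids over windows of three
peak times (about $7 \times 10^4$ time units for the quadratic basic
scenario, $3 \times 10^3$ for the cubic one); residuals are certified on
201-point grids and the randomized oracle comparison uses ten gentle
parameter draws. These sizes resolve all the structure the closed forms
contain — the solutions are smooth with a single interior extremum — so
larger grids change the reported quantities only at integrator tolerance.

The scenarios are idealized study conditions, not data: rates are
constant within a wave, the population is closed and well mixed, and no
content, network, or platform structure exists. Passing tests therefore
show that the implementation realizes this theory exactly and that the
theory is internally consistent — not that real news cascades follow SIR
dynamics, and no fitting of $\tau$, $\rho$ to observed cascades is
provided or implied. The regime where a wave consumes a large fraction of
the population ($R/N \to 1$) is outside the truncation's validity and is
deliberately not covered: the integrators handle it, the closed forms do
not claim it.
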