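---
title: "Methods: the super compact pairwise SIS model and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the super compact pairwise SIS model and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpw)
```

## The model

Pairwise models of SIS (susceptible–infectious–susceptible) epidemics on
contact networks track not only the expected numbers of susceptible and
infectious nodes, $[S]$ and $[I]$, but also the expected numbers of
connected pairs $[SI]$, $[SS]$, $[II]$. Closing the hierarchy at the
pair level requires approximating triples; the *super compact pairwise*
(SCPW) closure does so through a factor

$$Q = \frac{\alpha [S]}{([SI]+[SS])^2} + \frac{\beta}{[SI]+[SS]},$$

whose constants

$$\alpha = \frac{\langle k^2\rangle^2 - \langle k\rangle\langle
k^3\rangle}{\langle k^2\rangle - \langle k\rangle^2}, \qquad
\beta = \frac{\langle k^3\rangle - \langle k^2\rangle\langle
k\rangle}{\langle k^2\rangle - \langle k\rangle^2} - 1$$

depend on the network only through the first three raw moments of its
degree distribution. That is the model's defining economy: five
equations (four once a conservation law is used) whatever the maximum
degree, with all network structure entering through
$\langle k\rangle, \langle k^2\rangle, \langle k^3\rangle$.

`model_constants()` computes $\alpha$, $\beta$, the mean excess degree
$\bar k = (\langle k^2\rangle - \langle k\rangle)/\langle k\rangle$, the
epidemic threshold $\delta_c = 1/\bar k$, and the rescaled constants
$\sigma = \langle k\rangle\delta_c$,
$\lambda = \alpha\delta_c/\langle k\rangle$, $\mu = \beta\delta_c$. Two
identities tie these together — $\alpha/\langle k\rangle + \beta = \bar
k$ and hence $\lambda + \mu = 1$ — and are asserted at construction
time, because the perturbation analysis below silently depends on them.

Nondimensionalizing by node and pair fractions
($v = [S]/N$, $w = [I]/N$, $x = [SI]/\langle k\rangle N$,
$y = [SS]/\langle k\rangle N$, $z = [II]/\langle k\rangle N$) and by the
recovery time ($T = t\gamma$; we write the rescaled time this way
because it is the dimensionally consistent substitution that maps the
dimensional system onto the nondimensional one) reduces the
epidemiology to the single ratio $\delta = \tau/\gamma$. The flows
preserve $v + w = 1$ and $2x + y + z = 1$, which `scpw_simulate()`
monitors rather than enforces: drift beyond $10^{-6}$ aborts loudly,
and excursions outside $[0,1]$ are flagged, never clipped. Two
3-variable reductions are provided, $(w, x, z)$ (all coordinates vanish
at the disease-free equilibrium, convenient for stability analysis) and
$(v, x, y)$ (the most parsimonious form for steady-state algebra); the
test suite checks that all forms generate the same trajectories.

## Threshold and bifurcation

At the disease-free equilibrium the Jacobian of the $(w,x,z)$ system is
block triangular with one eigenvalue $-1$ and a $2\times 2$ block whose
eigenvalues are always real and whose determinant is
$2(1 - \delta\bar k)$. The DFE is therefore stable exactly for
$\delta < \delta_c = \langle k\rangle/(\langle k^2\rangle - \langle
k\rangle)$. Rather than reproducing the centre-manifold argument for
the transcritical bifurcation symbolically, the package verifies its
conclusions numerically: an exhaustive root enumeration of the
steady-state polynomial system (feasible because one polynomial is
quadratic in $y$) confirms in the tests that no feasible endemic root
exists below $\delta_c$ and that a unique, small, numerically stable
branch emerges just above it.

The endemic equilibrium itself solves two polynomials $P(x,y) = Q(x,y)
= 0$ in the pair fractions. One derivation note: eliminating $v$ from
the $(v,x,y)$ steady state and clearing denominators yields a term
$\mu x^2(x+y)$ in $P$; that is the form this package implements, since
it is the one consistent with both perturbation expansions and with the
re-derivation from the differential equations. `solve_endemic()` runs
damped Newton iteration with the analytic Jacobian, seeded from
whichever perturbation expansion matches the regime (the boundary
`seed_switch = 2` on $\delta/\delta_c$ is a heuristic; continuation
inside `bifurcation_diagram()` overrides it by seeding each grid point
with its predecessor). Roots are accepted only in the open feasible
region $x > 0$, $y \ge 0$, $x + y < 1$, $2x + y < 1$; convergence is
declared at residuals below $10^{-12}$ or steps below $10^{-14}$, with
at most 100 iterations, and a failed solve falls back to a 25-step
logarithmic continuation walk from just above the threshold. Stability
is assessed from finite-difference Jacobian eigenvalues (step
$10^{-7}$) of the $(v,x,y)$ field, because the analytic stability proof
covers only the neighbourhood of the threshold.

## Perturbation approximations of the endemic equilibrium

Two regimes admit explicit approximations; the intermediate regime has
none, which is why both evaluators carry domain guards rather than
extrapolating silently.

**Near the threshold** ($\eta = 1 - \delta_c/\delta$ small): the
endemic state perturbs the emergence point $(x, y) = (0, 1)$, giving

$$w^* \approx \frac{\sigma}{\lambda\sigma + \mu\delta_c + \mu -
\delta_c}\,\eta + O(\eta^2).$$

The constant term of this expansion cancels only because $\lambda + \mu
= 1$; `near_threshold_equilibrium()` asserts that identity before
evaluating. The default guard refuses $\eta > 0.5$.

**Far from the threshold** ($\epsilon = \delta_c/\delta$ small): almost
no $SS$ links survive, so the expansion linearizes about the $y = 0$
slice, where $P$ has the explicit root $\phi(\epsilon)$ and
implicit-function slope $\psi(\epsilon)$. The result keeps two orders
in the pair fraction and one in the prevalence:

$$x^* \approx \frac{\epsilon}{\sigma} + \frac{\delta_c + \mu -
\sigma}{\lambda\sigma^2}\epsilon^2, \qquad
w^* = \sigma\epsilon^{-1}x^* \approx 1 + \frac{\delta_c + \mu -
\sigma}{\lambda\sigma}\,\epsilon.$$

The guard refuses $\epsilon > 0.9$. Truncation orders follow the
source analysis: higher-order prevalence terms are not computed, and
the package reports signed approximation errors (via
`glance()` on a bifurcation diagram) instead of error bounds — the
remainders are verified empirically, by Richardson-style ratio tests
against the exact Newton solve, to scale as $O(\eta^2)$ and
$O(\epsilon^2)$.

Setting the far-regime line $w^* = 1 + G\epsilon$ to zero yields an
implied epidemic threshold $\delta^\ast = -G\,\delta_c$
(`far_threshold_estimate()`), classified as an over- or underestimate
of $\delta_c$; whenever $\langle k^2\rangle \ge \langle k\rangle^2 +
\langle k\rangle$ it is an overestimate, and otherwise the direction
depends on the third moment. For valid heterogeneous moment inputs the
slope $G$ is automatically negative (equality would force the
distribution onto the Jensen boundary, i.e. zero variance), so the
no-crossing error path can only trigger on hand-built constants.

## Moment sensitivities

Both prevalence approximations are explicit in the moments, so their
partial derivatives are closed forms. Near the threshold (evaluated at
$\delta = \delta_c$, holding $\delta$ fixed — the convention that
reproduces the closed forms):

$$\frac{\partial w^*}{\partial\langle k\rangle} =
-\frac{\langle k^2\rangle}{D}, \quad
\frac{\partial w^*}{\partial\langle k^2\rangle} =
\frac{\langle k\rangle}{D}, \quad
\frac{\partial w^*}{\partial\langle k^3\rangle} = 0, \qquad
D = \langle k\rangle - 2\langle k^2\rangle + \langle k^3\rangle.$$

Far from the threshold all three partials carry a common factor
$1/\delta$, so the evaluation $\delta$ (default 1.5, recorded in the
output) rescales but never reorders them. The signs of
$\partial w^*/\partial\langle k\rangle$ and
$\partial w^*/\partial\langle k^2\rangle$ reverse between regimes —
the basis for the observation that containment (low prevalence) and
mitigation (high prevalence) call for different network interventions.

`sensitivity_grid()` treats the moments as free reals (as heat maps of
this kind do) and masks the wedge outside the Jensen and Cauchy–Schwarz
inequalities; cells on the Cauchy–Schwarz boundary are additionally
flagged undefined, since the far-regime derivatives blow up there. The
near-regime sensitivities are reported as their threshold limits; the
$\delta$-dependent derivative of the near approximation is available
behind `sens_near(at_threshold = FALSE)`, evaluated by central
differences through the moment-to-constants chain.

## Numerical choices

* **Degeneracy guards.** $\alpha$ and $\beta$ are $0/0$ for a regular
  network; `model_constants()` refuses when the variance falls below
  $10^{-10}\langle k\rangle^2$ (relative) rather than guessing a limit.
  The closure denominator guard is $10^{-12}$ on $x + y$ (and on
  $[SI]+[SS]$): the closure is singular in the all-infected state,
  which the model is never evaluated at.
* **Integration.** `deSolve`'s `lsodar` with default relative/absolute
  tolerances $10^{-8}/10^{-10}$, horizon $T = 200$ and a root-function
  stop once the field norm drops below $10^{-10}$ (converged). Runs
  that must resolve the slow near-threshold approach use longer
  horizons; the early stop makes them cheap.
* **Initial conditions.** The analysis itself needs none, but dynamic
  runs default to prevalence $10^{-2}$ with proportionate-mixing pair
  fractions ($x = vw$, $y = v^2$, $z = w^2$, renormalized) — a
  conventional choice, stated here because no canonical one exists.
* **Poisson truncation.** Upper tail mass below $10^{-12}$, then exact
  renormalization; at mean 10 this keeps all three moments within
  $10^{-8}$ of the analytic values $m$, $m^2{+}m$, $m^3{+}3m^2{+}m$.
* **Fixture generators.** The bimodal reference sequence (10,000
  nodes, half degree 3, half degree 5; moments exactly 4, 17, 76) is
  deterministic. The Poisson mean-10 sequence is drawn with a mandatory
  seed and redrawn whole if its degree sum is odd, so the sequence is
  always graphical; its sampled moments are random, which is why
  analytic moments are the default route to the Poisson constants.

## What the tests do and do not show

The synthetic fixtures emulate the two idealized study networks
(bimodal 3/5 and Poisson mean-10 configuration models). They exercise
heterogeneous-degree effects but not clustering, degree correlations,
household structure, or heavy-tailed distributions; for power-law
networks in the large-$N$ limit the SCPW threshold is known to
overestimate the true (vanishing) threshold, and nothing in this
package's passing tests speaks to that regime. Problem sizes in the
test suite — 10,000-node fixtures, $\delta$ grids of tens of points,
integration horizons of a few thousand recovery times with early
stopping — were chosen as the smallest sizes at which the quantities
checked are stable to well below their test tolerances.

## Known limitations

* No approximation bridges the intermediate regime between the two
  expansions; the domain guards make that explicit.
* The exact endemic equilibrium is computed numerically (Newton on the
  polynomial system); no closed form is attempted.
* Stability of the endemic branch is assessed numerically pointwise,
  not proven globally.
* The model consumes only degree moments: networks differing in ways
  invisible to $\langle k\rangle, \langle k^2\rangle, \langle
  k^3\rangle$ are indistinguishable to every quantity computed here.
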