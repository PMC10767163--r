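---
title: "Optimal allocation between parental immunocompetence and offspring production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal allocation between parental immunocompetence and offspring production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunalloc)
```

## The model

A parent enters breeding period $t$ with reserves $R_t = r \in (0, 1]$ and
splits them between two uses: $r_i$ shields its own survival (immune
function) and $r_o$ produces offspring, with $r_i + r_o \le r$; anything
unspent is banked into the next period.  Three primitives define the
trade-off:

* **Offspring production** is concave in investment,
  $\Phi(r_o) = \Phi_{max}\, r_o^{\alpha}$ with $0 < \alpha < 1$: the first
  units of reserves buy more offspring than the last.
* **Within-season survival.**  The parent is exposed to background
  mortality $M$ for the fraction $f$ of the period it spends pregnant or
  brooding; immune investment divides the mortality exponent, so
  $S_{current}(r_i) = e^{-Mf/(1+\gamma r_i)}$.  The efficacy $\gamma$
  says how much survival one unit of investment buys — it summarizes host
  condition and the pathogen pressure of the environment.
* **Between-season survival** is the same shielding over the whole
  period, $S_{future}(r_i) = e^{-M/(1+\gamma r_i)}$.

Because offspring survive only if the caring parent survives the brooding
fraction of the season, the current reproductive payoff is the product
$\Phi(r_o)\,S_{current}(r_i)$.  This is the lever that links parental
investment time $f$ to immunocompetence: the longer the brood depends on
the parent, the more a unit of immune investment is worth.

### Single season (semelparous) case

With one reproductive episode and $r_o = r - r_i$, fitness is
$W(r_i) = \Phi_{max}(r - r_i)^{\alpha} e^{-Mf/(1+\gamma r_i)}$.  Setting
the derivative to zero gives a quadratic whose relevant root is, with
$k = Mf/\alpha$,

$$r_i^* = \frac{-(2+k) + \sqrt{(2+k)^2 - 4(1 - r k \gamma)}}{2\gamma}.$$

The root is non-negative exactly when $r M f \gamma / \alpha \ge 1$.
Below that threshold fitness is decreasing in $r_i$ at zero, so the
constrained optimum is the boundary $r_i^* = 0$ — `semelparous_optimum()`
returns that boundary answer flagged `interior = FALSE` rather than "no
solution", because zero is the true constrained maximizer.  Solved for
the efficacy, the threshold is $\gamma_{min} = \alpha/(rMf)$
(`feasibility_threshold_gamma()`).  The negative branch of the quadratic
is never the maximizer when the threshold condition holds (the test suite
asserts this numerically over random draws), and the root is clipped to
$[0, r]$ as a guard for extreme parameter combinations.

```{r}
p <- alloc_params(M = 1, gamma = 2, f = 0.5, alpha = 0.5)
semelparous_optimum(1, p)
```

### Many seasons: backward induction

For an iteroparous life history, `solve_policy()` computes the maximum
accumulated lifetime reproductive success $W(r, t)$ by dynamic
programming, backwards from reproductive senescence at $T$ where
$W(r, T) = 0$:

$$W(r,t) = \max_{r_i + r_o \le r}\ \Phi(r_o) S_{current}(r_i)
  + S_{future}(r_i)\, W\!\big(\min(r - r_o - r_i + g,\ 1),\ t+1\big).$$

With a deterministic gain model $g = g(t)$.  With a stochastic gain the
individual is assumed to observe the period's gain $g_n$ *before*
allocating (it first encounters a breeding site, then allocates knowing
what the site offers), so the policy is indexed by $(r, t, g_n)$ and the
value mixes the per-gain maxima:
$W(r,t) = \sum_n p(g_n) \max_{r_i+r_o\le r}[\,\cdot\,]$.
The gain distribution is a discrete Gaussian on an evenly spaced bounded
support, $p(g_n) \propto e^{-(g_n - \bar g)^2/2\sigma^2}$, normalized to
sum to one exactly.

The last decision of the program, where the continuation value vanishes,
is exactly the semelparous problem — the test suite exploits this as an
oracle, requiring the $t = T-1$ policy to match the closed form within
one grid step.

### Forward simulation and emergent mortality

`simulate()` follows $K$ individuals through the policy.  Per period and
individual, two uniform draws determine the gain category (via the
inverse cumulative distribution of $p(g_n)$) and survival (against
$S_{future}(r_i^*)$); reserves update as
$r' = \min(r - r_o^* - r_i^* + g_n, 1)$.  Within-season brood loss
reduces the reproductive-success credit but does not kill the parent;
only the between-season survival draw does.  The order of events within
a period is draw gain → allocate → accrue offspring → survival draw; the
gain is known at allocation time, consistent with the observed-gain
policy.

Because the optimal policy invests in immunity, the realized death rate
of a simulated population is below the background rate.
`emergent_mortality()` quantifies this by fitting
$S_{forward}(t) = e^{-M_{emergent} t}$: the emergent mortality is the
absolute slope of $\log S_{forward}(t)$ on $t$.  Periods with zero
survivors are dropped (their log is undefined) and at least three usable
periods are required; the regression weights each period by its survivor
count — the delta-method variance of $\log S$ is $\approx 1/S$ — so a
tail of one or two stragglers cannot dominate the fit.  Since
$S_{future}$ is bounded between $e^{-M}$ and $e^{-M/(1+\gamma)}$,
$M_{emergent}$ must land in $[M/(1+\gamma),\ M]$.

## Parameters, defaults, and why

| parameter | meaning | default | rationale |
|---|---|---|---|
| `M` | background mortality per breeding period | — | set per species; $1/M$ is the rough lifespan in periods |
| `gamma` | survival efficacy of immune investment | — | set per species/environment |
| `f` | brooding fraction of the period, dimensionless | — | the comparison axis of most experiments |
| `alpha` | concavity of offspring production | 0.5 | square-root production, the standard diminishing-returns choice |
| `phi_max` | offspring at full allocation | 100 | sets the fitness scale only |
| `r_max` | reserve ceiling | 1 | normalization; gains above it are wasted |
| `T` | reproductive senescence | 20 periods | long enough that early-life policy is horizon-insensitive |
| `n_grid` | reserve grid points | 101 | step 0.01; refining 51 → 201 moves $W(1,1)$ by < 1% |
| `g_min, g_max, N` | stochastic gain support | 0, 1, 20 | spans the reserve range at the grid's natural resolution |
| `g_bar, sigma` | gain mean and spread | 0.5, 0.4 | a broad, centered season-to-season food distribution |
| `K` | simulated population size | 200 (2000 for mortality fits) | trajectory means stabilize at 200; the log-count fit needs the larger tail |

The default deterministic gain is $g(t) = 0.32 + 4e^{-0.5t}$, a form that
declines toward a baseline of 0.32 with age.  Any other profile — for
instance a gain that *rises* toward an asymptote as the organism grows to
adult size — can be supplied as a callable via
`gain_deterministic(fn = ...)`; the coefficients are conventions, not
fitted quantities, and none of the package's qualitative conclusions
depend on the shape chosen.

## Numerical choices

* **Discretization.**  Allocations are restricted to reserve-grid
  multiples, and feasibility is enforced in integer grid steps, so
  $r_i + r_o \le r$ holds exactly with no floating-point leakage.  The
  full triangle $r_i + r_o \le r$ is searched rather than forcing the
  allocation to exhaust reserves, since banking into the next period is
  part of the state dynamics.
* **Continuation value** between grid points is linearly interpolated,
  which preserves the monotonicity of $W$ in reserves; next-period
  reserves are clipped to $[0, 1]$.
* **Ties** in the maximization are broken toward the smallest $r_i$,
  then the smallest $r_o$ (prefer not investing when indifferent), by
  enumeration order — deterministic and documented.
* **Degenerate inputs.**  $0^\alpha$ is 0 (the continuous limit);
  $\gamma = 0$ yields the boundary optimum flagged non-interior rather
  than an error; a single-point stochastic gain (`gain_point()`)
  reproduces the deterministic solver exactly, which the tests assert to
  machine precision.
* **Forward pass.**  Reserve-to-policy lookup snaps to the nearest grid
  point.  Initial reserves are drawn from the gain distribution and
  snapped to the grid.  Uniform draws are consumed for every individual
  every period, alive or dead, so one seed fixes the whole trajectory
  set regardless of when deaths happen.

## What the simulations do and do not show

The forward Monte Carlo emulates a cohort of independent individuals
under stationary stochastic food gain: no density dependence, no
inheritance or evolutionary dynamics (offspring are counted, never
instantiated), no explicit pathogens — $\gamma$ alone summarizes the
host–pathogen interaction — and no within-season death of the parent
(brood loss is a fitness cost, not a survival event).  Passing tests
therefore demonstrate internal consistency of the optimization and
simulation machinery and the direction of the comparative-statics
predictions (investment rising with $f$, with $M$ at fixed $\gamma$, and
emergent mortality falling below background); they do not calibrate any
parameter to data from a real species.

## Problem sizes used by the test suite

Unit and property tests run on reduced sizes (grids of 21–51 points,
horizons of 2–12, populations of tens to hundreds) chosen so each
property is still sharply testable; the end-to-end checks use the
package defaults ($T = 20$, 101-point grid, $K$ = 200–2000, five seeds)
— the scale at which the headline experiments are meant to be run.
Exhaustive-enumeration oracles for the stochastic solver use a 5-point
grid and two-point gain support, the largest size at which brute force
stays trivially correct by inspection.

## Known limitations

* The policy is tabulated, so lookups snap states to the grid; at very
  coarse grids the forward simulation inherits that quantization.
* The emergent-mortality fit assumes a single exponential; near the
  horizon the policy becomes semelparous-like and invests less, so the
  log-survivor curve steepens slightly — with the count-weighted fit
  this shows up as a modest downward bias in $R^2$, not in the rate.
* Stochastic gains are independent across periods and individuals; no
  autocorrelated environments.
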