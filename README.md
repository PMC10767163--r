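# immunalloc

State-dependent life-history modelling of the trade-off between a
parent's **immunocompetence** and its **offspring production**.

Across many taxa the sex that spends more of the breeding cycle in
pregnancy or brooding also mounts the stronger immune response — female
mammals, but male pipefishes and seahorses, whose males carry the
fertilized eggs.  `immunalloc` is for theoretical ecologists and
behavioural biologists who want to explore the hypothesis behind that
pattern quantitatively: when offspring survival depends on the caring
parent staying alive, how should a parent split its reserves between its
own immune defence and making offspring, and what does the optimal split
do to realized mortality and lifespan?

## The model

A parent with reserves $r \in (0, 1]$ at breeding period $t$ allocates
$r_i$ to immunity and $r_o$ to offspring ($r_i + r_o \le r$; the rest is
banked).  Offspring production is concave,
$\Phi(r_o) = \Phi_{max} r_o^{\alpha}$, and immune investment shields
against background mortality $M$ with efficacy $\gamma$:
survival through the brooding fraction $f$ of the season is
$S_{current}(r_i) = e^{-Mf/(1+\gamma r_i)}$ and survival to the next
season is $S_{future}(r_i) = e^{-M/(1+\gamma r_i)}$.  Offspring count
only if the parent survives the brooding, so the per-season payoff is
$\Phi(r_o) S_{current}(r_i)$.

The package provides, in one coherent toolchain:

* the **closed-form single-season optimum**
  $r_i^* = \bigl[-(2+k) + \sqrt{(2+k)^2 - 4(1 - rk\gamma)}\bigr]/2\gamma$
  with $k = Mf/\alpha$, its feasibility threshold
  $\gamma_{min} = \alpha/(rMf)$, and a brute-force cross-check
  (`semelparous_optimum()`, `feasibility_threshold_gamma()`);
* **backward-induction solvers** for the multi-season problem with
  deterministic or stochastic (discrete-Gaussian) reserve gain, where a
  stochastic policy is conditioned on the gain observed at the breeding
  site (`solve_policy()`);
* **forward Monte Carlo** of populations following a policy, and the
  **emergent mortality** rate fitted to the simulated survivor decay
  (`simulate()`, `emergent_mortality()`);
* **preset experiments** — parameter sweeps, short- vs long-lived
  comparisons, mortality curves — written as CSV with a reproducible
  config snapshot (`run_preset()`, plus a thin CLI in
  `inst/scripts/immunalloc-cli.R`).

## Worked example

A long-brooding, short-lived organism (`M = 1.5`, `gamma = 5`,
`f = 0.9`):

```r
library(immunalloc)
p <- alloc_params(M = 1.5, gamma = 5, f = 0.9)

semelparous_optimum(1, p)
#> Semelparous optimum (closed_form)
#>   r_i* = 0.379058 of r = 1 reserves (k = Mf/alpha = 2.7)
#>   interior: TRUE; feasibility r*k*gamma >= 1: TRUE
#>   fitness at optimum: 49.4339
```

With only one season to live, this parent already spends 38% of its
reserves on its own immunity.  Over an iteroparous lifetime the stakes
rise — surviving buys future broods too:

```r
pol <- solve_policy(p, gain_stochastic(), T = 20)
predict(pol, r = 1, t = 1, gn = 0.5)
#>   r t  gn r_i r_o
#> 1 1 1 0.5 0.5 0.5
```

At full reserves the optimal policy now puts half of everything into
immunity.  Following 2000 individuals through that policy shows what the
investment buys:

```r
run <- simulate(pol, seed = 1, K = 2000)
emergent_mortality(run)
#> Emergent mortality: 0.6704 per period (se 0.0081, R^2 0.998, 13 periods)
```

The realized death rate is 0.67 per period — less than half the
background rate of 1.5: optimal immune investment has more than doubled
the expected lifespan.  Re-running across brooding fractions
(`run_preset("emergent-mortality")`) shows the decay is slowest for the
longest brooding fraction, the model's core prediction: the more of the
breeding cycle the offspring depend on the parent, the more that parent
should invest in immunity, and the longer it lives.

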