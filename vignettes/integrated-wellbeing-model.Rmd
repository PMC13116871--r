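---
title: "The integrated-wellbeing lifecycle model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The integrated-wellbeing lifecycle model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iwbsim)
```

## The model

Integrated wellbeing is modelled as a Cobb–Douglas composite of bounded
domain indices,

$$IW_t = \prod_i x_{i,t}^{\theta_i}, \qquad \theta_i > 0,\ \sum_i \theta_i = 1,\ x_{i,t} \in [0,1],$$

which bakes in four structural assumptions: *complementarity* (a zero
in any domain annihilates the composite — no amount of wealth
compensates for collapsed health), *diminishing marginal returns* in
each single domain (each exponent is below one), *constant returns to
scale* (the unit exponent sum keeps $IW$ an index on $[0,1]$ and makes
it degree-one homogeneous), and *positive elasticities* (every domain
always helps). The two-domain instantiation uses a financial index $F$
and a physical index $P$.

Each domain evolves in discrete one-year periods. Ages are calendar
ages; the decay inflexion `t0` is an age. Physical wellbeing decays at
a bounded-logistic rate rising from `alpha_min` (early adulthood) to
`alpha_max` (late life) and absorbs a concave, saturating investment
response to health spending. Two regime functions of $P$ structure the
economics: the *health span* $h(P)$ — zero at or below the threshold
$\bar P_H$ — gates labour income, while the *lifespan* $g(P)$ responds
less steeply. Wealth compounds at an exogenous interest rate, collects
labour income only while the previous period's health span was open,
and pays for health spending, all under a within-period no-borrowing
budget.

## Functional forms the source model leaves open

The underlying framework fixes only qualitative shape (monotonicity,
concavity, bounds) for several maps; the package commits to specific
forms, chosen to be the simplest smooth functions satisfying every
stated shape constraint with interpretable parameters:

* **Financial index** $F = (OF/(OF+s))^{\lambda}\,SF^{1-\lambda}$.
  Bounded on $[0,1]$, strictly increasing in wealth $OF$ and in the
  subjective index $SF$, saturating in wealth. `s` (currency) is the
  half-saturation wealth; `lambda` the objective weight.
* **Health investment** $I_P(C) = \kappa(1 - e^{-C/c_0})$: zero at
  zero, increasing, strictly concave, bounded by `kappa` so the unit
  cap on $P$ rarely binds artificially.
* **Labour income** $Y(P) = y_{\max} P^{\eta}$ inside the health span,
  zero outside. $\eta < 1$ (default 0.5) gives the concave income the
  required-return convexity result needs; $Y' > 0$ is what the
  gradient result needs.
* **Spans** $h(P) = H_{\max}\big((P-\bar P_H)/(1-\bar P_H)\big)^a$
  above the threshold and $T(P) = T_{\min} + (T_{\max}-T_{\min})P^b$.

The span shape constraint deserves a note. The model requires
$h'(P) > g'(P) \ge 0$ on the whole supra-threshold interval. Since
$h(\bar P_H) = 0$, any curvature $a > 1$ forces $h' \to 0$ at the
threshold and violates the strict inequality there; all shipped
parameterisations therefore use $a = 1$ (linear health span) with
$T_{\min}$ close to $T_{\max}$ so that $g'$ is small. Rather than trust
parameters, `scenario()` validates $h \le g$ and the slope ordering
numerically on a 100-point grid and rejects offending configurations at
load.

Two bookkeeping decisions resolve internal ambiguities in the source
accounting. First, the budget is read *within-period*: spending in
period $t$ is limited by start-of-period wealth plus period-$t$ resource
flow. Second, "financial investment" $I_{OF}$ is the *retained* portion
of wealth — wealth not spent on health remains invested — so the wealth
law $OF_t = (1+r)OF_{t-1} + Y - C_{OF}$ is an accounting identity and
$I_{OF}$ never enters as an extra inflow (the variant that adds it
double-counts). The subjective index $SF$ has no dynamics in the model
and is held constant over a simulation.

## Parameters that matter

| Parameter | Units | Default (fixtures) | Why |
|---|---|---|---|
| `theta` | — | $\theta_F=\theta_P=0.5$ | no basis for asymmetry; symmetric weights make dominance results easiest to read |
| `alpha_min`, `alpha_max` | 1/year | 0.01, 0.21 | ~1%/yr physical decline in early adulthood, ~20%/yr in late life |
| `tau`, `t0` | 1/year, age | 0.1, 65 | decade-scale transition centred on conventional retirement age |
| `P_bar_H` | index | 0.3 | income capability lost when physical wellbeing falls below 30% of its ceiling |
| `kappa`, `c0` | index/yr, currency | 0.1, 10 | at most +0.1 index/yr from spending; 10 currency units buy 63% of it |
| `H_max`, `T_min`, `T_max` | years | 60, 70, 85 | spans on a human scale; small $T_{\max}-T_{\min}$ keeps $g'$ below $h'$ |
| `y_max`, `eta` | currency/yr, — | 50, 0.5 | concave income, ceiling 50/yr at perfect health |
| `r_path` | 1/year | 0.03 | a flat, realistic real return; exogenous by design |
| `s`, `lambda` | currency, — | 500, 0.5 | half-saturation at ten years of peak income |

Currency units are arbitrary but consistent (think thousands); all
comparative-statics results are invariant to rescaling them, and one
test asserts exactly that for the required-return gradient.

## What the fixtures emulate — and what a green test does not establish

`baseline_scenarios()` ships four deterministic worlds: **steady-midlife**
(never leaves the health span), **threshold-straddling** (zero health
spending crosses $\bar P_H$ mid-horizon; moderate spending never does),
**post-healthspan** (starts below the threshold; interest income only),
and **symmetric-static** (a linear, zero-carryover static allocation
problem whose optimum is the budget split in elasticity proportions).

The threshold-straddling fixture is *constructed* to straddle: that is
its defining precondition, and the proposition-1 spend levels (0, 3, 7
currency/year) are part of that construction — 7/year is the smallest
round level whose physical path never dips below the threshold. Given
the precondition, the full option-value chain (income periods,
cumulative income, terminal wealth, terminal financial index, all
monotone in spending) is a genuine model output, not an assumption. At
spend levels far past the interior optimum the direct cost of spending
overtakes the income it preserves and terminal wealth turns back down —
the diminishing returns the model predicts.

These fixtures are stylised single-agent worlds. A green suite
establishes the internal mathematics — invariants, accounting
conservation, the proposition chains — on those worlds. It does *not*
establish anything empirical: no elasticities are estimated, there are
no stochastic health or return shocks, no heterogeneity, no behavioural
response, and the specific functional forms above are choices the
source model deliberately left open.

## Numerical choices

* Elasticity sum tolerance $10^{-12}$ absolute; normalisation only on
  explicit request, never silently.
* $0^0$ convention: a zero level with positive exponent contributes a
  factor 0. Interior products are evaluated in log space.
* Physical state is floored at 0 as well as capped at 1; decay alone
  cannot undershoot, but the floor makes the type invariant
  unconditional.
* Static allocator: bracketed bisection on the Lagrange multiplier of
  the budget (200 iterations on a log scale), per-domain scalar roots
  by `uniroot` at $10^{-12}$, budget residual tolerance $10^{-10}$; any
  terminal residual is assigned to interior domains in elasticity
  proportions, respecting caps. Domains already at their cap receive
  nothing; if every domain can be capped within budget, only the
  capping amounts are spent.
* Policy search ties break toward the smaller health-spend fraction
  (deterministic and conservative). Policy requests exceeding the
  budget are clipped with a warning rather than erroring, keeping
  policy search total.
* Finite differences: step $10^{-5}$ (central) on the $P$ axis for the
  required-return gradient, relative tolerance $10^{-6}$ with an
  absolute floor $10^{-12}$; the proposition-1 monotonicity comparisons
  use a $10^{-12}$ slack for pointwise paths and $10^{-9}$ for
  accumulated currency sums.
* Termination: the fixed horizon by default; `stop_at_lifespan = TRUE`
  stops once the remaining-lifespan estimate $g(P_t)$ falls below one
  period. Both readings are supported because the lifespan map makes
  terminal time state-dependent; neither is privileged.
* Degenerate inputs: empty trajectories refuse to summarise or
  serialise; a wealth update that would go negative aborts the period
  as an infeasibility bug rather than silently flooring.

One documented deviation: the claimed policy-search invariant that
marginal objective gains are non-increasing past the argmax cannot hold
for a bounded objective (the decreasing tail must flatten, so its
differences increase); the suite tests the sign form instead — past the
argmax no successive gain is positive on any shipped fixture.

## The intertemporal objective

The source model optimises a single period's constraint and names no
intertemporal objective. Policy search therefore takes the objective as
an explicit argument — terminal $IW$, mean $IW$ (default, no
discounting), or a discounted sum with rate $\rho \ge 0$ — and every
optimum is reported alongside the objective that produced it.
Multi-period optimisation is a grid search over constant-fraction
policies, not dynamic programming: the model derives no Bellman
structure, and the policy family suffices to exhibit every
comparative-statics result.

## Known limitations

Deterministic dynamics only (stochastic shocks are future work in the
source framework); two domains; a single agent; no endogenous labour
supply (capability is assumed exercised); subjective financial
wellbeing static; elasticities and all parameters are illustrative, not
estimated. The CLI writes tabular text and JSON only.
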