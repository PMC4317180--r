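---
title: "Simulating carrot-and-stick forest conservation policy mixes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating carrot-and-stick forest conservation policy mixes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(policymix)
```

## The problem

Tropical forest agencies fight deforestation with two kinds of
instruments: *sticks* — fines or in-situ coercion applied to detected
illegal clearing — and *carrots* — per-hectare payments for environmental
services (PES) conditional on forest being kept standing. Both run through
the same scarce resource: field inspections. An agency with budget $B$
cannot visit every deforestation patch, so land users face an enforcement
*probability* below one, fines are only expected costs, and payment
conditionality is only partially enforced. `policymix` simulates one
policy year on a landscape of grid cells (by convention 20 × 20 km, i.e.
40,000 ha) nested in districts, and reports where deforestation falls, what
the mix costs, who gains and loses income, and how much of the payment
budget leaks away as an imperfect-enforcement rent.

## Land-use model

Within each cell, per-hectare profits of deforestation are assumed
normally distributed over the land area with location $\mu$ and scale
$\sigma$ (BRL/ha). Hectares are cleared in decreasing order of profit, so
the marginal profit after clearing $d$ of $A$ hectares is the
$(1 - d/A)$ quantile of $N(\mu, \sigma)$, and unregulated land users clear
exactly the positively profitable share: $d_0 = A\,\Phi(\mu/\sigma)$.

A policy mix confronts the land user with enforcement probability $p$, a
per-hectare disincentive $F$, and a conditional payment $PES$ enforced
through the same inspections. The expected income at deforestation level
$d'$ is

$$f(d') - d'\,p\,F + PES\,(d_0 - d'p),$$

where $f$ is total profit (the integral of the marginal-profit quantile,
available in closed form as
$f(d) = \mu d + A\sigma\,\varphi(\Phi^{-1}(1 - d/A))$). The payment term
reflects imperfect conditionality: avoided hectares are always paid, and
payment on residual deforestation is lost only when an inspection
establishes non-compliance. An equivalent reading — payment on $d_0 - d'$
certain, payment on $d'$ clawed back with probability $p$ — has the same
expectation; the package implements the expectation. The first-order
condition gives the closed-form response

$$d' = A\,\Phi\!\left(\frac{\mu - p\,(F + PES)}{\sigma}\right),$$

so only the *expected combined incentive* $p(F + PES)$ matters at the
deforestation margin: at that margin a retained hectare avoids the
expected fine and earns the expected payment alike. This is verified in
the test suite by dense grid search of the objective and by the
fine/payment swap symmetry.

## Calibrating opportunity costs from observed deforestation

The data a practitioner actually has are baseline deforestation per cell
and a district-level mean per-hectare profit of deforestation (the
conservation opportunity cost). The calibration inverts the model:

* per cell, the baseline rate identifies the standardized location,
  $\Phi(\mu_i/\sigma_i) = d_{0,i}/A_i$;
* per district, the deforestation-area-weighted average over cells of the
  conditional mean profit on cleared land, $E[X \mid X > 0]$, must equal
  the district mean profit.

One equation per cell cannot identify two parameters per cell, so the
scale $\sigma$ is taken **common within a district** — the minimal
assumption under which both identities above hold. With
$z_i = \Phi^{-1}(\text{rate}_i)$ the conditional mean is
$\sigma (z_i + \varphi(z_i)/\text{rate}_i)$, the district constraint is
linear in $\sigma$, and the solution is closed-form and exactly
conservative (tested to 1e-6 against numeric integration, with exact
parameter recovery when data are generated from the model). Alternatives
(a scale tied functionally to the location, or a regional scale) would
need information the input tables do not carry.

Numerical choices: baseline rates are clamped to
$[10^{-6}, 1 - 10^{-6}]$ before the quantile transform (which diverges at
0 and 1) and clamped cells are flagged; cells with no baseline
deforestation are *unresponsive* — they carry no distribution, clear
nothing at any incentive, receive no inspections or payments, and
contribute zero weight to the district constraint. The rate denominator
is cell area by default; any other per-cell column (e.g. remaining forest
area) can be selected, since the field convention is not settled.

Aggregating $d_0 - A\,\Phi((\mu - s)/\sigma)$ over cells for a grid of
effectively delivered incentives $s$ yields the avoided-deforestation
cost curve: zero at $s = 0$, monotone, with a vertical asymptote at total
baseline deforestation.

## The enforcement agency

The agency maximizes inspected deforestation area subject to expected
spending: $\max_p \sum_i d_i' p_i$ with
$\sum_i p_i\,(TC_i + nd_i\,TC_i') \le B$, where $TC$ is the travel cost of
reaching a cell's first patch, $TC'$ the average per-additional-patch
cost, and $nd$ the expected patch count (0.035 patches per hectare of
deforestation by default, kept fractional because the budget term is an
expected cost and rounding would put artificial steps into parameter
sweeps). Against *fixed* deforestation this is a fractional knapsack:
sort by $d'/\text{cost}$, fill to $p = 1$ until the budget runs out, at
most one fractional cell, ties broken by cell order for determinism. The
allocation is verified against exhaustive enumeration of the LP's basic
feasible solutions.

### The fixed point, and why it is solved in mixed strategies

Land users respond to $p$; the agency allocates against $d'(p)$. Naive
alternation of these best responses does not settle: the knapsack
response is bang-bang, and inspecting a cell suppresses the very
deforestation that made it worth inspecting, so the marginal cells cycle
in and out of the plan (observed as a persistent residual of order one
under damped alternation). The object that repeated yearly allocations
actually trace out — and the one land users would learn as an inspection
*frequency* — is the mixed-strategy equilibrium: a benefit/cost threshold
$r^*$ such that

* cells whose fully-enforced deforestation still clears the threshold
  ($d_i'(1) \ge r^* c_i$) are always inspected, $p_i = 1$;
* cells whose baseline does not reach it ($d_{0,i} \le r^* c_i$) are never
  inspected, $p_i = 0$;
* marginal cells receive the interior $p_i$ that pins
  $d_i'(p_i) = r^* c_i$, available in closed form from the land-user
  response;
* the budget binds.

Every marginal cell then offers the agency exactly $r^*$ hectares of
inspected deforestation per real, so the plan attains the knapsack
optimum against the equilibrium $d'$ (a tie among alternative optima) while
land users best-respond to $p$: a genuine fixed point of both decision
problems. `solve_equilibrium()` finds $r^*$ by root bisection on the
spending identity; the solution is exact (budget residual at machine
precision), deterministic, and fast. The tests verify it against
exhaustive product-grid search over probability vectors on small
landscapes, with the agency's optimality gap as the equilibrium
criterion.

With `naive_epa = TRUE` the agency instead targets baseline
deforestation — a one-shot allocation with no feedback — which brackets
the rational-expectations solution from above in enforcement pressure on
high-response cells.

### Logistic spatialization

Observed inspection patterns look like a smooth logistic surface in
deforestation and inspection costs rather than a sharp knapsack frontier.
`fit_logistic()` fits
$p = \text{logit}^{-1}(a + b_d \log(1+d') - b_c \log(1+\text{cost}))$ to
an allocation ($\log(1+\cdot)$ tames heavy-tailed costs); because knapsack
plans are ratio-separable, plain maximum likelihood diverges and a
ridge-penalized likelihood (per-observation penalty, default 0.02) is
used, which deliberately keeps the surface a smooth probability gradient
rather than a step reproduction of a single year's plan.
`allocate_logistic()` recalibrates the intercept by root finding so
expected spending equals the budget. In logistic mode the equilibrium is
found by damped alternation (step 0.5, halved once if a two-cycle is
detected, default tolerance 1e-6 on the maximum probability update, cap
1000 iterations); the smooth best response converges in a few dozen
iterations, and a non-converged state is always returned flagged, never
silently. Coefficients are fitted once against baseline deforestation —
the agency's historical strategy surface — and held fixed across
iterations; user-supplied coefficients bypass the fit.

## Outcome metrics

At equilibrium, per cell: avoided deforestation $d_0 - d'$; expected
payments $PES\,(d_0 - d'p)$; the imperfect-enforcement rent
$PES\,d'(1-p)$ (payments that buy no conservation); expected fines
$p F d'$; land-user income change
$PES(d_0 - d'p) - pFd' - (f(d_0) - f(d'))$; and the agency's net revenue
(collected fines, if the disincentive is a collected fine rather than
revenue-free coercion, minus inspection spending minus payments).
Cost-effectiveness is avoided deforestation per unit implementation cost,

$$CE = \frac{\sum_i \Delta d_i}{B + \sum_i PES(d_{0,i} - d_i'p_i)
  \; [-\; \textstyle\sum_i p_iFd_i' \text{ if fines are collected}]},$$

reported per BRL and per 1000 BRL. The committed budget $B$ enters the
denominator, not realized inspection spending (the agency's budget is
appropriated independently of how much the allocation consumes); realized
spending is reported separately. A denominator driven to zero or below by
fine revenue is a *self-financing* mix and is flagged rather than
reported as a meaningless negative ratio. Two accounting identities hold
exactly and are asserted on every run in the test suite: payments
decompose as outlay = $PES\times$avoided + rent, and transfers cancel
between agency and land users
($W + \sum\Delta f = \text{payments} - \text{fines}$).

## Scenario sweeps

Three sweeps reproduce the standard experiment designs:

* `sweep_tradeoff()` holds $B$ and $F + PES$ fixed and moves the split
  from pure sticks to pure carrots. Because behavior depends only on
  $p(F+PES)$ and the allocation only on $d'$ and $B$, avoided
  deforestation is *identical* across the sweep; cost-effectiveness falls
  monotonically as transfers replace coercion and land-user income rises.
  Default: 50 evenly spaced splits.
* `sweep_budget()` evaluates fixed $(F, PES)$ mixes over a budget grid.
  Pure command-and-control loses cost-effectiveness as budgets grow
  (additional avoided hectares come at rising opportunity cost); pure
  payments gain cost-effectiveness from low budgets, where most of the
  transfer is an unconditional gift.
* `sweep_income()` fixes the disincentive (default 5000 BRL/ha, the
  statutory fine value) and crosses payment levels with budgets.
  Aggregate land-user income always falls as the budget grows; the
  payment share lost to imperfect enforcement shrinks. Note the
  *per-avoided-hectare* income change need not fall monotonically at low
  payment levels: at small budgets the expected fine burden on residual
  deforestation dominates the per-hectare account, so the aggregate —
  not the per-hectare — monotonicity is the robust statement, and the one
  the tests assert.

Calibration depends only on the landscape and is computed once and shared
across sweep points; every sweep row equals an independent
`run_scenario()` call at that parameter point (asserted in tests), so
results are order-independent and deterministic.

```{r example}
ls1 <- generate_synthetic_landscape(
  synthetic_config(n_cells_x = 20, n_cells_y = 20, n_districts = 6,
                   seed = 42))
models <- calibrate_cell_distributions(ls1)
run_scenario(ls1, policy_mix(budget = 5e6, fine = 5000, pes = 500),
             models = models)
```

## The synthetic landscape generator

Real inputs of this kind (satellite deforestation rasters, district
opportunity-cost estimates, agency travel-cost surfaces) are rarely
redistributable, so the package ships a seeded generator that emulates
their joint structure: a travel-cost surface rising with distance from an
access-point corner (default 2000 BRL base, 25 BRL/km, 15% lognormal
noise); a latent profit gradient; baseline rates driven by that gradient
on the logit scale (median 2% of cell area per year, spread 1.2, noise
0.8 — strongly right-skewed, with near-zero cells and frontier cells an
order of magnitude above the median); within-cell patch costs uniform on
100–400 BRL; district mean profits spanning 200–1500 BRL/ha; and a
negative profit/travel-cost correlation, default −0.33, hit exactly by
bisection on the loading of the shared remoteness axis. The correlation
is tuned against the travel-cost surface (field enforcement cost), not
against the patch-count component of inspection cost, which is
deforestation-driven and would conflate the two axes. Generation is
bit-reproducible for a fixed seed and leaves the caller's RNG state
untouched.

What the generator does *not* emulate: the true spatial autocorrelation
and river/road network geometry of enforcement costs, multi-year rate
dynamics, land-tenure structure, and the absolute magnitudes of any real
region (aggregates scale with the configured rates and ranges). Passing
tests on synthetic landscapes therefore establish the model's internal
logic and qualitative response surfaces — monotonicities, conservation
identities, equilibrium optimality — not the absolute levels a real
landscape would produce.

## Problem sizes and tolerances

The test suite runs behavioral oracles on 100 random draws against
10,000-point grid searches (0.1%), allocation against exhaustive LP
enumeration on 200 instances of up to 12 cells (1e-9), equilibria against
hierarchically refined product-grid search on 20 four-cell landscapes (1%
on total deforestation), calibration conservation to 1e-6 on 400-cell
landscapes, exact money-conservation identities, and the qualitative
response surfaces on a seeded 50 × 50 (2500-cell) landscape. Equilibrium
solves on 2500 cells take well under a second, so full sweep suites run
in seconds.

## Known limitations

One simulated year with static expectations; no leakage between cells, no
strategic baseline inflation, no adverse selection into payment
contracts, no moral hazard or legal-additionality payment design, no
commodity-price or economy-wide feedbacks, uniform (untargeted) payment
and fine levels, and risk-neutral land users. Fines act per hectare of
residual deforestation, not per patch. These match the scope of the
single-period decision framework the package implements; several would be
natural extensions.
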