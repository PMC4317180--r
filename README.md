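# policymix

Single-period, spatially explicit simulation of anti-deforestation policy
mixes that combine **carrots** — per-hectare payments for environmental
services (PES) conditional on avoided deforestation — with **sticks** —
fines or in-situ coercion under imperfect, budget-constrained enforcement.
It is written for conservation and environmental economists doing ex-ante
assessment of enforcement budgets, fine levels and payment levels on
landscapes of grid cells (by convention 20 × 20 km) nested in districts.

## The model

Per-hectare profits of deforestation within a cell are normally
distributed over the land area, so unregulated land users clear the
positively profitable share: `d0 = A * pnorm(mu / sigma)`. District-level
mean profits (conservation opportunity costs) are disaggregated into
cell-level `(mu, sigma)` by matching each cell's baseline deforestation
rate and conserving the deforestation-weighted conditional mean profit per
district. A risk-neutral land user facing enforcement probability `p`,
disincentive `F` and conditional payment `PES` clears up to the point
where marginal profit equals the expected incentive:

    d' = A * pnorm((mu - p * (F + PES)) / sigma)

The enforcement agency maximizes inspected deforestation under its budget
`B`, with per-cell inspection cost `TC + nd * TC'` (first-patch travel
cost plus expected within-cell patch costs) — a fractional knapsack whose
equilibrium with the land-user response is solved exactly in mixed
strategies (a benefit/cost threshold with a binding budget), or smoothly
through a fitted logistic enforcement surface. Outcomes per mix:
equilibrium deforestation, cost-effectiveness
`CE = avoided / (B + PES outlay − collected fines)`, land-user income
change `W`, and the share of payments lost to imperfect enforcement
(`PES * d' * (1 − p)`).

## Worked example

```r
library(policymix)

ls1 <- generate_synthetic_landscape(
  synthetic_config(n_cells_x = 20, n_cells_y = 20, n_districts = 6,
                   seed = 42))
ls1
#> <landscape> 400 cells in 6 district(s)
#>   total baseline deforestation: 786,782.8 ha/yr
#>   source: synthetic

models <- calibrate_cell_distributions(ls1)
run_scenario(ls1, policy_mix(budget = 5e6, fine = 5000, pes = 500),
             models = models)
#> <scenario_result> B = 5e+06, F = 5000, PES = 500
#>   avoided deforestation: 762,015.3 ha
#>   cost-effectiveness:    1.942 ha per 1000 BRL
#>   land-user income change: -383,549,784 BRL
#>   PES lost to imperfect enforcement: 6,404,736 BRL
```

A 5 million BRL inspection budget backing a 5000 BRL/ha fine plus a 500
BRL/ha payment eliminates most of this landscape's baseline clearing
(762,015 of 786,783 ha), at 1.9 ha conserved per 1000 BRL of
implementation cost — low, because the payment bill enters the cost while
only its enforced share buys conservation (6.4 million BRL of it is paid
out on uninspected residual deforestation). Land users bear a 384 million
BRL income loss: the forgone profits plus expected fines, net of
payments. `cost_curve(models, ...)` gives the avoided-deforestation
supply curve, and `sweep_tradeoff()` / `sweep_budget()` /
`sweep_income()` run the standard experiment designs as tidy tables.

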