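Package: policymix
Title: Simulating Mixes of Conservation Payments and Enforcement Against
    Deforestation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-period, spatially explicit simulator of anti-deforestation
    policy mixes that combine conditional per-hectare payments for environmental
    services (PES, "carrots") with fines or in-situ coercion under imperfect,
    budget-constrained enforcement ("sticks"). Landscapes are grids of cells
    nested in districts; district-level mean profits of deforestation are
    disaggregated into cell-specific normal profit distributions calibrated to
    observed deforestation rates. Land users respond to the expected policy
    incentive, the enforcement agency allocates costly inspections under a
    budget via a fractional-knapsack rule or its logistic spatialization, and
    the two are solved to a fixed point. The package computes equilibrium
    deforestation, avoided-deforestation cost curves, cost-effectiveness,
    land-user income effects, and the share of payments lost to imperfect
    enforcement, and runs the parameter sweeps needed for policy tradeoff
    analysis. A seeded synthetic-landscape generator emulates the spatial
    structure of real enforcement landscapes for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
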