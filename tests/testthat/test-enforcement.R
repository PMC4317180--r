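test_that("inspection cost is first-patch travel plus expected within-cell patches", {
  cells <- data.frame(tc_first = c(1000, 500), tc_within = c(50, 80),
                      n_patches = c(35, 0))
  expect_equal(inspection_cost(cells), c(1000 + 35 * 50, 500))
})

test_that("the greedy allocation matches the worked three-cell instance", {
  plan <- allocate_knapsack(c(100, 50, 200), c(10, 10, 100), 25)
  expect_equal(plan$p, c(1, 1, 0.05))
  expect_equal(plan$objective, 160)
  expect_equal(plan$total_cost, 25)
})

test_that("degenerate budgets produce all-or-nothing plans", {
  d <- c(10, 20, 30)
  costs <- c(5, 5, 5)
  expect_equal(allocate_knapsack(d, costs, 0)$p, c(0, 0, 0))
  expect_equal(allocate_knapsack(d, costs, 100)$p, c(1, 1, 1))
  # ineligible cells are never purchased even under slack budgets
  plan <- allocate_knapsack(d, costs, 100, eligible = c(TRUE, FALSE, TRUE))
  expect_equal(plan$p, c(1, 0, 1))
  expect_error(allocate_knapsack(c(1, 1), c(0, 5), 10), "positive")
})

test_that("greedy allocation attains the LP optimum on random small instances", {
  set.seed(202)
  for (k in 1:30) {
    n <- sample(2:8, 1)
    d <- runif(n, 0, 500)
    costs <- runif(n, 1, 100)
    B <- runif(1, 0, sum(costs))
    plan <- allocate_knapsack(d, costs, B)
    expect_lte(plan$total_cost, B * (1 + 1e-9))
    expect_equal(plan$objective, knapsack_enum_oracle(d, costs, B),
                 tolerance = 1e-9)
  }
})

test_that("the fitted enforcement surface prefers high-deforestation cheap cells", {
  set.seed(7)
  n <- 100
  d <- exp(rnorm(n, 6, 1.5))
  costs <- exp(rnorm(n, 9, 0.8))
  plan <- allocate_knapsack(d, costs, 0.3 * sum(costs))
  co <- fit_logistic(plan, d, costs)
  expect_gt(co$b_defor, 0)
  expect_gt(co$b_cost, 0)
  # refitting on its own smooth predictions is stable
  p_hat <- plogis(co$a + co$b_defor * log1p(d) - co$b_cost * log1p(costs))
  plan2 <- structure(list(p = p_hat), class = "enforcement_plan")
  co2 <- fit_logistic(plan2, d, costs)
  expect_equal(co2$b_defor, co$b_defor, tolerance = 0.01)
  expect_equal(co2$b_cost, co$b_cost, tolerance = 0.01)
  # degenerate plans cannot identify a surface
  expect_error(fit_logistic(allocate_knapsack(d, costs, 2 * sum(costs)),
                            d, costs), "degenerate")
})

test_that("logistic spatialization spends the budget exactly and monotonically", {
  set.seed(9)
  n <- 10
  d <- runif(n, 100, 5000)
  costs <- runif(n, 1000, 50000)
  co <- structure(list(a = 0, b_defor = 0.8, b_cost = 0.5,
                       penalized = FALSE), class = "enforcement_coefs")
  B <- 0.5 * sum(costs)
  plan <- allocate_logistic(co, d, costs, B)
  expect_equal(plan$total_cost, B, tolerance = 1e-6)
  expect_true(all(plan$p >= 0 & plan$p <= 1))
  expect_equal(allocate_logistic(co, d, costs, 0)$p, rep(0, n))
  p_half <- allocate_logistic(co, d, costs, 0.25 * sum(costs))$p
  expect_true(all(plan$p >= p_half - 1e-12))  # doubling B raises every p
  expect_warning(allocate_logistic(co, d, costs, 2 * sum(costs)),
                 "exceeds")
})

test_that("equilibrium handles the no-budget and slack-budget limits in one pass", {
  inst <- random_small_instance(4L, seed = 5L)
  m <- inst$models
  cells <- inst$landscape$cells
  pol0 <- policy_mix(budget = 0, fine = 2000, pes = 500)
  st0 <- solve_equilibrium(m, cells, pol0)
  expect_true(st0$converged)
  expect_lte(st0$iterations, 2L)
  expect_equal(st0$p, rep(0, 4))
  expect_equal(st0$d_prime, m$d0)
  costs <- inspection_cost(cells)
  pol1 <- policy_mix(budget = sum(costs) * 2, fine = 2000, pes = 500)
  st1 <- suppressWarnings(solve_equilibrium(m, cells, pol1))
  expect_equal(st1$p, rep(1, 4))
  expect_equal(st1$d_prime,
               m$denominator * pnorm((m$mu - 2500) / m$sigma),
               tolerance = 1e-9)
  expect_lte(st1$iterations, 2L)
})

test_that("the knapsack equilibrium is a mutual best response with a binding budget", {
  for (seed in c(3L, 14L, 27L)) {
    inst <- random_small_instance(6L, seed = seed)
    m <- inst$models
    costs <- inspection_cost(inst$landscape$cells)
    pol <- policy_mix(budget = 0.4 * sum(costs), fine = 1500, pes = 500)
    st <- solve_equilibrium(m, inst$landscape$cells, pol)
    expect_true(st$converged)
    # land users sit on their closed-form best response
    expect_equal(st$d_prime, optimal_deforestation(m, st$p, pol),
                 tolerance = 1e-12)
    # the agency's plan attains the knapsack optimum against d'
    opt <- allocate_knapsack(st$d_prime, costs, pol$budget,
                             m$responsive)$objective
    expect_equal(sum(st$d_prime * st$p), opt, tolerance = 1e-6)
    # and the budget binds whenever some cell is not fully inspected
    expect_equal(st$enforcement_spending, pol$budget,
                 tolerance = 1e-6 * pol$budget)
  }
})

test_that("four-cell equilibria reproduce exhaustive product-grid search", {
  inst <- random_small_instance(4L, seed = 77L)
  m <- inst$models
  costs <- inspection_cost(inst$landscape$cells)
  pol <- policy_mix(budget = 0.45 * sum(costs), fine = 1200, pes = 300)
  st <- solve_equilibrium(m, inst$landscape$cells, pol)
  oracle <- grid_equilibrium_oracle(m, costs, pol)
  expect_equal(sum(st$d_prime), oracle$total_d,
               tolerance = 0.01 * oracle$total_d)
})

test_that("equilibrium deforestation falls weakly as the budget grows", {
  inst <- random_small_instance(5L, seed = 33L)
  costs <- inspection_cost(inst$landscape$cells)
  budgets <- seq(0, sum(costs), length.out = 9)
  totals <- vapply(budgets, function(B) {
    st <- solve_equilibrium(inst$models, inst$landscape$cells,
                            policy_mix(budget = B, fine = 2500, pes = 500))
    sum(st$d_prime)
  }, numeric(1))
  expect_true(all(diff(totals) <= 1e-6))
})

test_that("logistic-mode equilibrium converges and spends the budget", {
  ls1 <- generate_synthetic_landscape(
    synthetic_config(n_cells_x = 15, n_cells_y = 15, n_districts = 4,
                     seed = 21L))
  m <- calibrate_cell_distributions(ls1)
  costs <- inspection_cost(ls1$cells)
  pol <- policy_mix(budget = 0.3 * sum(costs), fine = 2500, pes = 500,
                    enforcement_mode = "logistic")
  st <- solve_equilibrium(m, ls1$cells, pol)
  expect_true(st$converged)
  expect_equal(st$enforcement_spending, pol$budget,
               tolerance = 1e-4 * pol$budget)
  expect_true(all(st$d_prime <= m$d0 + 1e-9))
})
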