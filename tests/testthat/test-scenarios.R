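make_sweep_landscape <- function(seed = 31L) {
  generate_synthetic_landscape(
    synthetic_config(n_cells_x = 12, n_cells_y = 12, n_districts = 4,
                     seed = seed))
}

test_that("replacing fines with payments holds avoidance fixed, trades CE for income", {
  ls1 <- make_sweep_landscape()
  models <- calibrate_cell_distributions(ls1)
  budget <- 0.4 * sum(inspection_cost(ls1$cells))
  tab <- sweep_tradeoff(ls1, budget = budget, total_incentive = 5000,
                        steps = 11, models = models)
  expect_true(all(tab$converged))
  # the expected incentive depends only on F + PES, so avoidance is flat
  expect_equal(tab$avoided, rep(tab$avoided[1], nrow(tab)),
               tolerance = 1e-9)
  expect_true(all(diff(tab$CE) <= 1e-12))
  expect_true(all(diff(tab$W_total) >= -1e-6))
  # pure command-and-control is the cost-effectiveness maximum
  expect_equal(tab$CE[1], max(tab$CE))
  expect_equal(tab$pes_share[1], 0)
})

test_that("budget sweeps show rising avoidance and the two instrument signatures", {
  ls1 <- make_sweep_landscape()
  models <- calibrate_cell_distributions(ls1)
  # budgets span the unsaturated enforcement range (saturation: p = 1
  # everywhere once B covers every cell's inspection cost)
  total_cost <- sum(inspection_cost(ls1$cells))
  budgets <- seq(0, 0.6 * total_cost, length.out = 7)
  tab <- sweep_budget(ls1,
                      policies = data.frame(fine = c(5000, 0),
                                            pes = c(0, 500)),
                      budget_grid = budgets, models = models)
  expect_true(all(tab$converged))
  for (k in seq_len(2)) {
    sub <- tab[tab$fine == c(5000, 0)[k], ]
    expect_equal(sub$budget, budgets)
    expect_true(all(diff(sub$avoided) >= -1e-6))
    expect_equal(sub$avoided[1], 0, tolerance = 1e-9)
    expect_equal(sub$CE[1], 0)
  }
  cc <- tab[tab$fine == 5000, ]   # pure sticks: CE falls beyond the start
  expect_true(all(diff(cc$CE[-1]) <= 1e-12))
  pes <- tab[tab$fine == 0, ]     # pure carrots: CE rises from low budgets
  expect_gt(pes$CE[nrow(pes)], pes$CE[2])
  expect_true(all(diff(pes$CE[-1]) >= -1e-12))
})

test_that("income sweeps show enforcement eroding land-user benefits and PES loss", {
  ls1 <- make_sweep_landscape()
  models <- calibrate_cell_distributions(ls1)
  total_cost <- sum(inspection_cost(ls1$cells))
  budgets <- seq(0.1, 0.6, length.out = 5) * total_cost
  tab <- sweep_income(ls1, fine = 5000, pes_grid = c(0, 100, 500),
                      budget_grid = budgets, models = models)
  expect_true(all(tab$converged))
  for (pes in c(0, 100, 500)) {
    sub <- tab[tab$pes == pes, ]
    # more enforcement always lowers aggregate land-user income
    expect_true(all(diff(sub$W_total) <= 1e-6))
    if (pes > 0) {
      expect_true(all(diff(sub$pes_loss_per_avoided_ha) <= 1e-9))
    }
  }
  # a pure disincentive can only reduce incomes, and only where baseline
  # deforestation exists
  pol <- policy_mix(budget = budgets[1], fine = 5000)
  res <- run_scenario(ls1, pol, models = models)
  expect_true(all(res$per_cell$income_change <= 1e-9))
  zero_cells <- res$per_cell$d0 == 0
  expect_true(all(res$per_cell$income_change[!zero_cells &
                                               res$per_cell$p > 0] < 0))
})

test_that("scenario runs are deterministic and sweep rows match standalone runs", {
  ls1 <- make_sweep_landscape()
  models <- calibrate_cell_distributions(ls1)
  budget <- 0.4 * sum(inspection_cost(ls1$cells))
  pol <- policy_mix(budget = budget, fine = 2500, pes = 500)
  r1 <- run_scenario(ls1, pol, models = models)
  r2 <- run_scenario(ls1, pol, models = models)
  expect_identical(r1$per_cell, r2$per_cell)
  tab <- sweep_tradeoff(ls1, budget = budget, total_incentive = 3000,
                        steps = 5, models = models)
  mid <- tab[3, ]
  solo <- run_scenario(ls1, policy_mix(budget = budget, fine = mid$fine,
                                       pes = mid$pes), models = models)
  expect_equal(mid$avoided, solo$avoided_total, tolerance = 1e-12)
  expect_equal(mid$CE, solo$CE, tolerance = 1e-12)
  expect_equal(mid$W_total, solo$W_total, tolerance = 1e-12)
})

test_that("the null policy changes nothing and fine collection only moves accounting", {
  ls1 <- make_sweep_landscape()
  models <- calibrate_cell_distributions(ls1)
  res0 <- run_scenario(ls1, policy_mix(), models = models)
  expect_equal(res0$avoided_total, 0, tolerance = 1e-9)
  expect_equal(res0$W_total, 0, tolerance = 1e-9)
  expect_equal(res0$pes_loss_total, 0)
  budget <- 0.4 * sum(inspection_cost(ls1$cells))
  pol_a <- policy_mix(budget = budget, fine = 4000, pes = 200,
                      fines_collected = FALSE)
  pol_b <- policy_mix(budget = budget, fine = 4000, pes = 200,
                      fines_collected = TRUE)
  ra <- run_scenario(ls1, pol_a, models = models)
  rb <- run_scenario(ls1, pol_b, models = models)
  expect_identical(ra$per_cell$p, rb$per_cell$p)
  expect_identical(ra$per_cell$d_prime, rb$per_cell$d_prime)
  expect_identical(ra$per_cell$income_change, rb$per_cell$income_change)
  expect_false(identical(ra$per_cell$net_revenue, rb$per_cell$net_revenue))
  expect_true(rb$implementation_cost < ra$implementation_cost)
})
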