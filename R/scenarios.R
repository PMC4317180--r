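#' Run a single policy-mix scenario
#'
#' Calibrates cell profit distributions (unless a cached `models` table is
#' supplied), solves the enforcement/land-use equilibrium, and computes all
#' outcome metrics. Calibration depends only on the landscape, never on the
#' policy, so a single `models` table can be reused across any number of
#' scenarios on the same landscape.
#'
#' @param landscape a `landscape`.
#' @param policy a [policy_mix()].
#' @param models optional pre-computed `cell_profit_models`.
#' @param ... passed to [solve_equilibrium()] (`tolerance`,
#'   `max_iterations`, `damping`, `naive_epa`, `coeffs`).
#' @return a `scenario_result` (see [scenario_metrics()]); the equilibrium
#'   state is attached as attribute `"state"`.
#' @export
run_scenario <- function(landscape, policy, models = NULL, ...) {
  validate_landscape(landscape)
  if (is.null(models)) models <- calibrate_cell_distributions(landscape)
  state <- solve_equilibrium(models, landscape$cells, policy, ...)
  res <- scenario_metrics(state, policy, models, landscape$cells)
  attr(res, "state") <- state
  res
}

.sweep_run <- function(landscape, models, policy, ...) {
  res <- tryCatch(run_scenario(landscape, policy, models = models, ...),
                  error = function(e) e)
  if (inherits(res, "error")) {
    list(ok = FALSE, msg = conditionMessage(res))
  } else {
    list(ok = TRUE, res = res)
  }
}

#' Sweep from pure enforcement to pure payments
#'
#' Holds the enforcement budget and the total per-hectare incentive
#' `F + PES` fixed while moving the split from pure command-and-control
#' (`PES = 0`) to pure payments (`F = 0`). Because land users respond only
#' to the product `p * (F + PES)` and the agency's allocation depends only
#' on deforestation and its budget, avoided deforestation is identical
#' across the sweep; what changes is who pays: cost-effectiveness falls
#' monotonically as payments replace fines while land-user income rises.
#'
#' @param landscape a `landscape`.
#' @param budget enforcement budget B, BRL.
#' @param total_incentive the fixed sum `F + PES`, BRL/ha.
#' @param steps number of evenly spaced splits (default 50).
#' @param fines_collected,enforcement_mode passed to [policy_mix()].
#' @param models optional cached calibration.
#' @param ... passed to [solve_equilibrium()].
#' @return data.frame with one row per split: `pes_share`, `fine`, `pes`,
#'   `avoided`, `CE`, `ce_per_1000`, `W_total`, `W_per_avoided_ha`,
#'   `pes_loss_per_avoided_ha`, `converged`, `note`.
#' @export
sweep_tradeoff <- function(landscape, budget, total_incentive, steps = 50L,
                           fines_collected = FALSE,
                           enforcement_mode = "knapsack",
                           models = NULL, ...) {
  stopifnot(total_incentive > 0, steps >= 2L)
  if (is.null(models)) models <- calibrate_cell_distributions(landscape)
  shares <- seq(0, 1, length.out = steps)
  rows <- lapply(shares, function(s) {
    pol <- policy_mix(budget = budget, fine = (1 - s) * total_incentive,
                      pes = s * total_incentive,
                      fines_collected = fines_collected,
                      enforcement_mode = enforcement_mode)
    run <- .sweep_run(landscape, models, pol, ...)
    if (!run$ok) {
      return(data.frame(pes_share = s, fine = pol$fine, pes = pol$pes,
                        avoided = NA_real_, CE = NA_real_,
                        ce_per_1000 = NA_real_, W_total = NA_real_,
                        W_per_avoided_ha = NA_real_,
                        pes_loss_per_avoided_ha = NA_real_,
                        converged = FALSE, note = run$msg))
    }
    r <- run$res
    av <- r$avoided_total
    data.frame(pes_share = s, fine = pol$fine, pes = pol$pes,
               avoided = av, CE = r$CE, ce_per_1000 = r$ce_per_1000,
               W_total = r$W_total,
               W_per_avoided_ha = if (av > 0) r$W_total / av else NA_real_,
               pes_loss_per_avoided_ha =
                 if (av > 0) r$pes_loss_total / av else NA_real_,
               converged = r$converged,
               note = if (r$converged) "" else "not converged")
  })
  do.call(rbind, rows)
}

#' Sweep the enforcement budget for alternative mixes
#'
#' Evaluates each policy (a fixed `(F, PES)` pair) on a grid of enforcement
#' budgets. On the usual landscapes, pure command-and-control shows
#' decreasing cost-effectiveness in the budget beyond the first interior
#' point (additional avoided hectares come at rising opportunity cost),
#' while pure payments show increasing cost-effectiveness at low budgets
#' (higher inspection probability turns unconditional transfers back into
#' effective incentives).
#'
#' @param landscape a `landscape`.
#' @param policies data.frame with columns `fine` and `pes` (one row per
#'   mix), optionally `fines_collected`.
#' @param budget_grid budgets to evaluate, BRL.
#' @param enforcement_mode passed to [policy_mix()].
#' @param models optional cached calibration.
#' @param ... passed to [solve_equilibrium()].
#' @return data.frame with columns `budget`, `fine`, `pes`, `avoided`,
#'   `CE`, `ce_per_1000`, `W_total`, `converged`, `note`.
#' @export
sweep_budget <- function(landscape, policies, budget_grid,
                         enforcement_mode = "knapsack", models = NULL,
                         ...) {
  policies <- as.data.frame(policies)
  stopifnot(all(c("fine", "pes") %in% names(policies)))
  if (is.null(policies$fines_collected)) policies$fines_collected <- FALSE
  if (any(budget_grid > 5e7)) {
    warning("budget grid extends beyond the usual simulation range ",
            "(0 to BRL 50,000,000)", call. = FALSE)
  }
  if (is.null(models)) models <- calibrate_cell_distributions(landscape)
  rows <- list()
  for (k in seq_len(nrow(policies))) {
    for (B in budget_grid) {
      pol <- policy_mix(budget = B, fine = policies$fine[k],
                        pes = policies$pes[k],
                        fines_collected = policies$fines_collected[k],
                        enforcement_mode = enforcement_mode)
      run <- .sweep_run(landscape, models, pol, ...)
      rows[[length(rows) + 1L]] <- if (!run$ok) {
        data.frame(budget = B, fine = pol$fine, pes = pol$pes,
                   avoided = NA_real_, CE = NA_real_,
                   ce_per_1000 = NA_real_, W_total = NA_real_,
                   converged = FALSE, note = run$msg)
      } else {
        r <- run$res
        data.frame(budget = B, fine = pol$fine, pes = pol$pes,
                   avoided = r$avoided_total, CE = r$CE,
                   ce_per_1000 = r$ce_per_1000, W_total = r$W_total,
                   converged = r$converged,
                   note = if (r$converged) "" else "not converged")
      }
    }
  }
  do.call(rbind, rows)
}

#' Sweep payments and budgets at a fixed disincentive
#'
#' Evaluates income effects and payment losses across a grid of payment
#' levels and enforcement budgets, holding the per-hectare disincentive
#' fixed (default 5000 BRL/ha, the statutory fine level). Higher budgets
#' raise inspection probabilities, which always lowers land-user income per
#' avoided hectare and shrinks the share of payments lost to imperfect
#' enforcement.
#'
#' @param landscape a `landscape`.
#' @param fine fixed per-hectare disincentive, BRL/ha.
#' @param pes_grid payment levels to evaluate, BRL/ha.
#' @param budget_grid budgets to evaluate, BRL.
#' @param fines_collected,enforcement_mode passed to [policy_mix()].
#' @param models optional cached calibration.
#' @param ... passed to [solve_equilibrium()].
#' @return data.frame with columns `budget`, `pes`, `avoided`,
#'   `W_per_avoided_ha`, `pes_loss_per_avoided_ha`, `W_total`,
#'   `pes_loss_total`, `converged`, `note`.
#' @export
sweep_income <- function(landscape, fine = 5000, pes_grid, budget_grid,
                         fines_collected = FALSE,
                         enforcement_mode = "knapsack", models = NULL,
                         ...) {
  if (is.null(models)) models <- calibrate_cell_distributions(landscape)
  rows <- list()
  for (pes in pes_grid) {
    for (B in budget_grid) {
      pol <- policy_mix(budget = B, fine = fine, pes = pes,
                        fines_collected = fines_collected,
                        enforcement_mode = enforcement_mode)
      run <- .sweep_run(landscape, models, pol, ...)
      rows[[length(rows) + 1L]] <- if (!run$ok) {
        data.frame(budget = B, pes = pes, avoided = NA_real_,
                   W_per_avoided_ha = NA_real_,
                   pes_loss_per_avoided_ha = NA_real_,
                   W_total = NA_real_, pes_loss_total = NA_real_,
                   converged = FALSE, note = run$msg)
      } else {
        r <- run$res
        av <- r$avoided_total
        data.frame(budget = B, pes = pes, avoided = av,
                   W_per_avoided_ha =
                     if (av > 0) r$W_total / av else NA_real_,
                   pes_loss_per_avoided_ha =
                     if (av > 0) r$pes_loss_total / av else NA_real_,
                   W_total = r$W_total, pes_loss_total = r$pes_loss_total,
                   converged = r$converged,
                   note = if (r$converged) "" else "not converged")
      }
    }
  }
  do.call(rbind, rows)
}
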