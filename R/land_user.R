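#' Define a policy mix
#'
#' A policy mix is a combination of the three government levers: the
#' enforcement agency's budget `B` (BRL), the per-hectare disincentive `F`
#' (a fine or coercive measure of equivalent value, BRL/ha), and the
#' per-hectare conditional payment `PES` (BRL/ha). `fines_collected` states
#' whether the disincentive generates agency revenue (fines actually
#' collected) or is delivered through in-situ coercion that generates none;
#' it affects accounting only, never behavior. `enforcement_mode` selects
#' how the agency spatializes its budget: the exact fractional-knapsack
#' allocation or its smooth logistic approximation.
#'
#' Values outside the ranges used in simulation practice (`B` up to 50
#' million BRL, `F` and `PES` up to 5000 BRL/ha) trigger a warning, not an
#' error.
#'
#' @param budget enforcement budget B, BRL.
#' @param fine per-hectare disincentive F, BRL/ha.
#' @param pes per-hectare conditional payment, BRL/ha.
#' @param fines_collected logical; do fines accrue to the agency?
#' @param enforcement_mode `"knapsack"` or `"logistic"`.
#' @return an object of class `policy_mix`.
#' @export
policy_mix <- function(budget = 0, fine = 0, pes = 0,
                       fines_collected = FALSE,
                       enforcement_mode = c("knapsack", "logistic")) {
  enforcement_mode <- match.arg(enforcement_mode)
  stopifnot(length(budget) == 1L, length(fine) == 1L, length(pes) == 1L,
            budget >= 0, fine >= 0, pes >= 0,
            is.logical(fines_collected), length(fines_collected) == 1L)
  if (budget > 5e7) warning("budget exceeds the usual simulation range ",
                            "(0 to BRL 50,000,000)", call. = FALSE)
  if (fine > 5000) warning("fine exceeds the usual simulation range ",
                           "(BRL 0-5000 per ha)", call. = FALSE)
  if (pes > 5000) warning("PES exceeds the usual simulation range ",
                          "(BRL 0-5000 per ha)", call. = FALSE)
  structure(list(budget = budget, fine = fine, pes = pes,
                 fines_collected = fines_collected,
                 enforcement_mode = enforcement_mode),
            class = "policy_mix")
}

#' @export
print.policy_mix <- function(x, ...) {
  cat("<policy_mix> B = ", format(x$budget, big.mark = ","),
      " BRL, F = ", x$fine, " BRL/ha, PES = ", x$pes, " BRL/ha\n",
      "  fines collected: ", x$fines_collected,
      ", enforcement mode: ", x$enforcement_mode, "\n", sep = "")
  invisible(x)
}

#' Optimal post-policy deforestation
#'
#' A risk-neutral land user facing enforcement probability `p` clears land up
#' to the point where the marginal profit equals the expected policy
#' incentive `p * (F + PES)` — every retained hectare avoids the expected
#' fine and earns the expected conditional payment, so fine and payment are
#' interchangeable at the deforestation margin. The interior solution is
#' `d' = denominator * pnorm((mu - p*(F + PES)) / sigma)`, which never
#' exceeds the baseline `d0` and reduces to it when the expected incentive
#' is zero. Unresponsive cells (no baseline deforestation) return 0.
#'
#' @param models a `cell_profit_models` table.
#' @param p enforcement probability (scalar or per-cell vector in `[0, 1]`).
#' @param policy a [policy_mix()].
#' @return per-cell post-policy deforestation `d'`, ha.
#' @export
optimal_deforestation <- function(models, p, policy) {
  .check_models(models)
  stopifnot(inherits(policy, "policy_mix"))
  n <- nrow(models)
  p <- rep_len(p, n)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  incentive <- p * (policy$fine + policy$pes)
  out <- numeric(n)
  r <- models$responsive
  out[r] <- models$denominator[r] *
    stats::pnorm((models$mu[r] - incentive[r]) / models$sigma[r])
  # a zero expected incentive leaves the baseline exactly: avoid roundoff
  # in pnorm(qnorm(rate)) contaminating avoided-deforestation accounting
  out[r & incentive == 0] <- models$d0[r & incentive == 0]
  # guard against roundoff pushing d' a hair above the model baseline
  pmin(out, models$d0)
}

#' Expected land-user income under a policy mix
#'
#' Evaluates the land user's expected income at a deforestation level `d'`:
#' profits from residual clearing, minus the expected fine on it, plus the
#' conditional payment. The payment accrues on `d0 - d' * p`: avoided
#' hectares are always paid, while payment on residual deforestation is only
#' lost when an inspection (probability `p`) establishes non-compliance — an
#' equivalent reading is that payment on `d0 - d'` is certain and the
#' payment on `d'` is clawed back with probability `p`.
#'
#' @param models a `cell_profit_models` table.
#' @param p enforcement probability (scalar or per-cell).
#' @param policy a [policy_mix()].
#' @param d_prime per-cell deforestation, ha; must not exceed the model
#'   baseline `d0`.
#' @return per-cell expected income, BRL.
#' @export
expected_land_user_income <- function(models, p, policy, d_prime) {
  .check_models(models)
  stopifnot(inherits(policy, "policy_mix"))
  n <- nrow(models)
  p <- rep_len(p, n)
  d_prime <- rep_len(d_prime, n)
  if (any(d_prime > models$d0 * (1 + 1e-12) + 1e-9)) {
    stop("d_prime must not exceed the baseline d0", call. = FALSE)
  }
  d_prime <- pmin(d_prime, models$d0)
  total_profit(models, d_prime) - d_prime * p * policy$fine +
    policy$pes * (models$d0 - d_prime * p)
}
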