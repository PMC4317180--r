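#' Outcome metrics of a policy mix at equilibrium
#'
#' Builds the full per-cell and aggregate accounting of a policy mix
#' evaluated at an equilibrium state. Per cell (with enforcement probability
#' `p`, baseline `d0`, post-policy deforestation `d'`):
#' \describe{
#'   \item{avoided}{`d0 - d'`, ha}
#'   \item{pes_paid}{`PES * (d0 - d'*p)`, the expected payment: avoided
#'     hectares are always paid, residual hectares only when enforcement
#'     fails to detect them}
#'   \item{pes_loss}{`PES * d' * (1 - p)`, the imperfect-enforcement rent:
#'     the share of payments that buys no conservation}
#'   \item{fines_paid}{`p * F * d'`, expected fines on residual
#'     deforestation}
#'   \item{income_change}{`pes_paid - fines_paid - (f(d0) - f(d'))`, the
#'     land user's income relative to laissez-faire}
#'   \item{net_revenue}{agency cash flow: collected fines (if any) minus
#'     expected inspection spending minus payments}
#' }
#' Cost-effectiveness is avoided deforestation per BRL of implementation
#' cost, `CE = sum(avoided) / (B + sum(pes_paid) - collected fines)`; the
#' budget `B` enters, not realized inspection spending, because the agency's
#' budget is committed independently of how much of it the allocation
#' actually consumes (realized spending is reported separately). When fine
#' revenue makes the denominator non-positive while deforestation is still
#' avoided, the mix is self-financing and `CE` is reported as `NA` with the
#' `self_financing` flag set rather than as a meaningless negative ratio.
#'
#' The payment accounting satisfies, exactly,
#' `sum(pes_paid) = PES * sum(avoided) + sum(pes_loss)`.
#'
#' @param state an `equilibrium_state` from [solve_equilibrium()].
#' @param policy the [policy_mix()] the state was solved for.
#' @param models the `cell_profit_models` table used.
#' @param cells the matching cell table or `landscape` (inspection costs).
#' @return an object of class `scenario_result` with aggregate fields
#'   (`avoided_total`, `implementation_cost`, `fine_revenue`,
#'   `fine_revenue_potential`, `CE`, `ce_per_1000`, `W_total`,
#'   `pes_paid_total`, `pes_loss_total`, `enforcement_spending`,
#'   `self_financing`, `converged`) and a `per_cell` data.frame.
#' @export
scenario_metrics <- function(state, policy, models, cells) {
  stopifnot(inherits(state, "equilibrium_state"),
            inherits(policy, "policy_mix"))
  .check_models(models)
  if (inherits(cells, "landscape")) cells <- cells$cells
  p <- state$p
  d0 <- models$d0
  dp <- state$d_prime
  costs <- inspection_cost(cells)

  avoided <- d0 - dp
  pes_paid <- policy$pes * (d0 - dp * p)
  pes_loss <- policy$pes * dp * (1 - p)
  fines_paid <- p * policy$fine * dp
  delta_f <- total_profit(models, d0) - total_profit(models, dp)
  income_change <- pes_paid - fines_paid - delta_f
  collected <- if (policy$fines_collected) fines_paid else 0 * fines_paid
  net_revenue <- collected - p * costs - pes_paid

  per_cell <- data.frame(cell_id = models$cell_id,
                         p = p, d0 = d0, d_prime = dp,
                         avoided = avoided,
                         income_change = income_change,
                         net_revenue = net_revenue,
                         pes_paid = pes_paid,
                         pes_loss = pes_loss,
                         fines_paid = fines_paid,
                         inspection_spending = p * costs)

  fine_revenue <- sum(collected)
  denom <- policy$budget + sum(pes_paid) - fine_revenue
  avoided_total <- sum(avoided)
  self_financing <- denom <= 0 && avoided_total > 0
  ce <- if (self_financing) NA_real_
        else if (avoided_total == 0) 0
        else avoided_total / denom
  structure(list(policy = policy,
                 avoided_total = avoided_total,
                 implementation_cost = denom,
                 fine_revenue = fine_revenue,
                 fine_revenue_potential = sum(fines_paid),
                 CE = ce,
                 ce_per_1000 = 1000 * ce,
                 W_total = sum(income_change),
                 pes_paid_total = sum(pes_paid),
                 pes_loss_total = sum(pes_loss),
                 enforcement_spending = state$enforcement_spending,
                 self_financing = self_financing,
                 converged = state$converged,
                 per_cell = per_cell),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> B = ", format(x$policy$budget, big.mark = ","),
      ", F = ", x$policy$fine, ", PES = ", x$policy$pes, "\n",
      "  avoided deforestation: ", format(round(x$avoided_total, 1),
                                          big.mark = ","), " ha\n",
      "  cost-effectiveness:    ",
      if (x$self_financing) "self-financing (fine revenue covers costs)"
      else paste0(format(signif(x$ce_per_1000, 4)), " ha per 1000 BRL"),
      "\n",
      "  land-user income change: ", format(round(x$W_total),
                                            big.mark = ","), " BRL\n",
      "  PES lost to imperfect enforcement: ",
      format(round(x$pes_loss_total), big.mark = ","), " BRL\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness of a policy mix
#'
#' Convenience wrapper returning the full [scenario_metrics()] result; the
#' cost-effectiveness fields are `CE` (ha per BRL), `ce_per_1000` (ha per
#' 1000 BRL, the usual reporting scale), `implementation_cost` and
#' `self_financing`.
#'
#' @inheritParams scenario_metrics
#' @return a `scenario_result`.
#' @export
cost_effectiveness <- function(state, policy, models, cells) {
  scenario_metrics(state, policy, models, cells)
}

#' Land-user income change per cell
#'
#' The change in expected land-user income relative to laissez-faire:
#' payments received, minus expected fines, minus the opportunity cost of
#' forgone deforestation `f(d0) - f(d')`. Negative values are losses.
#'
#' @inheritParams scenario_metrics
#' @return list with `per_cell` (BRL) and `total` (BRL).
#' @export
income_change <- function(state, policy, models) {
  stopifnot(inherits(state, "equilibrium_state"),
            inherits(policy, "policy_mix"))
  .check_models(models)
  dp <- state$d_prime
  w <- policy$pes * (models$d0 - dp * state$p) -
    state$p * policy$fine * dp -
    (total_profit(models, models$d0) - total_profit(models, dp))
  list(per_cell = w, total = sum(w))
}

#' Payments lost to imperfect enforcement
#'
#' The conservation-ineffective share of payments, `PES * d' * (1 - p)` per
#' cell: payments expected on residual deforestation that goes uninspected.
#' Zero under perfect enforcement (`p = 1` everywhere) or without payments.
#'
#' @inheritParams scenario_metrics
#' @return list with `per_cell` (BRL), `total` (BRL) and
#'   `per_avoided_ha` (BRL/ha; `NA` when nothing is avoided).
#' @export
pes_loss <- function(state, policy) {
  stopifnot(inherits(state, "equilibrium_state"),
            inherits(policy, "policy_mix"))
  loss <- policy$pes * state$d_prime * (1 - state$p)
  avoided <- sum(state$d0 - state$d_prime)
  total <- sum(loss)
  list(per_cell = loss, total = total,
       per_avoided_ha = if (avoided > 0) total / avoided else NA_real_)
}

#' Agency net revenue per cell
#'
#' The enforcement agency's cash flow per cell: fine revenue (when fines are
#' collected) minus expected inspection spending minus payments made. Maps
#' of this quantity show where a mix pays for itself and where it is a net
#' cost.
#'
#' @inheritParams scenario_metrics
#' @return per-cell net revenue, BRL.
#' @export
net_revenue_map <- function(state, policy, models, cells) {
  scenario_metrics(state, policy, models, cells)$per_cell$net_revenue
}
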