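#' Cost of inspecting a cell's deforestation once
#'
#' The budget cost of covering cell `i` at probability one: the travel cost
#' of reaching the first deforestation patch plus the expected within-cell
#' cost of visiting the remaining patches, `tc_first + n_patches *
#' tc_within`. A plan that inspects cell `i` with probability `p_i` spends
#' `p_i` times this amount in expectation.
#'
#' @param cells a cell data.frame (from a `landscape`) or a `landscape`.
#' @return per-cell inspection cost, BRL.
#' @export
inspection_cost <- function(cells) {
  if (inherits(cells, "landscape")) cells <- cells$cells
  cells$tc_first + cells$n_patches * cells$tc_within
}

.new_plan <- function(p, costs, d_prime) {
  structure(list(p = p, expected_cost = p * costs,
                 total_cost = sum(p * costs),
                 objective = sum(d_prime * p)),
            class = "enforcement_plan")
}

#' Budget-constrained inspection allocation (fractional knapsack)
#'
#' The enforcement agency maximizes the inspected area of deforestation,
#' `sum(d_prime * p)`, subject to the expected-spending constraint
#' `sum(p * costs) <= B` with `0 <= p <= 1`. The continuous relaxation is a
#' fractional knapsack: cells are sorted by deforestation per inspection
#' real, `d_prime / costs`, and receive `p = 1` until the budget is
#' exhausted; at most one cell receives a fractional probability, the rest
#' get 0. Ties in the ratio are broken by ascending cell order for
#' determinism. Ineligible cells (e.g. without baseline deforestation) are
#' never purchased.
#'
#' @param d_prime per-cell deforestation, ha.
#' @param costs per-cell inspection cost (see [inspection_cost()]), BRL.
#' @param B enforcement budget, BRL.
#' @param eligible logical mask of purchasable cells (default all).
#' @return an `enforcement_plan`: per-cell `p`, `expected_cost`,
#'   `total_cost`, and the attained `objective` (ha of inspected
#'   deforestation).
#' @export
allocate_knapsack <- function(d_prime, costs, B, eligible = NULL) {
  n <- length(d_prime)
  stopifnot(length(costs) == n, B >= 0)
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  if (any(eligible & d_prime > 0 & costs <= 0)) {
    stop("cells with positive deforestation must have positive inspection ",
         "cost (unbounded benefit/cost ratio)", call. = FALSE)
  }
  p <- numeric(n)
  idx <- which(eligible & costs > 0)
  if (length(idx) > 0L && B > 0) {
    ratio <- d_prime[idx] / costs[idx]
    ord <- idx[order(-ratio, idx)]
    cum <- cumsum(costs[ord])
    full <- cum <= B
    p[ord[full]] <- 1
    nxt <- which(!full)[1]
    if (!is.na(nxt)) {
      spent <- if (nxt > 1L) cum[nxt - 1L] else 0
      p[ord[nxt]] <- (B - spent) / costs[ord[nxt]]
    }
  }
  .new_plan(p, costs, d_prime)
}

#' Fit the logistic enforcement surface to an allocation
#'
#' Empirically, inspection probabilities look like a logistic function of
#' deforestation levels and inspection costs: high where there is much to
#' inspect cheaply, low in remote low-deforestation cells. This fits
#' `p = plogis(a + b_defor * log1p(d_prime) - b_cost * log1p(costs))` by
#' maximum likelihood to an [allocate_knapsack()] plan, treating the 0/1
#' probabilities as binary outcomes and weighting the fractional cell by its
#' fraction. Knapsack output is typically separable by a ratio threshold, in
#' which case plain ML diverges and a ridge-penalized likelihood (quadratic
#' penalty on the slopes) is used instead.
#'
#' @param plan an `enforcement_plan` with both low and high probabilities.
#' @param d_prime,costs the per-cell inputs the plan was computed from.
#' @param ridge per-observation penalty weight on the slopes, used on
#'   fallback. It controls how sharply the fitted surface separates
#'   inspected from uninspected cells: the penalty keeps the surface a
#'   smooth probability gradient (the multi-year inspection frequency the
#'   surface is meant to represent) rather than a step reproduction of a
#'   single year's bang-bang plan.
#' @return a list of class `enforcement_coefs` with elements `a`, `b_defor`,
#'   `b_cost` and `penalized` (logical).
#' @export
fit_logistic <- function(plan, d_prime, costs, ridge = 0.02) {
  stopifnot(inherits(plan, "enforcement_plan"))
  p <- plan$p
  if (max(p) - min(p) < 1e-12) {
    stop("degenerate plan (all probabilities equal); change the budget so ",
         "that both inspected and uninspected cells exist", call. = FALSE)
  }
  x1 <- log1p(d_prime)
  x2 <- log1p(costs)
  fit <- suppressWarnings(stats::glm(p ~ x1 + x2, family = stats::binomial))
  co <- stats::coef(fit)
  penalized <- !fit$converged || any(!is.finite(co)) || max(abs(co)) > 20
  if (penalized) {
    nll <- function(theta) {
      eta <- theta[1] + theta[2] * x1 + theta[3] * x2
      ll <- p * stats::plogis(eta, log.p = TRUE) +
        (1 - p) * stats::plogis(-eta, log.p = TRUE)
      -mean(ll) + ridge * (theta[2]^2 + theta[3]^2)
    }
    start <- c(0, 1, -1)
    opt <- stats::optim(start, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    co <- opt$par
  }
  structure(list(a = unname(co[1]), b_defor = unname(co[2]),
                 b_cost = -unname(co[3]), penalized = penalized),
            class = "enforcement_coefs")
}

#' Spatialize the enforcement budget through a logistic surface
#'
#' Given logistic coefficients (from [fit_logistic()] or user-supplied),
#' assigns each eligible cell the probability
#' `plogis(a + b_defor * log1p(d_prime) - b_cost * log1p(costs))`, with the
#' intercept `a` recalibrated by root finding so that expected spending
#' `sum(p * costs)` equals the budget. If the budget exceeds total
#' inspection cost, probabilities sit at their ceiling of 1 with a warning;
#' a zero budget drives all probabilities to 0.
#'
#' @param coeffs an `enforcement_coefs` object (or list with `a`, `b_defor`,
#'   `b_cost`).
#' @param d_prime,costs per-cell deforestation (ha) and inspection cost
#'   (BRL).
#' @param B enforcement budget, BRL.
#' @param eligible logical mask of purchasable cells (default all).
#' @param tol relative tolerance on the budget identity.
#' @return an `enforcement_plan`.
#' @export
allocate_logistic <- function(coeffs, d_prime, costs, B, eligible = NULL,
                              tol = 1e-6) {
  n <- length(d_prime)
  stopifnot(length(costs) == n, B >= 0)
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  slope <- coeffs$b_defor * log1p(d_prime) - coeffs$b_cost * log1p(costs)
  p <- numeric(n)
  idx <- which(eligible & costs > 0)
  total <- sum(costs[idx])
  if (length(idx) > 0L && B > 0) {
    if (B >= total) {
      if (B > total) {
        warning("budget exceeds total inspection cost; probabilities ",
                "capped at their ceiling", call. = FALSE)
      }
      p[idx] <- 1
    } else {
      spend <- function(a) sum(stats::plogis(a + slope[idx]) * costs[idx])
      lo <- -40 - max(slope[idx])
      hi <- 40 - min(slope[idx])
      a <- stats::uniroot(function(a) spend(a) - B, c(lo, hi),
                          tol = .Machine$double.eps^0.5)$root
      # polish: the spend function is smooth and strictly increasing
      for (i in 1:5) {
        err <- spend(a) - B
        if (abs(err) <= tol * B) break
        grad <- sum(stats::plogis(a + slope[idx]) *
                      (1 - stats::plogis(a + slope[idx])) * costs[idx])
        a <- a - err / max(grad, .Machine$double.xmin)
      }
      p[idx] <- stats::plogis(a + slope[idx])
    }
  }
  .new_plan(p, costs, d_prime)
}

#' Solve the enforcement / land-use fixed point
#'
#' Land users respond to the enforcement probabilities they expect
#' ([optimal_deforestation()]); the agency allocates its budget against the
#' deforestation it observes ([allocate_knapsack()] or
#' [allocate_logistic()]). The equilibrium is the fixed point of these two
#' best responses.
#'
#' In knapsack mode the fixed point is computed exactly. The greedy
#' allocation is bang-bang, and enforcement suppresses the very
#' deforestation that attracts it, so naive alternation of the two best
#' responses cycles: a cell that is inspected stops deforesting, loses its
#' priority, is dropped, deforests again, and so on. The equilibrium that
#' the cycle averages into — and the one that observed inspection
#' frequencies over repeated years would trace out — is the mixed-strategy
#' fixed point: a benefit/cost threshold `r*` such that cells whose
#' fully-enforced deforestation still clears the threshold are always
#' inspected (`p = 1`), cells whose baseline deforestation does not reach it
#' are never inspected (`p = 0`), and marginal cells receive the interior
#' probability that pins their post-policy ratio `d'(p)/cost` exactly at
#' `r*`, with the budget binding. At that point every marginal cell offers
#' the agency the same return per real, so the allocation attains the
#' knapsack optimum against the equilibrium `d'` (ties at the margin) while
#' land users best-respond to `p`: a genuine fixed point of both decision
#' problems. `r*` is found by root bisection on the spending identity; the
#' returned `residual` is the relative budget error.
#'
#' In logistic mode the best response is smooth and the fixed point is found
#' by damped alternation: each iteration computes `d'` given `p`, the
#' logistic allocation against that `d'`, and moves `p` a fraction `damping`
#' of the way toward it; convergence is declared when no probability would
#' move by more than `tolerance` in a full iteration, and a state that fails
#' to settle within `max_iterations` is returned flagged
#' `converged = FALSE`, never silently. If a two-cycle is detected the step
#' size is halved once. Coefficients are fitted once to the knapsack
#' allocation against baseline deforestation (the agency's historical
#' strategy surface) unless supplied via `coeffs`; within iterations only
#' the intercept is recalibrated to the budget.
#'
#' With `naive_epa = TRUE` the agency targets baseline deforestation `d0`
#' instead of anticipating responses; the allocation is then computed once
#' and no fixed point is needed.
#'
#' @param models a `cell_profit_models` table.
#' @param cells the matching cell table (or `landscape`) supplying
#'   inspection costs.
#' @param policy a [policy_mix()].
#' @param tolerance convergence tolerance on `max |delta p|`.
#' @param max_iterations iteration cap.
#' @param damping step fraction applied to probability updates.
#' @param naive_epa logical; allocate against baseline `d0` only.
#' @param coeffs optional `enforcement_coefs` for logistic mode.
#' @return an object of class `equilibrium_state`: `p`, `d_prime`,
#'   `iterations`, `converged`, `residual`, plus the realized
#'   `enforcement_spending` and the `plan` of the final allocation.
#' @export
solve_equilibrium <- function(models, cells, policy,
                              tolerance = 1e-6, max_iterations = 1000L,
                              damping = 0.5, naive_epa = FALSE,
                              coeffs = NULL) {
  .check_models(models)
  stopifnot(inherits(policy, "policy_mix"), tolerance > 0)
  if (inherits(cells, "landscape")) cells <- cells$cells
  stopifnot(nrow(cells) == nrow(models))
  costs <- inspection_cost(cells)
  eligible <- models$responsive
  d0 <- models$d0

  if (policy$enforcement_mode == "logistic" && is.null(coeffs)) {
    base_plan <- allocate_knapsack(d0, costs, policy$budget, eligible)
    coeffs <- fit_logistic(base_plan, d0, costs)
  }
  respond <- function(p) optimal_deforestation(models, p, policy)
  best_p <- function(dp) {
    plan <- switch(policy$enforcement_mode,
                   knapsack = allocate_knapsack(dp, costs, policy$budget,
                                                eligible),
                   logistic = allocate_logistic(coeffs, dp, costs,
                                                policy$budget, eligible))
    plan
  }

  plan <- best_p(d0)
  p <- plan$p
  if (naive_epa) {
    dp <- respond(p)
    return(structure(list(p = p, d_prime = dp, d0 = d0, iterations = 1L,
                          converged = TRUE, residual = 0,
                          enforcement_spending = plan$total_cost,
                          plan = plan, coeffs = coeffs),
                     class = "equilibrium_state"))
  }

  if (policy$enforcement_mode == "knapsack") {
    return(.solve_knapsack_equilibrium(models, costs, policy, eligible,
                                       tolerance, coeffs))
  }

  p_hist <- list()
  damped_once <- FALSE
  converged <- FALSE
  residual <- Inf
  iter <- 0L
  dp <- d0
  while (iter < max_iterations) {
    iter <- iter + 1L
    dp <- respond(p)
    plan <- best_p(dp)
    residual <- max(abs(plan$p - p))
    if (residual <= tolerance) {
      converged <- TRUE
      break
    }
    # two-cycle detection: p returning to where it was two iterations ago
    if (!damped_once && length(p_hist) >= 2L) {
      back2 <- max(abs(p - p_hist[[length(p_hist) - 1L]]))
      if (back2 < 0.1 * residual) {
        damping <- damping / 2
        damped_once <- TRUE
      }
    }
    p_hist[[length(p_hist) + 1L]] <- p
    if (length(p_hist) > 3L) p_hist <- p_hist[-1L]
    p <- p + damping * (plan$p - p)
  }
  dp <- respond(p)
  final_plan <- .new_plan(p, costs, dp)
  structure(list(p = p, d_prime = dp, d0 = d0, iterations = iter,
                 converged = converged, residual = residual,
                 enforcement_spending = final_plan$total_cost,
                 plan = final_plan, coeffs = coeffs),
            class = "equilibrium_state")
}

# Exact mixed-strategy fixed point for knapsack mode: bisection on the
# marginal benefit/cost threshold r (see solve_equilibrium details).
.solve_knapsack_equilibrium <- function(models, costs, policy, eligible,
                                        tolerance, coeffs) {
  d0 <- models$d0
  n <- length(d0)
  incentive <- policy$fine + policy$pes
  idx <- which(eligible & costs > 0)
  total <- sum(costs[idx])
  B <- policy$budget

  finish <- function(p, iterations, residual) {
    dp <- optimal_deforestation(models, p, policy)
    plan <- .new_plan(p, costs, dp)
    structure(list(p = p, d_prime = dp, d0 = d0, iterations = iterations,
                   converged = TRUE, residual = residual,
                   enforcement_spending = plan$total_cost,
                   plan = plan, coeffs = coeffs),
              class = "equilibrium_state")
  }

  # degenerate budgets and incentive-free mixes need no threshold search
  if (length(idx) == 0L || B <= 0) {
    return(finish(numeric(n), 1L, 0))
  }
  if (B >= total) {
    p <- numeric(n)
    p[idx] <- 1
    return(finish(p, 1L, 0))
  }
  if (incentive <= 0) {
    # land users never respond; the fixed point is the plain allocation
    # against baseline deforestation
    plan <- allocate_knapsack(d0, costs, B, eligible)
    return(finish(plan$p, 1L, 0))
  }

  mu <- models$mu[idx]
  sigma <- models$sigma[idx]
  denom <- models$denominator[idx]
  d0e <- d0[idx]
  ce <- costs[idx]
  d_full <- denom * stats::pnorm((mu - incentive) / sigma)  # d' at p = 1

  p_of_r <- function(r) {
    y <- r * ce  # deforestation a cell must offer to be worth inspecting
    p <- numeric(length(idx))
    p[d_full >= y] <- 1
    interior <- d_full < y & y < d0e
    if (any(interior)) {
      p[interior] <- (mu[interior] - sigma[interior] *
                        stats::qnorm(y[interior] / denom[interior])) /
        incentive
    }
    pmin(pmax(p, 0), 1)
  }
  spend <- function(r) sum(p_of_r(r) * ce)

  r_hi <- max(d0e / ce)
  it <- 0L
  root <- stats::uniroot(function(r) {
    it <<- it + 1L
    spend(r) - B
  }, c(0, r_hi), tol = r_hi * 1e-14)
  pe <- p_of_r(root$root)
  residual <- abs(sum(pe * ce) - B) / B
  p <- numeric(n)
  p[idx] <- pe
  finish(p, it, residual)
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("<equilibrium_state> ", length(x$p), " cells; ",
      if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " iteration(s), residual ",
      format(x$residual, digits = 3), "\n",
      "  total post-policy deforestation: ",
      format(sum(x$d_prime), big.mark = ","), " ha\n", sep = "")
  invisible(x)
}
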