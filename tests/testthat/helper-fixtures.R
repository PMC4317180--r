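# Fixtures and independent oracles shared across tests.

# A hand-written two-cell, one-district landscape.
toy_landscape <- function() {
  landscape(
    cells = data.frame(cell_id = c(1L, 2L), district_id = 1L,
                       area = 40000, d0 = c(8000, 2000),
                       tc_first = c(1000, 3000), tc_within = c(50, 80)),
    districts = data.frame(district_id = 1L, mean_profit = 600)
  )
}

# Build a cell_profit_models table directly from chosen (mu, sigma),
# bypassing calibration, for unit tests of the profit functions.
make_models <- function(mu, sigma, denominator = 40000,
                        district_id = 1L) {
  n <- length(mu)
  rate <- pnorm(mu / sigma)
  out <- data.frame(cell_id = seq_len(n),
                    district_id = rep_len(district_id, n),
                    denominator = rep_len(denominator, n),
                    d0 = rep_len(denominator, n) * rate,
                    rate = rate, mu = mu, sigma = sigma,
                    responsive = TRUE, clamped = FALSE)
  class(out) <- c("cell_profit_models", "data.frame")
  out
}

# Minimal equilibrium_state for testing the metric formulas on stated
# numbers (the state need not arise from the solver).
make_state <- function(p, d_prime, d0, spending = 0) {
  structure(list(p = p, d_prime = d_prime, d0 = d0,
                 iterations = 1L, converged = TRUE, residual = 0,
                 enforcement_spending = spending,
                 plan = NULL, coeffs = NULL),
            class = "equilibrium_state")
}

# Exhaustive LP oracle for the fractional knapsack: every basic feasible
# solution has p = 1 on a subset and at most one fractional cell, so
# enumerating subsets x fractional candidates covers the optimum.
knapsack_enum_oracle <- function(d_prime, costs, B) {
  n <- length(d_prime)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    cs <- sum(costs[sel])
    if (cs > B + 1e-9) next
    val <- sum(d_prime[sel])
    best <- max(best, val)
    for (j in which(!sel)) {
      frac <- min(1, (B - cs) / costs[j])
      best <- max(best, val + frac * d_prime[j])
    }
  }
  best
}

# LP value of the knapsack as a max over greedy fills in every cell order:
# the true-descending-ratio order attains the optimum and all others are
# feasible, so the maximum over all orders is the LP value. Returns the
# n_perm x n matrix of greedy probability vectors for a fixed cost vector,
# so the value at any d' is a vectorized row-max of D %*% t(P).
greedy_fill_matrix <- function(costs, B) {
  n <- length(costs)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n), ,
                 drop = FALSE]
  P <- matrix(0, nrow(perms), n)
  for (k in seq_len(nrow(perms))) {
    left <- B
    for (i in perms[k, ]) {
      take <- min(1, left / costs[i])
      P[k, i] <- take
      left <- left - take * costs[i]
      if (left <= 0) break
    }
  }
  P
}

# Random small landscape + calibrated models for equilibrium tests.
random_small_instance <- function(n_cells = 4L, seed = 1L) {
  set.seed(seed)
  denom <- 40000
  rate <- runif(n_cells, 0.1, 0.6)
  cells <- data.frame(cell_id = seq_len(n_cells), district_id = 1L,
                      area = denom, d0 = rate * denom,
                      tc_first = runif(n_cells, 5000, 60000),
                      tc_within = runif(n_cells, 50, 300))
  ls <- landscape(cells,
                  data.frame(district_id = 1L,
                             mean_profit = runif(1, 400, 1200)))
  list(landscape = ls, models = calibrate_cell_distributions(ls))
}

# Exhaustive product-grid search for the enforcement/land-use equilibrium:
# over a grid of probability vectors, keep budget-feasible points and pick
# the one minimizing the agency's optimality gap
#   gap(p) = LP-value(d'(p)) - sum(d'(p) * p),
# i.e. how far the plan is from a best response to the deforestation it
# induces (land users are exactly on their best response by construction).
# Hierarchical refinement keeps the search exhaustive at increasing
# resolution.
grid_equilibrium_oracle <- function(models, costs, policy,
                                    steps = 11L, refinements = 6L) {
  n <- nrow(models)
  B <- policy$budget
  PFULL <- greedy_fill_matrix(costs, B)
  lo <- rep(0, n)
  hi <- rep(1, n)
  best_p <- NULL
  for (stage in 0:refinements) {
    grids <- lapply(seq_len(n), function(i) {
      seq(lo[i], hi[i], length.out = steps)
    })
    P <- as.matrix(expand.grid(grids))
    feas <- as.vector(P %*% costs) <= B * (1 + 1e-9)
    if (B == 0) feas <- rowSums(P) == 0
    P <- P[feas, , drop = FALSE]
    D <- sapply(seq_len(n), function(i) {
      models$denominator[i] *
        pnorm((models$mu[i] - P[, i] * (policy$fine + policy$pes)) /
                models$sigma[i])
    })
    D <- matrix(D, ncol = n)
    lp_value <- do.call(pmax, as.data.frame(D %*% t(PFULL)))
    gap <- lp_value - rowSums(D * P)
    k <- which.min(gap)
    best_p <- P[k, ]
    width <- (hi - lo) / (steps - 1)
    lo <- pmax(0, best_p - 2 * width)
    hi <- pmin(1, best_p + 2 * width)
  }
  d_prime <- models$denominator *
    pnorm((models$mu - best_p * (policy$fine + policy$pes)) / models$sigma)
  list(p = best_p, d_prime = d_prime, total_d = sum(d_prime))
}
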