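#' Disaggregate district mean profits into cell profit distributions
#'
#' Within each cell, per-hectare profits of deforestation are assumed to be
#' spread over the land area following a normal distribution with location
#' `mu` and scale `sigma` (BRL/ha); land is cleared exactly where profit is
#' positive, so the baseline deforestation rate identifies the standardized
#' location: `pnorm(mu/sigma) = rate`. A single equation per cell cannot pin
#' down two parameters, so `sigma` is taken common within a district and
#' `mu_i = sigma * qnorm(rate_i)`. The district-level constraint — the
#' deforestation-area-weighted average over its cells of the conditional mean
#' profit on cleared land, `E[X | X > 0]`, equals the district's
#' `mean_profit` — is then linear in `sigma` and solves in closed form:
#' `E[X | X > 0] = sigma * (z_i + dnorm(z_i)/rate_i)` with
#' `z_i = qnorm(rate_i)`.
#'
#' Cells without baseline deforestation are unresponsive: they carry no
#' profit distribution, clear nothing at any incentive, and contribute zero
#' weight to the district constraint. Rates are clamped to
#' `[clamp, 1 - clamp]` before `qnorm` (the quantile diverges at 0 and 1);
#' clamped cells are flagged and their model baseline `d0` is the clamped
#' rate times the denominator.
#'
#' @param landscape a `landscape`.
#' @param denominator column of the cell table used as the rate denominator:
#'   `"area"` (default) or another supplied column such as remaining forest
#'   area.
#' @param clamp clamping bound for baseline rates.
#' @return a data.frame of class `cell_profit_models`, one row per cell with
#'   columns `cell_id`, `district_id`, `denominator` (ha), `d0` (model
#'   baseline, ha), `rate`, `mu`, `sigma` (BRL/ha), `responsive`, `clamped`.
#'   Unresponsive cells have `mu`/`sigma` set to `NA`.
#' @export
calibrate_cell_distributions <- function(landscape,
                                         denominator = "area",
                                         clamp = 1e-6) {
  validate_landscape(landscape)
  cells <- landscape$cells
  if (!denominator %in% names(cells)) {
    stop("denominator column not found in cell table: ", denominator,
         call. = FALSE)
  }
  denom <- cells[[denominator]]
  if (any(denom <= 0)) stop("rate denominator must be positive",
                            call. = FALSE)
  raw_rate <- cells$d0 / denom
  responsive <- cells$d0 > 0
  rate <- pmin(pmax(raw_rate, clamp), 1 - clamp)
  clamped <- responsive & (rate != raw_rate)

  mu <- rep(NA_real_, nrow(cells))
  sigma <- rep(NA_real_, nrow(cells))
  z <- stats::qnorm(rate)
  # per-cell conditional positive mean in units of sigma
  g <- z + stats::dnorm(z) / rate

  for (d in landscape$districts$district_id) {
    in_d <- cells$district_id == d & responsive
    if (!any(in_d)) next
    mean_profit <- landscape$districts$mean_profit[
      landscape$districts$district_id == d]
    if (!(mean_profit > 0)) {
      stop("district ", d, " has deforesting cells but mean_profit <= 0",
           call. = FALSE)
    }
    w <- cells$d0[in_d]
    gbar <- sum(w * g[in_d]) / sum(w)
    s <- mean_profit / gbar  # gbar > 0 always, so sigma > 0
    sigma[in_d] <- s
    mu[in_d] <- s * z[in_d]
  }

  d0_model <- ifelse(responsive, rate * denom, 0)
  out <- data.frame(cell_id = cells$cell_id,
                    district_id = cells$district_id,
                    denominator = denom,
                    d0 = d0_model,
                    rate = ifelse(responsive, rate, 0),
                    mu = mu, sigma = sigma,
                    responsive = responsive,
                    clamped = clamped)
  class(out) <- c("cell_profit_models", "data.frame")
  out
}

.check_models <- function(models) {
  if (!inherits(models, "cell_profit_models")) {
    stop("expected a cell_profit_models object from ",
         "calibrate_cell_distributions()", call. = FALSE)
  }
  invisible(models)
}

#' Marginal per-hectare profit of deforestation
#'
#' The profit of clearing the marginal hectare once `d` hectares are already
#' cleared: hectares are cleared in decreasing order of profit, so the
#' marginal profit is the `(1 - d/denominator)` quantile of the cell's normal
#' profit distribution. It is strictly decreasing in `d` and equals zero
#' exactly at the model baseline `d0` (the unregulated optimum: clear while
#' profit is positive).
#'
#' @param models a `cell_profit_models` table.
#' @param d deforestation level(s), ha; recycled against the rows of
#'   `models`. Must satisfy `0 <= d < denominator`.
#' @return marginal profit, BRL/ha (`+Inf` at `d = 0`; `NA` for unresponsive
#'   cells).
#' @export
marginal_profit <- function(models, d) {
  .check_models(models)
  n <- nrow(models)
  d <- rep_len(d, n)
  if (any(d < 0 | d >= models$denominator)) {
    stop("d must satisfy 0 <= d < denominator", call. = FALSE)
  }
  out <- rep(NA_real_, n)
  r <- models$responsive
  out[r] <- models$mu[r] +
    models$sigma[r] * stats::qnorm(1 - d[r] / models$denominator[r])
  out
}

#' Total profit of deforestation
#'
#' `f(d)`: the integral of [marginal_profit()] from 0 to `d`, i.e. the summed
#' profit of the `d` most profitable hectares. Uses the closed-form
#' antiderivative of the normal quantile,
#' `f(d) = mu*d + denominator*sigma*dnorm(qnorm(1 - d/denominator))`.
#' Concave in `d` and maximized at the baseline `d0`. Unresponsive cells
#' return 0.
#'
#' @inheritParams marginal_profit
#' @return total profit, BRL.
#' @export
total_profit <- function(models, d) {
  .check_models(models)
  n <- nrow(models)
  d <- rep_len(d, n)
  if (any(d < 0 | d >= models$denominator)) {
    stop("d must satisfy 0 <= d < denominator", call. = FALSE)
  }
  out <- numeric(n)
  r <- models$responsive
  out[r] <- models$mu[r] * d[r] + models$denominator[r] * models$sigma[r] *
    stats::dnorm(stats::qnorm(1 - d[r] / models$denominator[r]))
  out
}

#' Avoided-deforestation cost curve
#'
#' For a grid of effectively delivered per-hectare incentives `s`, computes
#' the total deforestation avoided relative to baseline when every land user
#' faces `s` at the margin: per responsive cell,
#' `avoided_i(s) = d0_i - denominator_i * pnorm((mu_i - s)/sigma_i)`.
#' The curve starts at 0, is non-decreasing, and approaches the total
#' baseline deforestation asymptotically as `s` grows (no payment can avoid
#' more deforestation than the baseline).
#'
#' @param models a `cell_profit_models` table.
#' @param incentives non-negative incentive grid, BRL/ha.
#' @return a data.frame of class `cost_curve` with columns `incentive` and
#'   `avoided` (ha); attribute `per_cell` holds the cells x incentives matrix
#'   of per-cell avoided deforestation (responsive cells only, rownames =
#'   cell_id) for percentile banding across cells.
#' @export
cost_curve <- function(models, incentives) {
  .check_models(models)
  if (any(incentives < 0)) stop("incentives must be non-negative",
                                call. = FALSE)
  r <- which(models$responsive)
  per_cell <- vapply(incentives, function(s) {
    # clamp at 0: an incentive can never raise deforestation above the
    # baseline, and pnorm(qnorm(rate)) roundoff must not leak through
    pmax(0, models$d0[r] - models$denominator[r] *
           stats::pnorm((models$mu[r] - s) / models$sigma[r]))
  }, numeric(length(r)))
  per_cell <- matrix(per_cell, nrow = length(r),
                     dimnames = list(models$cell_id[r], NULL))
  out <- data.frame(incentive = incentives,
                    avoided = colSums(per_cell))
  attr(out, "per_cell") <- per_cell
  attr(out, "total_baseline") <- sum(models$d0)
  class(out) <- c("cost_curve", "data.frame")
  out
}
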