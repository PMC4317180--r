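#' Configuration for the synthetic landscape generator
#'
#' Bundles the parameters of [generate_synthetic_landscape()]. Defaults
#' emulate the structure of an enforcement landscape like the Brazilian
#' Amazon at the 20 x 20 km cell scale: strongly right-skewed baseline
#' deforestation rates (median around 2% of cell area per year, a long tail
#' of frontier cells), travel costs that grow with remoteness from a single
#' access point, and per-hectare profits that are negatively correlated with
#' inspection costs (remote land is cheap to farm but expensive to police).
#'
#' @param n_cells_x,n_cells_y grid dimensions (cells).
#' @param n_districts number of districts tiling the grid.
#' @param seed RNG seed; generation is bit-reproducible for a fixed seed.
#' @param cell_size_km cell edge length, km (default 20, i.e. 40,000 ha).
#' @param mean_profit_range range of district mean per-hectare profits,
#'   BRL/ha.
#' @param rate_median median baseline deforestation rate (fraction of cell
#'   area cleared per year).
#' @param rate_spread logit-scale loading of the profit gradient on
#'   deforestation rates (larger = stronger spatial heterogeneity).
#' @param rate_noise_sd logit-scale idiosyncratic noise on rates.
#' @param tc_base travel cost of inspecting a patch adjacent to the access
#'   point, BRL.
#' @param tc_slope marginal travel cost, BRL per km of distance from the
#'   access point.
#' @param tc_noise_sd lognormal noise on travel costs (multiplicative).
#' @param tc_within_range range of the per-additional-patch inspection cost,
#'   BRL.
#' @param patches_per_ha patch density coefficient (see
#'   [patches_from_area()]).
#' @param target_cost_profit_correlation target Pearson correlation between
#'   the cell-level profit proxy and the travel-cost surface; the default
#'   -0.33 mirrors the empirical pattern that high-opportunity-cost frontier
#'   cells are cheap to reach.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells_x = 20L, n_cells_y = 20L,
                             n_districts = 9L, seed = 1L,
                             cell_size_km = 20,
                             mean_profit_range = c(200, 1500),
                             rate_median = 0.02,
                             rate_spread = 1.2,
                             rate_noise_sd = 0.8,
                             tc_base = 2000,
                             tc_slope = 25,
                             tc_noise_sd = 0.15,
                             tc_within_range = c(100, 400),
                             patches_per_ha = 0.035,
                             target_cost_profit_correlation = -0.33) {
  cfg <- list(n_cells_x = as.integer(n_cells_x),
              n_cells_y = as.integer(n_cells_y),
              n_districts = as.integer(n_districts),
              seed = as.integer(seed),
              cell_size_km = cell_size_km,
              mean_profit_range = mean_profit_range,
              rate_median = rate_median,
              rate_spread = rate_spread,
              rate_noise_sd = rate_noise_sd,
              tc_base = tc_base,
              tc_slope = tc_slope,
              tc_noise_sd = tc_noise_sd,
              tc_within_range = tc_within_range,
              patches_per_ha = patches_per_ha,
              target_cost_profit_correlation = target_cost_profit_correlation)
  stopifnot(cfg$n_cells_x >= 1L, cfg$n_cells_y >= 1L, cfg$n_districts >= 1L,
            cfg$cell_size_km > 0,
            length(cfg$mean_profit_range) == 2L,
            all(cfg$mean_profit_range > 0),
            cfg$rate_median > 0, cfg$rate_median < 1,
            cfg$tc_base >= 0, cfg$tc_slope >= 0,
            cfg$target_cost_profit_correlation >= -1,
            cfg$target_cost_profit_correlation <= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

# Run expr with a private RNG stream so generation neither depends on nor
# disturbs the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a seeded synthetic landscape
#'
#' Builds a rectangular grid of cells with (i) a travel-cost surface that
#' increases with distance from an access point in one corner, (ii) a latent
#' per-hectare profit gradient, and (iii) baseline deforestation rates driven
#' by that gradient. Profit and travel cost share the latent remoteness axis
#' with opposite-signed loadings; the loading magnitude is tuned by bisection
#' so that the realized Pearson correlation between the cell profit proxy and
#' the travel-cost surface hits the configured target. Districts tile the
#' grid into contiguous blocks and receive mean profits spanning
#' `mean_profit_range`.
#'
#' @param config a [synthetic_config()].
#' @return a validated `landscape`; `metadata` records the seed, the config,
#'   the tuned loading and the realized profit/cost correlation, and the cell
#'   table carries `x`, `y` centroids (km).
#' @export
generate_synthetic_landscape <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n <- cfg$n_cells_x * cfg$n_cells_y
  .with_seed(cfg$seed, {
    ix <- rep(seq_len(cfg$n_cells_x), times = cfg$n_cells_y)
    iy <- rep(seq_len(cfg$n_cells_y), each = cfg$n_cells_x)
    x <- (ix - 0.5) * cfg$cell_size_km
    y <- (iy - 0.5) * cfg$cell_size_km
    dist_km <- sqrt(x^2 + y^2)  # access point at the (0, 0) corner

    noise_tc <- stats::rnorm(n)
    noise_profit <- stats::rnorm(n)
    noise_rate <- stats::rnorm(n)
    tc_within <- stats::runif(n, cfg$tc_within_range[1],
                              cfg$tc_within_range[2])

    tc_first <- cfg$tc_base + cfg$tc_slope * dist_km *
      exp(cfg$tc_noise_sd * noise_tc - cfg$tc_noise_sd^2 / 2)

    rem <- if (n > 1L) as.vector(scale(dist_km)) else 0
    eps <- if (n > 1L) as.vector(scale(noise_profit)) else 0
    proxy_for <- function(lambda) -lambda * rem + sqrt(1 - lambda^2) * eps

    if (n > 2L) {
      cor_at <- function(lambda) stats::cor(proxy_for(lambda), tc_first)
      lo <- cor_at(1)   # most negative achievable correlation
      hi <- cor_at(0)   # pure-noise correlation, approximately zero
      target <- cfg$target_cost_profit_correlation
      if (target < min(lo, hi) - 1e-9 || target > max(lo, hi) + 1e-9) {
        stop("target profit/cost correlation ", signif(target, 3),
             " is outside the achievable range [", signif(min(lo, hi), 3),
             ", ", signif(max(lo, hi), 3),
             "]; adjust tc_slope, tc_noise_sd or the target", call. = FALSE)
      }
      f <- function(lambda) cor_at(lambda) - target
      lambda <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
    } else {
      lambda <- 0
    }
    profit_z <- proxy_for(lambda)

    rate <- stats::plogis(stats::qlogis(cfg$rate_median) +
                            cfg$rate_spread * profit_z +
                            cfg$rate_noise_sd * noise_rate)
    area <- rep((cfg$cell_size_km * 100)^2 / 100, n)  # km^2 -> ha
    d0 <- rate * area

    # Contiguous rectangular district blocks; surplus blocks merge into the
    # last district so the count is exact.
    gx <- max(1L, floor(sqrt(cfg$n_districts)))
    gy <- as.integer(ceiling(cfg$n_districts / gx))
    bx <- pmin(gx, 1L + ((ix - 1L) * gx) %/% cfg$n_cells_x)
    by <- pmin(gy, 1L + ((iy - 1L) * gy) %/% cfg$n_cells_y)
    district_id <- pmin(cfg$n_districts, (by - 1L) * gx + bx)
    district_id <- match(district_id, sort(unique(district_id)))

    # District mean profits: map the district-average profit proxy linearly
    # into mean_profit_range so richer (less remote) districts carry higher
    # conservation opportunity costs.
    dz <- tapply(profit_z, district_id, mean)
    rng <- range(dz)
    frac <- if (diff(rng) > 0) (dz - rng[1]) / diff(rng) else rep(0.5,
                                                                 length(dz))
    mean_profit <- cfg$mean_profit_range[1] +
      frac * diff(cfg$mean_profit_range)

    cells <- data.frame(cell_id = seq_len(n),
                        district_id = as.integer(district_id),
                        area = area, d0 = d0,
                        tc_first = tc_first, tc_within = tc_within,
                        n_patches = patches_from_area(d0,
                                                      cfg$patches_per_ha),
                        x = x, y = y)
    districts <- data.frame(district_id = sort(unique(district_id)),
                            mean_profit = as.numeric(mean_profit))
    realized <- if (n > 2L) stats::cor(profit_z, tc_first) else NA_real_
    landscape(cells, districts,
              metadata = list(source = "synthetic", seed = cfg$seed,
                              config = cfg, lambda = lambda,
                              realized_cost_profit_correlation = realized,
                              profit_proxy = profit_z),
              patches_per_ha = cfg$patches_per_ha)
  })
}
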