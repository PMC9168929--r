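#' Default Monte Carlo parameter ranges for the melting model
#'
#' Ranges and sampling laws for the batch-melting Monte Carlo: pressure and
#' solidus temperature uniform over the crustal column (0-0.5 GPa,
#' 1400-1445 K); source-rock CO2 log-uniform 50-1000 ppm and H2O log-uniform
#' 0.01-0.5 wt% (Earth-like mantle values); melt fraction uniform 0.05-0.3;
#' melt production log-uniform 1-100 km^3/y. All fields can be overridden to
#' drop in alternative calibrations.
#'
#' @param pressure,temperature,melt_fraction Length-2 `c(min, max)` bounds,
#'   sampled uniformly.
#' @param source_co2,source_h2o,melt_production Length-2 bounds, sampled
#'   log-uniformly.
#' @return A named list of class `melting_ranges`.
#' @export
melting_parameter_ranges <- function(pressure = c(0, 0.5),
                                     temperature = c(1400, 1445),
                                     source_co2 = c(50e-6, 1000e-6),
                                     source_h2o = c(1e-4, 5e-3),
                                     melt_fraction = c(0.05, 0.3),
                                     melt_production = c(1, 100)) {
  rng <- list(pressure = pressure, temperature = temperature,
              source_co2 = source_co2, source_h2o = source_h2o,
              melt_fraction = melt_fraction, melt_production = melt_production)
  for (nm in names(rng)) {
    v <- rng[[nm]]
    if (length(v) != 2 || !is.numeric(v) || v[1] > v[2]) {
      stop("range '", nm, "' must be numeric c(min, max)", call. = FALSE)
    }
  }
  structure(rng, class = "melting_ranges")
}

.runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# draw n melting scenarios (vectorised fields in one object)
.draw_scenarios <- function(ranges, n) {
  melting_scenario(
    pressure        = stats::runif(n, ranges$pressure[1], ranges$pressure[2]),
    temperature     = stats::runif(n, ranges$temperature[1], ranges$temperature[2]),
    delta_iw        = rep(0, n),
    source_co2      = .runif_log(n, ranges$source_co2[1], ranges$source_co2[2]),
    source_h2o      = .runif_log(n, ranges$source_h2o[1], ranges$source_h2o[2]),
    melt_fraction   = stats::runif(n, ranges$melt_fraction[1], ranges$melt_fraction[2]),
    melt_production = .runif_log(n, ranges$melt_production[1], ranges$melt_production[2])
  )
}

#' Monte Carlo graphite-sequestration curve versus oxygen fugacity
#'
#' For each oxygen fugacity on a delta-IW grid, propagates the batch-melting
#' partition over `n_draws` random scenarios and summarises the fraction of
#' source carbon retained as graphite by its mean and a 95% confidence
#' interval (2.5/97.5 percentiles). One common set of parameter draws is
#' reused across the whole fO2 grid (common random numbers), which removes
#' sampling jitter between adjacent grid points and preserves the exact
#' monotonic decline of graphite retention with increasing fO2.
#'
#' @param ranges A [melting_parameter_ranges()] object.
#' @param n_draws Number of Monte Carlo draws per grid point (>= 100).
#' @param seed Integer seed; mandatory so every curve is reproducible.
#' @param delta_iw_grid Oxygen fugacities (log10 offsets from the IW buffer)
#'   at which to evaluate; default integer steps from -11 to +5.
#' @return A data frame of class `graphite_mc_summary` with columns
#'   `delta_iw`, `mean`, `ci95_low`, `ci95_high`, plus attributes `n_draws`
#'   and `seed`.
#' @examples
#' mc <- monte_carlo_graphite_curve(n_draws = 500, seed = 1)
#' mc[mc$delta_iw == -2, ]
#' @export
monte_carlo_graphite_curve <- function(ranges = melting_parameter_ranges(),
                                       n_draws = 10000, seed,
                                       delta_iw_grid = -11:5) {
  stopifnot(inherits(ranges, "melting_ranges"))
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  if (length(delta_iw_grid) == 0) stop("delta_iw_grid is empty", call. = FALSE)
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sc <- .draw_scenarios(ranges, n_draws)

  out <- lapply(delta_iw_grid, function(diw) {
    sc$delta_iw <- rep(diw, n_draws)
    gf <- batch_partition(sc)$graphite_fraction
    q <- stats::quantile(gf, c(0.025, 0.975), names = FALSE)
    data.frame(delta_iw = diw, mean = mean(gf),
               ci95_low = q[1], ci95_high = q[2])
  })
  res <- do.call(rbind, out)
  attr(res, "n_draws") <- n_draws
  attr(res, "seed") <- seed
  class(res) <- c("graphite_mc_summary", "data.frame")
  res
}

#' @export
plot.graphite_mc_summary <- function(x, ...) {
  graphics::plot(x$delta_iw, x$mean, type = "l", ylim = c(0, 1.05),
                 xlab = expression(Delta * "IW (log10 units)"),
                 ylab = "graphite / initial carbon", ...)
  graphics::polygon(c(x$delta_iw, rev(x$delta_iw)),
                    c(x$ci95_low, rev(x$ci95_high)),
                    border = NA, col = grDevices::adjustcolor("grey40", 0.3))
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
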