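#' Generate a synthetic planet-scenario ensemble
#'
#' Seeded generators for the archetypal planet populations the assessment
#' framework must distinguish. Each archetype draws scenario parameters
#' from distributions anchored where possible to published ranges, and
#' fills in the tri-state context fields an observer of that archetype
#' would plausibly establish:
#'
#' * `archean_inhabited` - anoxic N2-CO2 world with a methane-cycling
#'   biosphere: f_CH4 log-uniform in `[1e-3, 1e-2]` (100-10,000 times
#'   modern), CO/CH4 log-uniform in `[0.03, 0.3]`, CO2 abundant, low water
#'   fraction, old star; all gating fields `TRUE`.
#' * `reduced_mantle_world` - ultrareduced interior: delta-IW uniform in
#'   `[-11, -2]`, with a full [melting_scenario()] drawn from
#'   [melting_parameter_ranges()] per scenario.
#' * `serpentinizing_world` - abiotic water-rock CH4 only: f_CH4 log-uniform
#'   in `[1e-5, 3e-4]` (below the biogenic abundance threshold), elevated
#'   CO/CH4 log-uniform in `[3, 300]`.
#' * `melted_exotitan` - volatile-rich migrant: water mass fraction
#'   log-uniform in `[1e-4, 1e-1]`, CH4 inventory uniform in `[1e-4, 1e-2]`,
#'   carried as a [planet_volatile_inventory()]; bulk density flagged
#'   non-terrestrial above 1 wt% water.
#' * `oxic_inhabited` - modern-Earth-like O2-rich atmosphere (fails the
#'   anoxic gate): f_CH4 log-uniform in `[1e-7, 1e-5]`, f_O2 near 0.2.
#' * `h2_dominated` - low mean-molecular-weight envelope (fails the
#'   high-MMW gate): f_H2 uniform in `[0.7, 0.95]`.
#'
#' @param archetype One of the six archetype names above.
#' @param n Number of scenarios (>= 1).
#' @param seed Integer seed; generation is reproducible.
#' @return An object of class `scenario_ensemble`: a list with `archetype`,
#'   `seed`, `n` and `scenarios`, a list whose elements each hold a
#'   `context` ([planet_context()]) plus, per archetype, a `melting`
#'   ([melting_scenario()]) or `inventory` ([planet_volatile_inventory()]).
#' @examples
#' ens <- generate_scenarios("archean_inhabited", n = 5, seed = 42)
#' sapply(ens$scenarios, function(s) as.character(assess_scenario(s$context)$verdict))
#' @export
generate_scenarios <- function(archetype, n, seed) {
  archetypes <- c("archean_inhabited", "reduced_mantle_world",
                  "serpentinizing_world", "melted_exotitan",
                  "oxic_inhabited", "h2_dominated")
  if (!archetype %in% archetypes) {
    stop("unknown archetype '", archetype, "'; must be one of: ",
         paste(archetypes, collapse = ", "), call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  scenarios <- switch(
    archetype,
    archean_inhabited = {
      f_ch4 <- .runif_log(n, 1e-3, 1e-2)
      co_ch4 <- .runif_log(n, 0.03, 0.3)
      f_co2 <- stats::runif(n, 0.02, 0.2)
      age <- stats::runif(n, 2e9, 8e9)
      lapply(seq_len(n), function(i) list(context = planet_context(
        TRUE, TRUE, TRUE, TRUE, stellar_age = age[i],
        water_mass_fraction_estimate = stats::runif(1, 1e-4, 2e-3),
        atmosphere = atmosphere_state(f_ch4 = f_ch4[i], f_co2 = f_co2[i],
                                      f_co = co_ch4[i] * f_ch4[i]))))
    },
    reduced_mantle_world = {
      rng <- melting_parameter_ranges()
      diw <- stats::runif(n, -11, -2)
      lapply(seq_len(n), function(i) {
        sc <- .draw_scenarios(rng, 1)
        sc$delta_iw <- diw[i]
        list(context = planet_context(TRUE, TRUE, TRUE, TRUE,
                                      stellar_age = stats::runif(1, 2e9, 8e9),
                                      atmosphere = atmosphere_state(
                                        f_ch4 = .runif_log(1, 1e-6, 1e-4),
                                        f_co2 = stats::runif(1, 0.01, 0.1),
                                        f_co = .runif_log(1, 1e-4, 1e-2))),
             melting = sc)
      })
    },
    serpentinizing_world = {
      f_ch4 <- .runif_log(n, 1e-5, 3e-4)
      ratio <- .runif_log(n, 3, 300)
      lapply(seq_len(n), function(i) list(context = planet_context(
        TRUE, TRUE, TRUE, TRUE, stellar_age = stats::runif(1, 2e9, 8e9),
        water_mass_fraction_estimate = stats::runif(1, 1e-4, 5e-3),
        atmosphere = atmosphere_state(f_ch4 = f_ch4[i],
                                      f_co2 = stats::runif(1, 0.01, 0.3),
                                      f_co = ratio[i] * f_ch4[i]))))
    },
    melted_exotitan = {
      wmf <- .runif_log(n, 1e-4, 1e-1)
      inv <- stats::runif(n, 1e-4, 1e-2)
      lapply(seq_len(n), function(i) list(
        context = planet_context(wmf[i] < 0.01, TRUE, TRUE, TRUE,
                                 stellar_age = stats::runif(1, 2e9, 8e9),
                                 water_mass_fraction_estimate = wmf[i],
                                 atmosphere = atmosphere_state(f_ch4 = 0.10,
                                                               f_co2 = 0.05)),
        inventory = planet_volatile_inventory(wmf[i], inv[i])))
    },
    oxic_inhabited = {
      f_ch4 <- .runif_log(n, 1e-7, 1e-5)
      lapply(seq_len(n), function(i) list(context = planet_context(
        TRUE, TRUE, TRUE, FALSE, stellar_age = stats::runif(1, 2e9, 8e9),
        water_mass_fraction_estimate = stats::runif(1, 1e-4, 2e-3),
        atmosphere = atmosphere_state(f_ch4 = f_ch4[i],
                                      f_co2 = stats::runif(1, 1e-4, 1e-3),
                                      f_o2 = stats::runif(1, 0.15, 0.25)))))
    },
    h2_dominated = {
      f_h2 <- stats::runif(n, 0.7, 0.95)
      lapply(seq_len(n), function(i) list(context = planet_context(
        FALSE, TRUE, FALSE, TRUE, stellar_age = stats::runif(1, 2e9, 8e9),
        atmosphere = atmosphere_state(mean_molar_mass = 0.004,
                                      f_ch4 = .runif_log(1, 1e-4, 1e-2),
                                      f_h2 = f_h2[i]))))
    }
  )

  structure(list(archetype = archetype, seed = seed, n = n,
                 scenarios = scenarios),
            class = "scenario_ensemble")
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat("<scenario_ensemble>", x$archetype, "- n =", x$n, ", seed =", x$seed, "\n")
  invisible(x)
}
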