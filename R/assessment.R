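#' Planetary context for biosignature assessment
#'
#' Everything known (or unknown) about a planet that bears on whether its
#' atmospheric methane could be biogenic. Tri-state fields take `TRUE`,
#' `FALSE` or `NA` (unknown); unknowns propagate through the rule engine
#' and cap how strong a verdict can be claimed.
#'
#' @param bulk_density_terrestrial Is the bulk density terrestrial (ruling
#'   out large surface volatile reservoirs)? `TRUE`/`FALSE`/`NA`.
#' @param in_habitable_zone Tri-state.
#' @param high_mean_molecular_weight_atm Is the atmosphere high mean
#'   molecular weight (not H2-dominated)? Tri-state.
#' @param anoxic Is the atmosphere anoxic? Tri-state.
#' @param stellar_age Host-star age in years, or `NA`.
#' @param water_mass_fraction_estimate Estimated water mass fraction of the
#'   planet, or `NA`.
#' @param atmosphere An [atmosphere_state()].
#' @return An object of class `planet_context`.
#' @examples
#' ctx <- planet_context(TRUE, TRUE, TRUE, TRUE, stellar_age = 4.5e9,
#'                       water_mass_fraction_estimate = 3e-4,
#'                       atmosphere = atmosphere_state(f_ch4 = 5e-3,
#'                                                     f_co2 = 0.1, f_co = 5e-4))
#' assess_scenario(ctx)
#' @export
planet_context <- function(bulk_density_terrestrial = NA,
                           in_habitable_zone = NA,
                           high_mean_molecular_weight_atm = NA,
                           anoxic = NA,
                           stellar_age = NA_real_,
                           water_mass_fraction_estimate = NA_real_,
                           atmosphere = atmosphere_state()) {
  tri <- list(bulk_density_terrestrial = bulk_density_terrestrial,
              in_habitable_zone = in_habitable_zone,
              high_mean_molecular_weight_atm = high_mean_molecular_weight_atm,
              anoxic = anoxic)
  for (nm in names(tri)) {
    if (!is.logical(tri[[nm]]) || length(tri[[nm]]) != 1) {
      stop("'", nm, "' must be TRUE, FALSE or NA", call. = FALSE)
    }
  }
  stopifnot(inherits(atmosphere, "atmosphere_state"))
  structure(
    c(tri, list(stellar_age = as.numeric(stellar_age),
                water_mass_fraction_estimate = as.numeric(water_mass_fraction_estimate),
                atmosphere = atmosphere)),
    class = "planet_context"
  )
}

# criteria names, in lattice order of reporting; first four are gating
.criteria_names <- c("terrestrial_density", "habitable_zone",
                     "high_mmw_atmosphere", "anoxic",
                     "ch4_abundant", "flux_exceeds_abiotic", "co2_detected",
                     "co_ch4_low", "water_fraction_low", "star_old")
.gating_criteria <- .criteria_names[1:4]

.verdict_levels <- c("not_assessable", "unlikely_biogenic",
                     "possible_abiotic_false_positive",
                     "candidate_biosignature_seek_corroboration")

#' Evaluate biosignature criteria for a planet context
#'
#' Scores each criterion of the methane-biosignature framework as `TRUE`
#' (pass), `FALSE` (fail) or `NA` (unknown). Gating criteria (terrestrial
#' density, habitable zone, high mean molecular weight, anoxic) establish
#' that the planet is one where methane is informative at all; evidence
#' criteria score the methane itself: mixing ratio above 1e-3, implied
#' surface flux above the ~10 Tmol/y ceiling of known abiotic sources,
#' CO2 detected alongside, CO/CH4 below 1, water mass fraction below 1 wt%
#' (ruling out a long-lived melted exo-Titan), and a host star old enough
#' to outlive impact-generated transients.
#'
#' @param ctx A [planet_context()].
#' @param implied_flux Implied CH4 surface flux in Tmol/y (e.g. from
#'   [implied_surface_flux()]), or `NA` if not inferable.
#' @param min_stellar_age Age (years) beyond which impact transients and
#'   melted exo-Titan atmospheres should have dissipated; default 1e9.
#' @return A named logical vector over the ten criteria, with an
#'   `annotations` attribute collecting qualitative notes (e.g. a CO/CH4
#'   ratio below 0.1, a strong sign of a methane-cycling biosphere).
#' @export
evaluate_criteria <- function(ctx, implied_flux = NA_real_,
                              min_stellar_age = 1e9) {
  stopifnot(inherits(ctx, "planet_context"))
  f <- ctx$atmosphere$mixing_ratios
  bm <- ch4_benchmarks()

  co_ch4 <- if (is.na(f[["co"]]) || is.na(f[["ch4"]]) || f[["ch4"]] == 0) {
    NA_real_
  } else f[["co"]] / f[["ch4"]]

  flags <- c(
    terrestrial_density  = ctx$bulk_density_terrestrial,
    habitable_zone       = ctx$in_habitable_zone,
    high_mmw_atmosphere  = ctx$high_mean_molecular_weight_atm,
    anoxic               = ctx$anoxic,
    ch4_abundant         = .na_gt(f[["ch4"]], bm$ch4_abundance_threshold),
    flux_exceeds_abiotic = .na_gt(implied_flux, bm$abiotic_plausibility_ceiling),
    co2_detected         = .na_gt(f[["co2"]], 0),
    co_ch4_low           = .na_lt(co_ch4, bm$co_ch4_threshold),
    water_fraction_low   = .na_lt(ctx$water_mass_fraction_estimate, 0.01),
    star_old             = .na_gt(ctx$stellar_age, min_stellar_age)
  )

  ann <- character(0)
  if (!is.na(co_ch4) && co_ch4 < bm$co_ch4_strong_biogenic) {
    ann <- c(ann, "co_ch4_below_0.1_strong_biogenic_sign")
  }
  attr(flags, "annotations") <- ann
  flags
}

.na_gt <- function(x, thr) if (is.na(x)) NA else x > thr
.na_lt <- function(x, thr) if (is.na(x)) NA else x < thr

#' Classify a criteria flag map into a verdict
#'
#' Deterministic mapping from the ten criterion flags to one of four
#' verdicts, ordered `not_assessable < unlikely_biogenic <
#' possible_abiotic_false_positive < candidate_biosignature_seek_corroboration`:
#'
#' * all flags unknown: `not_assessable`;
#' * any gating criterion fails, or methane is not abundant:
#'   `unlikely_biogenic` (the planet is not one where abundant methane
#'   demands a biosphere);
#' * every flag passes: `candidate_biosignature_seek_corroboration`;
#' * otherwise (some mix of unknowns and evidence failures):
#'   `possible_abiotic_false_positive`, with the matching false-positive
#'   hypotheses named in `notes`.
#'
#' Unknowns never upgrade a verdict: an unmeasured criterion caps the
#' outcome at `possible_abiotic_false_positive`.
#'
#' @param flags Named logical vector over the ten criteria (from
#'   [evaluate_criteria()]).
#' @return An object of class `assessment_verdict`: a list with `verdict`,
#'   `criteria_flags` and `notes` (triggered false-positive hypotheses and
#'   annotations).
#' @export
classify_verdict <- function(flags) {
  miss <- setdiff(.criteria_names, names(flags))
  if (length(miss)) {
    stop("missing criteria flags: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  flags_v <- as.logical(flags[.criteria_names])
  names(flags_v) <- .criteria_names

  gating <- flags_v[.gating_criteria]
  verdict <- if (all(is.na(flags_v))) {
    "not_assessable"
  } else if (any(!gating, na.rm = TRUE) || isFALSE(flags_v[["ch4_abundant"]])) {
    "unlikely_biogenic"
  } else if (!anyNA(flags_v) && all(flags_v)) {
    "candidate_biosignature_seek_corroboration"
  } else {
    "possible_abiotic_false_positive"
  }

  notes <- character(0)
  if (isFALSE(flags_v[["co_ch4_low"]]))
    notes <- c(notes, "reduced_mantle_outgassing")
  if (isFALSE(flags_v[["flux_exceeds_abiotic"]]))
    notes <- c(notes, "serpentinization")
  if (!isTRUE(flags_v[["star_old"]]))
    notes <- c(notes, "impact_transient")
  if (!isTRUE(flags_v[["water_fraction_low"]]))
    notes <- c(notes, "melted_exotitan")
  notes <- c(notes, attr(flags, "annotations"))

  structure(
    list(verdict = factor(verdict, levels = .verdict_levels),
         criteria_flags = flags_v, notes = notes),
    class = "assessment_verdict"
  )
}

#' @export
print.assessment_verdict <- function(x, ...) {
  cat("<assessment_verdict>", as.character(x$verdict), "\n")
  st <- ifelse(is.na(x$criteria_flags), "unknown",
               ifelse(x$criteria_flags, "pass", "fail"))
  for (nm in names(x$criteria_flags)) cat(sprintf("  %-22s %s\n", nm, st[[nm]]))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = ", "), "\n")
  invisible(x)
}

#' One-call assessment of a planet scenario
#'
#' Derives the implied CH4 surface flux from the context's atmosphere and a
#' lifetime regime, evaluates all criteria, and classifies. The lifetime
#' regime defaults to the short anoxic Archean-like preset (2,000 y), the
#' conservative choice for an anoxic high-MMW atmosphere.
#'
#' @param ctx A [planet_context()].
#' @param lifetime_regime Passed to [lifetime_preset()], or `NULL` to skip
#'   flux inference (flux criterion becomes unknown).
#' @param ... Passed to [evaluate_criteria()].
#' @return An `assessment_verdict`.
#' @export
assess_scenario <- function(ctx, lifetime_regime = "anoxic_archean_low", ...) {
  stopifnot(inherits(ctx, "planet_context"))
  flux <- NA_real_
  if (!is.null(lifetime_regime)) {
    tau <- lifetime_preset(lifetime_regime)$lifetime_years
    flux <- implied_surface_flux(ctx$atmosphere, tau)
  }
  classify_verdict(evaluate_criteria(ctx, implied_flux = flux, ...))
}
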