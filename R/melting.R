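#' Magmatic melting scenario
#'
#' One draw of the conditions under which newly produced crust partially
#' melts and partitions its volatiles between melt, residual solid and
#' graphite. Pressures span the top ~10 km of crust and temperatures the
#' corresponding solidus range.
#'
#' @param pressure Pressure in GPa (0-0.5 for the crustal column modelled).
#' @param temperature Solidus temperature in K (nominally 1400-1445).
#' @param delta_iw Oxygen fugacity as log10 offset from the iron-wustite
#'   buffer (-11 to +5 covers ultrareduced Mercury-like through terrestrial
#'   basalt conditions).
#' @param source_co2 CO2 mass fraction of the source rock (carbon is carried
#'   as CO2 equivalent throughout).
#' @param source_h2o H2O mass fraction of the source rock.
#' @param melt_fraction Fraction F of the source that melts, in (0, 1].
#' @param melt_production Planetary melt production in km^3/y (carried for
#'   downstream flux scaling; does not enter the partitioning itself).
#' @return An object of class `melting_scenario`.
#' @examples
#' sc <- melting_scenario(0.25, 1420, -2, source_co2 = 2e-4,
#'                        source_h2o = 1e-3, melt_fraction = 0.1)
#' batch_partition(sc)
#' @export
melting_scenario <- function(pressure, temperature, delta_iw,
                             source_co2, source_h2o, melt_fraction,
                             melt_production = 20) {
  stopifnot(
    is.numeric(pressure), is.numeric(temperature), is.numeric(delta_iw),
    is.numeric(source_co2), is.numeric(source_h2o), is.numeric(melt_fraction)
  )
  if (any(pressure < 0)) stop("pressure must be >= 0 GPa", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be positive", call. = FALSE)
  if (any(melt_fraction <= 0 | melt_fraction > 1)) {
    stop("melt_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (any(source_co2 < 0 | source_co2 >= 1) || any(source_h2o < 0 | source_h2o >= 1)) {
    stop("source volatile mass fractions must lie in [0, 1)", call. = FALSE)
  }
  if (any(melt_production <= 0)) stop("melt_production must be positive", call. = FALSE)
  structure(
    list(pressure = pressure, temperature = temperature, delta_iw = delta_iw,
         source_co2 = source_co2, source_h2o = source_h2o,
         melt_fraction = melt_fraction, melt_production = melt_production),
    class = "melting_scenario"
  )
}

#' @export
print.melting_scenario <- function(x, ...) {
  cat("<melting_scenario>\n")
  cat(sprintf("  P = %.3g GPa, T = %.4g K, dIW = %+.2f\n",
              x$pressure[1], x$temperature[1], x$delta_iw[1]))
  cat(sprintf("  source CO2 = %.3g, H2O = %.3g, F = %.3g\n",
              x$source_co2[1], x$source_h2o[1], x$melt_fraction[1]))
  invisible(x)
}

#' Graphite-saturated carbon capacity of a silicate melt
#'
#' Maximum carbon content (as dissolved carbonate, expressed as CO2-equivalent
#' mass fraction) a melt can hold while coexisting with graphite. The
#' equilibrium `C(graphite) + O2 <-> CO2(melt)` fixes a slope of exactly one
#' in log10 fO2, so at fixed T and P the capacity scales as `10^delta_iw`.
#' The law is
#' `log10 capacity = log10(ref_capacity) + delta_iw
#'                  + dlog_dP * (P - 0.25) - dH/(ln(10) R) * (1/T - 1/1420)`
#' with the reference capacity 1e-4 (100 ppm CO2) anchored at IW+0,
#' 1420 K, 0.25 GPa. The anchor places graphite exhaustion near IW+1 for
#' mantle-like source carbon contents: ultrareduced melts (<= IW-2) hold
#' essentially no carbon while terrestrial-basalt fO2 (~IW+3.5) dissolves
#' far more than any plausible source supplies, leaving no graphite.
#'
#' @param scenario A [melting_scenario()].
#' @param ref_capacity CO2-equivalent mass-fraction capacity at the
#'   reference state (IW+0, 1420 K, 0.25 GPa).
#' @param dlog_dP Pressure dependence, dex per GPa.
#' @param dH Apparent enthalpy of the dissolution equilibrium, J/mol
#'   (van 't Hoff temperature term).
#' @return Melt carbon capacity as CO2-equivalent mass fraction (capped at 1).
#' @export
graphite_saturated_melt_carbon <- function(scenario, ref_capacity = 1e-4,
                                           dlog_dP = 0.6, dH = 1e5) {
  stopifnot(inherits(scenario, "melting_scenario"))
  R <- 8.314462618
  lg <- log10(ref_capacity) + scenario$delta_iw +
    dlog_dP * (scenario$pressure - 0.25) -
    dH / (log(10) * R) * (1 / scenario$temperature - 1 / 1420)
  pmin(10^lg, 1)
}

#' Batch-melting volatile partitioning with graphite saturation
#'
#' Partitions source-rock H2O and carbon between partial melt, residual
#' solid and graphite, assuming the melt equilibrates with its residue
#' before extraction (batch melting). Water follows the standard relation
#' `C_melt = C_source / (F + D * (1 - F))` with a highly incompatible
#' partition coefficient. Carbon follows the same relation unless the
#' implied melt content exceeds the graphite-saturated capacity, in which
#' case the melt is pinned at capacity, the residue holds `D_co2 * capacity`,
#' and the excess carbon remains as graphite.
#'
#' @param scenario A [melting_scenario()].
#' @param d_h2o Melt/solid partition coefficient for H2O (default 0.01,
#'   highly incompatible).
#' @param d_co2 Partition coefficient for carbonate in the residual solid
#'   (default 1e-4; carbon is nearly perfectly incompatible).
#' @param ... Passed to [graphite_saturated_melt_carbon()].
#' @return An object of class `partition_result`: a list with `melt_co2`
#'   and `melt_h2o` (mass fractions in the melt), `residue_co2`,
#'   `graphite_fraction` (graphite carbon / source carbon, in `[0, 1]`)
#'   and the input `scenario`.
#' @examples
#' sc <- melting_scenario(0.1, 1430, -5, 5e-4, 2e-3, 0.15)
#' batch_partition(sc)$graphite_fraction  # essentially all carbon as graphite
#' @export
batch_partition <- function(scenario, d_h2o = 0.01, d_co2 = 1e-4, ...) {
  stopifnot(inherits(scenario, "melting_scenario"))
  FF <- scenario$melt_fraction
  if (any(FF <= 0)) stop("melt_fraction = 0: no melt to partition into", call. = FALSE)

  melt_h2o <- scenario$source_h2o / (FF + d_h2o * (1 - FF))

  capacity <- graphite_saturated_melt_carbon(scenario, ...)
  melt_co2_unsat <- scenario$source_co2 / (FF + d_co2 * (1 - FF))
  saturated <- melt_co2_unsat > capacity

  melt_co2 <- ifelse(saturated, capacity, melt_co2_unsat)
  residue_co2 <- d_co2 * melt_co2
  # carbon accounted per unit source mass
  in_melt    <- FF * melt_co2
  in_residue <- (1 - FF) * residue_co2
  graphite   <- pmax(scenario$source_co2 - in_melt - in_residue, 0)
  graphite_fraction <- ifelse(scenario$source_co2 > 0,
                              graphite / scenario$source_co2, 0)

  structure(
    list(melt_co2 = melt_co2, melt_h2o = melt_h2o,
         residue_co2 = residue_co2,
         graphite_fraction = graphite_fraction,
         scenario = scenario),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat("<partition_result>\n")
  cat(sprintf("  melt CO2 = %.3g, melt H2O = %.3g\n",
              x$melt_co2[1], x$melt_h2o[1]))
  cat(sprintf("  graphite fraction of source carbon = %.4f\n",
              x$graphite_fraction[1]))
  invisible(x)
}
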