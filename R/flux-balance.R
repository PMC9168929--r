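#' Observable atmospheric state of a terrestrial planet
#'
#' The composition and bulk parameters an observer can constrain: surface
#' pressure, mean molar mass, mixing ratios of the five diagnostic species
#' (any of which may be unknown, encoded as `NA`), gravity and radius.
#'
#' @param surface_pressure Surface pressure, Pa.
#' @param mean_molar_mass Mean molar mass of the atmosphere, kg/mol.
#' @param f_ch4,f_co2,f_co,f_o2,f_h2 Mixing ratios in `[0, 1]` or `NA` when
#'   unmeasured. Known ratios must sum to at most 1.
#' @param gravity Surface gravity, m/s^2.
#' @param planet_radius Planet radius, m.
#' @return An object of class `atmosphere_state`.
#' @examples
#' atm <- atmosphere_state(f_ch4 = 1e-3, f_co2 = 0.1, f_co = 1e-4)
#' implied_surface_flux(atm, lifetime_preset("anoxic_archean_low")$lifetime_years)
#' @export
atmosphere_state <- function(surface_pressure = 1e5,
                             mean_molar_mass = 0.028,
                             f_ch4 = NA_real_, f_co2 = NA_real_,
                             f_co = NA_real_, f_o2 = NA_real_,
                             f_h2 = NA_real_,
                             gravity = .gravity(.const$m_earth, .const$r_earth),
                             planet_radius = .const$r_earth) {
  f <- c(ch4 = f_ch4, co2 = f_co2, co = f_co, o2 = f_o2, h2 = f_h2)
  known <- f[!is.na(f)]
  if (any(known < 0 | known > 1)) stop("mixing ratios must lie in [0, 1]", call. = FALSE)
  if (sum(known) > 1 + 1e-12) stop("known mixing ratios sum to more than 1", call. = FALSE)
  if (surface_pressure <= 0) stop("surface_pressure must be positive", call. = FALSE)
  structure(
    list(surface_pressure = surface_pressure,
         mean_molar_mass = mean_molar_mass,
         mixing_ratios = f, gravity = gravity,
         planet_radius = planet_radius),
    class = "atmosphere_state"
  )
}

#' Photochemical lifetime presets for CH4
#'
#' Canonical kinetic lifetimes of atmospheric methane by redox regime:
#' ~10 y in O2-rich atmospheres, and 2,000 to 20,000 y in weakly reduced
#' (Archean-like) anoxic atmospheres.
#'
#' @param regime One of `"oxic"`, `"anoxic_archean_low"`,
#'   `"anoxic_archean_high"`.
#' @return A list with `regime` and `lifetime_years`.
#' @export
lifetime_preset <- function(regime = c("oxic", "anoxic_archean_low",
                                       "anoxic_archean_high")) {
  regime <- match.arg(regime)
  tau <- switch(regime,
                oxic = 10,
                anoxic_archean_low = 2000,
                anoxic_archean_high = 20000)
  list(regime = regime, lifetime_years = tau)
}

#' Vertical column density of an atmospheric species
#'
#' Column number density `N = f * P / (mbar * g)` with `mbar` the mean
#' molecular mass (`mean_molar_mass / N_A`). An unknown mixing ratio
#' (`NA`) propagates to an `NA` column.
#'
#' @param atm An [atmosphere_state()].
#' @param species One of `"ch4"`, `"co2"`, `"co"`, `"o2"`, `"h2"`.
#' @return Column density, molecules m^-2 (or `NA` if unmeasured).
#' @export
column_density <- function(atm, species = "ch4") {
  stopifnot(inherits(atm, "atmosphere_state"))
  species <- match.arg(species, names(atm$mixing_ratios))
  f <- atm$mixing_ratios[[species]]
  if (is.na(f)) return(NA_real_)
  mbar <- atm$mean_molar_mass / .const$N_A
  f * atm$surface_pressure / (mbar * atm$gravity)
}

#' Surface flux implied by an observed CH4 abundance
#'
#' In steady state an atmospheric column destroyed on a photochemical
#' lifetime `tau` must be replenished at `flux = column * area / tau`.
#' Expressed in Tmol/y for direct comparison with Earth's ~30 Tmol/y
#' biogenic emission and the ~10 Tmol/y ceiling of known abiotic sources.
#' An unknown CH4 mixing ratio yields `NA`.
#'
#' @param atm An [atmosphere_state()].
#' @param lifetime_years CH4 photochemical lifetime in years (e.g. from
#'   [lifetime_preset()]).
#' @return Global replenishment flux, Tmol/y.
#' @examples
#' atm <- atmosphere_state(f_ch4 = 1e-3)
#' implied_surface_flux(atm, 2000)  # ~90 Tmol/y, far above abiotic sources
#' @export
implied_surface_flux <- function(atm, lifetime_years) {
  stopifnot(inherits(atm, "atmosphere_state"))
  if (!is.numeric(lifetime_years) || lifetime_years <= 0) {
    stop("lifetime_years must be positive", call. = FALSE)
  }
  col <- column_density(atm, "ch4")
  if (is.na(col)) return(NA_real_)
  area <- 4 * pi * atm$planet_radius^2
  col * area / (lifetime_years * .const$N_A) / 1e12
}
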