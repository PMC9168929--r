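#' Volatile inventory of a melted Titan-like planet
#'
#' An Earth-mass planet that accreted a Titan-like volatile complement and
#' migrated to the habitable zone, melting its ice: the water mass fraction
#' sets the total volatile reservoir and the CH4 inventory fraction the
#' methane carried with it. The atmosphere maintains a fixed CH4 mixing
#' ratio (default 10%, conservative given CH4's low solubility relative to
#' CO2) until the reservoir is exhausted by hydrogen escape.
#'
#' @param water_mass_fraction Water mass as a fraction of planet mass
#'   (1e-4 to 0.1 spans 0.01-10 wt%).
#' @param ch4_inventory_fraction CH4 mass relative to water mass (1e-4 to
#'   0.01 spans 0.01-1%; Titan's value is ~0.0035).
#' @param ch4_mixing_ratio Steady-state atmospheric CH4 mixing ratio in
#'   (0, 1); default 0.10.
#' @param planet_mass,planet_radius Planet mass (kg) and radius (m);
#'   default Earth values.
#' @return An object of class `planet_volatile_inventory`.
#' @examples
#' inv <- planet_volatile_inventory(0.01, 0.0035)
#' ch4_lifetime(inv) / 1e6  # lifetime in My
#' @export
planet_volatile_inventory <- function(water_mass_fraction,
                                      ch4_inventory_fraction,
                                      ch4_mixing_ratio = 0.10,
                                      planet_mass = .const$m_earth,
                                      planet_radius = .const$r_earth) {
  stopifnot(is.numeric(water_mass_fraction), is.numeric(ch4_inventory_fraction))
  if (any(water_mass_fraction <= 0) || any(ch4_inventory_fraction <= 0)) {
    stop("water and CH4 inventory fractions must be positive", call. = FALSE)
  }
  if (any(ch4_mixing_ratio <= 0 | ch4_mixing_ratio >= 1)) {
    stop("ch4_mixing_ratio must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(water_mass_fraction = water_mass_fraction,
         ch4_inventory_fraction = ch4_inventory_fraction,
         ch4_mixing_ratio = ch4_mixing_ratio,
         planet_mass = planet_mass, planet_radius = planet_radius),
    class = "planet_volatile_inventory"
  )
}

#' Diffusion-limited hydrogen escape model
#'
#' Constants for the diffusion-limited escape of hydrogen through a
#' high-mean-molecular-weight background atmosphere. Methane photolysis
#' liberates hydrogen atoms that diffuse through the homopause and escape;
#' the limiting flux is `b * f_H / H_a`, with `b` the binary diffusion
#' parameter of atomic H in the background gas, `f_H` the total hydrogen
#' mixing ratio carried by CH4, and `H_a` the background scale height at
#' the homopause temperature. Defaults: homopause at 200 K, N2 background
#' (0.028 kg/mol), `b = 4.87e17 * T^0.698 cm^-1 s^-1` (the standard
#' tabulation for H in N2, converted to SI), and four hydrogen atoms lost
#' per CH4 destroyed (oxidation by OH is neglected, which maximises the
#' hydrogen carried per methane).
#'
#' @param homopause_temperature Homopause temperature, K.
#' @param background_molar_mass Background-gas molar mass, kg/mol.
#' @param binary_diffusion_b Binary diffusion parameter for H in the
#'   background gas, molecules m^-1 s^-1; by default evaluated from the
#'   power law above at `homopause_temperature`.
#' @param h_atoms_per_ch4 Hydrogen atoms irreversibly lost per CH4.
#' @return An object of class `escape_model`.
#' @export
escape_model <- function(homopause_temperature = 200,
                         background_molar_mass = .const$M_n2,
                         binary_diffusion_b =
                           4.87e17 * homopause_temperature^0.698 * 100,
                         h_atoms_per_ch4 = 4) {
  stopifnot(homopause_temperature > 0, background_molar_mass > 0,
            binary_diffusion_b > 0, h_atoms_per_ch4 > 0)
  structure(
    list(homopause_temperature = homopause_temperature,
         background_molar_mass = background_molar_mass,
         binary_diffusion_b = binary_diffusion_b,
         h_atoms_per_ch4 = h_atoms_per_ch4),
    class = "escape_model"
  )
}

# scale height of the background gas at the homopause, m
.scale_height <- function(model, gravity) {
  m <- model$background_molar_mass / .const$N_A
  .const$k_B * model$homopause_temperature / (m * gravity)
}

#' Diffusion-limited hydrogen escape flux
#'
#' Limiting escape flux of hydrogen atoms carried to the homopause by CH4:
#' `phi = b * (h_atoms_per_ch4 * f_ch4) / H_a`. Linear in the CH4 mixing
#' ratio; for Earth-like gravity and `f_ch4 = 0.1` the flux is of order
#' 1e17 atoms m^-2 s^-1 (1e13 cm^-2 s^-1, the classic terrestrial
#' diffusion-limited value for a 40% total hydrogen mixing ratio).
#'
#' @param f_ch4 CH4 mixing ratio in `[0, 1)`.
#' @param model An [escape_model()].
#' @param gravity Surface gravity, m/s^2.
#' @return Escaping hydrogen flux, atoms m^-2 s^-1.
#' @export
diffusion_limited_h_flux <- function(f_ch4, model = escape_model(),
                                     gravity = .gravity(.const$m_earth, .const$r_earth)) {
  stopifnot(inherits(model, "escape_model"))
  if (any(f_ch4 < 0 | f_ch4 >= 1)) stop("f_ch4 must lie in [0, 1)", call. = FALSE)
  f_h <- model$h_atoms_per_ch4 * f_ch4
  model$binary_diffusion_b * f_h / .scale_height(model, gravity)
}

#' Atmospheric CH4 lifetime under diffusion-limited escape
#'
#' Time to exhaust a planet's entire CH4 volatile inventory when the
#' atmosphere holds a fixed CH4 mixing ratio and hydrogen escapes at the
#' diffusion limit: total CH4 molecules divided by the global CH4
#' destruction rate (escaping H flux / atoms per CH4, integrated over the
#' planet surface). Exactly proportional to both the water mass fraction
#' and the CH4 inventory fraction, so lifetimes separate as
#' `tau = k * water_mass_fraction * ch4_inventory_fraction`.
#'
#' @param inventory A [planet_volatile_inventory()].
#' @param model An [escape_model()].
#' @return Lifetime in years.
#' @examples
#' # Titan-like inventory: ~10 My at 1 wt% water, ~100 My at 10 wt%
#' ch4_lifetime(planet_volatile_inventory(0.01, 0.0035)) / 1e6
#' @export
ch4_lifetime <- function(inventory, model = escape_model()) {
  stopifnot(inherits(inventory, "planet_volatile_inventory"),
            inherits(model, "escape_model"))
  g <- .gravity(inventory$planet_mass, inventory$planet_radius)
  water_mass <- inventory$water_mass_fraction * inventory$planet_mass
  ch4_mass <- water_mass * inventory$ch4_inventory_fraction
  if (any(ch4_mass <= 0)) stop("CH4 inventory is zero", call. = FALSE)
  n_ch4 <- ch4_mass / (.const$M_ch4 / .const$N_A)

  phi_h <- diffusion_limited_h_flux(inventory$ch4_mixing_ratio, model, g)
  area <- 4 * pi * inventory$planet_radius^2
  loss_rate <- phi_h / model$h_atoms_per_ch4 * area  # CH4 molecules / s
  n_ch4 / loss_rate / .const$sec_per_yr
}

#' Lifetime grid over water mass fraction and CH4 inventory
#'
#' Tabulates [ch4_lifetime()] over the product grid of water mass fractions
#' and CH4 inventory fractions (the two axes of the melted exo-Titan
#' parameter space).
#'
#' @param water_fracs Water mass fractions (planet-mass units).
#' @param inv_fracs CH4 inventory fractions (relative to water mass).
#' @param model An [escape_model()].
#' @param ch4_mixing_ratio Fixed atmospheric CH4 mixing ratio.
#' @return A data frame with columns `water_mass_fraction`,
#'   `ch4_inventory_fraction`, `lifetime_years`.
#' @export
lifetime_grid <- function(water_fracs, inv_fracs, model = escape_model(),
                          ch4_mixing_ratio = 0.10) {
  if (length(water_fracs) == 0 || length(inv_fracs) == 0) {
    stop("grids must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(water_mass_fraction = water_fracs,
                      ch4_inventory_fraction = inv_fracs,
                      KEEP.OUT.ATTRS = FALSE)
  grid$lifetime_years <- vapply(seq_len(nrow(grid)), function(i) {
    ch4_lifetime(planet_volatile_inventory(
      grid$water_mass_fraction[i], grid$ch4_inventory_fraction[i],
      ch4_mixing_ratio), model)
  }, numeric(1))
  grid
}
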