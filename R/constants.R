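# Physical constants (SI, CODATA) and package-wide benchmark values.
.const <- list(
  G          = 6.67430e-11,     # m^3 kg^-1 s^-2
  k_B        = 1.380649e-23,    # J/K
  N_A        = 6.02214076e23,   # mol^-1
  m_earth    = 5.972e24,        # kg
  r_earth    = 6.371e6,         # m
  M_ch4      = 0.01604,         # kg/mol
  M_n2       = 0.028,           # kg/mol
  sec_per_yr = 3.1557e7         # Julian year
)

#' Framework benchmark constants
#'
#' Reference quantities used throughout the assessment framework: Earth's
#' modern global biogenic methane emission, the ceiling of plausible abiotic
#' CH4 production summed over known mechanisms, the CO/CH4 discrimination
#' threshold between inhabited and lifeless anoxic worlds, the CH4 mixing
#' ratio above which photochemical stability demands biosphere-scale
#' replenishment on a Sun-like-star planet, and Titan's CH4 volatile
#' inventory relative to its water.
#'
#' @return A named list with elements `biogenic_flux_modern` (30 Tmol/y),
#'   `abiotic_plausibility_ceiling` (10 Tmol/y), `co_ch4_threshold` (1),
#'   `co_ch4_strong_biogenic` (0.1), `ch4_abundance_threshold` (1e-3 mixing
#'   ratio) and `titan_ch4_inventory` (0.0035, i.e. 0.35% of water mass).
#' @examples
#' ch4_benchmarks()$biogenic_flux_modern
#' @export
ch4_benchmarks <- function() {
  list(
    biogenic_flux_modern         = 30,     # Tmol/y
    abiotic_plausibility_ceiling = 10,     # Tmol/y
    co_ch4_threshold             = 1,
    co_ch4_strong_biogenic       = 0.1,
    ch4_abundance_threshold      = 1e-3,
    titan_ch4_inventory          = 0.0035
  )
}

# surface gravity from mass/radius
.gravity <- function(mass, radius) .const$G * mass / radius^2
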