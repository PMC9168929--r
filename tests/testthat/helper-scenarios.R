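# random but reproducible melting scenarios for property tests
random_scenarios <- function(n, seed, delta_iw = NULL) {
  set.seed(seed)
  melting_scenario(
    pressure      = runif(n, 0, 0.5),
    temperature   = runif(n, 1400, 1445),
    delta_iw      = if (is.null(delta_iw)) runif(n, -11, 5) else rep(delta_iw, n),
    source_co2    = exp(runif(n, log(50e-6), log(1000e-6))),
    source_h2o    = exp(runif(n, log(1e-4), log(5e-3))),
    melt_fraction = runif(n, 0.05, 0.3)
  )
}

# a fully characterised Archean-Earth-like context (all criteria satisfied)
archean_context <- function(f_ch4 = 5e-3, co_ch4 = 0.1) {
  planet_context(TRUE, TRUE, TRUE, TRUE,
                 stellar_age = 4.5e9,
                 water_mass_fraction_estimate = 3e-4,
                 atmosphere = atmosphere_state(f_ch4 = f_ch4, f_co2 = 0.1,
                                               f_co = co_ch4 * f_ch4))
}

# all 3^k tri-state combinations over the named criteria, others fixed
tri_state_grid <- function(vary, fixed = TRUE) {
  all_names <- c("terrestrial_density", "habitable_zone", "high_mmw_atmosphere",
                 "anoxic", "ch4_abundant", "flux_exceeds_abiotic",
                 "co2_detected", "co_ch4_low", "water_fraction_low", "star_old")
  vals <- list(TRUE, FALSE, NA)
  grid <- expand.grid(rep(list(1:3), length(vary)), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    flags <- rep(fixed, length(all_names))
    names(flags) <- all_names
    for (j in seq_along(vary)) flags[[vary[j]]] <- vals[[grid[i, j]]]
    flags
  })
}

verdict_rank <- function(v) {
  match(as.character(v), c("not_assessable", "unlikely_biogenic",
                           "possible_abiotic_false_positive",
                           "candidate_biosignature_seek_corroboration"))
}
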