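test_that("an Archean-Earth-like scenario passes every criterion", {
  ctx <- archean_context()
  flux <- implied_surface_flux(ctx$atmosphere,
                               lifetime_preset("anoxic_archean_low")$lifetime_years)
  flags <- evaluate_criteria(ctx, implied_flux = flux)
  expect_true(all(flags))
  # CO/CH4 = 0.1 is below the strong-biogenic annotation tier boundary? (== 0.1 is not <)
  v <- classify_verdict(flags)
  expect_equal(as.character(v$verdict), "candidate_biosignature_seek_corroboration")
  expect_length(setdiff(v$notes, "co_ch4_below_0.1_strong_biogenic_sign"), 0)
})

test_that("a high CO/CH4 ratio fails the antibiosignature criterion", {
  ctx <- archean_context(co_ch4 = 100)
  flags <- evaluate_criteria(ctx, implied_flux = 90)
  expect_false(flags[["co_ch4_low"]])
  v <- classify_verdict(flags)
  expect_equal(as.character(v$verdict), "possible_abiotic_false_positive")
  expect_true("reduced_mantle_outgassing" %in% v$notes)
})

test_that("fully unknown contexts yield unknown flags and not_assessable", {
  ctx <- planet_context()
  flags <- evaluate_criteria(ctx)
  expect_true(all(is.na(flags)))
  expect_equal(as.character(classify_verdict(flags)$verdict), "not_assessable")
})

test_that("gating failures and unknowns cap the verdict", {
  flags <- evaluate_criteria(archean_context(), implied_flux = 90)
  f_h2dom <- flags; f_h2dom[["high_mmw_atmosphere"]] <- FALSE
  expect_equal(as.character(classify_verdict(f_h2dom)$verdict), "unlikely_biogenic")
  f_unk <- flags; f_unk[["high_mmw_atmosphere"]] <- NA
  expect_lte(verdict_rank(classify_verdict(f_unk)$verdict),
             verdict_rank("possible_abiotic_false_positive"))
})

test_that("a 10 wt% water world is flagged as a possible melted exo-Titan", {
  ctx <- planet_context(TRUE, TRUE, TRUE, TRUE, stellar_age = 4.5e9,
                        water_mass_fraction_estimate = 0.10,
                        atmosphere = atmosphere_state(f_ch4 = 5e-3, f_co2 = 0.1,
                                                      f_co = 5e-4))
  v <- assess_scenario(ctx)
  expect_equal(as.character(v$verdict), "possible_abiotic_false_positive")
  expect_true("melted_exotitan" %in% v$notes)
})

test_that("a young star triggers the impact-transient hypothesis", {
  ctx <- archean_context()
  ctx$stellar_age <- 1e8
  v <- assess_scenario(ctx)
  expect_true("impact_transient" %in% v$notes)
})

test_that("classify_verdict is pure and rejects incomplete flag maps", {
  flags <- evaluate_criteria(archean_context(), implied_flux = 90)
  expect_identical(classify_verdict(flags), classify_verdict(flags))
  expect_error(classify_verdict(flags[-1]), "missing criteria")
})

test_that("verdict is monotone over exhaustive tri-state gating combinations", {
  # enumerate all 3^4 gating combinations x 3 evidence profiles; flipping a
  # single flag fail->pass or unknown->pass must never weaken the verdict
  all_names <- names(evaluate_criteria(archean_context(), implied_flux = 90))
  for (fixed in list(TRUE, FALSE, NA)) {
    combos <- tri_state_grid(c("terrestrial_density", "habitable_zone",
                               "high_mmw_atmosphere", "anoxic"), fixed = fixed)
    for (flags in combos) {
      base <- verdict_rank(classify_verdict(flags)$verdict)
      for (nm in all_names) {
        if (isTRUE(flags[[nm]])) next
        up <- flags; up[[nm]] <- TRUE
        expect_gte(verdict_rank(classify_verdict(up)$verdict), base)
      }
    }
  }
})

test_that("all four verdicts are reachable from some flag combination", {
  seen <- character(0)
  combos <- tri_state_grid(c("terrestrial_density", "ch4_abundant",
                             "co_ch4_low"), fixed = TRUE)
  combos <- c(combos, list(structure(rep(NA, 10),
                                     names = names(combos[[1]]))))
  for (flags in combos) {
    seen <- union(seen, as.character(classify_verdict(flags)$verdict))
  }
  expect_setequal(seen, c("not_assessable", "unlikely_biogenic",
                          "possible_abiotic_false_positive",
                          "candidate_biosignature_seek_corroboration"))
})
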