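test_that("packaged compendium loads, validates, and holds the printed bounds", {
  comp <- load_compendium()
  expect_s3_class(comp, "abiotic_compendium")
  expect_gte(nrow(comp), 10)

  need <- c("subaerial_volcanism", "submarine_volcanism", "mor_serpentinization",
            "axial_offaxis_vents", "hydrothermal_modern", "hydrothermal_hadean",
            "subduction_zone_fluids", "continental_settings",
            "cometary_impacts_hadean")
  expect_true(all(need %in% comp$source_id))

  get <- function(id) comp[comp$source_id == id, ]
  expect_equal(get("subaerial_volcanism")$flux_max_tmol_y, 1e-3)
  expect_equal(get("submarine_volcanism")$flux_max_tmol_y, 1e-2)
  expect_equal(get("hydrothermal_hadean")$flux_max_tmol_y, 1.5)
  expect_equal(get("axial_offaxis_vents")$flux_min_tmol_y, 0.015)
  expect_equal(get("axial_offaxis_vents")$flux_max_tmol_y, 0.03)
  expect_equal(get("hydrothermal_modern")$flux_min_tmol_y, 0.1)
  expect_equal(get("hydrothermal_modern")$flux_max_tmol_y, 0.4)
  expect_equal(get("subduction_zone_fluids")$flux_max_tmol_y, 1e-2)
  expect_equal(get("cometary_impacts_hadean")$flux_max_tmol_y, 1.25)
})

test_that("every carried flux sits below the biogenic benchmark", {
  comp <- load_compendium()
  bm <- ch4_benchmarks()
  fx <- comp$flux_max_tmol_y[!is.na(comp$flux_max_tmol_y)]
  expect_true(all(fx < bm$biogenic_flux_modern))
  # all but impact / Hadean entries are at least an order of magnitude below
  ordinary <- comp$category != "impact" & comp$era != "hadean_archean"
  fx_ord <- comp$flux_max_tmol_y[ordinary & !is.na(comp$flux_max_tmol_y)]
  expect_true(all(fx_ord <= bm$biogenic_flux_modern / 10))
})

test_that("max_abiotic_flux equals a brute-force scan and respects filters", {
  comp <- load_compendium()
  ok <- comp$quality != "contamination_suspect" & !is.na(comp$flux_max_tmol_y)
  expect_equal(max_abiotic_flux(comp), max(comp$flux_max_tmol_y[ok]))
  expect_equal(max_abiotic_flux(comp, era = "modern"),
               max(comp$flux_max_tmol_y[ok & comp$era == "modern"]))
  one <- comp[comp$source_id == "hydrothermal_hadean", ]
  class(one) <- class(comp)
  expect_equal(max_abiotic_flux(one, era = "hadean_archean"), 1.5)
  expect_error(max_abiotic_flux(one, era = "modern"), "no records")
})

test_that("contamination-suspect records are flagged and excluded by default", {
  comp <- load_compendium()
  suspect <- comp[comp$quality == "contamination_suspect", ]
  expect_gte(nrow(suspect), 1)
  expect_true(all(is.na(suspect$flux_max_tmol_y)))
})

test_that("empty or malformed compendium files fail fast", {
  empty <- tempfile(fileext = ".csv")
  writeLines("source_id,category,era,flux_min_tmol_y,flux_max_tmol_y,quality,provenance",
             empty)
  expect_error(load_compendium(empty), "empty")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("source_id,category,era,flux_min_tmol_y,flux_max_tmol_y,quality,provenance",
               "x,not_a_category,modern,0.1,0.2,ok,ref"), bad)
  expect_error(load_compendium(bad), "record 1")

  swapped <- tempfile(fileext = ".csv")
  writeLines(c("source_id,category,era,flux_min_tmol_y,flux_max_tmol_y,quality,provenance",
               "x,magmatic,modern,0.5,0.2,ok,ref"), swapped)
  expect_error(load_compendium(swapped), "validation")
})

test_that("framework constants match their benchmark values", {
  bm <- ch4_benchmarks()
  expect_equal(bm$biogenic_flux_modern, 30)
  expect_equal(bm$abiotic_plausibility_ceiling, 10)
  expect_equal(bm$co_ch4_threshold, 1)
  expect_equal(bm$titan_ch4_inventory, 0.0035)
})
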