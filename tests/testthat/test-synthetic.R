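test_that("ensembles are reproducible under a fixed seed", {
  a <- generate_scenarios("melted_exotitan", 25, seed = 17)
  b <- generate_scenarios("melted_exotitan", 25, seed = 17)
  expect_identical(a, b)
  c <- generate_scenarios("melted_exotitan", 25, seed = 18)
  expect_false(identical(a, c))
  expect_error(generate_scenarios("warm_neptune", 5, 1), "unknown archetype")
  expect_error(generate_scenarios("melted_exotitan", 0, 1), "n must be")
})

test_that("generated marginals match their declared distributions (KS, alpha = 0.01)", {
  n <- 10000
  ens <- generate_scenarios("archean_inhabited", n, seed = 23)
  f_ch4 <- vapply(ens$scenarios,
                  function(s) s$context$atmosphere$mixing_ratios[["ch4"]],
                  numeric(1))
  ks1 <- ks.test(log(f_ch4), "punif", log(1e-3), log(1e-2))
  expect_gt(ks1$p.value, 0.01)

  ratio <- vapply(ens$scenarios, function(s) {
    f <- s$context$atmosphere$mixing_ratios
    f[["co"]] / f[["ch4"]]
  }, numeric(1))
  ks2 <- ks.test(log(ratio), "punif", log(0.03), log(0.3))
  expect_gt(ks2$p.value, 0.01)

  et <- generate_scenarios("melted_exotitan", n, seed = 29)
  wmf <- vapply(et$scenarios, function(s) s$inventory$water_mass_fraction,
                numeric(1))
  inv <- vapply(et$scenarios, function(s) s$inventory$ch4_inventory_fraction,
                numeric(1))
  expect_gt(ks.test(log(wmf), "punif", log(1e-4), log(1e-1))$p.value, 0.01)
  expect_gt(ks.test(inv, "punif", 1e-4, 1e-2)$p.value, 0.01)
})

test_that("archean-inhabited ensembles classify as candidates end to end", {
  ens <- generate_scenarios("archean_inhabited", 50, seed = 31)
  verdicts <- vapply(ens$scenarios, function(s) {
    as.character(assess_scenario(s$context)$verdict)
  }, character(1))
  expect_true(all(verdicts == "candidate_biosignature_seek_corroboration"))
})

test_that("reduced-mantle ensembles sequester essentially all carbon", {
  ens <- generate_scenarios("reduced_mantle_world", 200, seed = 37)
  gf <- vapply(ens$scenarios, function(s) {
    batch_partition(s$melting)$graphite_fraction
  }, numeric(1))
  expect_gte(mean(gf), 0.99)
  diw <- vapply(ens$scenarios, function(s) s$melting$delta_iw, numeric(1))
  expect_true(all(diw >= -11 & diw <= -2))
})

test_that("gating-failure archetypes never reach candidate verdicts", {
  for (arch in c("oxic_inhabited", "h2_dominated")) {
    ens <- generate_scenarios(arch, 20, seed = 41)
    verdicts <- vapply(ens$scenarios, function(s) {
      as.character(assess_scenario(s$context)$verdict)
    }, character(1))
    expect_true(all(verdicts == "unlikely_biogenic"))
  }
})

test_that("serpentinizing worlds fall below the biogenic abundance threshold", {
  ens <- generate_scenarios("serpentinizing_world", 30, seed = 43)
  v <- lapply(ens$scenarios, function(s) assess_scenario(s$context))
  expect_true(all(vapply(v, function(x) !isTRUE(x$criteria_flags[["ch4_abundant"]]),
                         logical(1))))
  expect_true(all(vapply(v, function(x) as.character(x$verdict), character(1)) !=
                    "candidate_biosignature_seek_corroboration"))
})
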