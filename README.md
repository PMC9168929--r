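# methanesig

Planetary-context assessment of atmospheric methane as a biosignature on
habitable-zone terrestrial exoplanets.

Methane is photochemically short-lived in a high-mean-molecular-weight
atmosphere, so an abundant CH4 detection implies a large surface
replenishment flux — on Earth, a biological one (~30 Tmol/y). Whether that
inference holds for an exoplanet depends on context: could a reduced
mantle outgas the methane abiotically? Could the planet be a melted
Titan analogue living off a volatile inventory? Does the implied flux
actually exceed what known abiotic chemistry (~10 Tmol/y summed) can
supply? `methanesig` is for astrobiologists and exoplanet observers who
want those questions answered quantitatively and reproducibly.

The package implements:

* **Graphite sequestration in reduced magmas** — a batch-melting model
  (`C_melt = C_source / (F + D(1−F))`) with oxygen-fugacity-dependent
  graphite saturation (capacity ∝ `10^ΔIW`), propagated by Monte Carlo
  over crustal P/T and source-volatile ranges
  (`monte_carlo_graphite_curve()`).
* **Exo-Titan methane lifetimes** — diffusion-limited hydrogen escape,
  `Φ_H = b·4f_CH4 / H_a`, draining a Titan-like CH4 inventory at a fixed
  10% mixing ratio (`ch4_lifetime()`, `lifetime_grid()`).
* **Flux balance** — the surface flux a CH4 column demands given a
  kinetic-lifetime preset, `flux = N·4πR²/τ` in Tmol/y
  (`implied_surface_flux()`).
* **An abiotic CH4 source compendium** — validated records of known
  abiotic fluxes with provenance (`load_compendium()`,
  `max_abiotic_flux()`).
* **A tri-state rule engine** — ten pass/fail/unknown criteria mapped to
  an ordered verdict lattice, with named false-positive hypotheses
  (`assess_scenario()`).
* **Synthetic scenario ensembles** — six seeded planet archetypes for
  end-to-end testing (`generate_scenarios()`).

## Worked example

How much source carbon survives partial melting as oxygen fugacity varies,
and what does an Archean-like methane abundance demand of its source?

```r
library(methanesig)

mc <- monte_carlo_graphite_curve(n_draws = 10000, seed = 42)
mc[mc$delta_iw %in% c(-4, -2, 0, 2, 4), ]
#>    delta_iw   mean ci95_low ci95_high
#>          -4 1.0000   1.0000    1.0000
#>          -2 0.9988   0.9955    0.9999
#>           0 0.8831   0.5535    0.9895
#>           2 0.0048   0.0000    0.0000
#>           4 0.0000   0.0000    0.0000
```

At and below IW−2, over 99.8% of source carbon is locked up as graphite —
an ultrareduced interior cannot feed a methane-rich atmosphere. By IW+2
(toward terrestrial-basalt fugacities) the melt dissolves everything and
no graphite remains.

```r
ch4_lifetime(planet_volatile_inventory(0.01, 0.0035)) / 1e6
#> [1] 15
```

An Earth-mass planet with 1 wt% water and Titan's methane endowment
(0.35% of its water) exhausts its atmospheric methane in ~15 My — brief
against stellar ages, so a melted exo-Titan is a short-lived mimic.

```r
atm <- atmosphere_state(f_ch4 = 1e-3)  # 1 bar, N2 background
implied_surface_flux(atm, lifetime_preset("anoxic_archean_low")$lifetime_years)
#> [1] 92.8
```

Sustaining a 10⁻³ CH4 mixing ratio against a 2,000-y anoxic lifetime
demands ~93 Tmol/y — triple Earth's biogenic flux and far beyond every
entry in the abiotic compendium (`max_abiotic_flux(load_compendium())`
returns 3 Tmol/y). Feeding a fully characterised Archean-Earth-like
scenario to `assess_scenario()` returns
`candidate_biosignature_seek_corroboration` with all ten criteria passing.

A thin command-line front end over the same functions ships at
`inst/cli/methanesig.R` (subcommands `melt-mc`, `lifetime-grid`,
`implied-flux`, `compendium`, `assess`, `synth`).

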