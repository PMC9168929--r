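---
title: "Assessing atmospheric methane as a biosignature: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing atmospheric methane as a biosignature: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanesig)
```

## The scientific problem

Methane is photochemically fragile in the high-mean-molecular-weight
atmosphere of a habitable-zone terrestrial planet: without a large,
sustained surface flux, it disappears on timescales of years to tens of
thousands of years. On Earth that flux is overwhelmingly biological
(~30 Tmol/y), so an abundant CH4 detection on a terrestrial exoplanet is a
serious biosignature candidate — *if* the known abiotic production channels
can be shown to fall short, and *if* the planet is not one of the special
configurations that mimic a biosphere. `methanesig` implements the
quantitative machinery for that argument: forward models of the two most
important false-positive limits (reduced-mantle magmatic outgassing and
melted Titan-like volatile inventories), a flux-balance estimator
converting an observed CH4 abundance into the surface flux needed to
sustain it, a catalogue of known abiotic CH4 sources, and a transparent
rule engine that combines all of this into a verdict.

## Graphite sequestration in reduced magmas

Could a planet with an ultrareduced interior outgas biogenic-scale CH4?
The limiting step is whether carbon ever reaches the gas phase. We model
partial melting of the top ~10 km of newly produced crust (pressures
0–0.5 GPa, solidus temperatures 1,400–1,445 K) with a batch-melting model:
the melt equilibrates with its residue before extraction, water partitions
by the standard relation

$$C_\mathrm{melt} = \frac{C_\mathrm{source}}{F + D\,(1-F)},$$

with $D_{\mathrm{H_2O}} = 0.01$ (hydrous phases are highly incompatible;
this coefficient is not critical to any conclusion), and carbon is
capped by oxygen-fugacity-dependent graphite saturation. The equilibrium
$\mathrm{C_{(graphite)}} + \mathrm{O_2} \rightleftharpoons
\mathrm{CO_2^{(melt)}}$ fixes a slope of exactly one in
$\log_{10} f_{\mathrm{O_2}}$, so the melt's carbon capacity (as
CO2-equivalent mass fraction) is log-linear in the offset from the
iron–wüstite buffer:

$$\log_{10} c = \log_{10}(10^{-4}) + \Delta\mathrm{IW}
  + 0.6\,(P - 0.25) - \frac{\Delta H}{\ln 10\,R}
  \left(\frac{1}{T} - \frac{1}{1420}\right),$$

with $P$ in GPa, $T$ in K and $\Delta H = 100$ kJ/mol. The intercept —
100 ppm dissolved CO2 at IW+0, 1,420 K, 0.25 GPa — is the one genuinely
free constant in this module. It is pinned by two hard anchors: melts at
or below IW−2 must retain >99% of their source carbon as graphite (the
Mercury-like regime), while terrestrial-basalt oxygen fugacities (~IW+3.5)
must dissolve far more carbon than any plausible source supplies, leaving
no graphite. With mantle-like source carbon (50–1,000 ppm CO2) and melt
fractions of 0.05–0.3, this intercept places graphite exhaustion near
IW+1, comfortably between the anchors. The iron–wüstite buffer itself is
the linear-in-$1/T$ parameterization
$\log_{10} f_{\mathrm{O_2}} = 6.54 - 27215/T + 550\,P/T$, calibrated for
1,000–2,500 K; requests outside that range are errors, not extrapolations.

Residual solid carbon is handled explicitly: the residue carries
$D_{\mathrm{CO_2}} = 10^{-4}$ times the melt concentration, and graphite is
whatever the mass balance leaves. Carbon is conserved to 1 part in
$10^{12}$ on every draw, by construction and by test.

### Monte Carlo propagation

`monte_carlo_graphite_curve()` propagates the partition over random
scenarios: $P$ and $T$ uniform over the crustal column, source CO2
log-uniform 50–1,000 ppm, source H2O log-uniform 0.01–0.5 wt%, melt
fraction uniform 0.05–0.3, melt production log-uniform 1–100 km³/y. These
defaults are Earth-like mantle brackets; all are overridable through
`melting_parameter_ranges()` so alternative calibrations can be dropped
in. The default run uses 10,000 draws per oxygen-fugacity grid point on
integer steps from IW−11 to IW+5 and completes in seconds. One draw set is
shared across the grid (common random numbers): this removes sampling
jitter between adjacent fugacities and makes the mean curve exactly
monotone, which is a physical property of the capacity law, not an
artifact. Uncertainty is reported as the 2.5/97.5 percentile band of the
draws. Note that a percentile band of a distribution pinned at 0 or 1 need
not bracket the mean — at fugacities where fewer than 2.5% of draws retain
any graphite, the band collapses to zero while the mean stays positive;
this is a property of percentile summaries of skewed distributions, not a
numerical defect.

```{r fig.width=6, fig.height=4}
mc <- monte_carlo_graphite_curve(n_draws = 2000, seed = 1)
plot(mc)
mc[mc$delta_iw %in% c(-2, 0, 2), ]
```

## Methane lifetimes on melted exo-Titans

A volatile-rich (Titan-like) world that migrates into the habitable zone
melts its ice and can hold an N2 atmosphere with abundant CH4 and CO2 — a
biosignature mimic with no biosphere. Its methane is nonetheless mortal:
photolysis liberates hydrogen, which escapes at the diffusion limit

$$\Phi_\mathrm{H} = \frac{b\, f_\mathrm{H}}{H_a}, \qquad
  f_\mathrm{H} = 4\, f_{\mathrm{CH_4}},$$

with $b$ the binary diffusion parameter of the escaping hydrogen in the
background gas and $H_a$ the background scale height at the homopause.
Four hydrogen atoms are charged per CH4 destroyed, and oxidation by OH is
neglected — both choices maximise methane's survival, so the lifetimes are
upper bounds in spirit. The defaults are a 200 K homopause, an N2
background (0.028 kg/mol; CO2 admixture is ignored for the scale height),
and atomic hydrogen as the escaping species with the standard tabulated
$b = 4.87 \times 10^{17}\, T^{0.698}$ cm⁻¹ s⁻¹ for H in N2 — the paper
trail of the photolysis chain ends in free H atoms, so the atomic
parameter is the consistent choice. All of these are fields of
`escape_model()` and can be replaced. Surface gravity comes from the
planet's mass and radius; the added water mass is not fed back into
gravity (an error below 10% even at 10 wt% water).

The lifetime is the total CH4 inventory (water mass × inventory fraction)
divided by the global escape-limited destruction rate at a fixed 10% CH4
mixing ratio. Because the mixing ratio is held fixed, the lifetime
separates exactly:

$$\tau = k \cdot M_\mathrm{w} \cdot x_\mathrm{inv},$$

so every unprinted constant is absorbed into $k$ and ratios of lifetimes
are parameter-free. With Titan's inventory (0.35% CH4 relative to water)
the defaults give:

```{r}
ch4_lifetime(planet_volatile_inventory(0.01, 0.0035)) / 1e6  # My, 1 wt% water
ch4_lifetime(planet_volatile_inventory(0.10, 0.0035)) / 1e6  # My, 10 wt%
```

about 15 and 150 My — within a factor of two of the ~10/~100 My anchors,
with the 10× ratio exact. Sub-1 wt% water worlds always fall below
~20 My, far shorter than typical stellar ages, so a melted exo-Titan
cannot masquerade as an inhabited planet for long; and a 10 wt% water
world is identifiable by its low bulk density anyway.

## Flux balance: what an observed abundance demands

The full photochemistry of CH4 destruction requires a 1-D model; for
threshold logic a 0-D column balance suffices and is what
`implied_surface_flux()` implements. The observed column,
$N = f P / (\bar{m} g)$, destroyed over a kinetic lifetime $\tau$, must be
replenished at $N \cdot 4\pi R^2 / \tau$. Lifetimes are preset by redox
regime — ~10 y for O2-rich atmospheres, 2,000–20,000 y for weakly reduced
Archean-like atmospheres — and selectable per scenario:

```{r}
atm <- atmosphere_state(f_ch4 = 1e-3)  # 1 bar, N2 background
implied_surface_flux(atm, lifetime_preset("anoxic_archean_low")$lifetime_years)
```

A mixing ratio of $10^{-3}$ on a 1-bar Earth analog already demands
~90 Tmol/y — triple Earth's entire biogenic output and an order of
magnitude above the ~10 Tmol/y ceiling of known abiotic sources. At the
most forgiving preset (20,000 y) the same abundance implies ~9 Tmol/y,
i.e. the demand only brushes the abiotic ceiling at the extreme end of
the lifetime range; any larger abundance clears it under every preset.
Unmeasured mixing ratios propagate as `NA` rather than 0, so "we don't
know" is never silently treated as "absent".

## The abiotic source compendium

`load_compendium()` ships a validated catalogue of known abiotic CH4
sources — magmatic, water–rock/metamorphic, and impact-delivered, for both
the modern Earth and the Hadean/Archean — with per-record global flux
bounds in Tmol/y and a provenance sentence each. The largest entry (the
upper tail of the maximum-serpentinization-flux distribution, 3 Tmol/y)
sits an order of magnitude below the biogenic benchmark; laboratory yields
that would exceed the crustal iron supply are carried with
`quality = "contamination_suspect"`, no flux numbers, and are excluded
from `max_abiotic_flux()` by default.

```{r}
comp <- load_compendium()
max_abiotic_flux(comp)
max_abiotic_flux(comp, era = "modern")
```

## The assessment rule engine

`evaluate_criteria()` scores ten criteria as pass/fail/unknown
(`TRUE`/`FALSE`/`NA`): four *gating* criteria establish that the planet is
one where abundant methane is informative at all — terrestrial bulk
density, habitable zone, high mean molecular weight (not H2-dominated),
anoxic — and six *evidence* criteria score the methane itself: mixing
ratio above $10^{-3}$, implied flux above 10 Tmol/y, CO2 detected, CO/CH4
below 1 (with a note recorded below 0.1, the strong-biosphere tier), water
mass fraction below 1 wt%, and a host star older than $10^9$ y (beyond the
persistence of impact transients and most exo-Titan lifetimes).

`classify_verdict()` maps flags to a verdict on the ordered lattice
`not_assessable < unlikely_biogenic < possible_abiotic_false_positive <
candidate_biosignature_seek_corroboration`: all-unknown is not assessable;
a gating failure (or non-abundant methane) makes a biosignature claim
unsupportable; a fully passing slate is a candidate that still *requires*
corroborating evidence; anything in between is a possible false positive
with the matching hypotheses named (`reduced_mantle_outgassing` for high
CO/CH4, `serpentinization` for modest implied fluxes, `impact_transient`
for young or unknown stellar ages, `melted_exotitan` for large or unknown
water fractions). Unknowns cap the verdict — they never upgrade it —
reflecting that context must be established before biogenicity is claimed.
The mapping is a pure function and is exhaustively enumerated in the test
suite: flipping any single criterion from fail or unknown to pass can
never weaken the verdict.

```{r}
ctx <- planet_context(TRUE, TRUE, TRUE, TRUE, stellar_age = 4.5e9,
                      water_mass_fraction_estimate = 3e-4,
                      atmosphere = atmosphere_state(f_ch4 = 5e-3,
                                                    f_co2 = 0.1, f_co = 5e-4))
assess_scenario(ctx)
```

## Synthetic scenario ensembles

`generate_scenarios()` draws seeded ensembles from six archetypes
(Archean-inhabited, reduced-mantle, serpentinizing, melted exo-Titan,
oxic-inhabited, H2-dominated) so that every stage of the pipeline is
testable end to end without any external data. Ranges with a published
basis use it (Archean CH4 abundances 100–10,000× modern as log-uniform
$[10^{-3}, 10^{-2}]$; inhabited-world CO/CH4 around 0.1; exo-Titan water
log-uniform 0.01–10 wt% and inventory uniform 0.01–1%; reduced-mantle
ΔIW uniform $[-11, -2]$); the rest (e.g. oxic-world O2 levels,
serpentinizing-world CO/CH4) are test fixtures chosen for coverage, not
science claims. Marginal distributions are verified by Kolmogorov–Smirnov
tests at $\alpha = 0.01$ with $n = 10{,}000$.

What the generator deliberately does *not* emulate: observational noise
and retrieval posteriors (contexts arrive as clean tri-states, whereas a
real observation yields correlated credible intervals), stellar-type
dependence of the photochemistry, hazes when CH4 exceeds CO2, and any
self-consistent coupling between interior, outgassing and atmosphere
across archetypes. Passing tests therefore demonstrate the internal
consistency of the framework's logic, not its performance on noisy
retrievals.

## Numerical choices and limitations

* Problem sizes: 10,000 Monte Carlo draws per fugacity grid point (17
  points) run in seconds; the KS checks use 10,000-scenario ensembles.
* Degenerate inputs fail fast: zero melt fraction, zero CH4 inventory,
  non-positive lifetimes, empty grids and malformed compendium files are
  errors, not silent zeros.
* The 0-D flux balance replaces a full 1-D photochemical calculation by
  design; it reproduces threshold logic at order-of-magnitude fidelity and
  cannot reproduce a flux–abundance curve. Stellar type enters only
  through the lifetime presets.
* The melting model treats gas speciation of the outgassed phase
  (CH4/CO/CO2/H2 equilibria), degassing kinetics and long-term crustal
  graphite burial as out of scope; it bounds carbon availability, not the
  speciated CH4 flux.
* The staged decision procedure is reconstructed from the framework's
  narrative criteria; the branch structure (gating versus evidence, the
  verdict lattice, the 1 Gy stellar-age threshold) is this package's
  explicit, testable encoding of it.
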