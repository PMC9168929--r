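source_id,category,era,flux_min_tmol_y,flux_max_tmol_y,quality,provenance
subaerial_volcanism,magmatic,modern,,1e-3,ok,"~1500 active volcanoes at <1e-6 Tmol/y each give a global flux below 1e-3 Tmol/y (Etiope & Sherwood Lollar 2013; Etiope 2015)"
submarine_volcanism,magmatic,modern,,1e-2,ok,"Submarine volcanic CH4 flux estimated near 1e-2 Tmol/y (Schindler & Kasting 2000)"
mor_serpentinization,water_rock_metamorphic,modern,0.01,0.03,ok,"Mid-ocean-ridge serpentinization fluxes ~3 orders of magnitude below the 30 Tmol/y biogenic flux (Keir 2010; Cannat et al. 2010)"
axial_offaxis_vents,water_rock_metamorphic,modern,0.015,0.03,ok,"Axial and off-axis hydrothermal vent CH4 0.015-0.03 Tmol/y (Catling & Kasting 2017)"
hydrothermal_modern,water_rock_metamorphic,modern,0.1,0.4,ok,"Abiotic hydrothermal CH4 0.1-0.4 Tmol/y at present (Guzman-Marmolejo et al. 2013; Kasting 2005)"
hydrothermal_hadean,water_rock_metamorphic,hadean_archean,,1.5,ok,"Hydrothermal CH4 possibly ~1.5 Tmol/y during the Hadean, still over an order of magnitude below the modern biogenic flux (Kasting 2005)"
subduction_zone_fluids,water_rock_metamorphic,modern,,1e-2,ok,"Abiotic hydrothermal CH4 at subduction zones ~1e-2 Tmol/y (Brovarone et al. 2020; Fiebig et al. 2019)"
continental_settings,water_rock_metamorphic,modern,,0.03,ok,"Ophiolites, orogenic massifs, seeps and Precambrian shields; several orders of magnitude below the biogenic flux (Etiope & Sherwood Lollar 2013)"
serpentinization_upper_tail,water_rock_metamorphic,modern,,3,ok,"Upper tail of the maximum-serpentinization-flux probability distribution; Earth-like biogenic fluxes are at least an order of magnitude larger (Krissansen-Totton et al. 2018)"
metamorphic_siderite,water_rock_metamorphic,modern,,0.01,ok,"Metamorphic decomposition of Fe-bearing carbonates; experimental CH4 yields very low relative to CO2 (McCollom 2003)"
cometary_impacts_hadean,impact,hadean_archean,,1.25,ok,"Cometary impactor CH4 flux ~1.25 Tmol/y during the Hadean; 0.6 Tmol per 1-km comet (Kress & McKay 2004; Kasting 2005)"
experimental_catalyzed_serpentinization,water_rock_metamorphic,modern,,,contamination_suspect,"Catalysed laboratory serpentinization yields implying fluxes that exceed the crustal iron supply; attributed to organic contamination, so no flux is carried (Oze et al. 2012; Neubeck et al. 2011; cf. McCollom 2016)"
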