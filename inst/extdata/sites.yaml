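# Registry of the ten Italian Neolithic / Copper Age funerary communities.
# reference_water_range: modern local drinking-water d18O (permil V-SMOW),
# given only where a numeric range has been published for the area; sites
# whose modern waters are described only qualitatively carry no range and
# receive a "no_reference" verdict. Latitudes are approximate site
# latitudes, used to order plots north-to-south.
sites:
  - code: FR
    name: Fontenoce di Recanati
    period: copper_age
    reference_water_range: null   # foothill springs, no published bounds
    latitude: 43.40
  - code: SS
    name: Buca di Spaccasasso
    period: copper_age
    reference_water_range: [-6, -5]
    latitude: 42.63
  - code: CE
    name: Celano Pratovecchio
    period: copper_age
    reference_water_range: null   # Apennine precipitation, no published bounds
    latitude: 42.08
  - code: MC
    name: Mora Cavorso
    period: neolithic
    reference_water_range: null
    latitude: 41.89
  - code: OC
    name: Osteria del Curato-Via Cinquefrondi
    period: copper_age
    reference_water_range: [-7, -6]
    pooling_group: rome_copper_age
    latitude: 41.84
  - code: CM
    name: Casetta Mistici
    period: copper_age
    reference_water_range: [-7, -6]
    pooling_group: rome_copper_age
    latitude: 41.88
  - code: TC
    name: Torre della Chiesaccia
    period: copper_age
    reference_water_range: [-7, -6]
    pooling_group: rome_copper_age
    latitude: 41.80
  - code: PB
    name: Pantano Borghese
    period: copper_age
    reference_water_range: [-7, -6]
    pooling_group: rome_copper_age
    latitude: 41.86
  - code: GN
    name: Grotta Nisco
    period: copper_age
    reference_water_range: [-7, -6]
    latitude: 40.95
  - code: PA
    name: Galliano-Palagiano
    period: neolithic
    reference_water_range: null   # Apennine-fed sources suspected, no bounds
    latitude: 40.58
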