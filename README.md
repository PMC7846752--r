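# isomob

Oxygen and carbon isotope palaeomobility analysis for tooth enamel
carbonate.

## What it is for

Tooth enamel forms in childhood and is isotopically inert afterwards, so
the oxygen isotope composition of its carbonate fraction
(δ¹⁸O<sub>ca</sub>) records the drinking water of an individual's early
years. For a prehistoric funerary community whose members are mostly
local, the community's own δ¹⁸O distribution defines the "local range",
and individuals well outside it are candidates for non-local origin
("newcomers"). `isomob` is aimed at bioarchaeologists working with
exactly this kind of material: small cemetery assemblages (n ≈ 3–50 per
site), enamel carbonate measurements on the V-PDB scale, and at best a
coarse modern reference for local water.

## The method

Measured values are converted between scales with two fixed affine maps:

- V-PDB → V-SMOW: δ¹⁸O<sub>SMOW</sub> = 1.03091 · δ¹⁸O<sub>PDB</sub> + 30.91
- carbonate → drinking water: δ¹⁸O<sub>dw</sub> = 1.59 · δ¹⁸O<sub>SMOW</sub> − 48.634

Each community with n ≥ 9 is screened against four locality windows
built from its own values: mean ± 2σ; median ± 3 MAD (normal-consistent
MAD if a Shapiro–Wilk test accepts normality at α = 0.05, the
75th-percentile "MAD-Q3" variant otherwise); Tukey fences at
q1/q3 ∓ 1.5 IQR; and a fixed mean ± 2 ‰ band. A sample strictly outside
*all* applied windows is the consensus outlier — the defensible
newcomer candidate. Around the screen sit poolability testing for
neighbouring cemeteries (t / Kruskal–Wallis), reference-water verdicts,
a breastfeeding-enrichment screen for deciduous teeth, a two-endmember
diagenetic mixing diagnostic, and a seedable synthetic generator with
planted migrants for power analysis.

## Worked example

Generate the bundled ten-community synthetic scenario (126 individuals,
drawn at the published per-site means and sds), plant one newcomer at
exactly 24.7 ‰ V-SMOW in the largest community (2.1 ‰ below its mean),
and run the pipeline:

```r
library(isomob)

sc <- generate_scenario(seed = 42, plant_demo_migrant = FALSE)
samples <- sc$samples
idx <- which(samples$site_code == "SS")[1]
samples$d18O_ca_vpdb[idx] <- vsmow_to_vpdb(24.7)

run <- run_pipeline(samples, sc$sites)
run$screens$SS$windows
#> # A tibble: 4 × 4
#>   method         center lower upper
#>   <chr>           <dbl> <dbl> <dbl>
#> 1 two_sd           26.8  25.3  28.2
#> 2 three_mad_norm   26.7  25.2  28.2
#> 3 tukey_iqr        26.7  25.4  28.0
#> 4 two_permil       26.8  24.8  28.8

dplyr::filter(run$screens$SS$report, is_consensus_outlier)
#> # A tibble: 1 × 9
#>   sample_id value out_two_sd out_three_mad_norm out_tukey_iqr out_two_permil
#>   <chr>     <dbl> <lgl>      <lgl>              <lgl>         <lgl>
#> 1 SS_001     24.7 TRUE       TRUE               TRUE          TRUE

run$water_verdicts[run$water_verdicts$group == "SS", ]
#> # A tibble: 1 × 7
#>   group     n mean_dw sd_dw ref_lower ref_upper verdict
#>   <chr> <int>   <dbl> <dbl>     <dbl>     <dbl> <chr>
#> 1 SS       50   -6.08  1.14        -6        -5 consistent
```

Reading it: this community passes normality (W = 0.97, p = 0.33), so
the 3-MAD window uses the normal-consistent MAD; the planted individual
at 24.7 ‰ falls outside every window and is the single consensus
outlier, while the community's estimated drinking water
(−6.1 ± 1.1 ‰) overlaps the modern local range (−6 to −5 ‰).
`export_reports(run, "out/")` writes the per-site statistics, spread
measures, outlier JSON, water verdicts and a run log;
`violin_plot()` / `bivariate_plot()` draw the standard figures. A thin
command-line wrapper is installed as `exec/isomob`
(`isomob run|synth|stats`).

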