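---
title: "Screening tooth-enamel isotopes for non-local individuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tooth-enamel isotopes for non-local individuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomob)
```

## The problem

Tooth enamel mineralizes in childhood and is chemically inert afterwards,
so the oxygen isotope ratio of its carbonate fraction
($\delta^{18}O_{ca}$) records the water an individual drank while the
tooth formed. If most members of a funerary community grew up locally,
the community's own $\delta^{18}O$ distribution defines what "local"
looks like, and individuals far outside it are candidates for having
spent their childhood elsewhere. `isomob` implements this screen for
small prehistoric cemetery assemblages: communities of a handful to a
few dozen individuals, measured on enamel carbonate, with no external
isoscape reliable enough to classify individuals on its own.

## Scales and transfer functions

Measurements arrive on the V-PDB scale and are converted to V-SMOW with
the fixed affine map

$$\delta^{18}O_{SMOW} = 1.03091\,\delta^{18}O_{PDB} + 30.91,$$

and onward to an estimated drinking-water value with the linear
carbonate-calibrated transfer function

$$\delta^{18}O_{dw} = 1.59\,\delta^{18}O_{SMOW} - 48.634.$$

Both maps live in `iso_constants()` and are echoed in every run log.
Because they are affine, means, medians and quantiles move through them
directly and spreads scale by the slope (`propagate_scale()`); all
computation stays at full precision and the conventional one-decimal
presentation (`report_round()`, half away from zero) is applied only
when formatting. The drinking-water conversion carries a real-world
uncertainty of 1–2 ‰, which is why reference-water comparison is a
community-level verdict here, never an individual classifier. No
phosphate-based transfer equations are bundled; the constants are
deliberately not silently overridable.

## The locality screen

For each community with at least `min_n = 9` individuals (below that,
window statistics are too unstable; communities still get descriptive
statistics and plots) the screen builds four windows from the
community's own values:

| criterion | window | width |
|---|---|---|
| `two_sd` | mean ± 2 sd | 4 sd |
| `three_mad_norm` / `three_mad_q3` | median ± 3 MAD | 6 MAD |
| `tukey_iqr` | [q1 − 1.5 IQR, q3 + 1.5 IQR] | 4 IQR |
| `two_permil` | mean ± 2.0 ‰ | 4.0 ‰ |

The MAD variant is chosen by a Shapiro–Wilk test at $\alpha = 0.05$:
the normal-consistent MAD (`1.4826 ×` raw MAD) when normality is not
rejected, and the 75th percentile of absolute deviations from the
median (`mad_q3`) otherwise, with the boundary $p = \alpha$ counted as
non-normal. `mad_q3` was chosen over other skew-tolerant estimators
because it is never smaller than the raw MAD, consistent with the
published community spread tables this package mirrors; both variants
can be forced for sensitivity analysis.

A sample is flagged by a criterion iff it lies *strictly* outside the
closed window; values within 0.05 ‰ (half a reporting unit) of a bound
are annotated as boundary cases so they can be discussed rather than
silently classified. Windows are built from the full sample, candidates
included — a single pass, no iterative trimming — because with one or
two true migrants in 10–50 individuals the robust criteria already
resist masking, and leave-one-out would change what the published
procedure computes. A sample flagged by *all* applied criteria is the
consensus outlier: the defensible "newcomer" candidate.

Two numerical caveats are deliberate. First, the three statistical
windows are affine-equivariant, so classification does not depend on
whether the screen runs on V-PDB or V-SMOW values; the fixed 2 ‰ band
cannot be (a fixed width does not rescale), so it is defined on the
V-SMOW scale, where community results are reported. Second, quartiles
default to linear interpolation of order statistics (R's type 7,
`h = (n-1)p + 1`), with type 2 available; at these sample sizes the
choice can move a Tukey fence by a few hundredths of a per mil, which
is why it is exposed and logged.

## Pooling neighbouring communities

Small contemporaneous cemeteries a few kilometres apart can be pooled
to gain power. Sites sharing a `pooling_group` tag in the registry are
tested with a Kruskal–Wallis rank test (three or more groups; a
pooled-variance Student's t for two, Welch by flag) and merged only
when the test finds no difference at $\alpha$; pooling against a failed
test requires an explicit override, which is recorded. The bundled
registry tags the four Copper Age cemeteries around Rome
(`rome_copper_age`, n = 16 + 7 + 4 + 3 = 30). The package applies one
rank test across all member sites; a staged grouping (merging two tiny
sites first, then testing three groups) can be reproduced by calling
`poolability_tests()` on user-assembled groups.

## Provenance checks

**Reference waters.** A community's estimated drinking water
(mean ± 1 sd, propagated from the V-SMOW summary) is compared with the
modern local range from the registry: overlap ⇒ `consistent`,
otherwise `below`/`above` by the side of the mean, `no_reference` when
the area has no published bounds. The ± 1 sd overlap rule reproduces
the published qualitative verdicts for the bundled sites. Reference
ranges are data, not code: they come from isoscape literature that this
package cannot re-derive, and Holocene climate drift means they are
indicative, not probative.

**Breastfeeding.** Teeth mineralized before weaning can be enriched in
$^{18}$O by roughly 0.5–2 ‰. The screen compares deciduous values with
the permanent range and flags systematic enrichment only when the mean
deciduous–permanent offset falls inside that band *and* every deciduous
value exceeds the permanent median — a one-sided shift, not scatter.
This errs toward not flagging: with two or three deciduous teeth per
site, absence of a flag is weak evidence of absence.

**Diagenesis.** Post-mortem exchange with cave carbonate pulls tooth
values along a line toward the secondary-carbonate endmember. Given two
endmembers (e.g. speleothems from the burial cave), `mixing_check()`
solves the apparent mixing fraction on the carbon axis and reports the
perpendicular distance to the mixing segment in a space standardized by
the endmember separation (hence invariant to rescaling either axis).
It is diagnostic only — it never corrects or excludes measurements,
because a community whose carbon values are compatible with fluid
exchange simply cannot support mobility conclusions. No endmember
values are bundled: published figures show them graphically without
printing coordinates, so endmembers must be supplied by the user (the
test suite uses clearly-synthetic ones).

## The synthetic generator

`generate_site()` draws a community as i.i.d. Normal($\mu$, $\sigma$)
on the V-SMOW scale — the structure the screen itself assumes — and
stores values as V-PDB through the inverse conversion, as real data
arrive. Options plant migrants (draws at $\mu$ + offset, labelled in
truth columns), enrich a deciduous fraction by a fixed offset, and mix
carbon toward an endmember with per-sample fractions recorded.
`generate_scenario("prehistoric_italy")` instantiates all ten bundled
communities at their published V-SMOW means, sds and sample sizes
(126 individuals; the OC community uses the V-SMOW sd column, as the
published V-PDB sd for that site is inconsistent with it and is almost
certainly a misprint).

What the generator does *not* emulate: multi-modal water sources,
inter-tooth-type offsets, measurement error structure beyond the
community sd, age structure, or spatial isoscapes (migrants are defined
by isotopic offset, not geography). Passing recovery tests on this
generator therefore shows the screen behaves correctly under its own
assumptions — not that those assumptions hold for any particular
assemblage. Only statistical properties of the draws are promised under
a fixed seed, not exact sequences across R versions.

## Power and false positives, measured

With the bundled defaults the suite simulates 500 replicates of an
n = 30, $\sigma$ = 0.5 community: a single migrant at +3 ‰ is
consensus-flagged in ≥ 95 % of replicates (the binding criterion is the
fixed 2 ‰ band, since the migrant itself is drawn with $\sigma$ = 0.5),
and with no migrants the mean fraction flagged by `two_sd` is about
4 % (the theoretical ~4.6 % for a known-parameter 2σ rule, shrunk
slightly by estimating mean and sd from n = 30). The replicate counts
(500 for simulations, 1000 for the statistics-vs-oracle sweep) keep the
whole suite under a minute of simulation time while leaving Monte-Carlo
error well below the asserted tolerances.

## Known limitations

- The screen assumes the majority of each community is local; it cannot
  detect group-level relocation.
- Drinking-water conversion error (1–2 ‰) exceeds most inter-site
  contrasts; water verdicts are corroboration, not evidence.
- The n ≥ 9 gate is pragmatic; the robust-statistics literature
  suggests ~25 as a comfortable minimum, which few prehistoric Italian
  assemblages reach.
- No multiple-testing correction is applied across communities or
  criteria — the consensus rule is the (conservative) correction used
  in this field.
- Geographic origin assignment is out of scope by design.
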