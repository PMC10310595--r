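---
title: "Methods: censored statistics, pollution indices and oral-ingestion risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored statistics, pollution indices and oral-ingestion risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilrisk)
```

`soilrisk` chains four pieces of analysis that are usually done ad hoc in
spreadsheets: summary statistics for left-censored soil chemistry,
pollution indices against a local background, conversion of in vitro
bioaccessibility to relative bioavailability, and oral-ingestion exposure
arithmetic. This vignette records the models, the defaults, and the
numerical choices, so results can be interpreted — and questioned — without
reading the source.

## Censored concentrations

### The product-limit estimator on flipped data

XRF and ICP-MS panels report many results only as "below the limit of
detection": left-censored observations. Substituting 0, LOD/2 or the LOD
biases means and SDs in ways that depend on the censoring fraction.
`km_summary()` instead treats the empirical distribution seriously: the
data are flipped about a constant `M` larger than every observed value and
bound, which turns left-censored concentrations into right-censored
"survival times"; the Kaplan–Meier product-limit estimator (via
`survival::survfit()`) is fitted; and the estimated distribution is flipped
back. Means and SDs are moments of that distribution, quantiles its
generalized inverse.

Numerical conventions, all of which matter at the edges:

- **Flip constant.** Default `M = max(x) + 1`. The estimate is invariant to
  the choice of any valid `M` (this is tested); fixing one default makes
  runs reproducible and comparable.
- **Leftover mass.** When the smallest point in the data is a censored
  bound, the survival curve does not reach zero. The leftover mass is
  placed at that smallest bound — the restricted-mean convention of
  nondetect practice — and the summary carries a `mass_carried` flag. The
  resulting mean is therefore an upper-bounded estimate between the
  "censored → 0" and "censored → LOD" substitution extremes (also tested).
- **Ties.** An uncensored value tied with a censored bound is treated as
  occurring first on the flipped scale, the standard right-censoring rule.
- **Quantiles.** The KM quantile is the generalized inverse of the
  estimated CDF, i.e. a step-function (type-1) quantile. With zero
  censoring, mean and SD equal the arithmetic mean and sample SD exactly
  (the SD applies the n/(n−1) correction to the KM second moment), and
  quantiles equal `quantile(x, type = 1)`.
- **All-censored groups** return upper bounds at the smallest LOD with an
  `all_censored` flag rather than numbers that look like estimates.

### Group comparisons

`peto_peto()` compares two groups with the Peto–Peto generalized Wilcoxon
test on the flipped data. This weights differences by the pooled survival
curve, which is appropriate when censoring levels differ between groups —
exactly the situation with site-dependent detection frequencies. Two
inference paths:

- **Asymptotic**: `survival::survdiff(rho = 1)`, chi-square with 1 df.
- **Permutation**: the Prentice–Wilcoxon score statistic (scores computed
  from the pooled KM estimate; events score `S(t⁻) + S(t) − 1`, censored
  observations `S(t) − 1`) is enumerated over all group-label arrangements
  when there are at most 20,000 of them, otherwise sampled. For small
  groups this gives an exact test; the test suite checks it against an
  independently coded enumeration oracle.

`pairwise_screen()` runs all group pairs × elements and attaches
Benjamini–Hochberg adjusted p-values over the whole family. The screening
decision ("no group difference" → drop the element from site-contrast
interpretation) uses the adjusted values: with a dozen elements and three
site pairs, raw 0.05 screening would inflate the family error rate
substantially. Raw p-values are reported alongside.

A calibration property is part of the acceptance suite: with identical
lognormal groups (GM 1, GSD 2), ~30% censoring and n = 20 + 20, the
asymptotic test rejects at a rate within [0.03, 0.07] of nominal 0.05 over
2000 seeded replicates.

### Method-comparability QA

`comparability_regression()` is ordinary least squares of one method on the
other (confirmatory ICP-MS on field XRF), reporting slope, intercept, R²
and the slope p-value, with `tidy()`/`glance()` views; `srm_recovery()` is
the standard-reference-material percentage. Both are deliberately plain:
the QA question is "are these methods exchangeable at these
concentrations", not a measurement-error model.

## Pollution indices

The enrichment factor normalizes by iron to control for grain-size and
mineralogical effects: `EF = (Ms · Fe_b)/(Mb · Fe_s)`. The geoaccumulation
index is `Igeo = log2(Ms / 1.5 Mb)`; the 1.5 absorbs natural background
variability, so a sample exactly at background scores `log2(1/1.5) < 0`
("unpolluted"). Class bins are the standard descriptive vocabularies; bin
edges are closed on the right (an EF of exactly 2 is still "deficiency to
minimal"). Igeo above 6 keeps the top label and is flagged out-of-scale.
Both indices are scale-invariant, so unit mix-ups between mg/kg and ppm
cannot change a class.

Background means are deliberately **not packaged**: they are properties of
the local geology, estimated from control samples (the intended workflow is
a dozen samples from an undisturbed area of similar geology) and supplied
via `set_backgrounds()`. Indices can be computed per sample or on KM group
means (`by = "group"`), matching the usual "mean Igeo/EF per area" figures.

Guideline screening compares KM means against CCME residential/parkland
guidelines and Dutch Intervention values with a strict inequality — a mean
exactly at the guideline does not "exceed". This is the conservative
reading in the direction of not over-claiming pollution.

## Bioaccessibility and bioavailability

IVBA% is the gastric-extractable fraction:
`100 · (extract µg/L × fluid L / soil g) / total mg/kg`; with the standard
1 g / 100 mL vessel this is `10 · extract / total`. Records with extract
concentrations at or below the extract LOD get no IVBA (flagged), because a
ratio of two near-detection numbers is noise.

RBA resolution is element-specific (`resolve_rba()`):

| rule | elements | mapping |
|---|---|---|
| regression | As | `RBA% = 0.79·IVBA% + 3` |
| regression | Pb | `RBA% = 0.878·IVBA% − 2.8` |
| direct | Ag, Cr, Cu, Ni, Zn | `RBA = min(IVBA, 100)/100` |
| fixed | Cd, Mo, Sb, Sn (and Au) | `RBA = 1` |

Regression outputs and direct IVBA are clamped to [0, 100] before use as a
fraction: measured IVBA can exceed 100% (silver does, in heterogeneous
soils) and the lead regression goes negative below IVBA ≈ 3.2%, but a
bioavailability fraction outside [0, 1] is physically meaningless. Flags
(`ivba_gt_100`) preserve the information; the resolved fraction is always
in [0, 1] and monotone in IVBA (tested as a property). A direct-IVBA
element with no measurement falls back to RBA 1 — the conservative choice —
with an explicit `rba_defaulted` flag, never silently.

`rba_map()` aggregates per-sample fractions to one value per element
(arithmetic means; bioaccessibility tables conventionally carry no
censoring machinery) and fills the rest of the registry, so the risk stage
always sees a complete map. Packaged site-mean IVBA values are available as
a fallback (`ivba_reference_means()`).

## Oral-ingestion risk

The exposure model is deliberately minimal — incidental soil ingestion
only, the dominant pathway for the general population:

- `CDI = Msoil · IngR · ET / BW` (mg per kg body weight per day), with
  `ET` a **dimensionless fraction** `(days/week ÷ 7) × (weeks/year ÷ 52)`.
  Writing ET as the literal product "days/week × weeks/year" would give
  days/year and destroy the units, so the fraction form is used; the
  default is 1 (continuous residential exposure).
- For carcinogens only, CDI is further multiplied by
  `exposure_duration / life_expectancy` (default duration = LE = 64 y, so
  the default multiplier is 1). This keeps the lifetime amortization out of
  the non-cancer quotients.
- `HQ = CDI · RBA / TDI`, `HI = Σ HQ` over the elements with a TDI
  (Ag, As, Cd, Cr, Cu, Mo, Ni, Pb, Sb, Sn, Zn — gold is analysed for
  source structure but carries no TDI and is skipped with an explicit
  note, never zeroed). `HI > 1` flags non-carcinogenic concern.
- `CR = CDI · CSF · RBA` for arsenic, the one carcinogen with an oral
  slope factor here (1.8 (mg·kg⁻¹·d⁻¹)⁻¹; the CSF is a reciprocal-dose
  quantity so CR is dimensionless). The acceptability threshold is
  1 × 10⁻⁵ — one excess cancer per 100,000 exposed. Cancer risk defaults
  to adult receptors (`cr_receptors = "adult"`); a child carcinogen
  assessment can be requested explicitly.

Default receptors: child 0.0004 kg soil/day at 30 kg; adult 0.0001 kg/day
at 70 kg. These fix the child/adult intake ratio at 4 × 70/30 ≈ 9.33, which
the tests assert end to end.

Censored concentrations must become point values for exposure; the
convention is explicit and configurable (`censoring = "half_lod"` default,
`"lod"` and `"zero"` available for bracketing) and recorded in the result's
`conventions` attribute. The bracketing property — zero ≤ half-LOD ≤ LOD
risk — is tested.

## The synthetic generator

`synthetic_config()`/`generate_soil()` emulate the concentration structure
of an e-waste site so the pipeline can be exercised with known truth:

- **Lognormal base field** per element (GM, GSD), matching the heavy right
  skew of real site data where means far exceed medians.
- **Two multiplicative point sources** — a burning area (loadings on Cu,
  Pb, Sb, Sn, Zn, plus As and Cd) and a dismantling area (Ag, Au, Mo) —
  whose log-scale effect decays exponentially with distance
  (`exp(−d/decay_length)`, default 150 m). Burning and dismantling samples
  sit at their hotspots, community samples on a surrounding grid,
  background samples effectively at infinity.
- **Censoring** below per-element LODs, emitted as proper censored cells;
  the latent truth is returned alongside.
- **Group sizes** default to the field design the package targets:
  burning 14, dismantling 11, community 64, background 12.
- **Bioaccessibility** per sample × element from a normal truncated at 0
  (per-element mean/SD), with extract concentrations back-computed so
  `ivba_percent()` recovers the drawn value exactly.

Defaults were chosen once as field-realistic round numbers (e.g. background
Pb GM 25 mg/kg, GSD 2.5; burning Pb loading 250×) and are not calibrated to
any particular dataset. What the generator does **not** emulate: spatial
autocorrelation beyond the two deterministic decay kernels (no variogram
structure), analytical error distinct from field variability, correlated
censoring across elements, and compositional closure. Passing tests
therefore demonstrate that the pipeline recovers the truth of *this* data
model, not that any field dataset satisfies it.

Problem sizes used by the test and acceptance suites, chosen as the
package's own verification scale: KM-mean recovery on a 2,000-sample
uncensored field at GSD 2 (within 5% of the analytic lognormal mean
`exp(μ + σ²/2)` per element); null calibration over 2,000 replicates of
20 + 20; screen power over 200 replicates of the 14-versus-64 design with a
50× loading; exhaustive permutation oracles at ≤ 8 per group. The GSD-2
recovery configuration mirrors the calibration simulations' lognormal
convention and keeps the Monte-Carlo error of a 2,000-sample mean (~1.8%)
well inside the 5% recovery band.

## Known limitations

- Oral pathway only; no inhalation or dermal terms, no probabilistic
  (Monte-Carlo) exposure assessment.
- KM summaries only for nondetects; no regression-on-order-statistics or
  censored-MLE estimators.
- The guideline screen reports arithmetic as computed; where a site
  narrative disagrees with the numbers (e.g. an element whose mean sits
  below an intervention value), the numbers stand.
- Coordinates are abstract meters; no projections or geostatistics.
- Per-sample field data behind published exceedance counts are generally
  not distributed with papers, so such counts can only be checked
  qualitatively (via the generator's source structure), not numerically.
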