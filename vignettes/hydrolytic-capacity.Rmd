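---
title: "From chromogenic assays to feeding-phase hydrolysis capacity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chromogenic assays to feeding-phase hydrolysis capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agshydro)
```

This vignette is the package's own account of the science it implements:
the measurement model, the reactor model, the choices that were genuinely
open, and what the synthetic-data tests do and do not demonstrate about
real data.

## The measurement model

Chromogenic hydrolysis assays incubate sludge with an excess of a dye-coupled
substrate: *p*NP-palmitate (lipase, 410 nm), *p*NP-α- and
*p*NP-β-glucopyranoside (glucosidases, 400 nm), and azocasein (protease,
440 nm). Excess substrate makes product release zero order, so the absorbance
of sieved, TCA-quenched, NaOH-developed subsamples grows linearly in time and
the quantity of interest is a slope.

`fit_activities()` fits ordinary least squares with a **free intercept**.
The t₀ blank varies between vials (substrate preparations differ visibly in
initial absorbance, especially for the *p*NP-palmitate emulsion), and a free
intercept makes the slope invariant to any constant blank offset — which is
also why the package takes no position on whether blanks were subtracted
before fitting; absolute absorbances in fixtures should not be
over-interpreted.

Quality control follows two rules: a trace is discarded as below the
detection limit when its coefficient of determination is below 0.7, or when
fewer than 4 time points survive sampling and analysis. Both thresholds are
**inclusive**: R² exactly 0.7 and exactly 4 points pass, since the discard
rules are "lower than" and "less than". Two numerical corner cases needed a
decision:

* a perfectly flat trace has zero absorbance variance, so R² is formally
  0/0; the package defines it as 0, which routes flat traces into the
  below-detection branch — the scientifically intended outcome;
* a trace with fewer than 2 points cannot be fitted at all and is flagged
  `insufficient points` without a slope; duplicate time stamps raise an
  error rather than silently producing a degenerate axis.

Slopes convert to vial-total dye-release rates through the calibration slope
(AU per µmol dye per mL of measured solution) and the vial working volume
(default 40 mL; the vials are 40-mL and the liquid fill is not separately
specified, so the working volume is a parameter). The calibration is assumed
to be built on standards carried through the same 1:2 TCA and 1:2 NaOH
dilutions as the samples, so no extra dilution factor applies; a
`dilution_factor` argument exists for labs that calibrate on undiluted
standards. Negative fitted slopes on QC-passed traces are clamped to zero
with a warning — released product cannot be consumed in these assays, so a
negative slope is noise around zero.

**Replicate aggregation.** The combined uncertainty of a triplicate is not
fully specified by the phrase "aggregating the standard deviation between
triplicates and the standard deviation of the fits"; the package interprets
it as a root sum of squares,
`sqrt(var(rates) + mean(fit_se²))`,
i.e. between-replicate variance plus the average within-fit variance. This
is isolated in `aggregate_rates()` precisely so it can be swapped if a
different reading is preferred. QC-failed replicates are excluded before
averaging; a sample with no passing replicate is reported as below
detection, never as zero.

## Stoichiometry and COD conversion

*p*NP conjugates release one mole of dye per mole hydrolyzed. Azocasein
carries 6.9 tyrosine equivalents per mole, so protease rates in µmol Tyr
eq/h are divided by 6.9 (≈ 0.14 mol protein per mol Tyr eq; the 0.14 is
presentation rounding, the internal value is 1/6.9). Molar masses: 378 g/mol
for *p*NP-palmitate, 301 g/mol for the glucopyranosides, 23,000 g/mol for
azocasein. For lipase the mass basis is the full conjugate by default
(`pNP_palmitate`, 378), matching a conversion stated in terms of the
substrates' molecular weights; palmitate alone (256) is available in the
conversion table because either reading is defensible.

COD factors per gram of substrate (protein 1.5, carbohydrate 1.07, lipid
2.0 g COD/g) are **external literature defaults**, not measured values, and
are deliberately configurable; every downstream COD quantity scales linearly
with them, which the test suite checks as a sensitivity property.

## Reactor accounting

The bulk (liquid) volume of the reactor follows
`V_b = V_r (1 − TS · SVI₃₀ · (1 − ε))` with TS in g/L and SVI in mL/g
(their product over 1000 is the dimensionless settled-sludge volume
fraction) and a bed porosity ε = 0.52. The equation is written with SVI₃₀
while fast-settling granular sludge is usually characterized by SVI₅;
`reactor_state()` stores both so the aliasing is visible, and the shipped
example sets both to 40 mL/g. The stated plant bed volume (~3830 m³) is not
exactly reproducible from the TS range and SVI — the implied TS is ≈ 10 g/L
against a reported 12–15 g/L — so `bed_volume_m3` can be set directly,
overriding the SVI-derived value; the example configuration does exactly
that.

Reactor-level activity multiplies each fraction's biomass-specific activity
by its VS inventory (`V_r · TS · VS/TS · share`), the bulk activity by the
bulk volume, and the influent activity by the feed-batch volume. VS and TS
bases are kept distinct throughout: fraction composition is VS-based (84/7/9
% for large granules, small granules, flocs), loading computations TS-based.

## The tanks-in-series capacity model

The anaerobic feeding phase pushes one feed batch (default 3870 m³ over
1 h) bottom-up through the settled bed. The model splits the bed into
`n = 10` CSTR segments and assumes:

1. segment *j* hydrolyzes only once the influent front reaches it, at
   `(j − 1)·T/n`, and then at its full zero-order rate;
2. the bed is stratified by settling velocity — large granules at the
   bottom, then small granules, then flocs — and segments are filled
   bottom-up in that order by a cumulative-fill rule;
3. no substrate depletion: the assays measure maximum rates at excess
   substrate, so the result is a capacity, not an in-situ rate.

Total dye-equivalent release is converted to mg COD and divided by the fed
volume in litres. For a uniform bed the model collapses to the closed form
`k·M·T·(n+1)/(2n)/V_f`, which the test suite verifies to 10⁻⁹ relative
error for n ∈ {1, 2, 10, 100}; the exposure factor `(n+1)/(2n)` tends to ½
as the cascade refines.

Two open choices and how they were resolved:

* **Equal-VS segments.** The per-segment bookkeeping is mass-driven and the
  densities of the fractions are unknown, so segments hold equal VS rather
  than equal geometric volume (`mode = "equal_volume"` with explicit volume
  shares is available). With 84 % large-granule VS, equal segments put pure
  large granules in segments 1–8, a large/small mixture in segment 9 and a
  small/flocs mixture in segment 10 — a close approximation to the
  description of nine pure segments plus a mixed top segment, which an
  exact 10 × 10 % split cannot reproduce verbatim.
* **Bulk and influent enzymes are excluded by default.** The capacity is
  presented as sludge hydrolysis; dissolved bulk enzymes and enzymes
  arriving with the influent can be switched on per scenario flag. When
  included, bulk enzymes act for the whole feeding and influent parcels for
  T/2 on average (they arrive uniformly over the feeding).

## Influent characterization

Campaign averages use per-analyte arithmetic means with pairwise deletion —
the composition table has holes and nothing is imputed. The wet-weather
sample is excluded from the **COD averages only** (total and soluble COD):
storm dilution invalidates a COD mean, while sparse analytes such as lipids
keep every available measurement (the reported lipid mean of 20 g COD/m³
averages a dry- and a wet-weather value). A `weather_analytes = NULL`
switch applies the filter to every analyte for users who prefer a blanket
rule. Report rounding is to integers, applied at presentation only.

Activities measured on settled-and-concentrated influent are rescaled to
the original-influent basis by the volume ratio; when the settled fraction
is known to carry only part of the activity (43 % measured for lipase),
the extrapolated total is reported with an explicit flag, since the
extrapolation assumes supernatant activity scales with the settled share.

## The synthetic campaign generator

`generate_campaign()` inverts the measurement chain: a planted specific
activity × assay basis gives the vial rate, hence the absorbance slope,
from which noisy linear traces are drawn. It emulates the sampling design
(3 days × 7 sample types × 4 assays × triplicates × 6 time points) with:

* i.i.d. Gaussian absorbance noise (default 0.01 AU; spectrophotometer-like,
  deliberately homoscedastic);
* lognormal day-to-day multipliers on the true activities (CV 0.2, matching
  the large day-to-day variation reported for these assays);
* a 5 % probability that a replicate fails flat (near-zero slope plus
  noise), reproducing the real discard mode of poorly fitting traces;
* planted truths anchored to the mixed-sludge magnitudes (α-glucosidase 13,
  β-glucosidase 17, lipase 34 µmol *p*NP (g VS h)⁻¹, protease 10 µmol Tyr
  eq (g VS h)⁻¹) with the reported ordering flocs > small granules > large
  granules, and small per-mL activities for bulk and influent;
* one root seed; the whole output stream is reproducible byte for byte.

What passing tests show: the chain is an exact inverse at zero noise, is
unbiased (< 2 % pooled, < 2 % per cell for all biomass-bound activities
over 200 campaigns at 0.002 AU noise), and the QC filter removes planted
failures at the planted rate. What they do not show: real assays have
heteroscedastic noise, emulsion variability (*p*NP-palmitate), substrate
depletion near the end of long incubations, and sampling heterogeneity
between granules — none of which the generator models. One deliberate edge
case is informative: the influent protease truth is planted near the assay
detection limit (the corresponding real measurement was not sensitive
enough to succeed), and there the QC filter's censoring introduces a small
positive conditional bias (~1–2 %) in survivors — an intrinsic property of
threshold-based QC at the detection edge, worth remembering when
interpreting near-detection activities in real campaigns.

## Problem sizes and numerical conventions

The stochastic test battery uses 200 synthetic campaigns (≈ 50,000 traces)
at 0.002 AU noise for the recovery checks and ≈ 500 traces for the QC-rate
check; the acceptance script uses 25 campaigns. Capacity checks run the
cascade at n up to 1000. All regressions are closed-form OLS on grouped
tibbles, so the whole suite runs in about two minutes on one core.

Conventions: QC boundaries inclusive; flat traces R² = 0; negative
QC-passed rates clamped to zero with a warning; shares are percentages that
sum to 100 within each enzyme; mg COD/L and g COD/m³ are treated as the
same unit (they are numerically identical); all report CSVs carry full
precision plus rounded presentation columns, and report bundles embed a
configuration hash so identical inputs provably produce byte-identical
outputs.

## Known limitations

* The capacity model has no hydrodynamic dispersion, no granule-scale
  diffusion–reaction, and no substrate saturation; it bounds what the
  measured enzyme pools could do, not what they will do on real wastewater
  polymers, whose biodegradability is lower than the model substrates'.
* COD factors and the azocasein molar mass are configurable literature
  values; capacities scale linearly with them.
* The mixed-sludge activity table applied bed-wide is an
  order-of-magnitude anchor for the per-fraction capacities, not a
  reconstruction: per-fraction inputs behind the published per-enzyme
  capacities are not available as numbers.
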