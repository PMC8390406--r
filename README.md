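# agshydro

Hydrolysis of polymeric substrates — proteins, carbohydrates, lipids — is
often the rate-limiting step in biological wastewater treatment. In aerobic
granular sludge (AGS) reactors the influent is fed anaerobically from the
bottom, in plug flow, through a settled bed of granules and flocs, and the
question of *how much substrate the bed's hydrolytic enzymes can cleave
during that feeding phase* decides how much of the incoming COD is made
available to the slow-growing organisms that give AGS its advantages.

`agshydro` is an R package for researchers and process engineers who measure
hydrolytic enzyme activities of sludge with chromogenic assays
(*p*-nitrophenyl conjugates for lipase and α/β-glucosidase, azocasein for
protease) and want to take them all the way to a reactor-level answer. It
covers:

* **Assay processing** — per-replicate ordinary least-squares fits of
  absorbance vs time (the assays run at excess substrate, so product release
  is zero order), quality control (traces with R² < 0.7 or fewer than 4
  points are discarded as below detection), replicate aggregation with
  combined uncertainty, and biomass- (g VS) or volume-specific (mL)
  activities.
* **Stoichiometric and COD conversions** — dye release → substrate moles
  (1:1 for *p*NP conjugates; 6.9 Tyr equivalents per mole azocasein, so
  1 mol Tyr eq ≈ 0.14 mol protein) → substrate mass → g COD via per-class
  factors.
* **Reactor accounting** — solids inventory, the settled-bed bulk-volume
  relation `V_b = V_r (1 − TS·SVI·(1 − ε))`, fraction-weighted reactor-level
  activity totals and percentage shares, and plant loading descriptors.
* **Feeding-phase capacity** — a tanks-in-series (10-CSTR) model of the
  stratified bed: influent fills the bed bottom-up, segment *j* starts
  hydrolyzing at `(j−1)·T/n`, and the summed zero-order release over the
  feeding, converted to COD and divided by the fed volume, is the maximum
  hydrolyzable substrate per litre of influent. For a uniform bed this is
  `k·M·T·(n+1)/(2n)/V_f`.
* **Synthetic campaigns** — a generator that emulates a full sampling
  campaign (3 days × 7 sample types × 4 assays × triplicates) with known
  ground truth, so the entire chain is testable without plant data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` for the result objects.

## Worked example

Simulate a campaign and run the full chain against the shipped full-scale
reactor description (9500 m³, TS 13.5 g/L, VS/TS 0.80, SVI 40 mL/g, bed of
84/7/9 % large granules/small granules/flocs by VS, 3870 m³ fed over 1 h):

```r
library(agshydro)

campaign <- generate_campaign(campaign_spec(seed = 2024))
report <- run_pipeline(campaign$readings, out_dir = "report")
report
#> <hydro_report>
#>   sample conditions: 84
#>   fraction x enzyme means: 28
#>   capacities (mg COD/L influent):
#>     alpha_glucosidase      65.6
#>     beta_glucosidase       72.1
#>     lipase                382.4
#>     protease              670.5
#>   config hash: 49679ce60ce8cbe4ca3cc483006ec5fc
```

The capacities say that during one 1-h anaerobic feed, the bed's enzymes
could hydrolyze at most ~670 mg COD of protein per litre of influent fed —
far above typical soluble protein concentrations (tens of g COD/m³), i.e. a
large hydrolysis overcapacity. Per-fraction activities and reactor-level
shares are in the report:

```r
dplyr::filter(report$fraction_activities, enzyme_class == "protease")
#>   fraction         basis   specific_activity ...
#> 1 flocs            per_gVS            27.1          # flocs most active per g VS
#> 5 large_granules   per_gVS             8.74
#> 6 mixed            per_gVS             9.96

dplyr::filter(report$breakdown, enzyme_class == "protease")[, c("source", "share_pct")]
#>   source         share_pct
#> 1 large_granules     51.7     # but granules dominate at reactor level
#> 2 small_granules      7.44
#> 3 flocs              17.2
#> 4 bulk               17.4
#> 5 influent            6.29
```

Flocs are the most active fraction per gram VS, yet large granules carry
most of the reactor-level activity because they hold 84 % of the biomass —
the central observation this analysis chain is built to quantify.

Plant descriptors from the influent summary:

```r
loading_rates(garmerwolde_reactor(), flow_m3_d = 15500,
              avg_influent_cod_g_m3 = 619)
#>   volumetric_loading sludge_loading ver_pct
#> 1               1.63         0.0748    40.7
```

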