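# microtherm

Warming experiments on coastal seawater consistently show that heterotrophic
bacterioplankton get *smaller* and carry *less nucleic acid* when incubated a
few degrees above their collection temperature — a microbial expression of
the temperature–size rule, mirrored by faster growth (positive activation
energies) while community composition barely shifts. `microtherm` implements
the complete analysis pipeline behind that kind of study, for researchers
who assay bacterioplankton by flow cytometry in temperature-manipulation
incubations:

* **Cytometry** — automated gating of the high- and low-nucleic-acid
  populations (HNA/LNA) from side scatter (SSC) and green fluorescence,
  normalisation to internal 1 µm bead standards (`ru`/`fru` units),
  conversion of SSC to cell diameter via an empirical power-law calibration
  and to volume as a sphere, `V = (π/6)d³`, plus inter-calibration between
  nucleic-acid stains (Syto 13 ↔ Sybr-Green I).
* **Temperature response** — per-bottle means over the incubation, OLS
  slopes of mean cell volume and NAC against incubation temperature
  (n = 9: three replicates × three temperatures) with 95 % CIs, the
  percent-per-°C normalisation `% °C⁻¹ = −100·slope/ambient`, conversion of
  NAC loss to base pairs through the 2 Mbp (LNA) and 5 Mbp (HNA) genome-size
  anchors, growth rates from the log-linear phase of abundance, and
  activation energies *E* (eV) from Arrhenius plots of ln µ against 1/kT.
* **Community structure** — CARD-FISH probe counts as percentages of DAPI,
  ARISA peak filtering (100–1000 bp, RFI cutoff 0.09) and shifting-window
  3-bp OTU binning, Bray–Curtis dissimilarity, UPGMA dendrograms (Newick
  export) and a clade-concordance statistic for "same-month samples cluster
  together".
* **Synthetic data** — a generator that emulates the full monthly incubation
  design (12 months × {C, F} treatments × {−3, 0, +3 °C} × 3 replicates)
  with known ground truth: tri-modal log-normal event clouds, injected
  per-°C size/NAC effects, size–NAC event-level correlation, three-phase
  growth with Arrhenius temperature dependence, and CARD-FISH/ARISA
  community tables. Every downstream estimator can therefore be validated
  against the injected truth.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()`/`plot_*()` for figures.

## Worked example

Simulate three months of incubations, run the pipeline, and look at the
annual temperature responses:

```r
library(microtherm)

design <- experiment_design(months = month.abb[1:3],
                            ambient_temperature = c(13.2, 12.8, 13.1))
res <- run_pipeline(design, truth_params(), seed = 42, n_events = 1000)

res$temperature$annual
#> # A tibble: 8 × 6
#>   treatment group response  mean_slope   se_slope n_months
#>   <chr>     <chr> <chr>          <dbl>      <dbl>    <int>
#> 1 C         HNA   nac      -0.000150   0.0000123         3
#> 2 C         HNA   volume   -0.000257   0.0000253         3
#> 3 C         LNA   nac      -0.00000515 0.0000177         3
#> 4 C         LNA   volume    0.00000586 0.0000206         3
#> 5 F         HNA   nac      -0.0000653  0.0000103         3
#> 6 F         HNA   volume   -0.000203   0.0000564         3
#> 7 F         LNA   nac      -0.00000512 0.00000600        3
#> 8 F         LNA   volume   -0.0000754  0.0000716         3
```

Negative slopes mean cells get smaller (volume, µm³ °C⁻¹) or lose nucleic
acid (NAC, fru °C⁻¹) per degree of warming; the HNA group in the
whole-community (C) treatment responds most strongly, the LNA groups
weakly. Per month the slopes come with significance calls and the
percent/base-pair equivalents:

```r
dplyr::filter(res$temperature$slopes, month == "Feb", group == "HNA")
#>   month treatment group response      slope      se significant percent_per_degc
#> 1 Feb   C         HNA   volume   -0.000306  7.09e-5 TRUE                   0.499
#> 2 Feb   C         HNA   nac      -0.000141  2.78e-5 TRUE                   0.406
#> 3 Feb   F         HNA   volume   -0.000106  8.97e-5 FALSE                  0.171
#> 4 Feb   F         HNA   nac      -0.0000584 3.08e-5 FALSE                  0.168
```

so in February the C-treatment HNA cells shrank by ≈ 0.5 % °C⁻¹ in volume
and lost ≈ 0.4 % °C⁻¹ of NAC — ≈ 20 kbp °C⁻¹ through the 5 Mbp HNA anchor
(`kbp_per_degc` column). Growth responds in the opposite direction:

```r
res$temperature$arrhenius[1:4, ]
#>   month treatment group  e_ev  slope     se     n r_squared
#> 1 Jan   C         HNA   0.587 -0.587 0.0414     3     0.995
#> 2 Jan   C         LNA   0.484 -0.484 0.0342     3     0.995
#> 3 Jan   F         HNA   0.567 -0.567 0.0267     3     0.998
#> 4 Jan   F         LNA   0.553 -0.553 0.0490     3     0.992
```

positive activation energies (≈ 0.5–0.6 eV here) meaning faster growth in
the warmer bottles. Community structure, by contrast, stays organised by
month rather than by temperature:

```r
res$community$arisa_trees$C$concordance
#> <mt_concordance> 100% of groups exclusive (100% of multi-leaf groups)
```

`autoplot()` on gated events, `plot_temperature_slopes()` on the monthly
slope table and `autoplot()` on an Arrhenius fit give the corresponding
figures; `write_results(res, dir)` writes every table (TSV), dendrogram
(Newick) and the ground-truth record (JSON) to disk.

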