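---
title: "Methods: temperature responses of bacterioplankton size and nucleic acid content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature responses of bacterioplankton size and nucleic acid content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtherm)
```

## The experimental system

`microtherm` analyses short (4–7 day) warming incubations of coastal
seawater. Each monthly experiment splits water into a whole-community
treatment (**C**, 200 µm pre-filtered, grazers present) and a filtered
treatment (**F**, 0.8 µm pre-filtered, essentially bacteria only), incubated
in triplicate at the ambient collection temperature and at fixed offsets
(−3 and +3 °C by default): 18 bottles per month. Bottles are subsampled one
to two times per day; each subsample is a flow-cytometry acquisition in
which stained cells report green fluorescence (a nucleic-acid-content
proxy, NAC) and side scatter (SSC, a cell-size proxy), and 1 µm reference
beads provide an internal standard.

Two bacterial populations are distinguished by their nucleic-acid
fluorescence: **HNA** (high) and **LNA** (low). The scientific questions the
pipeline answers are: how much smaller do cells get per degree of warming,
how much nucleic acid do they lose, how strongly do growth rates accelerate
(activation energy), and does community composition reorganise under
warming or stay structured by season.

## Cytometry model

* **Bead normalisation.** Each signal is divided by the arithmetic mean of
  the bead-labelled events in that channel, so the bead mean is exactly
  1 `ru`/`fru` and all downstream relative quantities are invariant to
  instrument gain. At least 20 bead events are required (a smaller
  denominator makes the normalisation unstable); fewer is a hard error
  naming the acquisition.
* **Gating.** Beads are removed first as events within ±1 natural-log unit
  of the known nominal bead position in both channels. The HNA/LNA split is
  a threshold on log green fluorescence at the deepest minimum of a kernel
  density estimate (`stats::density`, 512 grid points, default bandwidth)
  between the two highest modes. Two robustness rules avoid phantom splits:
  a mode must reach at least 5 % of the peak density, and the valley
  between the two modes must dip below 90 % of the lower peak. If no
  admissible threshold exists the distribution is treated as unimodal: all
  bacterial events are labelled as a single population (HNA, an arbitrary
  but documented choice) and the gate is flagged. Gating is deliberately
  one-dimensional: the group definition is by fluorescence, and an
  automated, auditable threshold replaces manual two-dimensional gates.
* **Size conversion.** SSC in bead-relative units maps to diameter through
  a strictly increasing power law `d = a·ssc^b` (equivalently linear on
  log–log axes); coefficients are instrument/site calibrations supplied by
  the user. The defaults (`a = 1`, `b = 0.25`, valid range 10⁻⁴–2 ru) place
  ambient bacterial volumes in the realistic 0.035–0.091 µm³ window. Inputs
  outside the valid range are converted but flagged as extrapolated;
  non-monotone models are rejected at construction. Volume assumes spheres,
  `V = (π/6)d³`.
* **Per-event conversion.** Population mean volume is the average of
  per-event volumes, not the volume of the mean scatter. The two differ by
  a Jensen gap (the cube is convex); the per-event mean is the biologically
  meaningful average cell volume and is what the generator's ground truth
  refers to.
* **Dye inter-calibration.** Fluorescence measured with a different
  nucleic-acid stain is mapped onto the reference scale by an OLS line
  fitted to paired runs of the same samples; a non-positive fitted slope is
  rejected as non-monotone, and converting without a fitted model is an
  error.

## Temperature-response inference

* **Per-bottle means.** The response entering the regression is the mean
  over all sampling times of a bottle's per-acquisition population mean
  (volume or NAC). Cell size drifts with growth phase, so two robustness
  variants are also computed: the mean over the detected exponential
  window, and the value at maximum abundance. Bottles need at least two
  usable time points; missing time points are logged, not fatal.
* **OLS slopes.** For each month × treatment × group, the bottle means are
  regressed on incubation temperature (`stats::lm`; typically n = 9). The
  95 % CI uses the t distribution with n − 2 df, and a slope is
  "significant" when the CI excludes zero. Regressions proceed with
  missing bottles down to n = 3 (with a warning below 4); a design with a
  single temperature is rejected.
* **Percent per °C.** `% °C⁻¹ = −100·slope/reference`, positive = reduction.
  The reference is by default the mean of the ambient-temperature
  replicates at time 0 for that month/treatment/group; any positive
  reference (e.g. the initial value) can be supplied, and the percent is
  invariant to common unit rescaling of slope and reference.
* **Base pairs.** NAC percent converts to absolute nucleic-acid loss by
  equating each group's ambient NAC to a genome-size anchor — 2 Mbp (LNA)
  and 5 Mbp (HNA), the two peaks of the bimodal distribution of bacterial
  genome sizes: `kbp °C⁻¹ = (%/100)·anchor·1000`.
* **Growth rates.** µ is the OLS slope of ln(abundance) on time (days) over
  the linear phase, found by exhaustive search over contiguous windows of
  ≥ 3 points: among windows reaching r² ≥ 0.95 the largest slope wins,
  ties going to the longer and then the earlier window. If no window
  reaches the threshold the best-slope window is returned flagged; a
  non-positive best slope (declining series, as happens for LNA in the C
  treatment in some seasons) is flagged rather than discarded.
* **Activation energy.** ln µ is regressed on 1/(kT) with
  k = 8.617×10⁻⁵ eV K⁻¹ and T in Kelvin. The raw slope of that regression
  is −E; the package reports `E = −slope` so that **positive E means faster
  growth when warmer**, and stores the raw slope alongside. Non-positive
  rates are dropped with a warning; fewer than two usable temperatures is
  an error.
* **Cross-correlations.** Monthly slope series for every
  response × group × treatment combination are correlated pairwise
  (Pearson, two-sided t-based p values); zero-variance series are flagged
  rather than propagating NaNs.

## Community-structure methods

* **CARD-FISH.** Probe counts become percentages of the DAPI total; the
  summed coverage of the probe set is reported per sample. Counts exceeding
  DAPI are rejected.
* **ARISA filtering.** Intensities are normalised to sum 1 over all raw
  peaks, then peaks outside 100–1000 bp or below the 0.09 cutoff are
  removed, then survivors are renormalised. The cutoff applies to the
  *normalised* scale and is inclusive (a peak exactly at 0.09 is
  retained); the order normalise → cutoff → renormalise is a documented
  choice, as is inclusivity. Samples left empty are flagged.
* **Binning.** Fragments go into 3-bp bins `[start, start+3)`. Candidate
  frames shift the anchor (100 bp) in 0.1-bp steps across one window;
  the frame maximising the mean pairwise sample similarity (1 − Bray–Curtis)
  of the resulting table is selected — the published shifting-window
  criterion. Each fragment lands in exactly one bin per frame, so
  per-sample intensity totals are preserved; an occupied bin is an OTU.
* **Dissimilarity and trees.** Bray–Curtis via `vegan::vegdist`; UPGMA
  (average linkage, `stats::hclust`) as the default dendrogram with
  complete/single as options; Newick serialisation via `ape`. The
  qualitative claim "samples from the same month cluster together" is
  quantified as the fraction of label groups whose leaves form an exclusive
  subtree; singleton groups are trivially concordant and reported
  separately.

## The synthetic-data generator

The generator produces the complete dataset of a monthly study with known
ground truth, so every estimator above can be validated by simulation.

* **Event clouds** are bivariate log-normal per cluster (LNA, HNA, beads):
  positive support and right skew are what cytometry channels actually look
  like. Cluster locations are arithmetic means; the log-scale SSC–
  fluorescence correlation within a population defaults to 0.82. Because
  log-volume is linear in log-SSC under the power-law calibration, that
  injected value is recovered as the Pearson r of the log signals within a
  population; pooling populations adds a between-cluster component, so the
  recovery checks are per population.
* **Injected effects.** Mean volume and NAC at temperature T equal
  `ambient + slope·(T − T_ambient)` plus a per-bottle Gaussian offset.
  The default slopes are expressed as percent-of-ambient per °C
  (size: 0.42/0.16/0.53/0.05 % °C⁻¹ and NAC: 0.22/0.12/0.44/0.04 % °C⁻¹
  for HNA F / LNA F / HNA C / LNA C). Printed annual slope tables of this
  kind of study have magnitudes (~10⁻³ µm³ °C⁻¹) that are mutually
  inconsistent with the printed ambient scales (~0.05 µm³) — taken
  literally they imply multi-percent reductions per °C and would invert the
  HNA/LNA ordering within the ±3 °C span. The generator therefore treats
  the *relative* pattern as the study condition and keeps the absolute
  event-cloud scale coherent; the summary-level slope-recovery study
  (below) still injects the literal µm³ °C⁻¹ value, where no event-cloud
  coherence is involved.
* **Noise levels.** Bottle-level SDs (5×10⁻⁴ µm³, 2.5×10⁻⁴ fru) are chosen
  so the implied slope standard errors at the n = 9 design
  (SE = SD/√54) keep the reported SE-to-slope ratios (≈ 0.2 for the HNA C
  responses, larger for LNA — whose slopes are then, correctly, mostly
  non-significant). Event-level log-SDs default to 0.15 (SSC) and 0.09
  (fluorescence); the latter puts the LNA and HNA modes ≈ 6 combined SDs
  apart, the separation at which automated gating is essentially lossless.
* **Growth** is three-phase: flat lag (1 d), exact exponential at the
  Arrhenius rate for the bottle temperature (µ_ref = 0.6 d⁻¹ at ambient,
  E = 0.65 eV, LNA rates scaled by 0.7), and a hard carrying-capacity
  ceiling (6×10⁶ cells mL⁻¹ against 2×10⁵ initial). A hard ceiling rather
  than a smooth logistic keeps log-abundance exactly linear inside the
  exponential phase, which is what makes "window detection recovers the
  injected rate" a sharp test; a smooth logistic depresses every finite
  window's slope by design and would conflate generator curvature with
  estimator bias. Per-bottle rate noise (CV 5 %) and per-acquisition
  abundance measurement noise (CV 3 %) are lognormal.
* **Phase drift.** Mean size/NAC optionally drift by phase (+2 % in lag,
  −2 % in exponential by default) so whole-experiment vs growth-phase mean
  comparisons are exercisable; tests of exact zero-noise arithmetic set the
  drift to zero as part of the zero-noise condition.
* **Communities.** Each month gets its own CARD-FISH composition (log-normal
  jitter, SD 0.5, around global proportions summing to 0.704 of DAPI, with
  total coverage held within ≈ 1 %) and its own ARISA profile: 35 true
  fragments at least 4 bp apart, of which 6 dominant fragments carry 85 %
  of the intensity (they survive the 0.09 cutoff; the rare tail exercises
  the filter), lengths jittered by SD 0.4 bp per sample so 3-bp binning is
  non-trivial, plus below-cutoff and out-of-range nuisance peaks.
* **Reproducibility.** One master seed is split deterministically into
  per-bottle substreams (plus one for the community tables), so identical
  `(design, truth, seed)` give identical output while replicates remain
  independent.

What the generator does **not** emulate: real seasonal climatology of the
ambient values (ambient temperature follows a smooth coastal cycle but
sizes/NAC are constant across months by default), doublets and spillover,
autotroph channels, explicit grazer or viral dynamics (the C–F contrast is
only a difference in truth parameters), PCR/primer bias in ARISA, and
taxonomy of bins. Passing tests therefore demonstrate that the estimators
recover known truth under a faithful rendering of the design and noise
structure — not that any particular field dataset would yield the same
numbers.

## Numerical choices and degenerate inputs

* Natural logs throughout; Boltzmann constant housed as `boltzmann_ev()`.
* Window search ties broken by longer window, then earlier start
  (tolerance 10⁻¹²); a perfectly flat window has r² defined as 1 (zero
  residual on zero variance) but can only win if nothing grows.
* Binning frames anchored at 100.0 bp + offset, offsets 0–2.9 bp in 0.1-bp
  steps; equal frame scores resolve to the smallest offset. Single-fragment
  input yields a single bin.
* Degenerate gates (zero events in a group) give abundance 0 with `NA`
  means and an `empty` flag; zero acquired volume is rejected.
* All-zero sample pairs have undefined Bray–Curtis distance (flagged);
  fewer than three samples give a trivial dendrogram with a warning.
* Arrhenius fits drop non-positive rates (log-undefined) with a warning
  and fail below two usable temperatures.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale, chosen to keep the full suite in a few minutes while leaving
Monte-Carlo error well below the tolerances tested: 10⁵-event cytograms for
gating/correlation checks, 500-replicate studies for CI coverage and
Arrhenius bias, 100 random toy sets for the brute-force binning
equivalence, 20–40 replicate community simulations for clade concordance,
and a full 12-month × 18-bottle year at 400–1000 events per acquisition for
the end-to-end determinism and headline-quantity runs.

## Known limitations

* The gating threshold is one-dimensional; populations separated only in
  scatter would need the two-channel information the paper-style manual
  gate uses implicitly.
* The SSC→diameter calibration is user-supplied; the defaults are
  order-of-magnitude realistic, not an instrument calibration.
* Growth-window selection by maximum slope is slightly optimistic under
  strong noise (selection bias); the acceptance checks quantify bias at
  the noise levels the design implies.
* Activation energies inherit any truncation of the exponential window at
  warm temperatures (earlier saturation), which can bias monthly E a few
  percent low relative to the injected value — visible in, and quantified
  by, the generator-based checks.
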