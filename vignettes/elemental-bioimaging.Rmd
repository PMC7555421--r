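---
title: "Methods: LA-ICP-MS elemental bioimaging with elamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LA-ICP-MS elemental bioimaging with elamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elamap)
```

## The measurement model

A line-scanning LA-ICP-MS experiment rasters a thin cryosection (30 µm in
the liver protocol this package models) with a laser moving at
50–60 µm/s, while a sequential quadrupole cycles through an isotope menu —
¹³C, ²³Na, ²⁴Mg, ⁴⁴Ca, ⁵⁵Mn, ⁵⁶Fe, ⁶³Cu, ⁶⁴Zn — spending a 20 ms dwell on
each. One full sweep over 8 isotopes plus a 20 ms settling overhead takes
0.18 s, during which the laser advances `55 µm/s × 0.18 s = 9.9 µm`; that
product is the along-scan pixel pitch, and adjacent lines are spaced by
the same distance for square pixels. The expected signal of isotope *e*
at time *t* on line *y* is

    E[I_e(t)] = S_e · c_e(x(t), y) · d(t) + B_e

with sensitivity `S_e` (cps per µg/g), concentration field `c_e`,
a multiplicative drift `d(t)` shared by all isotopes (`d(0) = 1`), and a
gas-blank background `B_e` that is *not* subject to drift (it originates
in the carrier gas and electronics, not in ablation yield). Observed
intensities add Poisson counting noise at `cps × dwell` counts plus
Gaussian electronic noise (σ = 2 cps), floored at zero.

Three modelling assumptions matter downstream:

* **Carbon uniformity.** ¹³C is treated as spatially uniform in tissue
  (the generator gives it a 2% between-pixel CV, one fifth of the other
  elements' 10%). This is what justifies using the analyte/¹³C ratio to
  cancel drift and ablation-yield variation; where carbon genuinely
  varies (severe steatosis, for instance), the ratio inherits that
  variation.
* **Shared drift.** Drift multiplies every isotope identically, so it
  cancels exactly in the ratio. Isotope-specific drift would not.
* **Additive, drift-free background.** Background is estimated from
  pooled laser-off cycles per run (per-line blanks are short and noisy)
  and subtracted before normalization.

## Image assembly

Assembly is a pure reshape: one map row per line (ordered by the laser
log's y-coordinate), one pixel per laser-on cycle, `NA` padding for lines
of unequal length, no resampling or smoothing — published element maps of
this kind are raw pixel maps, and any interpolation belongs in
visualization only. The implementation is verified against an
independent nested-loop re-implementation on all small runs.

Normalization order: the package subtracts background first, then forms
the analyte/¹³C ratio. The reverse order would leave a `B_e/I_13C` term
varying with carbon signal. Pixels whose ¹³C signal falls below 5% of the
¹³C tissue median become `NA` (division guard); the threshold is relative
so it scales with instrument sensitivity.

## Calibration

Standards are modelled on the matrix-matched practice of spiking
homogenized tissue with a multi-element salt solution. Each standard is a
homogeneous raster at `matrix baseline + spike`, scanned with the sample
protocol, and is characterized by its **total** content — as certified
reference materials are — so the calibration quantifies absolute
concentration rather than concentration-above-homogenate. The level-0
(unspiked) standard anchors the low end; the OLS intercept stays free to
absorb residual blank. The response statistic is the *mean* ratio over
all standard pixels (standards are homogeneous, so the mean is efficient;
a median would discard precision for no robustness gain here).

Detection limits follow the 3σ/10σ convention: `LOD = 3 σ_blank/slope`,
`LOQ = 10 σ_blank/slope`, with σ_blank taken from the laser-off cycles of
the lowest standard, expressed in ratio units. Concentrations below zero
after inversion are floored (and counted); pixels below LOD keep their
value but carry a flag, so summary statistics remain computable while the
below-LOD fraction is reported alongside.

Default spike levels (four per element) bracket the expected hepatic
ranges — for copper `0, 5, 50, 200 µg/g`, wide enough to cover both the
~2–3.5 µg/g wild-type and the ~113 µg/g knockout regime without
extrapolation. No weighted or robust regression is attempted: four
homogeneous standards give no leverage structure worth reweighting.

## Segmentation and reporting

Tissue is segmented on the ¹³C channel — never on an analyte, so that the
mask cannot bias the quantity under study. The mask is Otsu's threshold
on the intensity histogram, then the largest connected component with
holes filled (EBImage). Per-element statistics (mean, SD with n−1,
median, 5th/95th percentiles) are computed over masked, non-`NA` pixels.

Group comparison is deliberately descriptive — group means, fold changes,
differences, and within-section Cu-to-element pixel correlations — with
no inferential tests: the biological contrasts the package reproduces
were reported as means ± SD, and synthetic replicates would make p-values
meaningless anyway.

The diagnostic rule compares copper against 250 µg/g **dry** weight while
sections are measured wet. The wet-to-dry factor is an explicit,
configurable parameter (default 3.3, reflecting ~70% liver water
content, documented as a convention); both wet and dry-equivalent values
are always reported, never silently converted.

## The synthetic generator

The phantom generator encodes the study conditions the pipeline is
validated against:

* Copper: a smooth random field, relatively homogeneous, with preset
  means of 3.41, 3.45, 2.09 µg/g (wild type at 9, 13, 36 weeks) and
  112.72 µg/g (*Atp7b*⁻/⁻), between-pixel SD 10% of the mean, rescaled so
  the tissue-mask mean matches the preset exactly. Reported hepatic
  copper levels for these genotypes come as animal-level means with
  between-animal spreads; those spreads say nothing about pixel-scale
  texture, so the pixel CV is a separate, documented choice.
* Magnesium: baseline 200 µg/g with a negative coupling to copper
  (slope −0.27 relative to the wild-type copper reference 3.41 µg/g),
  yielding the ~15% knockout drop; zinc: baseline 25 µg/g scaled ×1.2 in
  the knockout ("slight increase"); both retain their own 10%
  heterogeneity, so the Cu–Mg pixel correlation is negative but modest.
* Iron: baseline 150 µg/g, elevated ×1.5 within a 30 µm band along the
  edges of a hexagonal tiling (lobule rims, pitch 250 µm), built as the
  Voronoi boundaries of a triangular lattice. Manganese: baseline
  1.2 µg/g with low-frequency zonal structure (contrast 1.3). Sodium
  1000, calcium 50 µg/g at baseline; carbon proxy 10⁵ µg/g.
* Baselines for Mg/Zn/Fe/Mn/Na/Ca are order-of-magnitude liver values,
  chosen once and documented in `elamap_defaults()`. Magnesium is often
  left out of imaging isotope menus of this kind; it is carried here
  because the knockout magnesium drop is one of the contrasts the
  generator encodes, and its baseline is flagged as inferred rather than
  measured.
* The tissue mask is a single connected, boundary-roughened ellipse; all
  fields are zero outside it.

The instrument defaults (sensitivities 0.5–500 cps per µg/g, backgrounds
5–150 cps, Poisson + 2 cps Gaussian noise, linear 1 → 1.05 drift over the
run) were chosen so that count rates, relative noise and detection limits
land in realistic ranges — the default copper LOD works out near
0.4 µg/g, comfortably below the leanest wild-type preset.

What the generator does **not** emulate: ablation-crater physics and
aerosol washout tailing (which blur real maps along the scan direction),
isobaric/polyatomic interferences, inter-line registration errors, and
genuine biological microstructure (cells, vessels, bile ducts). Passing
recovery tests therefore demonstrates that the *pipeline arithmetic* is
unbiased under a realistic noise model — not that the instrument model
captures every artifact of a physical laser system.

## Numerical and design choices

* **Determinism.** Every stochastic artifact takes one integer seed;
  element fields and noise draws use fixed per-stream sub-seeds, so
  identical inputs give byte-identical runs, and pipeline reports
  re-run byte-identically from the same config.
* **Degenerate inputs.** Uniform ¹³C maps refuse to segment ("no
  tissue detected"); calibrations with non-positive slope or a single
  level are errors; runs whose laser log contradicts the recorded cycles
  fail validation with the offending line and cycle named; maps without
  a declared unit are rejected outright to keep cps and µg/g apart.
* **Flooring.** Intensities, background-subtracted maps and
  concentrations are floored at zero with counts recorded in provenance;
  this introduces a small positive bias exactly at the blank level,
  which is why blank-residual checks compare the unfloored mean.
* **Problem sizes.** Validation uses 64×64-pixel sections (≈ 630 µm
  square at the 9.9 µm pitch, ~2500 tissue pixels), 32×8 standards, and
  10–20 replicate seeds per property; these sizes give sub-percent
  standard errors on recovered means while keeping the whole suite fast.
* **Recovery performance.** At default noise and drift, the full
  pipeline recovers each preset's copper mean well within 5% (typically
  within 1%), preserves the knockout > wild-type copper ordering and the
  magnesium/zinc contrasts for every seed, and segments tissue at
  Jaccard ≥ 0.95 against the phantom mask — all recomputed by the test
  suite and `scripts/acceptance.R`, which this vignette does not
  duplicate.

## Limitations

Quantification is single-session: no drift-corrected calibration
transfer between sessions, no weighted regression, no co-registration
with histology, and no lobule-level zonation statistics beyond the
rim/interior contrast. The wet-to-dry factor is a convention, not a
measured quantity; diagnostic flags near the 250 µg/g boundary should be
read with that in mind.
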