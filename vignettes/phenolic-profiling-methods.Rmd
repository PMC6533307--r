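---
title: "Methods: response surfaces, MSn annotation rules and RRF quantification"
author: "phenolProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response surfaces, MSn annotation rules and RRF quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolProfiler)
```

phenolProfiler implements the three stages of a phenolic-profiling
study — extraction optimization, spectral annotation, quantification —
as independent, composable modules. This vignette is the package's own
account of the models behind each stage, the parameters that matter,
the numerical choices made where the design was genuinely open, and
what the synthetic-data generator does and does not emulate.

## Stage 1: response-surface extraction optimization

### Model and assumptions

A central composite circumscribed (CCC) design in three factors
(extraction time, solid/liquid ratio, temperature) supports a full
second-order polynomial fitted by ordinary least squares **on coded
factors**:

$$y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
      \sum_{i<j} \beta_{ij} x_i x_j + \varepsilon,
      \qquad \varepsilon \sim N(0, \sigma^2).$$

Coding ($x = (X - X_0)/\Delta X$) puts the factorial block at $\pm 1$,
keeps the design matrix well conditioned, and makes coefficients
directly comparable across factors; uncoded values are derived for
display only. The model assumes independent homoscedastic Gaussian
response errors and a locally quadratic response — standard RSM
assumptions, checkable through the lack-of-fit test that the replicated
center points enable (`anovaTable()` splits the residual into pure
error, with $n_c - 1$ degrees of freedom, and lack of fit).

The solid/liquid ratio is parameterized as the continuous denominator
$D$ of "1:$D$ g/mL" (mL solvent per g material), center 20, step 10, so
that coded $\pm 1$ maps to 1:10 and 1:30. The packaged reference design
uses $\alpha = 1.68$ — the value as reported for the study, kept rather
than the rotatable 1.682 — and its axial settings are stored exactly
(e.g. 46.8 min, not the display-rounded 47).

The full 10-term quadratic is always fitted; no stepwise reduction is
attempted. The reference study reported a reduced-or-full model
ambiguously ("statistic results were not shown"), and the full-model
fit reproduces the reported $R^2$ within 0.001, so a reduced variant
was never needed.

### Optimization

`optimizeSurface()` maximizes the fitted polynomial over a finite coded
box by a dense grid scan (default resolution 0.01 coded units) followed
by an `L-BFGS-B` polish clamped to the box. The optimizer is entirely
deterministic; grid ties within $10^{-10}$ resolve to the
lexicographically smallest coded point. A quadratic in a box attains
its maximum either at an interior stationary point or on the boundary;
the grid-then-polish scheme handles both without case analysis and is
validated in the test suite against a brute-force 0.05-resolution grid
oracle over 50 random surfaces.

The default search region is the **factorial cube** $[-1, 1]^3$, not
the axial cube $[-1.68, 1.68]^3$: the factorial cube is the region
where all three factors were jointly varied (axial points probe one
axis at a time), so predictions there do not extrapolate the
interaction structure. The reference optimum lies exactly on two of its
faces, which is consistent with that convention. Users wanting the
axial envelope pass `region = c(-1.68, 1.68)`.

### Degenerate inputs

Missing responses raise an incomplete-design error; a rank-deficient
quadratic basis (e.g. duplicated factor columns) raises a
singular-design error; designs without center replicates return an
ANOVA table flagged `lack_of_fit_available = FALSE` rather than
erroring, since the model fit itself is unaffected.

## Stage 2: rule-based MSn annotation

### Data model

A `SpectralTree` holds one chromatographic peak: precursor [M−H]⁻ m/z,
UV absorbance maxima, retention time, and staged fragments
(MS2, MS3, MS4) each tied to its parent ion. Intensities are percent of
the level base peak in (0, 100]; at most one ion per level sits at
exactly 100 (printed spectra occasionally omit the base peak, so a
level without a 100 is tolerated). Fragments must be strictly lighter
than their parents — violated input is rejected at construction, which
is what makes `neutralLosses()` deltas provably positive.

### Tolerance and rules

All m/z matching uses a **0.5 Da tolerance**: the reference spectra are
nominal-mass ion-trap data, where unit resolution is the honest
granularity. The default neutral-loss table is small and diagnostic:
methyl 15, water 18, CO₂ 44, coumaroyl/deoxyhexosyl 146,
caffeoyl/hexosyl 162, and a 30 Da "methoxy-pair unit" used only by the
precursor-453 rule (that 60 = 2 × 30 reading is chemically loose, but
it is the published annotation convention for this compound and is
reproduced as stated, with a note attached to the output).

### The cascade

`annotate()` applies rules in a fixed priority order — flavone
aglycones/glucosides, quinic acid esters, oleuropein derivatives,
hydroxybenzoic specials (gallic acid monohydrate, the shikimic-mass
isomer), the precursor-453 rule, hydroxy fatty acids — and the first
firing rule wins. The order encodes the reasoning priority of targeted
profiling: an aglycone mass match is stronger evidence than a generic
neutral loss. Running the cascade is deterministic and
order-independent across a batch.

Design choices worth recording:

* **UV windows are inclusive candidate sets, not verdicts.**
  Flavones require a band in 330–360 nm plus one in 240–280 nm;
  hydroxycinnamates a band in 300–335 nm; hydroxybenzoics all bands
  below 330 nm or the 250/270/320 triple. The windows overlap
  deliberately (a spectrum with maxima at 240 and 330 nm is a
  candidate for both flavone and hydroxycinnamate), because several
  genuine hydroxycinnamates in the reference data carry band pairs
  that would satisfy an exclusive flavone test. Fragmentation rules,
  not UV, make the final call; UV only gates the flavone rule.
* **Hydroxy fatty acids** fire on precursor mass in 290–320 Da, a
  `[M−H−H₂O]⁻` ion at ≥ 25% relative intensity, and a precursor not
  coinciding with a flavone aglycone mass. The water-loss ion is *not*
  required to be the base peak: in dihydroxy acids the CO₂-loss
  channel can dominate while the water loss stays strong, and the
  reference data contain exactly that pattern. The aglycone-mass
  exclusion (rather than a UV exclusion) keeps chrysoeriol (m/z 299,
  inside the window) safe without rejecting fatty acids whose UV
  happens to show late bands.
* **+18 monohydrate rule.** A precursor exactly 18 Da above a library
  compound whose fragments then match that compound's cascade is
  named "`<compound>` monohydrate" (applies to the dicaffeoylquinic
  ester at 533 and gallic acid at 187).
* **3,5-regiochemistry** of dicaffeoylquinic esters uses a simplified
  intensity key (MS2 base 353; MS3 of 353 base 191 with 179 ≥ 10%);
  full hierarchical fragmentation keys from the chlorogenic-acid
  literature are out of scope, and trees failing the key demote to
  "isomer" with `tentative_isomer` confidence.
* The m/z 293 fatty acid keeps the reference spelling
  "monohydroxy-octadecaditrienoic acid" (flagged in the annotation's
  notes as a likely typographical variant of
  monohydroxy-octadecatrienoic acid) so that outputs remain comparable
  with the published identification table.

Confidence levels: `standard_matched` for the three flavones backed by
authentic standards (luteolin, apigenin, acacetin), `deduced` for
cascade-derived structures, `tentative_isomer` where a mass matches but
fragments diverge, `unknown` otherwise.

## Stage 3: quantification and validation

External standards give linear calibration curves (area on
concentration, OLS, ≥ 3 distinct levels required). Sensitivity limits
follow the signal-to-noise convention, LOD = 3σ/slope and
LOQ = 10σ/slope, from a user-supplied baseline noise σ — the original
instrument-derived S/N values are not recomputable, so σ is an explicit
input rather than a pretended constant. Accuracy and precision use
spike recovery, `[(after − before)/spiked]·100`, and the sample
(n−1) RSD — the conventional analytical choices for 3–5 replicates.

Compounds without standards are quantified against structurally
similar internal standards via the relative response factor
`RRF = (A_k/A_i)/(C_k/C_i)`, inverted as
`C = (A/A_i)·C_i/RRF/R`. The assignment map (protocatechuic acid for
simple phenolic acids, ferulic acid for hydroxycinnamoyl esters,
hesperidin for flavone glycosides and methoxyflavones) is shipped as
`defaultQuantMap()`. Recovery R defaults to 1.0 for RRF-quantified
compounds — the reference study does not state which standard's
recovery applies to which compound — and is configurable per compound.
Negative back-calculated concentrations clamp to zero with a warning:
blank-level areas below the intercept are routine and should not abort
a batch.

Contents convert to dry weight as
`conc · dilution · V_extract / m_dry / 1000` (mg/g DW); defaults
describe 0.5 g extracted in 15 mL, the optimal 1:30 ratio. The
colorimetric total-phenolic assay converts through the gallic acid
curve to g GAE/100 g DW. Class aggregation sums hydroxybenzoic,
hydroxycinnamic and flavonoid contents into the phenolic total; the
two published "around 25%" readings of the luteolin share are
disambiguated by always reporting the HPLC-based ratio (top compound
over the HPLC-quantified phenolic total), labelled as such.

The ± values attached to the packaged contents are treated as
extraction-replicate scatter (their replicate structure is not stated
in the source); they are carried as data, not recomputed.

## The synthetic-data generator

Each stage's generator inverts the stage's own model, so
generate-then-analyze round trips are exact at zero noise:

* **Surfaces**: responses are the quadratic polynomial plus additive
  Gaussian noise — exactly the fitting model.
* **Spectra**: library templates (all 23 reference peaks, including
  the three unknowns as distractors) perturbed by a **per-acquisition
  mass-axis offset** uniform in ±j Da applied to the precursor and
  every fragment, plus multiplicative Gaussian intensity noise on
  non-base ions (clamped to (0, 100)). The shared-offset model is how
  calibration drift actually moves a unit-resolution spectrum, and it
  keeps neutral losses invariant; independent per-ion jitter of ±0.3
  Da would produce loss errors up to 0.6 Da — beyond the 0.5 Da rule
  tolerance — and would misrepresent the instrument. Annotation is
  therefore provably robust to offsets within the tolerance, and the
  test suite verifies 100% round-trip agreement at ±0.3 Da.
* **Peak tables**: areas from the calibration or RRF relation times
  mean-corrected lognormal noise of specified CV — multiplicative
  noise matching the roughly constant relative variability of
  integrated chromatographic areas.

All generators are bit-reproducible under a fixed seed. What they do
**not** emulate: chromatographic peak shape and co-elution, isotope
envelopes, detector saturation, retention-time drift, matrix effects
on ionization, and between-batch biological variability. Passing
round-trip tests therefore demonstrates internal consistency of rules
and formulas, not robustness to those real-data phenomena.

## Problem sizes and numerical tolerances

The test suite exercises: exact coefficient recovery at $10^{-8}$;
200-replicate Monte-Carlo checks of estimator bias (noise sd 0.05) and
of quantification error (1% area CV, median relative content error
required < 2%); optimizer dominance over a 0.05-grid oracle for 50
random surfaces; and annotation round trips over the full 23-compound
library at zero noise and across 25 jittered replicates per compound.
These sizes give stable verdicts for the properties tested while
keeping the default run in the tens of seconds; all seeds are fixed.

## Known limitations

* The annotator is a targeted rule cascade for this compound family,
  not a general metabolite identifier: no elemental-formula
  decomposition, isotope patterns, spectral-library similarity, or
  positive-ion mode.
* The regiochemistry key is a simplification; positional isomers of
  caffeoylquinic esters other than the 3,5 pattern are reported as
  unlocalized isomers.
* RRF quantification inherits the structural-similarity assumption of
  its internal-standard map; a poorly matched standard biases
  concentrations proportionally.
* The RSM stage models a single response; multi-response desirability
  optimization and alternative designs (Box-Behnken, D-optimal) are
  out of scope.
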