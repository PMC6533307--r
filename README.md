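# phenolProfiler

Profiling phenolic compounds in botanical extracts — from extraction
optimization through MS<sup>n</sup> annotation to quantification — as a
tested, reusable R pipeline. The package was built around the
ultrasound-assisted extraction and HPLC-PDA-ESI-MS<sup>n</sup>
characterization of *Dendranthema indicum* var. *aromaticum* flower, a
Chinese medicinal chrysanthemum whose phenolic profile (chlorogenic-type
quinic acid esters, oleuropein derivatives, flavones, hydroxy fatty
acids) it ships as packaged reference data. It is aimed at analytical
chemists and natural-product researchers who want the three stages of
such a study to be reproducible and testable without instrument access.

## What it computes

**1. Response-surface extraction optimization.** A central composite
circumscribed (CCC) design in *k* factors combines the 2^k factorial
block at coded levels ±1, 2*k* axial points at ±α, and replicated
center runs. Factor settings are coded as *x* = (X − X₀)/ΔX, and the
total-phenolic yield *y* (g gallic acid equivalents / 100 g dry weight)
is fitted by ordinary least squares to the full second-order polynomial

y = β₀ + Σᵢ βᵢxᵢ + Σᵢ βᵢᵢxᵢ² + Σᵢ<ⱼ βᵢⱼxᵢxⱼ

with ANOVA (including the pure-error / lack-of-fit split from the
center replicates) and deterministic grid-then-polish maximization of
the fitted surface over a coded box.

**2. Rule-based MS<sup>n</sup> annotation.** Negative-mode spectral
trees ([M−H]⁻ precursor, UV λmax, staged fragment lists) pass through a
decision cascade of neutral-loss and marker-ion rules: hexosyl/caffeoyl
(162 Da) and deoxyhexosyl/coumaroyl (146 Da) losses, the quinic acid
marker m/z 191 (179/173/135 secondary), the oleuropein 539→377 glucosyl
signature, flavone aglycone masses with methyl-radical chains for
methoxyflavones, +18 monohydrate adducts, and consecutive water losses
for hydroxy C18 fatty acids — all at 0.5 Da tolerance for
unit-resolution ion-trap data.

**3. Quantification and validation.** Calibration curves
(area = aX + b), LOD/LOQ at S/N 3 and 10 (3σ/slope, 10σ/slope), spike
recovery and RSD statistics, and internal-standard quantification for
compounds without authentic standards via the relative response factor

RRF = (A_k/A_i)/(C_k/C_i),  C_unknown = (A/A_i)·C_i/RRF/R

followed by conversion to mg/g dry weight and per-class aggregation.

A synthetic-data generator mirrors each stage's data-generating process
(quadratic surface + Gaussian noise; rule-library fragmentation trees
with mass-axis jitter and intensity noise; calibration/RRF peak areas
with lognormal noise), so every stage is testable end to end.

## Worked example

```r
library(phenolProfiler)

design <- exampleDesign()          # 20-run CCC with observed TP yields
model  <- fitQuadratic(design)
model
#> QuadraticSurfaceModel: 3 factors, R^2 = 0.9203, F(9, 10) = 12.83, p = 0.000216

optimizeSurface(model)             # maximize over the factorial cube
#> OptimizationResult
#>   coded optimum:    -1.0000, 1.0000, 0.7356
#>   uncoded optimum:  20.00, 30.00, 57.36
#>   predicted response: 1.2958
```

The fitted surface explains 92% of the response variance (p ≈ 2×10⁻⁴),
and the constrained optimum lands at 20 min extraction, a 1:30 g/mL
solid/liquid ratio and 57 °C, predicting 1.30 g GAE/100 g DW — the
extraction condition a bench scientist would carry forward.

```r
batch <- annotateBatch(exampleSpectralTrees())
batch$counts
#>  hydroxybenzoic_acid hydroxycinnamic_acid            flavonoid
#>                    2                    6                    6
#>   hydroxy_fatty_acid              unknown        phenolic_acid
#>                    6                    3                    8
#>             phenolic
#>                   14

aggregateByClass(exampleContents())$total
#> [1] 6.42
```

Of the 23 chromatographic peaks, the cascade identifies 14 phenolics
(8 phenolic acids, 6 flavonoids) and 6 hydroxy fatty acids, leaving 3
unknowns; the quantified phenolics total 6.42 mg/g DW with luteolin the
most abundant (1.61 mg/g DW).

A thin command-line front end is included at
`inst/scripts/phenolprofiler` (subcommands `design`, `fit`, `optimize`,
`annotate`, `quantify`, `simulate`, `run`).

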