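---
title: "Methods: simulating and analyzing chip-based iterative cytometry of CSF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing chip-based iterative cytometry of CSF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcsf)
```

## The measurement problem

Iterative slide-based cytometry immobilizes the cells of one sample on a
microfluidic chip and measures one marker per stain-image-bleach cycle.
Because the sample is never consumed, an open-ended panel can be run on the
few thousand cells a CSF sample yields — but three method-specific artifacts
must be handled by the analysis:

1. **Autofluorescence and illumination inhomogeneity.** A cell's raw mean
   fluorescence intensity (MFI) mixes dye signal with cellular
   autofluorescence and position-dependent illumination.
2. **Cell detachment.** Fluid exchange shears cells off the chip. A cell
   lost mid-panel reads spuriously negative for all later markers; a cell
   that reattaches elsewhere reads negative for all earlier ones. Both are
   *artificial phenotypes*.
3. **Sparse chips.** Normocellular CSF (< 5 cells/µl) often cannot populate
   the chip densely enough for reliable analysis; density below 20 cells
   per field of view (FOV) makes a chip unanalyzable.

## The generative model

`simulate_cycles()` produces, for cell $i$ on FOV $p$ in cycle $k$:

$$\mathrm{MFI}^{stained}_{ik} = L_p\,(g\,E_{ik} + A_i) + B_p + \varepsilon,
\qquad
\mathrm{MFI}^{bleached}_{ik} = L_p\,(\rho\,g\,E_{ik} + A_i) + B_p + \varepsilon'$$

| parameter | meaning | default | rationale |
|---|---|---|---|
| $E$ | true expression (AU) | per population/marker | see below |
| $g$ | stain gain | 1 | AU scale is arbitrary |
| $\rho$ | residual dye after bleaching | 0 | complete bleaching |
| $A_i$ | per-cell autofluorescence | lognormal(log 50, 0.4) | modest vs positive signal |
| $L_p$ | per-FOV illumination factor | lognormal(0, 0.1) | ±10% field flatness |
| $B_p$ | per-FOV additive offset (AU) | U(0, 20) | camera/background offset |
| $\varepsilon$ | measurement noise sd (AU) | 8 | small vs the low mode |
| detach probability | per cell per fluid exchange | 0.02 | noticeable cumulative loss over 11 cycles |
| reattach probability | given detachment | 0.3 | reattachment is common but not dominant |

Autofluorescence is fully retained through bleaching ($A_i$ appears in both
images): whether real autofluorescence partially bleaches is unknown, and
full retention is the conservative choice — it is exactly what bleach
subtraction is designed to remove. Illumination is modelled as per-FOV
constants rather than smooth fields; this is the simplest model against
which the subtraction claim (removal of *local* inhomogeneity) is testable.
Detachment is applied once per cycle (shear acts during staining and
washing, whose relative contributions are unpublished), so the probability
of surviving an $n$-cycle panel attached is $(1-p_{detach})^n$.

**Expression states.** The instrument reports no absolute units, only
ordinal gates, so each population's marker expression is an ordinal state
realised as a lognormal mode: negative ($E = 0$; the measured signal is
pure autofluorescence plus background), low (mode 150 AU — the CD19^low
plasmablast niche), positive (1100 AU), high (8200 AU), log-sd 0.25. The
decade-spaced modes make bands well separated at the default noise, which
is deliberate: the gates are reconstructions of a gating strategy that was
never published numerically, and the simulator's job is to make the
*logic* testable, not to reproduce a specific instrument's dynamic range.

**Cohort model.** Concentrations come from a two-component mixture:
normocellular, lognormal(log 1.5, 0.6) truncated below 5/µl; pleocytic,
$5 + \mathrm{lognormal}(2.14, 1.75)$/µl, fitted once to the published
cumulative stratification of pleocytic samples (about 62%/27%/14% at
≥ 10/30/50 per µl). Volumes are lognormal with median 4 ml clamped to
[1, 15] ml (routine punctures versus large-volume withdrawals).
Centrifugation loses each cell independently with probability 0.593, the
published mean loss. A single seed feeds named substreams
(cohort/preanalytics/loading/cycles/render/compare) so each stage is
independently reproducible.

## Correction and quality control

Bleach subtraction computes `stained − postbleach`, cancelling $A_i$ and
$B_p$ *exactly* (the same realization enters both images) and leaving
$L_p\,g\,E\,(1-\rho)$ plus noise. Two design points:

* Negative differences are floored at 0 for gating (gates expect
  non-negative intensities) but the signed difference is kept: the
  diagnostic "true-negative cells have mean corrected MFI ≈ 0" must use the
  signed mean, because flooring a zero-centred noise distribution biases
  its mean upward by $\sigma/\sqrt{2\pi}$.
* Subtraction uses the post-bleach image of the *same* cycle. Subtracting
  the previous cycle's post-bleach image would behave identically under
  complete bleaching ($\rho = 0$) and is noted as the alternative reading.

Tracking links detections cycle-to-cycle by greedy nearest neighbour within
a 5 µm radius (about half a lymphocyte diameter; the instrument's own
repositioning logic is proprietary), ties broken by distance then id.
Unmatched later-cycle detections start new tracks. QC then retains only
tracks spanning every cycle: late-starting tracks are candidate reattached
cells, early-ending tracks are lost cells. After QC no retained cell can
have a missing marker value — the artificial-phenotype hazard is
structurally impossible, replacing the original workflow's manual review
with deterministic rules.

## Imaging mode

The pipeline runs in two interchangeable modes: *table mode* (simulator
MFIs feed correction directly; fast, used by most tests) and *image mode*,
where `render_fov()` draws each cell as a Gaussian-blurred disk (radial erf
profile; amplitude = stained MFI on the fluorescence channel, fixed
contrast on the transmitted channel; default 0.5 µm/px on a ≤ 512²
raster), `detect_cells()` applies Otsu thresholding plus connected
components with an area filter (15–400 µm², the surrogate for manually
rejecting debris), and `measure_mfi()` averages fluorescence over each
component mask. Mean-over-mask underestimates the planted amplitude by a
rim-blur factor that grows with PSF width (a few percent at σ = 0.25 µm,
~6% at 0.5 µm); round-trip checks therefore use the narrow PSF and a 10%
tolerance, and ratios between cells are unaffected because the geometry
cancels.

## Gating, clonality, sufficiency, agreement

Bands on $\log_{10}(\mathrm{MFI}+1)$ use thresholds at 45/410/3000 AU — the
geometric midpoints of adjacent expression modes, with the negative/low
boundary anchored just above the corrected-MFI noise floor. Predicate
semantics: `pos` means positive-or-high, `low` and `high` are exact bands,
`pos_or_low` means any expression. The default tree (ordered,
first-match-wins) reconstructs the named clinical populations; the
original "predefined gating strategies" were never printed, and the tree is
documented as a reconstruction. Light-chain clonality calls κ/λ restriction
outside the κ:λ ratio interval [0.26, 1.65] — the conventional clinical
reference interval, a documented convention rather than a measured
property — with a 10-B-cell minimum for a determinate call.

Chip sufficiency uses mean cells per FOV with an inclusive cut-off of 20
(the published rule; whether the original assessment used the mean or the
minimum FOV is unstated, so a min-over-FOVs alternative is configurable).
Stratified reports use cumulative ≥-bands and half-up rounding to one
decimal, matching the printed style.

Bland-Altman differences are reference − chip, so *negative bias means the
chip reads higher*; this sign convention keeps the published monocyte
interpretation (chip overestimates monocytes) consistent, and an optional
per-population adhesion weight in the simulator reproduces that mechanism
(monocytes adhering more strongly than lymphocytes). Limits of agreement
are bias ± 1.96·SD with the sample SD; no small-sample t-correction is
applied, as none is indicated in the source analysis. Pooling across
populations (the "all cells and samples" style of summary) pools the raw
differences; averaging per-population biases is the noted alternative.

## Problem sizes and numerical choices

Tests and the acceptance script run at desk scale, chosen as the smallest
sizes at which the statistical claims are stable: composition recovery at
50 000 cells (binomial 3·SE), full-pipeline fraction recovery at 5 000
cells × 20 seeds (binomial 95% CI coverage ≥ 90%, the honest reading of a
95% criterion), QC recall on 3 000-cell chips, Monte-Carlo oracles at
1 000–10 000 replicates, image round-trips on ≤ 512² rasters. The
recovery experiment caps chips at 10 000 cells; a lower cap would truncate
pleocytic chips and artificially erase the cellularity contrast in
agreement widths. Ties in clustering and tracking are broken
deterministically; negative sampled MFIs are clamped to 0 and counted;
degenerate inputs (empty chips, zero denominators, constant markers) return
typed errors or flagged NA values, never infinities.

## What the simulation does and does not show

The generator reproduces the *structure* the analysis relies on:
cellularity mixture, Bernoulli cell loss, composition sampling, the
additive/multiplicative background model, detachment/reattachment, and
ordinal expression. Passing tests therefore validate the pipeline's logic
and its statistical behaviour under that model. They do not certify
performance on real chips: real autofluorescence spectra, focus and
repositioning errors, debris, doublets, erythrocyte contamination, antibody
titration effects, and storage-time decay are not modelled (storage is at
most a marker-stability multiplier). Absolute sufficiency rates in
simulated cohorts depend on the unpublished chip area — the FOV grid is a
free parameter — so simulated sufficiency supports orderings and
monotonicity claims, not the published absolute percentages, which the
reporting functions re-derive from their printed count pairs instead. The
published per-patient agreement values are likewise not reproducible (the
raw data were never printed); agreement is validated by parameter-recovery
properties — injected offsets are recovered as bias, limits of agreement
scale linearly with injected noise, and pleocytic cohorts agree more
tightly than normocellular ones.
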