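---
title: "Methods: absolute IPP quantification and PHO-pathway activation dynamics"
author: "ippdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute IPP quantification and PHO-pathway activation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ippdyn)
```

## The problem

Inositol pyrophosphates (IPPs) — here 1-IP₇, 5-IP₇ and 1,5-IP₈ — are
signalling metabolites that report cytosolic phosphate status to the
yeast PHO pathway through SPX receptor domains. Reasoning about which
species represses the pathway, and at what concentration, requires
*absolute* cytosolic concentrations, not relative peak areas, together
with a quantitative readout of pathway activation. This package
implements both measurement chains and the kinetic argument that links
them, with a synthetic-data module that generates every input with known
ground truth.

## Quantification chain (CE-MS MRM)

Each biological sample is a cell pellet (by default $N = 10^7$ cells)
extracted with perchloric acid, enriched on TiO₂, dried and resuspended
in $V_e = 20$ µL of water; $V_a = 15$ µL of this extract is spiked with a
¹³C-labelled internal-standard mixture (1.5 pmol 1,5-IP₈, 7.5 pmol each
IP₇ isomer, 30 pmol IP₆ per aliquot) and analysed by CE-ESI-MS in
multiple-reaction-monitoring mode. For a species $s$ with analyte peak
area $A_s$ and standard area $A^{13}_s$, the chain is

$$
C_s \;=\; \underbrace{\frac{A_s}{A^{13}_s}\, n^{13}_s}_{\text{isotope dilution}}
\cdot \frac{V_e}{V_a}
\cdot \frac{1}{r_s}
\cdot \frac{1}{N}
\cdot \frac{1}{V_\mathrm{acc}},
$$

where $n^{13}_s$ are the spiked standard moles, $r_s$ the species'
extraction recovery and $V_\mathrm{acc}$ the Pi-accessible cell volume.
Every factor is an exported function (`quantify_isotope_dilution()`,
`scale_to_extract()`, `correct_recovery()`, `per_cell_amount()`,
`cytosolic_concentration()`); `run_quant_pipeline()` composes them and
the tests assert that the composition equals this closed form to
$10^{-9}$ relative error.

Key parameters, with defaults and rationale:

* **Recoveries** $r_s$ = 0.89 (1-IP₇), 0.90 (5-IP₇), 0.75 (1,5-IP₈),
  determined by spiking standards onto cells *before* extraction
  (`recovery_from_spike()`). Whether such recoveries should correct the
  reported concentrations or serve only as QC is genuinely open; we
  apply them by default (`quant_config(apply_recovery = )` toggles it)
  because uncorrected values would be systematic underestimates.
* **Volume model**: mean cell volume 42 fL, of which the nucleus
  occupies ~8 % and other organelles ~18 %. Since small molecules
  equilibrate across the nuclear envelope, the accessible volume
  subtracts only the organelle fraction:
  $V_\mathrm{acc} = 42 \times (1 - 0.18) = 34.44$ fL. The alternative
  reading (subtract 26 %) is available via
  `volume_model(exclude_nucleus = TRUE)`; it would scale all
  concentrations up by ~11 %, well inside the 2-significant-figure
  reporting precision.
* **Response ratio** analyte/standard defaults to 1: ¹³C isotopologues
  co-ionise with their ¹²C analytes and no calibration data says
  otherwise. Configurable.
* **Species naming**: the MRM transition cannot distinguish
  pyrophosphorylation at the 1- vs 3-position, so "1-IP7" labels the
  1/3-indistinguishable isomer throughout.
* **IP₆** shares the workflow but is not a pyrophosphate endpoint; it is
  quantified and excluded from reporting unless
  `quant_config(include_ip6 = TRUE)`.

### Peak assignment

Isomers share a transition (both IP₇ species monitor 368.9→319.9) and
are discriminated by CE migration time against the co-injected ¹³C
standards, which define the isomer order (5-IP₇ migrates before 1-IP₇
under the default conditions). `assign_peaks()` first removes a global
migration drift — the median analyte-minus-nearest-standard offset,
used only when at least three offsets are available, so a single stray
peak cannot define the alignment — then matches each analyte to the
nearest same-transition reference within 0.2 min. Contested references
go to the smaller residual; an exact residual tie raises an ambiguity
error listing the candidates, and an analyte with no reference in
tolerance is flagged unassigned rather than failing the run.

## Synthetic MRM data

`generate_ms_fixture()` emulates the sample flow exactly as bookkept
above. Per-cell ground-truth amounts (zmol) per strain and starvation
timepoint are fixed in `default_truth_table()`; they were chosen so that
noise-free fixtures land on the study conditions: wild-type replete
cells at 0.5 / 0.7 / 0.3 µM (1-IP₇ / 5-IP₇ / 1,5-IP₈), 47 / 40 / 75 %
declines after 30 min of Pi starvation, 3 % of 5-IP₇ (≈21 nM) left at
4 h, a 20-fold 5-IP₇ excess in *vip1Δ*, 10-fold 1-IP₇ in *ddp1Δ* and
5-fold 5-IP₇ in *siw14Δ*. Strains without printed values (*kcs1Δ*
residual 1-IP₇, the double mutant) carry plausible small amounts
consistent with the qualitative description (strong reduction,
epistatic loss).

Replicate noise is multiplicative lognormal on the *per-cell amounts*
(biological variation between cultures), not on peak areas: the
isotope-dilution ratio itself is close to exact in practice, and placing
the noise upstream keeps the noise-free round trip an identity. The
default CV of 0.15 with $n = 4$ replicates reflects the replicate
scatter typical of such measurements. ¹³C standard areas are noise-free
by construction (the same mixture is pipetted into every sample).
Migration times carry a shared per-sample/per-species jitter
(SD 0.05 min) plus a smaller per-peak term, so analyte and standard
co-migrate as in a real run; only ordering and co-migration are
meaningful.

## Imaging: segmentation and I~N~/I~C~

Pathway activation is read from the nuclear/cytosolic distribution of a
fluorescent transcription factor. The generator places non-overlapping
disc cells (radius 10–16 px) with darker rims on a bright-field-like
channel, Gaussian-blurred nuclear-marker discs at 8 % of the cell area,
and a sharp reporter channel whose per-cell nuclear:cytosolic ratio is
drawn from a configurable truncated normal (replete mean 0.45, starved
mean 1.8 — the two ends of the relocation curves). Additive Gaussian
noise (SD 60 counts against rim contrast 400) is applied everywhere.

The original study segmented with a trained (AI-based) model whose
weights are not available; the package substitutes a deterministic
classical pipeline with the same output contract: Gaussian smoothing
(σ = 2 px), absolute deviation from the median background, Otsu
threshold, hole filling, erosion by 3 px, distance-transform watershed
and a size filter. The erosion compensates the outward spread of the
rim by smoothing: without it the mask includes a background halo that
dilutes the cytosolic mean and biases I~N~/I~C~ upward by several
percent; with it the mask sits just inside the true boundary, which
costs nothing because the cytosol is uniform at its edge. On default
noisy fields this detects ~99 % of ground-truth cells at IoU ≥ 0.5,
comfortably above the ≥ 90 % bar the study reports for its segmenter,
and measured ratios track generator truth with |bias| < 2 %.

Nuclei are thresholded per cell (Otsu restricted to the cell's pixels,
largest component kept; multinucleate and nucleus-free cells flagged).
The ratio uses background-subtracted means (background = median
reporter intensity outside all cells), with the cytosol defined as the
cell minus the nucleus dilated by a 1 px guard ring to limit
bleed-through; border-touching cells are excluded from statistics.
These last three conventions are not specified by the source workflow —
they are fixtures-validated choices, exact on the synthetic geometry.
Manually drawn ROIs can be supplied directly to `measure_nc_ratio()`.

What the generator does **not** emulate: optical blur on the reporter
channel, uneven illumination, out-of-focus cells, clumping and budding
morphology, photobleaching. Passing tests therefore demonstrate the
correctness of the measurement logic and its noise robustness, not
performance on real micrographs; the classical segmenter would need
revalidation on real bright-field images.

## Kinetics and the repression threshold

The argument: in cells that overaccumulate 5-IP₇ ~20-fold (no 1-IP₇ or
1,5-IP₈ to confound), Pi starvation triggers nuclear relocation of the
transcription factor only once the decaying 5-IP₇ level crosses the
repressive threshold. Two fits formalise it:

* `fit_exponential_decay()`: $C(t) = C_0 e^{-kt}$, log-linear
  initialisation on positive points (values at 0 are below detection
  and excluded from the log fit), Levenberg–Marquardt refinement with
  $k \ge 0$. A single exponential is a modelling choice — the data show
  monotone depletion without naming a mechanism — and is the simplest
  form consistent with first-order turnover.
* `fit_logistic()`: $R(t) = b + a/(1 + e^{-(t - t_{1/2})/w})$ with
  $a \ge 0$, $t_{1/2}$ bounded to the observed range, $w > 0$; restarts
  from a small grid of initial half-times; a fitted amplitude
  indistinguishable from noise is flagged "no transition".

`infer_threshold()` evaluates the decay at the relocation half-time:
$C_\mathrm{thr} = C_0 e^{-k\,t_{1/2}}$. The half-maximum is the default
anchor because it is the most robustly estimated point of a logistic;
an earlier "onset" anchor (5 % rise) is exposed as an option and yields
a correspondingly higher threshold. On the noise-free fixture
($C_0 = 14$ µM, $k = 0.01716$ min⁻¹, $t_{1/2} = 60$ min) the threshold
is 5.0 µM; across 50 noisy replicates the median estimate stays within
10 % of that value.

## Reporter statistics

`normalize_plate()` subtracts the mean blank (untagged wells, or a
configured dark count) and divides by cells per well; negative values
are clipped to zero and flagged. `induction_ratio()` is the starved /
replete mean ratio. `compare_groups()` wraps the tests used in the
figure annotations — Student's t (equal variance, as quoted), Tukey's
HSD over all pairs, Mann–Whitney — and attaches the star coding
(**** < 10⁻⁴, *** < 10⁻³, ** < 10⁻², * < 0.05). A null simulation in the
test suite checks the Tukey family-wise error sits at ~5 %.

## Numerical choices and degenerate inputs

* Migration tolerance 0.2 min, m/z tolerance 0.3; exact residual ties
  in assignment are errors, not silent choices.
* All-constant images yield zero cells without error; all-zero nuclear
  channels flag every cell nucleus-free; cytosolic means ≤ 0 after
  background subtraction exclude the cell.
* Concentrations are kept at full precision internally; rounding to the
  2 significant figures used in reporting happens only at presentation.
* TIFF output stores rounded 16-bit counts exactly (the writer
  truncates, so a half-count offset is applied before scaling).
* Seeds: every generator takes an explicit integer seed and is
  byte-reproducible for the same seed.

## Problem sizes

The shipped analyses and tests use fields of 512² px with ~100 cells
(256² with ~20–25 cells in the unit tests), 20 fields for the pooled
segmentation benchmark, 50 noisy replicates for threshold robustness
and 1,000 null replicates for the family-wise error check. These sizes
give stable statistics for the quantities checked while keeping the
whole suite fast on a single CPU.

## Known limitations

* The quantification chain starts from peak tables; peak detection and
  integration from raw electropherograms (or mzML) are out of scope.
* The classical segmenter is validated only on the synthetic geometry.
* No external-calibration (standard-curve) quantification mode.
* The decay/logistic forms are phenomenological; no mechanistic ODE
  model of IPP turnover is attempted, and pulse-labelling turnover
  inference is explicitly out of scope.
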