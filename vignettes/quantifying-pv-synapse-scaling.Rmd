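---
title: "Quantifying activity-dependent scaling of perisomatic PV-PV synapses"
author: "pvquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying activity-dependent scaling of perisomatic PV-PV synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvquant)
```

Parvalbumin-positive (PV⁺) cortical interneurons inhibit one another
through perisomatic synapses, and sustained changes in a PV⁺ cell's
activity rescale the PV-PV inhibition it receives. Detecting that
rescaling is not one measurement but a stack of small rule-based
quantifications — image-based synapse counting, immediate-early-gene and
transcript readouts, a gene-prioritization scheme over ribosome-associated
mRNA counts, and event-train electrophysiology summaries. This vignette
documents how `pvquant` implements each stage, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
establish about real micrographs.

## The synapse colocalization model

A perisomatic PV-PV synapse is operationalized as a colocalized pair of
fluorescent puncta: a presynaptic bouton (SYT2 or VGaT staining) and a
postsynaptic scaffold cluster (gephyrin staining), meeting at the soma
surface of a PV⁺ cell. The pipeline applies, per image:

1. **Preprocessing** (`preprocess()`): rolling-ball-style background
   subtraction (grayscale opening with a disc), Gaussian blur, median
   smoothing, percentile contrast rescaling — in that order, identically
   on all channels. Every step is optional; the synthetic fields have flat
   backgrounds, so the default pipeline applies none of them, while real
   micrographs typically need all four.
2. **Soma segmentation** (`segment_somata()`): intensity threshold on the
   cell-marker channel, morphological opening/closing with a disc
   (default radius 0.5 µm; the element size is a free parameter left in
   the configuration), hole filling, 8-connected components and an area
   filter. Hand-drawn polygon outlines can replace the automatic path and
   receive identical downstream treatment.
3. **Punctum detection** (`detect_puncta()`): intensity threshold,
   optional distance-map watershed to split touching blobs (the
   scriptable equivalent of an adjustable binary watershed), connected
   components, and a minimum particle size of 0.05 µm². The unit of that
   minimum is not self-evident in common particle-analysis protocols; we
   read it as µm² because every other synaptic threshold in the scheme is
   in µm², and the value is configurable.
4. **Classification and pairing** (`classify_puncta()`,
   `pair_synapses()`): boutons must sit outside the soma mask with
   ≥ 0.1 µm² overlap with the perimeter band; clusters inside with
   ≥ 0.2 µm²; synapses are bouton–cluster pairs with ≥ 0.03 µm² mask
   colocalization. Overlaps are literal pixel-set intersections, so they
   agree exactly with a brute-force pixel-enumeration oracle.

Thresholds are chosen once per experiment (the package ships
`calibrate_threshold()` to report foreground fractions over a calibration
set, a reproducible stand-in for the manual by-eye choice) and then held
fixed across that experiment's images.

### The perimeter band

How thick the "soma perimeter" is for overlap purposes is a genuinely
open design point. We define the band as all pixels within Chebyshev
distance `band_width` (default 2 px at 15.4 px/µm, i.e. ±0.13 µm) of the
1-px inner rim of the filled mask. A narrower band — one pixel either
side — makes the ≥ 0.2 µm² postsynaptic rule nearly unsatisfiable for
realistically sized gephyrin clusters at this magnification, which argues
that the effective perimeter region in this kind of analysis is a few
pixels thick; the parameter remains configurable.

### Pairing multiplicity

Whether one bouton may count toward several clusters is not specified by
the rule "contacting each other". The default is one-to-one greedy
matching by descending colocalization area (ties broken by lowest bouton
id, then cluster id), which prevents double-counting; `mode = "many"`
emits every qualifying contact. Greedy matching is deterministic and
order-invariant but not guaranteed to maximize total overlap — a bouton
claimed by its best partner can leave a second-best pair unmade; we judge
determinism and no-double-counting more important for a counting
statistic than total-overlap optimality.

### Density and the comparison statistic

Per soma, density = synapses per µm of perimeter. Perimeter length uses a
four-direction Cauchy–Crofton estimator (transition counts at 0°, 45°,
90°, 135°), which is within ~1% of the analytic circumference for discs
of soma size, where naive boundary-pixel counting errs by up to ~27% on
oblique boundaries. The group comparison is

$$\text{Density change} = \left(\frac{\bar d_{\text{infected}}}{\bar d_{\text{uninfected}}} - 1\right)\times 100,$$

with group means taken, by default, over animals (mean of per-animal mean
cell densities; the animal is the experimental unit), with a per-cell
mode available. With 30 cells per group the two aggregations coincide in
the balanced synthetic populations. Being a ratio estimator, its
expectation carries a small positive bias of order the squared
coefficient of variation of the denominator group mean (about +1
percentage point at the default population settings — planted +30%
recovers +31.0 ± 0.4 over 1,000 simulations); the Monte-Carlo tests use
tolerances wide enough that this bias is visible rather than hidden.

## FOS intensity and smFISH counting

`fos_intensity()` reports the mean immediate-early-gene channel intensity
over each segmented soma ROI — the activity readout used to verify
chemogenetic manipulations.

`count_particles()` implements the area-based transcript estimator: the
thresholded probe signal area inside the ROI divided by the area of one
mRNA particle (0.16 µm² by default). The estimate stays real-valued; it
is an area ratio, and rounding would bias low counts. Staining intensity
differs between brains, so `brain_normalization()` measures each image's
mean probe intensity excluding *all* segmented cell ROIs (the original
procedure this emulates excludes the PV⁺ interneuron ROIs; excluding
every segmented ROI is the natural generalization), averages per brain, and normalizes to the
dimmest brain; `intensity_correction()` divides each raw count by its
brain's ratio, so corrected counts never exceed raw ones. mCherry⁺/⁻
status is an annotation column — an intensity-threshold helper
(`classify_infection()`) exists but is never the default — and a
`pair_id` column survives the correction so neighbouring-cell paired
comparisons remain possible.

## Gene filtering, differential expression, and the four-criterion ranking

Counts are filtered by the literal rule "fewer than 10 reads in at least
4 samples → excluded". The common filtering idiom (*keep* genes with
≥ 10 reads in ≥ 4 samples) differs for unbalanced designs; both are
implemented, the literal reading is the default, and the two agree on the
balanced 4 + 4 design the package emulates.

The DE stage is deliberately pluggable. The in-package `nb_exact` method
equalizes library sizes to their geometric mean (rounded pseudo-counts —
exact for the generator's equal libraries, a documented approximation
otherwise), estimates a common negative binomial dispersion by
conditional maximum likelihood, moderates per-gene dispersions by adding
`prior_n = 30` genes' worth of the shared likelihood (strong moderation;
with 4 replicates per group, per-gene dispersion estimates are too noisy
to stand alone), and computes a two-sided conditional exact test in which
the unknown mean cancels. The reported p-value is the *mid-p* variant —
all outcomes strictly less probable than the observed split plus half the
probability of equally probable ones — because a plain exact test on
discrete data is systematically conservative; with mid-p the measured
type-I error on planted-null matrices (1,000 genes, 4 vs 4, dispersion
0.05) is 0.0495 over ~10⁵ simulated null genes, against 0.047 without
it. The robust-GLM machinery of a full RNA-seq framework is intentionally
not reproduced: `external_table` mode accepts a published DE table and
re-evaluates only the cut-offs, so the ranking can run downstream of any
DE engine. An independent NB implementation (edgeR) serves as a
cross-check in the test suite, never as the implementation.

A gene responds to activation iff |fold change| > 1.5 (two-sided — both
up- and downregulated genes count), BH FDR < 0.05, and abundance > 1 in
at least one condition. With no transcript lengths available the
abundance metric is CPM and is flagged as such in the output; supplying
gene lengths switches to TPM.

The four scores, each over the passing genes and each in [0, 1]:

- **Fold change**: min–max scaled |log₂FC| — response magnitude.
- **CoV**: within each condition, sd/mean of normalized expression;
  summed over the two conditions ("from each sample" cannot mean one
  sample — sd/mean is undefined per sample — so the per-condition-then-sum
  reading is used); min–max scaled and *inverted*, because the criterion
  measures reproducibility, so low variability must score high. The
  uninverted variant sits behind a flag. Genes with a zero-mean condition
  are flagged rather than scored.
- **Interaction**: the summed interaction scores of each gene's edges to
  *other passing genes* (a STRING-style export read from a 3-column
  table; no live queries), min–max scaled.
- **Secretome**: binary membership of a secreted-protein gene set,
  matched case-insensitively.

When all raw values of a criterion are equal, min–max scaling is
undefined; all scores are then set to 1 (no information to discriminate).
The composite is the equal-weight sum (weights configurable — the
combination rule behind the published ranking figure is unstated, and an
unweighted sum is the assumption-free default), ranked descending with
ties broken by fold-change score then gene id, which makes the rank
monotone in every individual score.

## Electrophysiology summaries

Event *detection* is upstream; the package consumes detected-event
tables. Frequency is the exact event count over the recording duration
(no binning); current per second = mean event charge × frequency; E/I
ratio = excitatory over inhibitory current per second, per cell, and is
invariant to a common charge rescaling. The paired-pulse ratio is
peak2/peak1 after subtracting the residual of the first response at the
second pulse. QC excludes cells with Ra > 25 MΩ, |Ihold| > 200 pA (the
absolute value, since the sign of the holding current depends on the
holding potential), or — where measured — a series-resistance change
> 20%; all three are strict inequalities, boundary values are kept, and
the exclusion reason lists every violated rule. A trapezoidal
baseline-subtracted integrator (`event_charge()`) covers event tables
that lack charges.

## What the synthetic data emulate — and what they do not

The generators plant ground truth and return it alongside the data, so
tests never re-derive truth from rendered output:

- `make_synapse_image()` renders somata as filled discs and puncta as
  isotropic Gaussian spots whose spot width is solved per object so that
  the footprint above the nominal detection threshold contains exactly
  the planted pixel count (sub-pixel centre jitter breaks distance
  ties). Planted pairs straddle the soma rim (bouton centre 3 px
  outside, cluster 2 px inside); unpaired perimeter objects and off-soma
  distractors probe precision. After rendering, the generator verifies
  every planted role against the actual classification rules and aborts
  naming the object if placement failed. Defaults mirror the acquisition
  scale of a 100× objective at 1.75× zoom (15.4 px/µm), 8 µm somata,
  0.5 µm² boutons and 0.8 µm² clusters.
- `make_counts()` draws NB counts (4 vs 4 by default) with the planted
  log₂ fold change split symmetrically around each gene's baseline, so
  the between-condition mean ratio is exactly 2^log₂FC; dispersion 0
  degenerates to Poisson.
- `make_fish_image()` plants non-overlapping particles whose *total*
  footprint per soma is rounded once (not per particle), keeping the
  planted signal area within one pixel of n × 0.16 µm²; the brain `gain`
  scales both the particle footprint and the off-cell background, the
  regime the intensity-ratio correction is built to undo.
- `make_events()` draws Poisson event times and gamma amplitudes/charges
  (positive support; physically nonnegative).
- `make_density_population()` simulates per-cell density records directly
  (Poisson synapse counts around density × perimeter), which is what
  makes 100-seed Monte-Carlo recovery of the density change tractable.

Seeds are mandatory everywhere; there is no hidden global random state,
and identical seeds give bit-identical outputs.

These fixtures establish that the *rules* are implemented exactly and
recoverable under additive Gaussian noise up to the documented level
(sd 8 against spot amplitude 200 at threshold 50). They do not emulate
point-spread blurring, uneven illumination, autofluorescence, dendritic
structures, overlapping cells, or segmentation ambiguity — so passing
tests certify the quantification logic, not detection performance on
real tissue.

## Numerical choices and problem sizes

- Rule thresholds compare pixel-quantized areas, which are integer
  multiples of pixel_size²; comparisons use an absolute 1e-9 tolerance so
  floating-point rounding of k × pixel_size² cannot flip a boundary case,
  while true sub-threshold areas (at least one pixel smaller) are
  unaffected.
- Connected components use 8-connectivity by default (4 available);
  labels are assigned in raster order of each component's first pixel,
  making labelings deterministic.
- Grayscale morphology is computed on replicate-padded, [0, 1]-rescaled
  images so frame effects and intensity clamping cannot distort the
  background estimate.
- The exact test enumerates the conditional distribution fully for group
  totals up to 10⁵ and windows the enumeration (±50 sd) above that.
- Test and verification problem sizes: 512×512 px fields with 2 somata;
  1,000-gene matrices; 100–200 simulation replicates for calibration and
  recovery checks; 100 seeds for the density-change Monte-Carlo. The full
  test suite runs in about a minute.

## Known limitations

- Dendritic ROIs are supported as additional masks, but the default
  pipeline quantifies somatic densities only.
- The library-size equalization rounds pseudo-counts; for strongly
  unequal libraries a GLM-based engine supplied through `external_table`
  is the better route.
- The CoV reading ("sum of the ratio of the standard deviation to the
  mean from each sample") and the composite weighting are interpretations
  of underspecified procedures; both alternatives ship behind flags.
- `intensity_correction()` assumes signal area scales linearly with
  staining efficiency; strong saturation would violate that assumption.
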