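# pvquant

Quantification pipeline for studies of activity-dependent scaling of
perisomatic inhibitory synapses onto parvalbumin-positive (PV⁺) cortical
interneurons.

When the activity of a PV⁺ interneuron is raised or lowered (e.g.
chemogenetically) the inhibitory synapses it receives from neighbouring PV⁺
cells rescale. Measuring that rescaling takes a stack of small, rule-based
quantifications spread across imaging, sequencing and electrophysiology.
`pvquant` implements that stack as one tested R package:

- **Synapse colocalization quantification** — presynaptic (SYT2/VGaT-like)
  and postsynaptic (gephyrin-like) puncta are detected by intensity
  thresholding, particle analysis and optional watershed splitting. Against
  each segmented soma, a presynaptic punctum is a *bouton* iff its centroid
  lies outside the soma and ≥ 0.1 µm² of it colocalizes with the soma
  perimeter; a postsynaptic punctum is a *cluster* iff its centroid lies
  inside and the perimeter overlap is ≥ 0.2 µm²; a *synapse* is a
  bouton–cluster pair with mask colocalization ≥ 0.03 µm². Densities are
  synapses per µm of soma perimeter, and groups are compared with

  Density change = (density_infected / density_uninfected − 1) × 100.

- **FOS ROI intensity and smFISH particle counts** — mean
  immediate-early-gene channel intensity per soma ROI, and transcript
  abundance estimated as thresholded probe signal area divided by the area
  of a single mRNA particle (~0.16 µm²), with a per-brain intensity-ratio
  correction (each brain's off-cell mean intensity normalized to the
  dimmest brain).

- **Activity-dependent gene ranking** — low-count filtering (genes with
  fewer than 10 reads in ≥ 4 samples are excluded), a negative binomial
  exact-style test (qCML dispersion with tagwise moderation, mid-p
  conditional test) or an external DE table, the >1.5-fold / FDR < 0.05 /
  abundance > 1 cut-offs, and a composite ranking over four criteria each
  scaled to [0, 1]: fold-change magnitude, CoV reproducibility (inverted),
  summed interaction scores to other responding genes, and binary secretome
  membership.

- **Electrophysiology summaries** — per-cell amplitude/frequency/charge,
  current per second = (mean event charge) × frequency, E/I ratio =
  excitatory / inhibitory current per second, residual-corrected
  paired-pulse ratio, and quality-control exclusion (Ra > 25 MΩ,
  |Ihold| > 200 pA, Rs change > 20%).

- **Synthetic data with planted ground truth** — every stage is exercised
  on generated inputs: rendered soma+puncta fields whose planted objects
  are recoverable exactly at the nominal thresholds, negative binomial
  count matrices with planted DEGs, smFISH fields with planted particle
  counts, Poisson event trains, and per-cell density populations with a
  planted density ratio.

## Worked example

```r
library(pvquant)

# a synthetic field: 2 somata, 3 planted synapse pairs each, plus
# unpaired perimeter puncta and off-soma distractors
tr  <- image_truth(n_somata = 2, n_pairs_per_soma = 3,
                   infected = c(TRUE, FALSE), seed = 42)
sim <- make_synapse_image(tr, noise_sd = 0)
q   <- quantify_synapses(sim$image)
q$records[, c("cell_id", "group", "n_synapses", "perimeter_length", "density")]
#>   cell_id      group n_synapses perimeter_length    density
#> 1   cell1   infected          3         50.22741 0.05972835
#> 2   cell2 uninfected          3         50.22741 0.05972835
```

Each row is one soma: 3 of 3 planted pairs recovered, a perimeter close to
the analytic 2π·8 ≈ 50.3 µm for the planted 8 µm soma radius, and the
resulting density in synapses/µm. The numbered scripts under `analysis/`
run the same machinery over every stage (simulation, synapse density and
density change, FOS/smFISH, gene ranking, ephys) and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R 1 && Rscript analysis/02_synapse_density.R 1
Rscript analysis/03_fos_smfish.R && Rscript analysis/04_gene_ranking.R
Rscript analysis/05_ephys.R
```

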