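#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analysis
# scripts: two synapse-quantification fields (one noise-free, one at the
# documented noise level), FOS and smFISH fields, a planted count matrix,
# and miniature-event trains. Everything is written under
# results/simulated/ with its ground truth alongside.

suppressMessages(library(pvquant))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# synapse fields: 2 somata (one infected), 3 planted pairs each,
# unpaired perimeter objects and off-soma distractors probing precision
for (cfg in list(list(name = "field_clean", noise = 0),
                 list(name = "field_noisy", noise = 8))) {
  tr <- image_truth(n_somata = 2, n_pairs_per_soma = 3,
                    n_unpaired_boutons = 2, n_unpaired_clusters = 2,
                    n_distractors = 4, infected = c(TRUE, FALSE),
                    seed = seed)
  sim <- make_synapse_image(tr, noise_sd = cfg$noise)
  write_image_stack(sim$image, file.path(out, paste0(cfg$name, ".tif")))
  write.csv(tr$planted_pairs,
            file.path(out, paste0(cfg$name, "_truth_pairs.csv")),
            row.names = FALSE)
  message(sprintf("%s: %d planted pairs, noise sd %g",
                  cfg$name, nrow(tr$planted_pairs), cfg$noise))
}

# FOS field at 0.88 px/um (10x objective scale)
fos_tr <- image_truth(n_somata = 2, pixel_size = 1 / 0.88, soma_radius_um = 8,
                      n_pairs_per_soma = 0, n_unpaired_boutons = 0,
                      n_unpaired_clusters = 0, n_distractors = 0,
                      fos_intensity = c(120, 60), infected = c(TRUE, FALSE),
                      seed = seed + 1L)
write_image_stack(make_fos_image(fos_tr, noise_sd = 2)$image,
                  file.path(out, "fos_field.tif"))

# smFISH fields at 5.544 px/um (63x objective scale), two brain gains
for (g in c(1, 1.5)) {
  fish_tr <- image_truth(n_somata = 2, width = 360, height = 360,
                         pixel_size = 1 / 5.544, soma_radius_um = 8,
                         n_pairs_per_soma = 0, n_unpaired_boutons = 0,
                         n_unpaired_clusters = 0, n_distractors = 0,
                         particle_count = c(12, 25),
                         infected = c(TRUE, FALSE), seed = seed + 2L)
  write_image_stack(make_fish_image(fish_tr, gain = g)$image,
                    file.path(out, sprintf("fish_field_gain%g.tif", g)))
}
message("fish fields: planted 12 and 25 particles per soma, gains 1 and 1.5")

# vTRAP-style count matrix: 4 vs 4, 20 planted DEGs at |log2FC| = 1.5
ct <- counts_truth(n_genes = 1000, n_deg = 20, planted_log2fc = 1.5,
                   dispersion = 0.05, seed = seed + 3L)
cm <- make_counts(ct)$counts
write_counts_tsv(cm, file.path(out, "counts.tsv"),
                 file.path(out, "samples.tsv"))
writeLines(ct$planted_deg_ids, file.path(out, "truth_planted_degs.txt"))
message(sprintf("counts: %d genes x %d samples, %d planted DEGs",
                nrow(cm$counts), ncol(cm$counts),
                length(ct$planted_deg_ids)))

# miniature-event trains for one cell (exc 4 Hz x 0.5 pC, inh 4 Hz x 1 pC)
rows <- list()
for (cfg in list(list(pol = "excitatory", rate = 4, q = 0.5, off = 4L),
                 list(pol = "inhibitory", rate = 4, q = 1.0, off = 5L))) {
  t <- make_events(event_truth(rate = cfg$rate, mean_charge = cfg$q,
                               duration = 200, seed = seed + cfg$off),
                   cell_id = "cell1", polarity = cfg$pol)$train
  rows[[cfg$pol]] <- data.frame(cell_id = "cell1", polarity = cfg$pol,
                                time_s = t$event_times,
                                amplitude_pA = t$amplitudes,
                                charge_pC = t$charges, duration_s = 200)
}
write.csv(do.call(rbind, rows), file.path(out, "events.csv"),
          row.names = FALSE)
message("events: planted E/I ratio (4*0.5)/(4*1.0) = 0.5")
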