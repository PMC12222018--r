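#!/usr/bin/env Rscript
# Event-train summaries (amplitude, frequency, charge, current/second),
# the E/I ratio, a residual-corrected paired-pulse ratio example, and
# quality-control exclusion on a toy cell table.
#
# Reads results/simulated/events.csv; writes results/ephys_summary.csv
# and results/ephys_qc.csv.

suppressMessages(library(pvquant))
dir.create("results", showWarnings = FALSE)

trains <- read_event_csv("results/simulated/events.csv")
summ <- do.call(rbind, lapply(trains, train_summary))
summ$ei_ratio <- NA_real_
exc <- trains[["cell1.excitatory"]]
inh <- trains[["cell1.inhibitory"]]
summ$ei_ratio[summ$polarity == "excitatory"] <- ei_ratio(exc, inh)
message(sprintf("cell1: exc %.2f pC/s, inh %.2f pC/s, E/I %.2f (planted 0.5)",
                summ$current_per_second[summ$polarity == "excitatory"],
                summ$current_per_second[summ$polarity == "inhibitory"],
                summ$ei_ratio[summ$polarity == "excitatory"]))
message(sprintf("PPR example: peaks 300/330 pA with 30 pA residual -> %.2f",
                ppr(300, 330, 30)))
write.csv(summ, "results/ephys_summary.csv", row.names = FALSE)

qc <- apply_qc(data.frame(
  cell_id = sprintf("cell%d", 1:6),
  Ra = c(12, 25, 26, 18, 30, 15),
  Ihold = c(-80, 200, 50, -250, 120, 30),
  Rs_change = c(NA, 20, NA, NA, 25, 21)))
message(sprintf("QC: %d of %d cells excluded (%s)", sum(qc$excluded),
                nrow(qc), paste(qc$cell_id[qc$excluded], collapse = ", ")))
write.csv(qc, "results/ephys_qc.csv", row.names = FALSE)
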