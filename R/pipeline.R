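#' Default run configuration
#'
#' Every stage threshold in one serializable structure, with units in the
#' key names. The defaults are the quantification rules the pipeline is
#' built around: perimeter-overlap floors of 0.1 um^2 (boutons) and
#' 0.2 um^2 (clusters), a 0.03 um^2 colocalization floor for synapses, a
#' 0.05 um^2 minimum particle size, a 0.16 um^2 single-mRNA-particle
#' area, the <10 reads in >=4 samples count filter, the 1.5-fold /
#' FDR 0.05 / abundance 1 activation-response cut-offs, and the
#' Ra 25 MOhm / Ihold 200 pA / Rs-change 20% QC bounds.
#'
#' @param seed Integer seed used by every stage's synthetic input.
#' @param stages Character vector of stages to run, from
#'   `c("synapses", "fos", "fish", "rank", "ephys")`.
#' @return A nested `run_config` list.
#' @export
default_config <- function(seed = 1L,
                           stages = c("synapses", "fos", "fish", "rank",
                                      "ephys")) {
  structure(list(
    stages = stages,
    seed = as.integer(seed),
    pixel_size_um = 1 / 15.4,
    band_width_px = 2,
    pairing = "one_to_one",
    thresholds = list(
      soma_intensity_au = 90,
      puncta_intensity_au = 50,
      bouton_min_overlap_um2 = 0.1,
      cluster_min_overlap_um2 = 0.2,
      synapse_min_coloc_um2 = 0.03,
      min_particle_area_um2 = 0.05,
      single_particle_area_um2 = 0.16,
      min_reads = 10,
      min_samples = 4,
      fold_change = 1.5,
      fdr = 0.05,
      min_abundance = 1,
      qc_ra_max_mohm = 25,
      qc_ihold_max_pa = 200,
      qc_rs_change_max_pct = 20
    )
  ), class = "run_config")
}

#' Validate a run configuration against the schema
#'
#' Unknown keys, missing thresholds and non-numeric threshold values are
#' reported (all of them, by name) before any stage runs.
#'
#' @param config A `run_config`-shaped list.
#' @return The validated config, invisibly; errors otherwise.
#' @export
validate_config <- function(config) {
  ref <- unclass(default_config())
  bad <- setdiff(names(config), names(ref))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  miss <- setdiff(names(ref), names(config))
  if (length(miss))
    stop("missing config key(s): ", paste(miss, collapse = ", "))
  badt <- setdiff(names(config$thresholds), names(ref$thresholds))
  if (length(badt))
    stop("unknown threshold key(s): ", paste(badt, collapse = ", "))
  misst <- setdiff(names(ref$thresholds), names(config$thresholds))
  if (length(misst))
    stop("missing threshold key(s): ", paste(misst, collapse = ", "))
  nonnum <- names(config$thresholds)[!vapply(config$thresholds,
                                             is.numeric, logical(1))]
  if (length(nonnum))
    stop("non-numeric threshold(s): ", paste(nonnum, collapse = ", "))
  unknown_stage <- setdiff(config$stages,
                           c("synapses", "fos", "fish", "rank", "ephys"))
  if (length(unknown_stage))
    stop("unknown stage(s): ", paste(unknown_stage, collapse = ", "))
  invisible(config)
}

#' Write / read a run configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `read_config`: the config (validated).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path,
                   precision = 15)  # round-trip numeric thresholds losslessly
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  config <- yaml::read_yaml(path)
  class(config) <- "run_config"
  validate_config(config)
  config
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the demonstration pipeline over synthetic inputs
#'
#' Executes the requested stages over in-package synthetic data generated
#' from `config$seed`, writing one CSV per stage, the resolved
#' configuration, and a structured run log (stage, rows in, rows out) to
#' `out_dir`. Identical config and seed give byte-identical outputs.
#'
#' @param config A `run_config` (validated before any stage runs).
#' @param out_dir Output directory (created if needed).
#' @return Path to `out_dir`, invisibly; side effect: CSV outputs,
#'   `resolved_config.yml`, `run_log.csv`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_config(config)
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  log <- list()
  note <- function(stage, n_in, n_out)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out)

  if ("synapses" %in% config$stages) {
    tr <- image_truth(n_somata = 2, pixel_size = config$pixel_size_um,
                      infected = c(TRUE, FALSE), seed = config$seed)
    sim <- make_synapse_image(tr, noise_sd = 0)
    q <- quantify_synapses(sim$image,
                           soma_thresh = th$soma_intensity_au,
                           puncta_thresh = th$puncta_intensity_au,
                           min_particle_area = th$min_particle_area_um2,
                           band_width = config$band_width_px,
                           pairing = config$pairing)
    write_stage_csv(q$records, out_dir, "synapse_density")
    note("synapses", nrow(tr$planted_pairs), nrow(q$records))
  }
  if ("fos" %in% config$stages) {
    tr <- image_truth(n_somata = 2, pixel_size = 1 / 0.88, soma_radius_um = 8,
                      n_pairs_per_soma = 0, n_unpaired_boutons = 0,
                      n_unpaired_clusters = 0, n_distractors = 0,
                      fos_intensity = c(120, 60), infected = c(TRUE, FALSE),
                      seed = config$seed + 1L)
    sim <- make_fos_image(tr, noise_sd = 2)
    somata <- segment_somata(sim$image, "cell",
                             intensity_thresh = th$soma_intensity_au,
                             min_area = 30, max_area = 800,
                             band_width = config$band_width_px)
    fr <- fos_intensity(sim$image, somata)
    write_stage_csv(fr, out_dir, "fos_intensity")
    note("fos", length(somata), nrow(fr))
  }
  if ("fish" %in% config$stages) {
    recs <- list()
    means <- c(); brains <- c()
    gains <- c(brainA = 1, brainB = 1.5)
    for (b in names(gains)) {
      tr <- image_truth(n_somata = 2, width = 360, height = 360,
                        pixel_size = 1 / 5.544, soma_radius_um = 8,
                        n_pairs_per_soma = 0, n_unpaired_boutons = 0,
                        n_unpaired_clusters = 0, n_distractors = 0,
                        particle_count = c(12, 25),
                        infected = c(TRUE, FALSE),
                        seed = config$seed + 2L + match(b, names(gains)))
      sim <- make_fish_image(tr, gain = gains[[b]],
                             single_particle_area = th$single_particle_area_um2)
      somata <- segment_somata(sim$image, "cell",
                               intensity_thresh = th$soma_intensity_au,
                               min_area = 30, max_area = 800)
      for (s in somata)
        recs[[length(recs) + 1L]] <-
          count_particles(sim$image, s,
                          intensity_thresh = th$puncta_intensity_au,
                          single_particle_area = th$single_particle_area_um2,
                          cell_id = paste0(b, "_cell", s$id), brain_id = b)
      means <- c(means, roi_excluded_mean(sim$image, somata))
      brains <- c(brains, b)
    }
    recs <- do.call(rbind, recs)
    norm <- brain_normalization(means, brains)
    recs <- intensity_correction(recs, norm)
    write_stage_csv(recs, out_dir, "fish_counts")
    write_stage_csv(norm, out_dir, "fish_brain_normalization")
    note("fish", length(brains), nrow(recs))
  }
  if ("rank" %in% config$stages) {
    ct <- counts_truth(n_genes = 400, n_deg = 12, seed = config$seed + 9L)
    sim <- make_counts(ct)
    res <- rank_activity_genes(sim$counts,
                               min_reads = th$min_reads,
                               min_samples = th$min_samples,
                               fold_change = th$fold_change,
                               fdr_cutoff = th$fdr,
                               min_abundance = th$min_abundance)
    write_stage_csv(res$degs, out_dir, "deg_table")
    if (!is.null(res$ranking))
      write_stage_csv(res$ranking, out_dir, "gene_scores")
    note("rank", ct$n_genes,
         if (is.null(res$ranking)) 0L else nrow(res$ranking))
  }
  if ("ephys" %in% config$stages) {
    et_e <- event_truth(rate = 4, mean_charge = 0.5, seed = config$seed + 20L)
    et_i <- event_truth(rate = 6, mean_charge = 0.8, seed = config$seed + 21L)
    exc <- make_events(et_e, cell_id = "cell1", polarity = "excitatory")$train
    inh <- make_events(et_i, cell_id = "cell1", polarity = "inhibitory")$train
    summ <- rbind(train_summary(exc), train_summary(inh))
    summ$ei_ratio <- c(ei_ratio(exc, inh), NA)
    write_stage_csv(summ, out_dir, "ephys_summary")
    note("ephys", 2L, nrow(summ))
  }

  write_config(config, file.path(out_dir, "resolved_config.yml"))
  utils::write.csv(do.call(rbind, log), file.path(out_dir, "run_log.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
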