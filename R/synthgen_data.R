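#' Ground truth for a synthetic ribosome-associated mRNA count matrix
#'
#' Describes a two-condition (vehicle vs CNO) negative binomial count
#' matrix with planted differentially expressed genes. Defaults emulate
#' the study conditions: 4 biological replicates per condition and a
#' 1.5-fold planted response. The fold change is split symmetrically
#' around each gene's baseline mean so the planted between-condition mean
#' ratio is exactly `2^planted_log2fc`.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per condition (default 4).
#' @param n_deg Number of planted DEGs (ignored when `planted_log2fc` is a
#'   named vector).
#' @param planted_log2fc Either a single log2 fold change applied to
#'   `n_deg` genes (alternating sign to plant both up- and downregulated
#'   genes) or a full per-planted-gene vector.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline mean counts.
#' @param lib_sizes Optional per-sample relative library-size factors
#'   (length `2 * n_per_group`); default all 1.
#' @param seed Mandatory integer seed.
#' @return A `counts_truth` object; planted gene ids are
#'   `planted_deg_ids`.
#' @export
counts_truth <- function(n_genes = 1000, n_per_group = 4, n_deg = 20,
                         planted_log2fc = 1.5, dispersion = 0.05,
                         baseline_meanlog = log(100), baseline_sdlog = 1,
                         lib_sizes = NULL, seed) {
  if (missing(seed)) stop("a seed is required; no global random state is used")
  if (n_per_group != as.integer(n_per_group))
    stop("n_per_group must be an integer")
  n_per_group <- as.integer(n_per_group)
  if (dispersion < 0) stop("dispersion must be >= 0")
  n_samples <- 2L * n_per_group
  if (is.null(lib_sizes)) lib_sizes <- rep(1, n_samples)
  if (length(lib_sizes) != n_samples || any(lib_sizes <= 0))
    stop("lib_sizes must be ", n_samples, " positive factors")
  with_seed(seed, {
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    lfc <- stats::setNames(numeric(n_genes), gene_ids)
    if (length(planted_log2fc) > 1L) {
      n_deg <- length(planted_log2fc)
      planted <- sample(gene_ids, n_deg)
      lfc[planted] <- planted_log2fc
    } else if (n_deg > 0L && planted_log2fc != 0) {
      planted <- sample(gene_ids, n_deg)
      lfc[planted] <- planted_log2fc * rep_len(c(1, -1), n_deg)
    } else planted <- character(0)
    structure(list(
      n_genes = n_genes, n_per_group = n_per_group,
      planted_deg_ids = sort(planted),
      planted_log2fc = lfc[lfc != 0],
      log2fc_all = lfc,
      baseline = stats::setNames(baseline, gene_ids),
      dispersion = dispersion, lib_sizes = lib_sizes,
      seed = as.integer(seed)
    ), class = "counts_truth")
  })
}

#' Simulate the count matrix described by a [counts_truth]
#'
#' Counts are NB with per-gene mean `baseline * 2^(±log2fc/2) *
#' lib_size`, size `1/dispersion` (Poisson in the `dispersion = 0` limit).
#' The first `n_per_group` samples are labelled `vehicle`, the rest `CNO`.
#'
#' @param truth A [counts_truth].
#' @return List with `counts` (a [counts_matrix]) and `truth`.
#' @export
make_counts <- function(truth) {
  stopifnot(inherits(truth, "counts_truth"))
  with_seed(truth$seed + 1L, {
    n <- truth$n_genes
    npg <- truth$n_per_group
    cond <- rep(c("vehicle", "CNO"), each = npg)
    mu_veh <- truth$baseline * 2^(-truth$log2fc_all / 2)
    mu_cno <- truth$baseline * 2^(truth$log2fc_all / 2)
    mu <- cbind(matrix(mu_veh, n, npg), matrix(mu_cno, n, npg))
    mu <- sweep(mu, 2, truth$lib_sizes, `*`)
    counts <- if (truth$dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), n)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / truth$dispersion), n)
    }
    dimnames(counts) <- list(names(truth$baseline),
                             paste0(cond, rep(seq_len(npg), 2)))
    cm <- counts_matrix(counts, condition = cond)
    list(counts = cm, truth = truth)
  })
}

#' Ground truth for a synthetic miniature-event train
#'
#' @param rate Event rate in Hz (>= 0).
#' @param mean_amplitude Mean event amplitude in pA.
#' @param mean_charge Mean per-event charge in pC.
#' @param duration Recording duration in s (> 0).
#' @param cv Coefficient of variation of amplitudes and charges (gamma
#'   shape `1/cv^2`; gamma keeps both physically nonnegative).
#' @param seed Mandatory integer seed.
#' @return An `event_truth` object.
#' @export
event_truth <- function(rate = 4, mean_amplitude = 20, mean_charge = 0.5,
                        duration = 100, cv = 0.5, seed) {
  if (missing(seed)) stop("a seed is required; no global random state is used")
  if (rate < 0) stop("rate must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (cv <= 0) stop("cv must be > 0")
  structure(list(rate = rate, mean_amplitude = mean_amplitude,
                 mean_charge = mean_charge, duration = duration, cv = cv,
                 seed = as.integer(seed)),
            class = "event_truth")
}

#' Simulate a detected-event train
#'
#' Homogeneous Poisson event times on `[0, duration]`; amplitudes and
#' charges drawn from gamma distributions around the planted means.
#'
#' @param truth An [event_truth].
#' @param cell_id,polarity Passed through to the [event_train].
#' @return List with `train` (an [event_train]) and `truth`.
#' @export
make_events <- function(truth, cell_id = "cell1", polarity = "inhibitory") {
  stopifnot(inherits(truth, "event_truth"))
  with_seed(truth$seed + 3L, {
    n <- stats::rpois(1, truth$rate * truth$duration)
    times <- sort(stats::runif(n, 0, truth$duration))
    shape <- 1 / truth$cv^2
    amps <- if (n) stats::rgamma(n, shape, rate = shape / truth$mean_amplitude) else numeric(0)
    chg <- if (n) stats::rgamma(n, shape, rate = shape / truth$mean_charge) else numeric(0)
    list(train = event_train(cell_id, polarity, times, amps, chg,
                             duration = truth$duration),
         truth = truth)
  })
}

#' Simulate populations of per-cell synapse-density records
#'
#' Generates infected and uninfected (internal-control) cell populations
#' with a planted density ratio: per-cell perimeters are drawn from a
#' normal distribution and per-cell synapse counts from a Poisson around
#' `density * perimeter`, which reproduces the counting noise of scoring
#' a few dozen perisomatic synapses per cell.
#'
#' @param n_cells Cells per group.
#' @param base_density Uninfected mean density in synapses/um.
#' @param density_ratio Planted infected/uninfected density ratio (1.30
#'   plants a +30% density change).
#' @param perimeter_mean,perimeter_sd Soma perimeter distribution in um
#'   (truncated at 20 um).
#' @param n_animals Animals per group; cells are split evenly for the
#'   per-animal aggregation of the density-change statistic.
#' @param seed Mandatory integer seed.
#' @return List with `infected` and `uninfected` density-record data
#'   frames (see [density_record]) and `truth` (the planted parameters).
#' @export
make_density_population <- function(n_cells = 30, base_density = 0.12,
                                    density_ratio = 1.30,
                                    perimeter_mean = 55, perimeter_sd = 6,
                                    n_animals = 5, seed) {
  if (missing(seed)) stop("a seed is required; no global random state is used")
  stopifnot(n_cells >= 1, base_density > 0, density_ratio > 0)
  with_seed(seed, {
    gen <- function(group, dens) {
      per <- pmax(stats::rnorm(n_cells, perimeter_mean, perimeter_sd), 20)
      n_syn <- stats::rpois(n_cells, dens * per)
      data.frame(
        cell_id = paste0(group, seq_len(n_cells)),
        animal_id = paste0("m", rep_len(seq_len(n_animals), n_cells)),
        group = group,
        n_boutons = n_syn, n_clusters = n_syn, n_synapses = n_syn,
        perimeter_length = per,
        density = n_syn / per
      )
    }
    list(infected = gen("infected", base_density * density_ratio),
         uninfected = gen("uninfected", base_density),
         truth = list(n_cells = n_cells, base_density = base_density,
                      density_ratio = density_ratio, n_animals = n_animals,
                      seed = as.integer(seed)))
  })
}
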