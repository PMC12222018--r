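# Conditional log-likelihood of the dispersion for one group of NB
# replicates with equal effective library sizes (qCML). `y` is a genes x
# reps matrix; returns a per-gene vector at dispersion `phi`.
group_cond_loglik <- function(y, phi) {
  r <- 1 / max(phi, 1e-8)
  n <- ncol(y)
  s <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(s + n * r)
}

cond_loglik <- function(counts, condition, phi) {
  ll <- 0
  for (lev in levels(condition))
    ll <- ll + group_cond_loglik(counts[, condition == lev, drop = FALSE], phi)
  ll
}

#' Estimate NB dispersions by conditional maximum likelihood
#'
#' Common dispersion maximizes the conditional likelihood (given
#' per-group totals, valid for equal effective library sizes) summed over
#' genes; tagwise dispersions maximize each gene's conditional likelihood
#' plus `prior_n` times the average per-gene likelihood, shrinking noisy
#' per-gene estimates toward the common value.
#'
#' @param cm A [counts_matrix] (counts should be library-size-equalized
#'   pseudo-counts; see [differential_expression]).
#' @param prior_n Weight (in genes) of the shared likelihood (default 30;
#'   strong moderation suits small-replicate designs where per-gene
#'   dispersion estimates are noisy).
#' @param grid_length Number of grid points for the tagwise search.
#' @return List with `common` and `tagwise` dispersions.
#' @export
estimate_dispersion <- function(cm, prior_n = 30, grid_length = 31) {
  stopifnot(inherits(cm, "counts_matrix"))
  counts <- cm$counts
  common <- stats::optimize(function(lphi)
    sum(cond_loglik(counts, cm$condition, exp(lphi))),
    interval = c(log(1e-6), log(5)), maximum = TRUE)
  common <- exp(common$maximum)
  grid <- exp(seq(log(common / 20), log(common * 20), length.out = grid_length))
  ll <- vapply(grid, function(phi) cond_loglik(counts, cm$condition, phi),
               numeric(nrow(counts)))
  shared <- colMeans(ll)
  wl <- ll + matrix(prior_n * shared, nrow(counts), grid_length, byrow = TRUE)
  tagwise <- grid[max.col(wl, ties.method = "first")]
  list(common = common, tagwise = stats::setNames(tagwise, rownames(counts)))
}

# Two-sided exact NB test: conditional distribution of the first group's
# total given the overall total, with per-sample size r = 1/phi. The mean
# cancels, leaving a Polya-like weight. The two-sided p-value sums all
# outcomes strictly less probable than the observed split plus half the
# probability of the outcomes exactly as probable (mid-p); the mid-p
# correction removes most of the conservativeness discreteness imposes on
# a plain exact test, giving near-nominal type-I error.
nb_exact_pvalue <- function(sa, sb, na, nb, phi, midp = TRUE) {
  s <- sa + sb
  if (s == 0) return(1)
  r <- 1 / max(phi, 1e-8)
  a <- 0:s
  if (s > 100000) {
    mode <- s * na / (na + nb)
    hw <- ceiling(50 * sqrt(mode * (1 + phi * mode / na)) + 1000)
    a <- max(0, floor(mode - hw)):min(s, ceiling(mode + hw))
    if (!(sa %in% a)) return(.Machine$double.xmin)
  }
  lw <- lgamma(a + na * r) - lgamma(a + 1) +
    lgamma(s - a + nb * r) - lgamma(s - a + 1)
  lw <- lw - max(lw)
  p <- exp(lw) / sum(exp(lw))
  p_obs <- p[match(sa, a)]
  if (midp)
    min(1, sum(p[p < p_obs * (1 - 1e-12)]) +
          0.5 * sum(p[abs(p - p_obs) <= p_obs * 1e-12]))
  else min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Differential expression between two conditions
#'
#' `method = "nb_exact"` runs the in-package NB exact-style test:
#' counts are equalized to the geometric-mean library size
#' (pseudo-counts, rounded), dispersion is estimated by conditional
#' maximum likelihood with tagwise moderation ([estimate_dispersion]),
#' and each gene gets a two-sided mid-p exact p-value from the
#' conditional distribution of the group totals (mid-p keeps the
#' discrete test's type-I error at its nominal level instead of below
#' it). `method = "external_table"` passes a
#' published DE table through unchanged, re-evaluating only the filters,
#' so an upstream analysis can drive the ranking.
#'
#' A gene passes the activation-response filters iff its linear fold
#' change exceeds `fold_change` in either direction, its BH FDR is below
#' `fdr_cutoff`, and its mean abundance exceeds `min_abundance` in at
#' least one condition. With no transcript lengths the abundance metric
#' is CPM (flagged in the output); supplying `gene_lengths` (in bp)
#' switches to TPM.
#'
#' @param cm A [counts_matrix] with exactly two conditions and >= 2
#'   replicates each (already filtered with [filter_low_counts]).
#' @param method `"nb_exact"` or `"external_table"`.
#' @param external For `external_table`: data.frame with `gene_id`,
#'   `log2fc`, `p_value` and optionally `mean_abund_ref` /
#'   `mean_abund_alt` (computed from `cm` when absent).
#' @param fold_change Linear fold-change cutoff (default 1.5, applied
#'   two-sidedly as `|log2fc| > log2(1.5)`).
#' @param fdr_cutoff BH FDR cutoff (default 0.05).
#' @param min_abundance Abundance cutoff (default 1).
#' @param gene_lengths Optional named vector of gene lengths in bp
#'   (enables TPM).
#' @param prior_n Dispersion-moderation weight (see
#'   [estimate_dispersion]).
#' @return data.frame with `gene_id`, `log2fc` (second condition over
#'   first), `p_value`, `fdr`, `mean_abund_ref`, `mean_abund_alt`,
#'   `passes_filters`; attributes `conditions`, `abundance_metric`,
#'   `dispersion`.
#' @export
differential_expression <- function(cm,
                                    method = c("nb_exact", "external_table"),
                                    external = NULL, fold_change = 1.5,
                                    fdr_cutoff = 0.05, min_abundance = 1,
                                    gene_lengths = NULL, prior_n = 30) {
  stopifnot(inherits(cm, "counts_matrix"))
  method <- match.arg(method)
  cond <- droplevels(cm$condition)
  if (nlevels(cond) != 2)
    stop("differential expression requires exactly two conditions")
  if (any(tabulate(cond) < 2)) stop("need >= 2 replicates per condition")
  ref <- levels(cond)[1]; alt <- levels(cond)[2]

  if (is.null(gene_lengths)) {
    abund <- cpm(cm)
    metric <- "cpm"
  } else {
    len <- gene_lengths[rownames(cm$counts)]
    if (anyNA(len)) stop("gene_lengths missing for some genes")
    rpk <- cm$counts / (len / 1e3)
    abund <- sweep(rpk, 2, colSums(rpk), `/`) * 1e6
    metric <- "tpm"
  }
  m_ref <- rowMeans(abund[, cond == ref, drop = FALSE])
  m_alt <- rowMeans(abund[, cond == alt, drop = FALSE])

  if (method == "nb_exact") {
    # equalize library sizes to their geometric mean (pseudo-counts)
    lib <- cm$lib_sizes
    lstar <- exp(mean(log(lib)))
    pseudo <- round(sweep(cm$counts, 2, lstar / lib, `*`))
    pcm <- counts_matrix(pseudo, cond)
    disp <- estimate_dispersion(pcm, prior_n = prior_n)
    na <- sum(cond == ref); nb <- sum(cond == alt)
    sa <- rowSums(pseudo[, cond == ref, drop = FALSE])
    sb <- rowSums(pseudo[, cond == alt, drop = FALSE])
    pval <- vapply(seq_len(nrow(pseudo)), function(i)
      nb_exact_pvalue(sa[i], sb[i], na, nb, disp$tagwise[i]), numeric(1))
    prior <- 0.5 / mean(lib) * 1e6
    lfc <- log2((m_alt + prior) / (m_ref + prior))
    out <- data.frame(gene_id = rownames(cm$counts), log2fc = lfc,
                      p_value = pval, row.names = NULL)
    attr(out, "dispersion") <- disp
  } else {
    need <- c("gene_id", "log2fc", "p_value")
    if (is.null(external) || !all(need %in% names(external)))
      stop("external table needs columns: ", paste(need, collapse = ", "))
    out <- data.frame(gene_id = external$gene_id, log2fc = external$log2fc,
                      p_value = external$p_value, row.names = NULL)
    if (all(c("mean_abund_ref", "mean_abund_alt") %in% names(external))) {
      m_ref <- external$mean_abund_ref
      m_alt <- external$mean_abund_alt
    } else {
      i <- match(out$gene_id, rownames(cm$counts))
      if (anyNA(i)) stop("external genes absent from the counts matrix: ",
                         paste(out$gene_id[is.na(i)], collapse = ", "))
      m_ref <- m_ref[i]; m_alt <- m_alt[i]
    }
  }
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$mean_abund_ref <- m_ref
  out$mean_abund_alt <- m_alt
  out$passes_filters <- abs(out$log2fc) > log2(fold_change) &
    out$fdr < fdr_cutoff &
    pmax(out$mean_abund_ref, out$mean_abund_alt) > min_abundance
  attr(out, "conditions") <- c(ref = ref, alt = alt)
  attr(out, "abundance_metric") <- metric
  out
}
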