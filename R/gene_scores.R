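minmax_scale <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1])) return(rep(NA_real_, length(x)))
  if (rng[2] == rng[1]) return(rep(1, length(x)))  # degenerate: no information
  (x - rng[1]) / (rng[2] - rng[1])
}

passing_genes <- function(degs) {
  g <- degs$gene_id[degs$passes_filters]
  if (length(g) == 0L) stop("no genes pass the filters")
  g
}

#' Fold-change score
#'
#' Magnitude of the response: `|log2fc|` of the passing genes, min-max
#' scaled to \[0, 1\]. When all magnitudes are equal (including a single
#' passing gene) every score is 1.
#'
#' @param degs DE table from [differential_expression].
#' @return Named numeric vector over passing genes.
#' @export
fc_score <- function(degs) {
  g <- passing_genes(degs)
  x <- abs(degs$log2fc[match(g, degs$gene_id)])
  stats::setNames(minmax_scale(x), g)
}

#' Coefficient-of-variation (reproducibility) score
#'
#' For each passing gene the CoV (sd/mean of normalized expression) is
#' computed within each condition and the two are summed; the sums are
#' min-max scaled and, by default, inverted so that low replicate
#' variability scores high (the score measures reproducibility).
#' `invert = FALSE` gives the uninverted scaling. A gene whose mean is
#' zero in some condition has no defined CoV there; its score is NA and
#' it is listed in the `flagged` attribute.
#'
#' @param cm The [counts_matrix] the DE table came from.
#' @param degs DE table from [differential_expression].
#' @param invert Low CoV scores high (default TRUE).
#' @return Named numeric vector over passing genes; attribute `flagged`
#'   names zero-mean genes.
#' @export
cov_score <- function(cm, degs, invert = TRUE) {
  stopifnot(inherits(cm, "counts_matrix"))
  g <- passing_genes(degs)
  expr <- cpm(cm)[g, , drop = FALSE]
  cond <- droplevels(cm$condition)
  summed <- rep(0, length(g))
  for (lev in levels(cond)) {
    e <- expr[, cond == lev, drop = FALSE]
    mu <- rowMeans(e)
    cv <- apply(e, 1, stats::sd) / mu
    cv[mu == 0] <- NA
    summed <- summed + cv
  }
  flagged <- g[is.na(summed)]
  sc <- minmax_scale(summed)
  rng <- range(summed, na.rm = TRUE)
  degenerate <- is.finite(rng[1]) && rng[1] == rng[2]
  if (invert && !degenerate) sc <- 1 - sc
  structure(stats::setNames(sc, g), flagged = flagged)
}

#' Interaction network from an edge table
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `score`
#'   (undirected; scores in \[0, 1\]; self-loops are an error). A
#'   STRING-style export with `combined_score` on a 0-1000 scale can be
#'   divided by 1000 before loading.
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(edges) {
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(edges)))
    stop("edge table needs columns: ", paste(need, collapse = ", "))
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  if (any(edges$score < 0 | edges$score > 1))
    stop("interaction scores must lie in [0, 1]")
  structure(list(edges = edges[need]), class = "interaction_network")
}

#' @rdname interaction_network
#' @param file 3-column TSV (`gene_a`, `gene_b`, `score`).
#' @export
read_network_tsv <- function(file) {
  interaction_network(utils::read.delim(file))
}

#' Interaction (network) score
#'
#' Each passing gene's co-interaction with the other activation-response
#' genes: the sum of its interaction scores to other passing genes,
#' min-max scaled to \[0, 1\]. Genes absent from the network sum to 0.
#'
#' @param degs DE table from [differential_expression].
#' @param net An [interaction_network].
#' @return Named numeric vector over passing genes.
#' @export
string_score <- function(degs, net) {
  stopifnot(inherits(net, "interaction_network"))
  g <- passing_genes(degs)
  e <- net$edges
  keep <- e$gene_a %in% g & e$gene_b %in% g
  raw <- stats::setNames(rep(0, length(g)), g)
  if (any(keep)) {
    e <- e[keep, ]
    for (i in seq_len(nrow(e))) {
      raw[e$gene_a[i]] <- raw[e$gene_a[i]] + e$score[i]
      raw[e$gene_b[i]] <- raw[e$gene_b[i]] + e$score[i]
    }
  }
  stats::setNames(minmax_scale(raw), g)
}

#' Secretome membership score
#'
#' Binary: 1 when the gene is part of the (human) secretome gene set,
#' else 0. Symbols are matched case-insensitively so mouse/human symbol
#' casing differences do not matter; ortholog mapping beyond casing is
#' the caller's concern.
#'
#' @param degs DE table from [differential_expression].
#' @param secretome Character vector of secreted-gene symbols (e.g. read
#'   from a 1-column TSV with [read_secretome_tsv]).
#' @return Named 0/1 vector over passing genes.
#' @export
secretome_score <- function(degs, secretome) {
  g <- passing_genes(degs)
  stats::setNames(as.numeric(tolower(g) %in% tolower(secretome)), g)
}

#' @rdname secretome_score
#' @param file 1-column TSV (header optional via `header`).
#' @param header Whether the file has a header row.
#' @export
read_secretome_tsv <- function(file, header = TRUE) {
  as.character(utils::read.delim(file, header = header)[[1]])
}

#' Combine the four scores into a ranked gene table
#'
#' Composite = weighted sum of the four criteria (default weights all 1,
#' so the composite lies in \[0, 4\]); genes are ranked by descending
#' composite, ties broken by higher fold-change score and then by gene
#' id. All four score vectors must cover exactly the same passing-gene
#' set; NA scores (e.g. flagged CoV genes) must be resolved by the caller
#' before ranking.
#'
#' @param fc,cov,string,secretome Named score vectors over the same
#'   genes.
#' @param weights Numeric length-4 weights (fc, cov, string, secretome).
#' @return data.frame with the four scores, `composite` and `rank`
#'   (a permutation of 1..n), ordered by rank.
#' @export
rank_genes <- function(fc, cov, string, secretome, weights = c(1, 1, 1, 1)) {
  g <- names(fc)
  if (is.null(g)) stop("score vectors must be named by gene")
  for (v in list(cov, string, secretome))
    if (!setequal(names(v), g))
      stop("all four score vectors must cover the same gene set")
  if (length(weights) != 4) stop("weights must have length 4")
  cov <- cov[g]; string <- string[g]; secretome <- secretome[g]
  if (anyNA(c(fc, cov, string, secretome)))
    stop("NA scores present; resolve flagged genes before ranking")
  composite <- weights[1] * fc + weights[2] * cov +
    weights[3] * string + weights[4] * secretome
  out <- data.frame(gene_id = g, fc_score = as.numeric(fc),
                    cov_score = as.numeric(cov),
                    string_score = as.numeric(string),
                    secretome_score = as.numeric(secretome),
                    composite = as.numeric(composite), row.names = NULL)
  out <- out[order(-out$composite, -out$fc_score, out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Filter, test and rank activity-dependent genes
#'
#' The full prioritization pipeline: low-count filtering, differential
#' expression, the stated activation-response cut-offs, and the
#' four-criterion ranking.
#'
#' @param cm A [counts_matrix].
#' @param net An [interaction_network] (or NULL for an edgeless network).
#' @param secretome Character vector of secreted-gene symbols.
#' @param min_reads,min_samples Low-count filter settings.
#' @param weights Composite weights (see [rank_genes]).
#' @param ... Passed to [differential_expression].
#' @return List with `degs` (full DE table) and `ranking` (the
#'   [rank_genes] table over passing genes).
#' @export
rank_activity_genes <- function(cm, net = NULL, secretome = character(0),
                                min_reads = 10, min_samples = 4,
                                weights = c(1, 1, 1, 1), ...) {
  fcm <- filter_low_counts(cm, min_reads, min_samples)
  degs <- differential_expression(fcm, ...)
  if (!any(degs$passes_filters))
    return(list(degs = degs, ranking = NULL))
  if (is.null(net))
    net <- interaction_network(data.frame(gene_a = character(),
                                          gene_b = character(),
                                          score = numeric()))
  fc <- fc_score(degs)
  cov <- cov_score(fcm, degs)
  cov[is.na(cov)] <- 0  # zero-mean flagged genes carry no reproducibility signal
  st <- string_score(degs, net)
  se <- secretome_score(degs, secretome)
  list(degs = degs, ranking = rank_genes(fc, cov, st, se, weights))
}
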