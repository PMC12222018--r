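#' Gene-level counts with condition labels
#'
#' @param counts Nonnegative integer matrix, genes x samples, with gene
#'   ids as rownames (generated if absent).
#' @param condition Per-sample condition labels; exactly the comparison
#'   design is not fixed here, but downstream differential expression
#'   requires two conditions. The first factor level is the reference
#'   (vehicle) and fold changes are reported as level2/level1.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return A `counts_matrix` object.
#' @export
counts_matrix <- function(counts, condition, lib_sizes = NULL) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (length(condition) != ncol(counts))
    stop("every sample needs a condition label")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (length(lib_sizes) != ncol(counts) || any(lib_sizes <= 0))
    stop("lib_sizes must be one positive value per sample")
  cond <- if (is.factor(condition)) condition else
    factor(condition, levels = unique(condition))
  structure(list(counts = counts, condition = cond,
                 lib_sizes = as.numeric(lib_sizes)),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("counts_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", levels(x$condition),
                            tabulate(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Counts per million
#' @param cm A [counts_matrix].
#' @return Matrix of CPM values.
#' @export
cpm <- function(cm) {
  stopifnot(inherits(cm, "counts_matrix"))
  sweep(cm$counts, 2, cm$lib_sizes, `/`) * 1e6
}

#' Exclude genes with too few reads
#'
#' Default (`rule = "literal"`): a gene is excluded when the number of
#' samples with fewer than `min_reads` reads is at least `min_samples`
#' ("less than 10 reads in at least 4 samples"). `rule = "at_least"` is
#' the common filtering idiom instead: keep genes having at least
#' `min_reads` reads in at least `min_samples` samples. The two agree on
#' a balanced 4 + 4 design but differ for unbalanced ones.
#'
#' @param cm A [counts_matrix].
#' @param min_reads Read-count threshold (default 10).
#' @param min_samples Sample-count threshold (default 4; must not exceed
#'   the number of samples).
#' @param rule `"literal"` or `"at_least"`.
#' @return Filtered [counts_matrix].
#' @export
filter_low_counts <- function(cm, min_reads = 10, min_samples = 4,
                              rule = c("literal", "at_least")) {
  stopifnot(inherits(cm, "counts_matrix"))
  rule <- match.arg(rule)
  if (min_samples > ncol(cm$counts))
    stop("min_samples exceeds the number of samples")
  keep <- if (rule == "literal")
    rowSums(cm$counts < min_reads) < min_samples
  else
    rowSums(cm$counts >= min_reads) >= min_samples
  counts_matrix(cm$counts[keep, , drop = FALSE], cm$condition,
                cm$lib_sizes)
}

#' Read counts and sample sheet from TSV
#'
#' @param counts_file TSV, first column gene ids, remaining columns one
#'   per sample.
#' @param sample_file TSV with columns `sample` and `condition`.
#' @return A [counts_matrix].
#' @export
read_counts_tsv <- function(counts_file, sample_file) {
  tab <- utils::read.delim(counts_file, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  ss <- utils::read.delim(sample_file)
  if (!all(c("sample", "condition") %in% names(ss)))
    stop("sample sheet needs 'sample' and 'condition' columns")
  i <- match(colnames(counts), ss$sample)
  if (anyNA(i)) stop("samples missing from the sample sheet: ",
                     paste(colnames(counts)[is.na(i)], collapse = ", "))
  counts_matrix(counts, condition = ss$condition[i])
}

#' Write a counts matrix (and its sample sheet) to TSV
#' @param cm A [counts_matrix].
#' @param counts_file,sample_file Output paths.
#' @export
write_counts_tsv <- function(cm, counts_file, sample_file) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(cm$counts), condition = cm$condition),
    sample_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_file)
}
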