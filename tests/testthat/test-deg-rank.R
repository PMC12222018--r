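# external-table DE results give full control over which genes pass the
# filters, which keeps the score tests independent of the DE stage
forced_degs <- function(cm, genes, lfc = NULL) {
  g <- rownames(cm$counts)
  ext <- data.frame(gene_id = g,
                    log2fc = if (is.null(lfc)) ifelse(g %in% genes, 2, 0)
                             else lfc,
                    p_value = ifelse(g %in% genes, 1e-6, 0.9))
  differential_expression(cm, method = "external_table", external = ext)
}

small_cm <- function(counts, cond = rep(c("vehicle", "CNO"), each = 4)) {
  counts_matrix(counts, cond)
}

test_that("low-count filter drops the quoted example and keeps full rows", {
  m <- rbind(g1 = c(0, 0, 0, 0, 50, 50, 50, 50),   # 4 samples below 10
             g2 = c(10, 12, 15, 20, 30, 40, 50, 60),
             g3 = c(9, 9, 9, 50, 50, 50, 50, 50))  # only 3 below 10
  cm <- small_cm(m)
  kept <- rownames(filter_low_counts(cm)$counts)
  expect_setequal(kept, c("g2", "g3"))
})

test_that("low-count filter agrees exactly with the brute-force oracle", {
  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(rnbinom(300 * 8, mu = 12, size = 0.8), 300, 8)
    cm <- small_cm(m)
    got <- rownames(filter_low_counts(cm)$counts)
    ref <- rownames(cm$counts)[oracle_filter(cm$counts)]
    expect_identical(got, ref)
  }
})

test_that("the literal and at-least filter readings differ when unbalanced", {
  # 9 samples: 4 below 10, 5 at or above
  m <- rbind(g = c(0, 0, 0, 0, 20, 20, 20, 20, 20),
             filler = rep(30, 9))
  cm <- counts_matrix(m, c(rep("vehicle", 5), rep("CNO", 4)))
  expect_false("g" %in% rownames(filter_low_counts(cm, rule = "literal")$counts))
  expect_true("g" %in% rownames(filter_low_counts(cm, rule = "at_least")$counts))
})

test_that("fold-change score is the min-max scaled |log2fc|", {
  set.seed(3)
  m <- matrix(rnbinom(3 * 8, mu = 100, size = 20), 3, 8,
              dimnames = list(c("a", "b", "c"), NULL))
  cm <- small_cm(m)
  degs <- forced_degs(cm, c("a", "b", "c"), lfc = c(1, -2, 3))
  sc <- fc_score(degs)
  expect_equal(unname(sc[c("a", "b", "c")]), c(0, 0.5, 1))
  # single passing gene: degenerate scaling gives 1
  degs1 <- forced_degs(cm, "a", lfc = c(2, 0, 0))
  expect_equal(unname(fc_score(degs1)), 1)
  degs_none <- forced_degs(cm, character(0))
  expect_error(fc_score(degs_none), "pass")
})

test_that("CoV score inverts min-max scaled summed variability", {
  m <- rbind(flat = rep(c(100, 200), each = 4),       # zero within-group sd
             noisy = c(50, 150, 80, 120, 30, 170, 60, 140))
  cm <- small_cm(m)
  degs <- forced_degs(cm, c("flat", "noisy"))
  sc <- cov_score(cm, degs)
  expect_equal(unname(sc["flat"]), 1)   # zero variance = max reproducibility
  expect_equal(unname(sc["noisy"]), 0)
  un <- cov_score(cm, degs, invert = FALSE)
  expect_equal(unname(un["flat"]), 0)
  expect_equal(unname(un["noisy"]), 1)
})

test_that("a zero-mean condition flags the gene instead of scoring it", {
  m <- rbind(ok = rep(50, 8),
             dead = c(0, 0, 0, 0, 40, 44, 38, 42),
             mid = c(10, 12, 9, 11, 30, 28, 33, 29))
  cm <- small_cm(m)
  degs <- forced_degs(cm, rownames(m))
  sc <- cov_score(cm, degs)
  expect_true(is.na(sc["dead"]))
  expect_equal(attr(sc, "flagged"), "dead")
})

test_that("CoV rises with planted NB dispersion", {
  set.seed(8)
  disp <- c(0.01, 0.1, 0.5)
  m <- do.call(rbind, lapply(disp, function(d)
    matrix(rnbinom(60 * 8, mu = 200, size = 1 / d), 60, 8)))
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  cm <- small_cm(m)
  degs <- forced_degs(cm, rownames(m))
  raw <- cov_score(cm, degs, invert = FALSE)
  grp <- rep(seq_along(disp), each = 60)
  means <- tapply(raw, grp, mean)
  expect_true(all(diff(means) > 0))
})

test_that("network score sums edges to other passing genes and scales", {
  set.seed(5)
  m <- matrix(rnbinom(5 * 8, mu = 100, size = 20), 5, 8,
              dimnames = list(c("a", "b", "c", "d", "e"), NULL))
  cm <- small_cm(m)
  degs <- forced_degs(cm, c("a", "b", "c", "d"))   # e does not pass
  net <- interaction_network(data.frame(
    gene_a = c("a", "a", "b", "c"),
    gene_b = c("b", "c", "c", "e"),
    score = c(0.9, 0.5, 0.3, 0.8)))
  sc <- string_score(degs, net)
  raw <- oracle_string_sums(c("a", "b", "c", "d"), net$edges)
  # edge c-e must not count (e fails the filters); d is isolated
  expect_equal(unname(raw), c(1.4, 1.2, 0.8, 0))
  expect_equal(unname(sc), unname((raw - min(raw)) / (max(raw) - min(raw))))
  expect_equal(unname(sc["d"]), 0)
})

test_that("a clique with equal edge scores degenerates to all-1 scores", {
  set.seed(6)
  m <- matrix(rnbinom(3 * 8, mu = 100, size = 20), 3, 8,
              dimnames = list(c("a", "b", "c"), NULL))
  degs <- forced_degs(small_cm(m), c("a", "b", "c"))
  net <- interaction_network(data.frame(gene_a = c("a", "a", "b"),
                                        gene_b = c("b", "c", "c"),
                                        score = 0.5))
  expect_equal(unname(string_score(degs, net)), c(1, 1, 1))
})

test_that("network scores match the brute-force adjacency oracle on random graphs", {
  set.seed(40)
  genes <- sprintf("g%02d", 1:20)
  m <- matrix(rnbinom(20 * 8, mu = 100, size = 20), 20, 8,
              dimnames = list(genes, NULL))
  degs <- forced_degs(small_cm(m), genes)
  for (rep in 1:5) {
    pairs <- t(combn(genes, 2))
    keep <- runif(nrow(pairs)) < 0.2
    net <- interaction_network(data.frame(gene_a = pairs[keep, 1],
                                          gene_b = pairs[keep, 2],
                                          score = round(runif(sum(keep)), 3)))
    sc <- string_score(degs, net)
    raw <- oracle_string_sums(genes, net$edges)
    rng <- range(raw)
    ref <- if (rng[1] == rng[2]) rep(1, 20) else (raw - rng[1]) / diff(rng)
    expect_equal(unname(sc[genes]), unname(ref))
  }
})

test_that("network constructors reject malformed edge tables", {
  expect_error(interaction_network(data.frame(gene_a = "a", gene_b = "a",
                                              score = 0.5)), "self-loop")
  expect_error(interaction_network(data.frame(gene_a = "a", gene_b = "b",
                                              score = 1.5)), "0, 1")
})

test_that("secretome membership is binary and case-insensitive", {
  set.seed(7)
  m <- matrix(rnbinom(3 * 8, mu = 100, size = 20), 3, 8,
              dimnames = list(c("Vgf", "Bdnf", "Gapdh"), NULL))
  degs <- forced_degs(small_cm(m), c("Vgf", "Bdnf", "Gapdh"))
  sc <- secretome_score(degs, c("VGF", "bdnf"))
  expect_equal(unname(sc), c(1, 1, 0))
  expect_equal(unname(secretome_score(degs, character(0))), c(0, 0, 0))
})

test_that("score files round-trip through their TSV readers", {
  tmp <- withr::local_tempdir()
  net_path <- file.path(tmp, "net.tsv")
  write.table(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                         score = c(0.4, 0.9)),
              net_path, sep = "\t", row.names = FALSE, quote = FALSE)
  net <- read_network_tsv(net_path)
  expect_equal(nrow(net$edges), 2)
  sec_path <- file.path(tmp, "sec.tsv")
  writeLines(c("gene", "Vgf", "Bdnf"), sec_path)
  expect_equal(read_secretome_tsv(sec_path), c("Vgf", "Bdnf"))
})

test_that("counts matrices round-trip through TSV with their sample sheet", {
  ct <- counts_truth(n_genes = 30, n_deg = 3, seed = 61)
  cm <- make_counts(ct)$counts
  tmp <- withr::local_tempdir()
  write_counts_tsv(cm, file.path(tmp, "counts.tsv"), file.path(tmp, "samples.tsv"))
  back <- read_counts_tsv(file.path(tmp, "counts.tsv"),
                          file.path(tmp, "samples.tsv"))
  expect_equal(back$counts, cm$counts)
  expect_equal(as.character(back$condition), as.character(cm$condition))
})

test_that("composite ranking orders extremes and applies tie-breaks", {
  fc <- c(top = 1, bottom = 0, t1 = 0.9, t2 = 0.4)
  cov <- c(top = 1, bottom = 0, t1 = 0.1, t2 = 0.6)
  st <- c(top = 1, bottom = 0, t1 = 0.5, t2 = 0.5)
  se <- c(top = 1, bottom = 0, t1 = 0, t2 = 0)
  out <- rank_genes(fc, cov, st, se)
  expect_equal(out$gene_id[1], "top")
  expect_equal(out$gene_id[4], "bottom")
  # t1 and t2 tie on composite 1.5; higher fc_score wins
  expect_lt(out$rank[out$gene_id == "t1"], out$rank[out$gene_id == "t2"])
  expect_equal(sort(out$rank), 1:4)
  expect_error(rank_genes(fc, cov[1:3], st, se), "same gene set")
})

test_that("raising any single score never worsens a gene's rank", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 12
    g <- sprintf("g%02d", 1:n)
    scores <- replicate(4, setNames(round(runif(n), 3), g), simplify = FALSE)
    base <- rank_genes(scores[[1]], scores[[2]], scores[[3]], scores[[4]])
    pick <- sample(n, 1); crit <- sample(4, 1)
    bumped <- scores
    bumped[[crit]][pick] <- min(1, bumped[[crit]][pick] + runif(1, 0, 0.5))
    after <- rank_genes(bumped[[1]], bumped[[2]], bumped[[3]], bumped[[4]])
    expect_lte(after$rank[after$gene_id == g[pick]],
               base$rank[base$gene_id == g[pick]])
  }
})

test_that("reported FDR agrees with the step-up oracle on short vectors", {
  set.seed(50)
  for (rep in 1:6) {
    n <- sample(3:20, 1)
    m <- matrix(rnbinom(n * 8, mu = 100, size = 20), n, 8,
                dimnames = list(sprintf("g%02d", 1:n), NULL))
    cm <- small_cm(m)
    p <- round(runif(n), 4)
    ext <- data.frame(gene_id = rownames(m), log2fc = 1, p_value = p)
    degs <- differential_expression(cm, method = "external_table",
                                    external = ext)
    expect_equal(degs$fdr, oracle_bh(p))
  }
})
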