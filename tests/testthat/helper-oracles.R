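# Brute-force oracles, kept deliberately naive and independent of the
# package's implementations.

# flood-fill connected components by repeated neighbour scanning
oracle_components <- function(mask, connectivity = 8) {
  mask <- mask > 0
  nx <- nrow(mask); ny <- ncol(mask)
  labels <- matrix(0L, nx, ny)
  nbrs <- if (connectivity == 8)
    expand.grid(dx = -1:1, dy = -1:1)[-5, ]
  else data.frame(dx = c(-1, 1, 0, 0), dy = c(0, 0, -1, 1))
  cur <- 0L
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (!mask[x, y] || labels[x, y] > 0L) next
    cur <- cur + 1L
    queue <- list(c(x, y))
    labels[x, y] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        qx <- p[1] + nbrs$dx[k]; qy <- p[2] + nbrs$dy[k]
        if (qx >= 1 && qx <= nx && qy >= 1 && qy <= ny &&
            mask[qx, qy] && labels[qx, qy] == 0L) {
          labels[qx, qy] <- cur
          queue[[length(queue) + 1L]] <- c(qx, qy)
        }
      }
    }
  }
  labels
}

# pixel-by-pixel overlap area between two pixel-index sets
oracle_overlap <- function(pix_a, pix_b, pixel_size) {
  hits <- 0L
  for (p in pix_a) if (any(pix_b == p)) hits <- hits + 1L
  hits * pixel_size^2
}

# Benjamini-Hochberg step-up, literal definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# literal low-count filter: drop gene if >= min_samples samples are below
# min_reads
oracle_filter <- function(counts, min_reads = 10, min_samples = 4) {
  keep <- logical(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    below <- 0L
    for (s in seq_len(ncol(counts)))
      if (counts[g, s] < min_reads) below <- below + 1L
    keep[g] <- below < min_samples
  }
  keep
}

# per-gene sum of interaction scores to other listed genes
oracle_string_sums <- function(genes, edges) {
  sums <- stats::setNames(rep(0, length(genes)), genes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (a %in% genes && b %in% genes) {
      sums[a] <- sums[a] + edges$score[i]
      sums[b] <- sums[b] + edges$score[i]
    }
  }
  sums
}

# best 1:1 bouton-cluster assignment by total overlap, found by
# enumerating every injective assignment (tiny inputs only)
oracle_best_pairing <- function(ov, min_coloc) {
  nb <- nrow(ov); nc <- ncol(ov)
  best <- list(total = -1, pairs = NULL)
  assignments <- function(bs, used, acc) {
    if (length(bs) == 0L) {
      tot <- if (nrow(acc)) sum(acc$coloc) else 0
      if (tot > best$total) best <<- list(total = tot, pairs = acc)
      return(invisible())
    }
    b <- bs[1]
    assignments(bs[-1], used, acc)  # bouton left unpaired
    for (cl in setdiff(seq_len(nc), used))
      if (ov[b, cl] >= min_coloc)
        assignments(bs[-1], c(used, cl),
                    rbind(acc, data.frame(bouton = b, cluster = cl,
                                          coloc = ov[b, cl])))
  }
  assignments(seq_len(nb), integer(0),
              data.frame(bouton = integer(), cluster = integer(),
                         coloc = numeric()))
  best
}

# construct a punctum object from an explicit pixel set
make_punctum <- function(id, role, pixels, nx, pixel_size) {
  xs <- ((pixels - 1L) %% nx) + 1L
  ys <- ((pixels - 1L) %/% nx) + 1L
  structure(list(id = id, role = role, pixels = pixels,
                 area = length(pixels) * pixel_size^2,
                 centroid = c(x = mean(xs), y = mean(ys))),
            class = "punctum")
}

# rectangular block of pixels as linear indices of an nx x ny matrix
block_pixels <- function(x0, y0, w, h, nx) {
  as.vector(outer(x0:(x0 + w - 1L), (y0:(y0 + h - 1L) - 1L) * nx, `+`))
}

# soma ROI whose mask is an axis-aligned disc, built directly
disc_soma <- function(id, cx, cy, r_px, nx, ny, pixel_size, band_width = 2) {
  m <- outer(seq_len(nx), seq_len(ny),
             function(x, y) (x - cx)^2 + (y - cy)^2 <= r_px^2)
  soma_roi(id, m, pixel_size = pixel_size, band_width = band_width)
}
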