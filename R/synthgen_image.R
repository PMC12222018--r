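#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required; no global random state is used")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# intensity constants for rendered synthetic images (a.u.)
SYNTH_SPOT_AMPLITUDE <- 200
SYNTH_SOMA_INTENSITY <- 180
SYNTH_NOMINAL_THRESHOLD <- 50
SYNTH_SOMA_THRESHOLD <- 90

#' Nominal detection thresholds matched to the synthetic renderer
#'
#' The image generator places fluorescent objects so that, at these
#' thresholds, their footprints have exactly the planted pixel areas. A
#' real experiment would pick its own per-experiment thresholds (see
#' [calibrate_threshold]); these are the defaults the synthetic study
#' conditions are calibrated to.
#' @return Named list with `puncta` and `soma` thresholds (a.u.).
#' @export
nominal_thresholds <- function() {
  list(puncta = SYNTH_NOMINAL_THRESHOLD, soma = SYNTH_SOMA_THRESHOLD)
}

#' Ground truth for a synthetic multi-channel micrograph
#'
#' Describes one simulated field of view: soma positions and radii, planted
#' presynaptic boutons and postsynaptic gephyrin-like clusters with their
#' pairings, and optional per-cell FOS intensities and smFISH particle
#' counts. Paired objects are placed on the soma perimeter so that a
#' correctly implemented colocalization pipeline recovers exactly the
#' planted pairs; unpaired perimeter objects and off-soma distractors probe
#' precision. Object positions are drawn deterministically from `seed`.
#'
#' @param n_somata Number of somata (laid out on a diagonal grid; an error
#'   is raised if they cannot fit without touching).
#' @param width,height Image size in px.
#' @param pixel_size um/px; default 1/15.4 (100x objective at 1.75x zoom,
#'   15.4 px/um).
#' @param soma_radius_um Soma radius in um.
#' @param n_pairs_per_soma Planted synapse pairs per soma.
#' @param n_unpaired_boutons,n_unpaired_clusters Perimeter objects without
#'   a partner, per soma.
#' @param n_distractors Off-soma puncta (alternating channels) in the whole
#'   field.
#' @param bouton_area_um2,cluster_area_um2 Planted footprint areas in um^2
#'   at the nominal detection threshold.
#' @param infected Logical vector (recycled) of per-soma infection status.
#' @param fos_intensity Optional per-soma FOS channel intensity (a.u.).
#' @param particle_count Optional per-soma planted smFISH particle count.
#' @param seed Mandatory integer seed.
#' @return An `image_truth` object with planted object tables
#'   (`planted_boutons`, `planted_clusters`, `planted_pairs`).
#' @export
image_truth <- function(n_somata = 2, width = 512, height = 512,
                        pixel_size = 1 / 15.4, soma_radius_um = 8,
                        n_pairs_per_soma = 3, n_unpaired_boutons = 2,
                        n_unpaired_clusters = 2, n_distractors = 4,
                        bouton_area_um2 = 0.5, cluster_area_um2 = 0.8,
                        infected = TRUE, fos_intensity = NULL,
                        particle_count = NULL, seed) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (missing(seed)) stop("a seed is required; no global random state is used")
  r_px <- soma_radius_um / pixel_size
  margin <- r_px + 14  # room for the bouton ring and spot tails
  if (2 * margin > min(width, height))
    stop("soma radius too large for the image")

  with_seed(seed, {
    # diagonal-first grid of soma centers spanning the usable field
    ncell <- ceiling(sqrt(n_somata))
    sx <- if (ncell == 1) width / 2 else
      seq(margin, width - margin, length.out = ncell)
    sy <- if (ncell == 1) height / 2 else
      seq(margin, height - margin, length.out = ncell)
    grid <- expand.grid(i = seq_len(ncell), j = seq_len(ncell))
    grid <- grid[order(abs(grid$i - grid$j), grid$i), , drop = FALSE]
    if (n_somata > nrow(grid)) stop("cannot place ", n_somata, " somata")
    centers <- data.frame(x = sx[grid$i[seq_len(n_somata)]],
                          y = sy[grid$j[seq_len(n_somata)]])
    dmin <- if (n_somata > 1) min(stats::dist(centers)) else Inf
    if (dmin <= 2 * r_px + 28)
      stop("somata cannot be placed without overlap at this radius")
    if (any(centers$x < margin | centers$x > width - margin |
            centers$y < margin | centers$y > height - margin))
      stop("somata do not fit inside the image bounds")

    infected <- rep_len(as.logical(infected), n_somata)
    boutons <- clusters <- list()
    pairs <- list()
    bid <- cid <- 0L
    max_diam_px <- 2 * sqrt(max(bouton_area_um2, cluster_area_um2) /
                              pixel_size^2 / pi)
    for (s in seq_len(n_somata)) {
      m <- n_pairs_per_soma + n_unpaired_boutons + n_unpaired_clusters
      if (m > 0) {
        if (2 * pi * r_px / m < max_diam_px + 8)
          stop("too many perimeter objects for soma ", s,
               ": puncta would touch")
        ang <- 2 * pi * (seq_len(m) - 1) / m + stats::runif(1, 0, 2 * pi) +
          stats::runif(m, -0.25, 0.25) * (2 * pi / m) * 0.3
        kinds <- c(rep("pair", n_pairs_per_soma),
                   rep("ub", n_unpaired_boutons),
                   rep("uc", n_unpaired_clusters))
        for (k in seq_len(m)) {
          ca <- cos(ang[k]); sa <- sin(ang[k])
          jit <- stats::runif(2, 0.1, 0.4)  # sub-pixel, breaks distance ties
          if (kinds[k] %in% c("pair", "ub")) {
            bid <- bid + 1L
            boutons[[bid]] <- data.frame(
              id = bid, soma = s,
              x = centers$x[s] + (r_px + 3) * ca + jit[1],
              y = centers$y[s] + (r_px + 3) * sa + jit[2],
              area_um2 = bouton_area_um2, paired = kinds[k] == "pair",
              on_perimeter = TRUE)
          }
          if (kinds[k] %in% c("pair", "uc")) {
            cid <- cid + 1L
            clusters[[cid]] <- data.frame(
              id = cid, soma = s,
              x = centers$x[s] + (r_px - 2) * ca + jit[1],
              y = centers$y[s] + (r_px - 2) * sa + jit[2],
              area_um2 = cluster_area_um2, paired = kinds[k] == "pair",
              on_perimeter = TRUE)
          }
          if (kinds[k] == "pair")
            pairs[[length(pairs) + 1L]] <-
              data.frame(bouton_id = bid, cluster_id = cid, soma = s)
        }
      }
    }
    # off-soma distractor puncta, alternating channels
    if (n_distractors > 0) {
      placed <- 0L; tries <- 0L
      pts <- matrix(numeric(0), ncol = 2)
      while (placed < n_distractors && tries < 2000L) {
        tries <- tries + 1L
        p <- c(stats::runif(1, 12, width - 12), stats::runif(1, 12, height - 12))
        dc <- sqrt((p[1] - centers$x)^2 + (p[2] - centers$y)^2)
        if (any(dc < margin)) next
        if (nrow(pts) > 0 &&
            min(sqrt((p[1] - pts[, 1])^2 + (p[2] - pts[, 2])^2)) < 18) next
        pts <- rbind(pts, p)
        placed <- placed + 1L
        if (placed %% 2L == 1L) {
          bid <- bid + 1L
          boutons[[bid]] <- data.frame(id = bid, soma = NA_integer_,
                                       x = p[1] + 0.23, y = p[2] + 0.31,
                                       area_um2 = bouton_area_um2,
                                       paired = FALSE, on_perimeter = FALSE)
        } else {
          cid <- cid + 1L
          clusters[[cid]] <- data.frame(id = cid, soma = NA_integer_,
                                        x = p[1] + 0.23, y = p[2] + 0.31,
                                        area_um2 = cluster_area_um2,
                                        paired = FALSE, on_perimeter = FALSE)
        }
      }
      if (placed < n_distractors)
        stop("could not place ", n_distractors, " distractors in this field")
    }

    fos <- if (is.null(fos_intensity)) NULL else rep_len(fos_intensity, n_somata)
    npart <- if (is.null(particle_count)) NULL
      else rep_len(as.integer(particle_count), n_somata)

    structure(list(
      width = width, height = height, pixel_size = pixel_size,
      soma_centers = centers, soma_radii = rep(soma_radius_um, n_somata),
      soma_infected = infected,
      planted_boutons = if (length(boutons)) do.call(rbind, boutons) else
        data.frame(id = integer(), soma = integer(), x = numeric(),
                   y = numeric(), area_um2 = numeric(), paired = logical(),
                   on_perimeter = logical()),
      planted_clusters = if (length(clusters)) do.call(rbind, clusters) else
        data.frame(id = integer(), soma = integer(), x = numeric(),
                   y = numeric(), area_um2 = numeric(), paired = logical(),
                   on_perimeter = logical()),
      planted_pairs = if (length(pairs)) do.call(rbind, pairs) else
        data.frame(bouton_id = integer(), cluster_id = integer(),
                   soma = integer()),
      planted_fos_intensity = fos,
      planted_particle_count = npart,
      seed = as.integer(seed)
    ), class = "image_truth")
  })
}

# Gaussian spot whose thresholded footprint has exactly `k` pixels.
# Returns the additive intensity patch and the footprint pixel indices.
spot_footprint <- function(cx, cy, k, nx, ny, amplitude, eff_threshold) {
  w <- ceiling(sqrt(k / pi)) + 5L
  gx <- (round(cx) - w):(round(cx) + w)
  gy <- (round(cy) - w):(round(cy) + w)
  gx <- gx[gx >= 1 & gx <= nx]; gy <- gy[gy >= 1 & gy <= ny]
  d2 <- outer(gx, gy, function(x, y) (x - cx)^2 + (y - cy)^2)
  o <- order(d2)
  if (length(o) < k + 1) stop("spot does not fit inside the image")
  dk <- d2[o[k]]; dk1 <- d2[o[k + 1]]
  if (dk1 - dk < 1e-9)
    stop("degenerate spot placement (distance tie); adjust sub-pixel position")
  # sigma chosen so pixels with d2 <= (dk+dk1)/2 are exactly the footprint
  sig2 <- ((dk + dk1) / 2) / (2 * log(amplitude / eff_threshold))
  patch <- amplitude * exp(-d2 / (2 * sig2))
  fp_local <- o[seq_len(k)]
  idx <- as.vector(outer(gx, (gy - 1L) * nx, `+`))
  list(gx = gx, gy = gy, patch = patch, footprint = idx[fp_local])
}

disc_pixels <- function(cx, cy, r_px, nx, ny) {
  gx <- max(1L, floor(cx - r_px - 1)):min(nx, ceiling(cx + r_px + 1))
  gy <- max(1L, floor(cy - r_px - 1)):min(ny, ceiling(cy + r_px + 1))
  d2 <- outer(gx, gy, function(x, y) (x - cx)^2 + (y - cy)^2)
  idx <- as.vector(outer(gx, (gy - 1L) * nx, `+`))
  idx[d2 <= r_px^2]
}

#' Render a synthetic synapse-quantification image
#'
#' Produces a 4-channel stack (cell marker, infection marker, presynaptic,
#' postsynaptic). Somata are bright filled discs on the cell channel (and
#' on the infection channel when infected); puncta are isotropic Gaussian
#' spots whose footprint at the nominal detection threshold contains
#' exactly the planted number of pixels, so the planted area is meaningful
#' to the downstream thresholding pipeline to within one pixel's area.
#' Additive Gaussian noise is applied last.
#'
#' After rendering (before noise) the planted geometry is verified against
#' the classification and pairing rules; an object that cannot satisfy its
#' planted role raises an error naming it.
#'
#' @param truth An [image_truth].
#' @param noise_sd Additive Gaussian noise sd (a.u.), >= 0.
#' @param background Constant background level (a.u.); must stay below the
#'   nominal detection threshold.
#' @return List with `image` (an [image_stack]) and `truth` (the input,
#'   with per-object rendered footprints attached as `footprints`).
#' @export
make_synapse_image <- function(truth, noise_sd = 0, background = 10) {
  stopifnot(inherits(truth, "image_truth"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (background >= SYNTH_NOMINAL_THRESHOLD)
    stop("background must stay below the nominal detection threshold")
  nx <- truth$width; ny <- truth$height
  ps <- truth$pixel_size
  cell <- infect <- presyn <- postsyn <- matrix(background, nx, ny)

  soma_pix <- vector("list", nrow(truth$soma_centers))
  for (s in seq_along(soma_pix)) {
    soma_pix[[s]] <- disc_pixels(truth$soma_centers$x[s], truth$soma_centers$y[s],
                                 truth$soma_radii[s] / ps, nx, ny)
    cell[soma_pix[[s]]] <- cell[soma_pix[[s]]] + SYNTH_SOMA_INTENSITY
    if (truth$soma_infected[s])
      infect[soma_pix[[s]]] <- infect[soma_pix[[s]]] + SYNTH_SOMA_INTENSITY
  }

  render_set <- function(tbl, target) {
    fps <- vector("list", nrow(tbl))
    for (i in seq_len(nrow(tbl))) {
      k <- round(tbl$area_um2[i] / ps^2)
      sp <- spot_footprint(tbl$x[i], tbl$y[i], k, nx, ny,
                           SYNTH_SPOT_AMPLITUDE,
                           SYNTH_NOMINAL_THRESHOLD - background)
      target[sp$gx, sp$gy] <- target[sp$gx, sp$gy] + sp$patch
      fps[[i]] <- sp$footprint
    }
    list(img = target, fps = fps)
  }
  rb <- render_set(truth$planted_boutons, presyn)
  rc <- render_set(truth$planted_clusters, postsyn)
  presyn <- rb$img; postsyn <- rc$img

  validate_planted(truth, soma_pix, rb$fps, rc$fps, nx)

  if (noise_sd > 0) {
    with_seed(truth$seed + 7L, {
      cell <- cell + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
      infect <- infect + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
      presyn <- presyn + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
      postsyn <- postsyn + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    })
  }
  img <- image_stack(list(cell = cell, infection = infect,
                          presyn = presyn, postsyn = postsyn), ps)
  truth$footprints <- list(boutons = rb$fps, clusters = rc$fps,
                           somata = soma_pix)
  list(image = img, truth = truth)
}

# check the rendered geometry satisfies every planted role exactly
validate_planted <- function(truth, soma_pix, bouton_fp, cluster_fp, nx) {
  ps <- truth$pixel_size
  band_masks <- lapply(soma_pix, function(pix) {
    m <- matrix(FALSE, truth$width, truth$height); m[pix] <- TRUE
    which(perimeter_band(m, band_width = 2))
  })
  centroid_in <- function(fp, pix) {
    xs <- ((fp - 1L) %% nx) + 1L; ys <- ((fp - 1L) %/% nx) + 1L
    cx <- round(mean(xs)); cy <- round(mean(ys))
    (cx + (cy - 1L) * nx) %in% pix
  }
  tb <- truth$planted_boutons
  for (i in seq_len(nrow(tb))) {
    if (!tb$on_perimeter[i]) next
    s <- tb$soma[i]
    if (centroid_in(bouton_fp[[i]], soma_pix[[s]]))
      stop("bouton ", tb$id[i], " of soma ", s, " landed inside the soma")
    if (length(intersect(bouton_fp[[i]], band_masks[[s]])) * ps^2 < 0.1)
      stop("bouton ", tb$id[i], " of soma ", s,
           " has <0.1 um^2 perimeter overlap")
  }
  tc <- truth$planted_clusters
  for (i in seq_len(nrow(tc))) {
    if (!tc$on_perimeter[i]) next
    s <- tc$soma[i]
    if (!centroid_in(cluster_fp[[i]], soma_pix[[s]]))
      stop("cluster ", tc$id[i], " of soma ", s, " landed outside the soma")
    if (length(intersect(cluster_fp[[i]], band_masks[[s]])) * ps^2 < 0.2)
      stop("cluster ", tc$id[i], " of soma ", s,
           " has <0.2 um^2 perimeter overlap")
  }
  pp <- truth$planted_pairs
  ov <- function(i, j) length(intersect(bouton_fp[[i]], cluster_fp[[j]])) * ps^2
  planted <- paste(pp$bouton_id, pp$cluster_id)
  for (k in seq_len(nrow(pp)))
    if (ov(pp$bouton_id[k], pp$cluster_id[k]) < 0.03)
      stop("planted pair (bouton ", pp$bouton_id[k], ", cluster ",
           pp$cluster_id[k], ") has <0.03 um^2 colocalization")
  for (i in seq_len(nrow(tb)))
    for (j in seq_len(nrow(tc)))
      if (!(paste(i, j) %in% planted) && ov(i, j) >= 0.03)
        stop("bouton ", i, " and cluster ", j,
             " colocalize without a planted pairing")
  invisible(TRUE)
}

#' Render a synthetic FOS-intensity image
#'
#' 3-channel stack (cell marker, infection marker, FOS). Each soma carries
#' its planted FOS intensity on the FOS channel over a constant background.
#'
#' @param truth An [image_truth] built with `fos_intensity`.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param background Background level of the FOS channel (a.u.).
#' @return List with `image` and `truth`.
#' @export
make_fos_image <- function(truth, noise_sd = 0, background = 10) {
  stopifnot(inherits(truth, "image_truth"))
  if (is.null(truth$planted_fos_intensity))
    stop("truth has no planted FOS intensities")
  nx <- truth$width; ny <- truth$height; ps <- truth$pixel_size
  cell <- infect <- matrix(background, nx, ny)
  fos <- matrix(background, nx, ny)
  soma_pix <- vector("list", nrow(truth$soma_centers))
  for (s in seq_along(soma_pix)) {
    pix <- disc_pixels(truth$soma_centers$x[s], truth$soma_centers$y[s],
                       truth$soma_radii[s] / ps, nx, ny)
    soma_pix[[s]] <- pix
    cell[pix] <- cell[pix] + SYNTH_SOMA_INTENSITY
    if (truth$soma_infected[s]) infect[pix] <- infect[pix] + SYNTH_SOMA_INTENSITY
    fos[pix] <- truth$planted_fos_intensity[s]
  }
  if (noise_sd > 0) {
    with_seed(truth$seed + 11L, {
      cell <- cell + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
      infect <- infect + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
      fos <- fos + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    })
  }
  truth$footprints <- list(somata = soma_pix)
  list(image = image_stack(list(cell = cell, infection = infect, fos = fos), ps),
       truth = truth)
}

#' Render a synthetic smFISH image
#'
#' 3-channel stack (cell marker, infection marker, probe). Each soma
#' contains its planted number of non-overlapping mRNA particles; a
#' particle's footprint is the set of `round(gain * 0.16 um^2 / pixel
#' area)` pixels nearest a grid-jittered centre, so planted counts convert
#' exactly to signal area. `gain` emulates per-brain staining efficiency:
#' it scales both the particle footprint area and the off-cell background
#' intensity, which is the regime the per-brain intensity-ratio correction
#' is designed to undo.
#'
#' @param truth An [image_truth] built with `particle_count`; for RNAscope
#'   realism use `pixel_size = 1/5.544` (63x objective, 5.544 px/um).
#' @param gain Brain-level staining gain (>= such that footprints stay
#'   >= 1 px).
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param background Off-cell probe background at gain 1 (a.u.).
#' @param single_particle_area Area of one mRNA particle in um^2.
#' @return List with `image` and `truth`.
#' @export
make_fish_image <- function(truth, gain = 1, noise_sd = 0, background = 8,
                            single_particle_area = 0.16) {
  stopifnot(inherits(truth, "image_truth"))
  if (is.null(truth$planted_particle_count))
    stop("truth has no planted particle counts")
  if (gain <= 0) stop("gain must be > 0")
  nx <- truth$width; ny <- truth$height; ps <- truth$pixel_size
  k_base <- gain * single_particle_area / ps^2  # px per particle, real-valued
  cell <- infect <- matrix(10, nx, ny)
  probe <- matrix(gain * background, nx, ny)
  soma_pix <- vector("list", nrow(truth$soma_centers))
  with_seed(truth$seed + 13L, {
    for (s in seq_len(nrow(truth$soma_centers))) {
      r_px <- truth$soma_radii[s] / ps
      cx <- truth$soma_centers$x[s]; cy <- truth$soma_centers$y[s]
      pix <- disc_pixels(cx, cy, r_px, nx, ny)
      soma_pix[[s]] <- pix
      cell[pix] <- cell[pix] + SYNTH_SOMA_INTENSITY
      if (truth$soma_infected[s]) infect[pix] <- infect[pix] + SYNTH_SOMA_INTENSITY
      n <- truth$planted_particle_count[s]
      if (n == 0L) next
      # per-particle pixel counts: the soma's total footprint is rounded
      # once, not per particle, so the planted signal area stays within
      # one pixel of n * gain * single_particle_area
      total_px <- max(n, round(n * k_base))
      ks <- rep(total_px %/% n, n)
      extra <- total_px - sum(ks)
      if (extra > 0) ks[seq_len(extra)] <- ks[seq_len(extra)] + 1L
      # particle centres on a jittered grid inside the soma, non-overlapping
      spacing <- ceiling(2 * sqrt(max(ks) / pi)) + 2L
      gx <- seq(cx - r_px + spacing, cx + r_px - spacing, by = spacing)
      gy <- seq(cy - r_px + spacing, cy + r_px - spacing, by = spacing)
      cand <- expand.grid(x = gx, y = gy)
      cand <- cand[(cand$x - cx)^2 + (cand$y - cy)^2 <= (r_px - spacing)^2, ]
      if (nrow(cand) < n)
        stop("soma ", s, " cannot hold ", n, " particles at this gain")
      sel <- cand[sample.int(nrow(cand), n), , drop = FALSE]
      for (i in seq_len(n)) {
        px <- sel$x[i] + stats::runif(1, 0.1, 0.4)
        py <- sel$y[i] + stats::runif(1, 0.1, 0.4)
        w <- ceiling(sqrt(ks[i] / pi)) + 2L
        ggx <- (round(px) - w):(round(px) + w)
        ggy <- (round(py) - w):(round(py) + w)
        d2 <- outer(ggx, ggy, function(x, y) (x - px)^2 + (y - py)^2)
        idx <- as.vector(outer(ggx, (ggy - 1L) * nx, `+`))
        fp <- idx[order(d2)[seq_len(ks[i])]]
        probe[fp] <- gain * SYNTH_SPOT_AMPLITUDE
      }
    }
    if (noise_sd > 0) {
      cell <- cell + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
      infect <- infect + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
      probe <- probe + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    }
  })
  truth$footprints <- list(somata = soma_pix)
  list(image = image_stack(list(cell = cell, infection = infect, probe = probe), ps),
       truth = truth)
}
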