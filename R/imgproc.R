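#' Preprocessing parameters
#'
#' Settings for the fixed four-step preprocessing chain applied to every
#' channel: rolling-ball background subtraction, Gaussian blurring, median
#' smoothing, and percentile-based linear contrast enhancement, in that
#' order. Each step can be disabled by passing `NULL` (backgrounds of the
#' in-package synthetic images are flat, so the default pipeline leaves all
#' steps off; real micrographs typically want them on).
#'
#' @param rolling_ball_radius Background structuring-element radius in um,
#'   or `NULL` to skip. Must exceed the largest feature to preserve it.
#' @param gaussian_sigma Gaussian blur sigma in um, or `NULL` to skip.
#' @param median_radius Median-filter radius in px, or `NULL` to skip.
#' @param saturation Fraction of pixels saturated at each end by the
#'   contrast rescale (0 = identity mapping), or `NULL` to skip.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(rolling_ball_radius = NULL, gaussian_sigma = NULL,
                              median_radius = NULL, saturation = NULL) {
  chk <- function(x, nm, allow_zero = FALSE) {
    if (is.null(x)) return(invisible())
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (if (allow_zero) x < 0 else x <= 0))
      stop(sprintf("'%s' must be a positive number or NULL", nm))
  }
  chk(rolling_ball_radius, "rolling_ball_radius")
  chk(gaussian_sigma, "gaussian_sigma")
  chk(median_radius, "median_radius")
  chk(saturation, "saturation", allow_zero = TRUE)
  if (!is.null(saturation) && saturation >= 1)
    stop("'saturation' must be a fraction in [0, 1)")
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 gaussian_sigma = gaussian_sigma,
                 median_radius = median_radius,
                 saturation = saturation),
            class = "preprocess_params")
}

gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  g <- stats::dnorm(-r:r, sd = sigma_px)
  k <- outer(g, g)
  k / sum(k)
}

# pixel areas are integer multiples of pixel_size^2, so a true value can
# never sit within 1e-9 of a rule threshold; the tolerance only absorbs
# floating-point rounding of k * pixel_size^2
ge_tol <- function(x, thr, tol = 1e-9) x >= thr - tol

disc_brush <- function(radius_px) {
  r <- max(1L, round(radius_px))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

#' Preprocess all channels of an image stack
#'
#' Applies, in order: rolling-ball-style background subtraction (grayscale
#' morphological opening with a disc, subtracted from the image), Gaussian
#' blur, median smoothing, and contrast enhancement (linear rescale of the
#' central `1 - saturation` quantile range onto the channel's original
#' intensity range, clipping outside). Identical settings are applied to
#' all channels; the input stack is not modified.
#'
#' @param img An [image_stack].
#' @param params A [preprocess_params] object.
#' @return A new [image_stack] of the same geometry.
#' @export
preprocess <- function(img, params = preprocess_params()) {
  stopifnot(inherits(img, "image_stack"), inherits(params, "preprocess_params"))
  ps <- img$pixel_size
  out <- lapply(img$channels, function(ch) {
    if (!is.null(params$rolling_ball_radius)) {
      r <- max(1L, round(params$rolling_ball_radius / ps))
      brush <- disc_brush(r)
      # replicate-pad so the zero padding of the morphology kernels cannot
      # drag the background estimate down near the frame
      padded <- ch[c(rep(1L, r), seq_len(nrow(ch)), rep(nrow(ch), r)),
                   c(rep(1L, r), seq_len(ncol(ch)), rep(ncol(ch), r))]
      # grayscale morphology operates on [0, 1] intensities
      hi <- max(padded, 1e-12)
      bg <- ebi_mat(EBImage::opening(EBImage::Image(padded / hi), brush)) * hi
      bg <- bg[r + seq_len(nrow(ch)), r + seq_len(ncol(ch))]
      ch <- pmax(ch - bg, 0)
    }
    if (!is.null(params$gaussian_sigma)) {
      k <- gaussian_kernel(params$gaussian_sigma / ps)
      ch <- ebi_mat(EBImage::filter2(EBImage::Image(ch), k, boundary = 0))
    }
    if (!is.null(params$median_radius)) {
      hi <- max(ch, 1e-12)
      ch <- ebi_mat(EBImage::medianFilter(EBImage::Image(ch / hi),
                                          size = as.integer(params$median_radius))) * hi
    }
    if (!is.null(params$saturation) && params$saturation > 0) {
      q <- stats::quantile(ch, c(params$saturation / 2, 1 - params$saturation / 2),
                           names = FALSE)
      lo <- min(ch); hi <- max(ch)
      if (q[2] > q[1]) {
        ch <- (pmin(pmax(ch, q[1]), q[2]) - q[1]) / (q[2] - q[1]) * (hi - lo) + lo
      }
    }
    ch
  })
  image_stack(out, pixel_size = ps)
}

#' Segmented soma region of interest
#'
#' @param id Integer id.
#' @param mask Logical matrix, the filled soma mask.
#' @param pixel_size um/px.
#' @param band_width Perimeter-band dilation radius in px.
#' @param infected,activated Optional logical annotations (infection /
#'   immediate-early-gene status); classification is normally supplied by a
#'   per-cell annotation, not inferred.
#' @return A `soma_roi`: filled mask, perimeter band, perimeter length (um,
#'   Crofton estimate), and annotations.
#' @export
soma_roi <- function(id, mask, pixel_size, band_width = 2,
                     infected = NA, activated = NA) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  structure(list(
    id = as.integer(id),
    mask = mask,
    band = perimeter_band(mask, band_width),
    perimeter_length = crofton_perimeter(mask, pixel_size),
    pixel_size = pixel_size,
    infected = infected,
    activated = activated
  ), class = "soma_roi")
}

rasterize_polygon <- function(poly, nx, ny) {
  # even-odd rule over the bounding box; poly is a 2-column (x, y) matrix in px
  if (any(poly[, 1] < 0.5) || any(poly[, 1] > nx + 0.5) ||
      any(poly[, 2] < 0.5) || any(poly[, 2] > ny + 0.5))
    stop("polygon extends outside image bounds")
  ys <- seq_len(ny)
  m <- matrix(FALSE, nx, ny)
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  for (y in ys) {
    j <- c(n, seq_len(n - 1L))
    crosses <- (py < y) != (py[j] < y)
    if (!any(crosses)) next
    xint <- px[crosses] + (y - py[crosses]) / (py[j][crosses] - py[crosses]) *
      (px[j][crosses] - px[crosses])
    xint <- sort(xint)
    for (k in seq(1L, length(xint) - 1L, by = 2L)) {
      lo <- ceiling(xint[k]); hi <- floor(xint[k + 1L])
      if (hi >= lo) m[max(1L, lo):min(nx, hi), y] <- TRUE
    }
  }
  # trace the outline itself so boundary pixels (e.g. horizontal edges at
  # integer rows, missed by the scanline's crossing rule) are included
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    steps <- max(2L, ceiling(2 * max(abs(px[j] - px[k]), abs(py[j] - py[k]))))
    t <- seq(0, 1, length.out = steps)
    ex <- pmin(pmax(round(px[k] + t * (px[j] - px[k])), 1L), nx)
    ey <- pmin(pmax(round(py[k] + t * (py[j] - py[k])), 1L), ny)
    m[cbind(ex, ey)] <- TRUE
  }
  m
}

#' Segment cell somata from a marker channel
#'
#' Automatic path: intensity threshold, morphological opening then closing
#' with a disc structuring element, hole filling, connected components and
#' an area filter. Manual path: caller-supplied polygon outlines are
#' rasterized to filled masks (mirroring hand-drawn ROIs) and the same
#' perimeter measurements are taken.
#'
#' @param img An [image_stack].
#' @param role Channel role carrying the cell marker (default `"cell"`).
#' @param intensity_thresh Threshold in a.u.; pixels `>= intensity_thresh`
#'   are foreground.
#' @param min_area,max_area Soma area bounds in um^2.
#' @param disk_radius Structuring-element radius in um for opening/closing.
#' @param band_width Perimeter-band radius in px (see [perimeter_band]).
#' @param manual_outlines Optional list of 2-column (x, y) vertex matrices;
#'   when given, the automatic path is skipped.
#' @param connectivity Component connectivity (default 8).
#' @return List of [soma_roi] objects (possibly empty).
#' @export
segment_somata <- function(img, role = "cell", intensity_thresh,
                           min_area = 30, max_area = 500,
                           disk_radius = 0.5, band_width = 2,
                           manual_outlines = NULL, connectivity = 8) {
  stopifnot(inherits(img, "image_stack"))
  if (min_area >= max_area) stop("min_area must be < max_area")
  ps <- img$pixel_size
  d <- dim(img)
  if (!is.null(manual_outlines)) {
    masks <- lapply(manual_outlines, rasterize_polygon, nx = d[1], ny = d[2])
  } else {
    ch <- get_channel(img, role)
    mask <- ch >= intensity_thresh
    r_px <- disk_radius / ps
    if (r_px >= 1) {
      brush <- disc_brush(r_px)
      m <- EBImage::Image(mask * 1)
      mask <- ebi_mat(EBImage::closing(EBImage::opening(m, brush), brush)) > 0
    }
    labels <- label_components(mask, connectivity)
    n <- max(labels)
    if (n == 0L) return(list())
    masks <- lapply(seq_len(n), function(i) {
      ebi_mat(EBImage::fillHull(EBImage::Image((labels == i) * 1))) > 0
    })
    areas <- vapply(masks, sum, numeric(1)) * ps^2
    masks <- masks[areas >= min_area & areas <= max_area]
  }
  lapply(seq_along(masks), function(i)
    soma_roi(i, masks[[i]], pixel_size = ps, band_width = band_width))
}

#' @export
print.soma_roi <- function(x, ...) {
  cat(sprintf("soma_roi #%d: %d px, perimeter %.2f um, infected=%s\n",
              x$id, sum(x$mask), x$perimeter_length, as.character(x$infected)))
  invisible(x)
}

#' Detect fluorescent puncta in a synaptic channel
#'
#' Intensity threshold, optional distance-map watershed split of touching
#' blobs (the scriptable equivalent of an adjustable binary watershed),
#' connected components, and a minimum-size filter. Components smaller than
#' `min_particle_area` are discarded; components exactly at the minimum are
#' kept.
#'
#' @param img An [image_stack].
#' @param role Channel role (`"presyn"`, `"postsyn"`, `"probe"`, ...).
#' @param intensity_thresh Threshold in a.u. (foreground is
#'   `>= intensity_thresh`); chosen upstream per experiment and held fixed
#'   across its images (see [calibrate_threshold]).
#' @param min_particle_area Minimum particle area in um^2 (default 0.05).
#' @param watershed_on Split touching blobs by watershed (default FALSE).
#' @param watershed_tolerance Minimum distance-map depth between objects
#'   for a split, in px.
#' @param connectivity Component connectivity when watershed is off.
#' @return List of `punctum` objects: `id`, `role`, `pixels` (linear pixel
#'   indices into the channel matrix), `area` (um^2), `centroid` (x, y px).
#' @export
detect_puncta <- function(img, role, intensity_thresh, min_particle_area = 0.05,
                          watershed_on = FALSE, watershed_tolerance = 1,
                          connectivity = 8) {
  stopifnot(inherits(img, "image_stack"))
  ch <- get_channel(img, role)
  ps <- img$pixel_size
  mask <- ch >= intensity_thresh
  if (watershed_on) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    labels <- ebi_mat(EBImage::watershed(dm, tolerance = watershed_tolerance))
    storage.mode(labels) <- "integer"
  } else {
    labels <- label_components(mask, connectivity)
  }
  n <- max(labels)
  if (n == 0L) return(list())
  idx <- which(labels > 0L)
  by_lab <- split(idx, labels[idx])
  out <- list()
  id <- 0L
  nx <- nrow(ch)
  for (pix in by_lab) {
    area <- length(pix) * ps^2
    if (!ge_tol(area, min_particle_area)) next
    id <- id + 1L
    xs <- ((pix - 1L) %% nx) + 1L
    ys <- ((pix - 1L) %/% nx) + 1L
    out[[id]] <- structure(list(id = id, role = role, pixels = pix,
                                area = area,
                                centroid = c(x = mean(xs), y = mean(ys))),
                           class = "punctum")
  }
  out
}

#' Summarize a list of puncta as a data frame
#' @param puncta List of `punctum` objects from [detect_puncta].
#' @return data.frame with id, role, area and centroid columns.
#' @export
puncta_table <- function(puncta) {
  if (length(puncta) == 0L)
    return(data.frame(id = integer(), role = character(), area_um2 = numeric(),
                      x = numeric(), y = numeric()))
  data.frame(
    id = vapply(puncta, `[[`, integer(1), "id"),
    role = vapply(puncta, `[[`, character(1), "role"),
    area_um2 = vapply(puncta, `[[`, numeric(1), "area"),
    x = vapply(puncta, function(p) p$centroid[["x"]], numeric(1)),
    y = vapply(puncta, function(p) p$centroid[["y"]], numeric(1))
  )
}

#' Overlap area between two pixel sets
#'
#' @param pixels_a,pixels_b Integer vectors of linear pixel indices.
#' @param pixel_size um/px.
#' @return Shared area in um^2.
#' @export
overlap_area <- function(pixels_a, pixels_b, pixel_size) {
  length(intersect(pixels_a, pixels_b)) * pixel_size^2
}

#' Report foreground fraction across a calibration image set
#'
#' Thresholds for synaptic markers are chosen once per experiment from a
#' set of calibration images and then held fixed. This helper reports, for
#' each candidate threshold, the mean fraction of foreground pixels across
#' the set — a reproducible aid for picking that per-experiment value.
#'
#' @param imgs List of [image_stack] objects.
#' @param role Channel role to inspect.
#' @param thresholds Numeric vector of candidate thresholds.
#' @return data.frame with `threshold` and `foreground_fraction`.
#' @export
calibrate_threshold <- function(imgs, role, thresholds) {
  fr <- vapply(thresholds, function(th) {
    mean(vapply(imgs, function(im) mean(get_channel(im, role) >= th), numeric(1)))
  }, numeric(1))
  data.frame(threshold = thresholds, foreground_fraction = fr)
}
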