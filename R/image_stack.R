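#' Calibrated multi-channel image stack
#'
#' Container for a single-plane multi-channel fluorescence image with a
#' physical pixel calibration. Channels are stored as numeric matrices in
#' arbitrary intensity units (a.u.) and addressed by *role* rather than by
#' index: a role names what the channel stains for (e.g. `"cell"` for the
#' PV marker, `"infection"` for mCherry, `"presyn"` for SYT2/VGaT,
#' `"postsyn"` for gephyrin, `"fos"`, `"probe"` for an smFISH probe).
#'
#' Matrices are indexed `[x, y]`: the first dimension is the image x axis,
#' matching [EBImage::Image] conventions so the two interoperate without
#' transposition.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions. Names are the channel roles; each role maps to exactly one
#'   channel.
#' @param pixel_size Pixel size in micrometres per pixel (must be > 0).
#'   The study-style default elsewhere in the package is 1/15.4 um/px,
#'   i.e. 15.4 pixels per micrometre as acquired with a 100x objective at
#'   1.75x digital zoom.
#' @return An object of class `image_stack`.
#' @examples
#' img <- image_stack(list(cell = matrix(0, 64, 64)), pixel_size = 1 / 15.4)
#' dim(img)
#' @export
image_stack <- function(channels, pixel_size) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of matrices")
  nms <- names(channels)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("channel roles must be unique non-empty names")
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop("every channel must be a numeric matrix")
  dims <- vapply(channels, dim, integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1]))
    stop("all channels must share the same dimensions")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/px)")
  structure(
    list(channels = lapply(channels, function(m) {
      storage.mode(m) <- "double"
      m
    }),
    pixel_size = as.numeric(pixel_size)),
    class = "image_stack"
  )
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "image_stack: %d x %d px, %.4f um/px, channels: %s\n",
    d[1], d[2], x$pixel_size, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Extract one channel by role
#'
#' @param img An [image_stack].
#' @param role Channel role name.
#' @return The channel's intensity matrix.
#' @export
get_channel <- function(img, role) {
  stopifnot(inherits(img, "image_stack"))
  if (!role %in% names(img$channels))
    stop(sprintf("channel role '%s' not present (have: %s)", role,
                 paste(names(img$channels), collapse = ", ")))
  img$channels[[role]]
}

#' Area of one pixel in square micrometres
#' @param img An [image_stack].
#' @return Pixel area in um^2.
#' @export
pixel_area <- function(img) {
  stopifnot(inherits(img, "image_stack"))
  img$pixel_size^2
}

#' Write / read an image stack as multi-page TIFF plus sidecar metadata
#'
#' The pixel data go to a 32-bit float multi-page TIFF (one page per
#' channel); channel roles and the pixel calibration go to a YAML sidecar
#' (`<path>.yml`) so a round trip preserves the full object. Arbitrary-unit
#' intensities are stored scaled to [0, 1] with the per-channel scale
#' factor recorded in the sidecar and re-applied on read.
#'
#' @param img An [image_stack].
#' @param path Output TIFF path.
#' @return `write_image_stack`: the path, invisibly. `read_image_stack`:
#'   the reconstructed [image_stack].
#' @export
write_image_stack <- function(img, path) {
  stopifnot(inherits(img, "image_stack"))
  # tiff::writeTIFF stores [0, 1] intensities ([row, col] = [y, x]); a.u.
  # channels are affinely rescaled with the offset and scale recorded in
  # the sidecar so negative values (noise below baseline) survive
  offsets <- vapply(img$channels, function(ch) min(ch, 0), numeric(1))
  scales <- vapply(seq_along(img$channels), function(i)
    max(img$channels[[i]] - offsets[i], 1), numeric(1))
  pages <- Map(function(ch, o, s) t(ch - o) / s, img$channels, offsets, scales)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = img$pixel_size,
               channel_roles = as.list(names(img$channels)),
               channel_offsets = as.list(unname(offsets)),
               channel_scales = as.list(unname(scales)))
  yaml::write_yaml(meta, paste0(path, ".yml"), precision = 15)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  roles <- unlist(meta$channel_roles)
  if (length(pages) != length(roles))
    stop("sidecar lists ", length(roles), " roles but TIFF has ",
         length(pages), " pages")
  scales <- if (is.null(meta$channel_scales)) rep(1, length(roles)) else
    unlist(meta$channel_scales)
  offsets <- if (is.null(meta$channel_offsets)) rep(0, length(roles)) else
    unlist(meta$channel_offsets)
  channels <- Map(function(p, s, o) t(p) * s + o, pages, scales, offsets)
  names(channels) <- roles
  image_stack(channels, pixel_size = meta$pixel_size_um)
}

#' Export a label mask as 16-bit label TIFF
#'
#' @param labels Integer matrix of component labels (0 = background).
#' @param path Output path.
#' @export
write_label_mask <- function(labels, path) {
  stopifnot(is.matrix(labels))
  if (max(labels) > 65535L) stop("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(t(labels) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
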