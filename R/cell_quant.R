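#' Mean FOS intensity per soma ROI
#'
#' Measures the average FOS-channel intensity inside each segmented soma
#' mask, the immediate-early-gene activity readout.
#'
#' @param img An [image_stack] with a `fos` channel.
#' @param somata List of [soma_roi] objects (empty list gives an empty
#'   result).
#' @param group Optional per-soma grouping labels (e.g. infected /
#'   uninfected), recycled.
#' @return data.frame with `cell_id`, `mean_intensity`, `group`.
#' @export
fos_intensity <- function(img, somata, group = NA_character_) {
  stopifnot(inherits(img, "image_stack"))
  ch <- get_channel(img, "fos")
  if (length(somata) == 0L)
    return(data.frame(cell_id = character(), mean_intensity = numeric(),
                      group = character()))
  d <- dim(ch)
  for (s in somata)
    if (!all(dim(s$mask) == d)) stop("ROI ", s$id, " does not match the image")
  data.frame(
    cell_id = paste0("cell", vapply(somata, `[[`, integer(1), "id")),
    mean_intensity = vapply(somata, function(s) mean(ch[s$mask]), numeric(1)),
    group = rep_len(group, length(somata))
  )
}

#' Estimate mRNA particle count in one ROI
#'
#' The smFISH estimator: the thresholded probe-signal area inside the ROI,
#' divided by the area of a single mRNA particle (~0.16 um^2). The
#' estimate is left real-valued — it is an area ratio, and rounding would
#' bias low counts. Background subtraction is assumed to have been applied
#' upstream (see [preprocess]).
#'
#' @param img An [image_stack] with a `probe` channel.
#' @param roi A [soma_roi].
#' @param intensity_thresh Signal threshold in a.u. (foreground `>=`).
#' @param single_particle_area Single-particle area in um^2 (> 0;
#'   default 0.16).
#' @param cell_id,brain_id,marker_status,pair_id Annotations carried into
#'   the record; `pair_id` links neighbouring-cell pairs for paired
#'   comparisons.
#' @return One-row data.frame: `cell_id`, `brain_id`, `pair_id`,
#'   `marker_status`, `signal_area` (um^2), `raw_count`,
#'   `corrected_count` (NA until [intensity_correction]).
#' @export
count_particles <- function(img, roi, intensity_thresh,
                            single_particle_area = 0.16,
                            cell_id = paste0("cell", roi$id),
                            brain_id = NA_character_,
                            marker_status = NA_character_,
                            pair_id = NA_character_) {
  stopifnot(inherits(img, "image_stack"), inherits(roi, "soma_roi"))
  if (single_particle_area <= 0) stop("single_particle_area must be > 0")
  ch <- get_channel(img, "probe")
  if (!all(dim(roi$mask) == dim(ch))) stop("ROI does not match the image")
  signal_area <- sum(ch[roi$mask] >= intensity_thresh) * pixel_area(img)
  data.frame(cell_id = cell_id, brain_id = brain_id, pair_id = pair_id,
             marker_status = marker_status, signal_area = signal_area,
             raw_count = signal_area / single_particle_area,
             corrected_count = NA_real_)
}

#' Mean image intensity excluding all segmented cell ROIs
#'
#' @param img An [image_stack].
#' @param somata List of [soma_roi] objects to exclude.
#' @param role Channel role to measure (default `"probe"`).
#' @return Mean off-ROI intensity in a.u.
#' @export
roi_excluded_mean <- function(img, somata, role = "probe") {
  ch <- get_channel(img, role)
  excl <- matrix(FALSE, nrow(ch), ncol(ch))
  for (s in somata) excl <- excl | s$mask
  mean(ch[!excl])
}

#' Per-brain intensity normalization
#'
#' Staining intensity varies between brains; the correction measures the
#' off-ROI mean probe intensity of every image, averages it per brain, and
#' normalizes the per-brain means to the lowest brain to obtain intensity
#' ratios (the dimmest brain has ratio exactly 1).
#'
#' @param image_means Per-image off-ROI mean intensities (from
#'   [roi_excluded_mean]).
#' @param brain_ids Brain assignment of each image (same length).
#' @return data.frame with `brain_id`, `brain_mean`, `intensity_ratio`.
#' @export
brain_normalization <- function(image_means, brain_ids) {
  if (length(image_means) != length(brain_ids))
    stop("image_means and brain_ids must have the same length")
  if (length(image_means) == 0L) stop("at least one brain is required")
  brain_ids <- as.character(brain_ids)
  if (is.factor(brain_ids)) brain_ids <- droplevels(brain_ids)
  bm <- tapply(image_means, brain_ids, mean)
  if (anyNA(bm)) stop("a brain has zero images")
  data.frame(brain_id = names(bm), brain_mean = as.numeric(bm),
             intensity_ratio = as.numeric(bm) / min(bm),
             row.names = NULL)
}

#' Apply the per-brain intensity correction to particle records
#'
#' Divides each record's raw particle count by its brain's intensity
#' ratio. Since ratios are >= 1, corrected counts never exceed raw counts.
#'
#' @param records data.frame of records from [count_particles], with
#'   `brain_id` filled in.
#' @param normalization data.frame from [brain_normalization].
#' @return `records` with `corrected_count` populated.
#' @export
intensity_correction <- function(records, normalization) {
  if (!all(c("brain_id", "raw_count") %in% names(records)))
    stop("records must carry brain_id and raw_count")
  i <- match(records$brain_id, normalization$brain_id)
  if (anyNA(i))
    stop("records reference brains absent from the normalization: ",
         paste(unique(records$brain_id[is.na(i)]), collapse = ", "))
  records$corrected_count <- records$raw_count / normalization$intensity_ratio[i]
  records
}
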