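#' Classify puncta as presynaptic boutons or postsynaptic clusters
#'
#' Applies the rule-based definitions against one soma ROI:
#' a presynaptic punctum is a *bouton* iff its centroid lies outside the
#' filled soma mask and its mask shares at least 0.1 um^2 with the soma
#' perimeter band; a postsynaptic punctum is a *cluster* iff its centroid
#' lies inside the filled mask and the perimeter overlap is at least
#' 0.2 um^2. All other puncta are discarded.
#'
#' @param puncta List of `punctum` objects with roles `"presyn"` or
#'   `"postsyn"` (any other role is an error).
#' @param soma A [soma_roi].
#' @param bouton_min_overlap,cluster_min_overlap Perimeter-overlap floors
#'   in um^2 (defaults 0.1 and 0.2).
#' @return List with `boutons` and `clusters` (lists of puncta, each
#'   annotated with its perimeter overlap in `$band_overlap`).
#' @export
classify_puncta <- function(puncta, soma, bouton_min_overlap = 0.1,
                            cluster_min_overlap = 0.2) {
  stopifnot(inherits(soma, "soma_roi"))
  ps <- soma$pixel_size
  nx <- nrow(soma$mask)
  band_idx <- which(soma$band)
  boutons <- clusters <- list()
  for (p in puncta) {
    if (!p$role %in% c("presyn", "postsyn"))
      stop("punctum ", p$id, " has role '", p$role,
           "'; expected 'presyn' or 'postsyn'")
    cx <- round(p$centroid[["x"]]); cy <- round(p$centroid[["y"]])
    inside <- soma$mask[cx, cy]
    ov <- length(intersect(p$pixels, band_idx)) * ps^2
    p$band_overlap <- ov
    if (p$role == "presyn" && !inside && ge_tol(ov, bouton_min_overlap))
      boutons[[length(boutons) + 1L]] <- p
    else if (p$role == "postsyn" && inside && ge_tol(ov, cluster_min_overlap))
      clusters[[length(clusters) + 1L]] <- p
  }
  list(boutons = boutons, clusters = clusters)
}

#' Pair boutons with clusters into synapses
#'
#' A synapse is a bouton and a cluster whose masks share at least
#' `min_coloc` (default 0.03 um^2). In the default one-to-one mode,
#' candidate pairs are matched greedily by descending colocalization area
#' (ties broken by lowest bouton id, then lowest cluster id) so that no
#' bouton or cluster is counted twice; `mode = "many"` emits every
#' candidate pair.
#'
#' @param boutons,clusters Classified puncta lists from [classify_puncta],
#'   against the same soma.
#' @param pixel_size um/px.
#' @param min_coloc Colocalization floor in um^2.
#' @param mode `"one_to_one"` (default) or `"many"`.
#' @return data.frame with `bouton_id`, `cluster_id`, `coloc_area` (um^2).
#' @export
pair_synapses <- function(boutons, clusters, pixel_size, min_coloc = 0.03,
                          mode = c("one_to_one", "many")) {
  mode <- match.arg(mode)
  empty <- data.frame(bouton_id = integer(), cluster_id = integer(),
                      coloc_area = numeric())
  if (length(boutons) == 0L || length(clusters) == 0L) return(empty)
  cand <- list()
  for (b in boutons) for (cl in clusters) {
    a <- overlap_area(b$pixels, cl$pixels, pixel_size)
    if (ge_tol(a, min_coloc))
      cand[[length(cand) + 1L]] <- data.frame(bouton_id = b$id,
                                              cluster_id = cl$id,
                                              coloc_area = a)
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$coloc_area, cand$bouton_id, cand$cluster_id), ]
  if (mode == "many") {
    rownames(cand) <- NULL
    return(cand)
  }
  used_b <- used_c <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$bouton_id[i] %in% used_b || cand$cluster_id[i] %in% used_c) next
    keep[i] <- TRUE
    used_b <- c(used_b, cand$bouton_id[i])
    used_c <- c(used_c, cand$cluster_id[i])
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Per-cell synapse density record
#'
#' @param cell_id Cell identifier.
#' @param group Grouping label (e.g. `"infected"` / `"uninfected"`).
#' @param n_boutons,n_clusters Classified punctum counts.
#' @param pairs data.frame of synapses from [pair_synapses].
#' @param perimeter_length Soma perimeter in um (> 0).
#' @param animal_id Optional animal identifier for per-animal aggregation.
#' @return One-row data.frame; `density` is synapses per um of perimeter.
#' @export
density_record <- function(cell_id, group, n_boutons, n_clusters, pairs,
                           perimeter_length, animal_id = NA_character_) {
  if (perimeter_length <= 0) stop("perimeter_length must be > 0")
  n <- nrow(pairs)
  data.frame(cell_id = cell_id, animal_id = animal_id, group = group,
             n_boutons = n_boutons, n_clusters = n_clusters,
             n_synapses = n, perimeter_length = perimeter_length,
             density = n / perimeter_length)
}

#' Density change between infected and internal-control cells
#'
#' The headline comparison statistic:
#' \deqn{\mathrm{Density\ change} =
#'   \left(\frac{\mathrm{density}_{infected}}
#'        {\mathrm{density}_{uninfected}} - 1\right) \times 100}
#' Group densities are, by default, the mean over animals of per-animal
#' mean cell densities (the experimental unit is the animal); `level =
#' "cell"` averages cells directly.
#'
#' @param infected,uninfected Density-record data.frames (rows from
#'   [density_record] or [make_density_population]).
#' @param level `"animal"` (default; requires `animal_id`) or `"cell"`.
#' @return Density change in percent.
#' @export
density_change <- function(infected, uninfected, level = c("animal", "cell")) {
  level <- match.arg(level)
  if (nrow(infected) == 0L || nrow(uninfected) == 0L)
    stop("both groups must be non-empty")
  gmean <- function(df) {
    if (level == "animal" && !all(is.na(df$animal_id)))
      mean(tapply(df$density, df$animal_id, mean))
    else mean(df$density)
  }
  m_u <- gmean(uninfected)
  if (m_u == 0) stop("uninfected mean density is zero; ratio undefined")
  (gmean(infected) / m_u - 1) * 100
}

#' Quantify perisomatic synapses in one image
#'
#' End-to-end per-image pipeline: segment somata from the cell-marker
#' channel, detect presynaptic and postsynaptic puncta, classify them
#' against each soma, pair them into synapses and emit one density record
#' per soma. Infection status comes from `infected` (a per-soma annotation
#' vector) or, if absent, from [classify_infection].
#'
#' @param img An [image_stack] with `cell`, `presyn` and `postsyn`
#'   channels.
#' @param soma_thresh,puncta_thresh Intensity thresholds (a.u.); defaults
#'   are the [nominal_thresholds] of the synthetic renderer.
#' @param min_particle_area Minimum punctum area in um^2 (default 0.05).
#' @param band_width Perimeter band radius in px.
#' @param min_soma_area,max_soma_area Soma size filter in um^2.
#' @param watershed_on Split touching puncta by watershed.
#' @param pairing `"one_to_one"` or `"many"` (see [pair_synapses]).
#' @param infected Optional logical per-soma annotation, in soma id order.
#' @param cell_id_prefix Prefix for generated cell ids.
#' @param animal_id Animal identifier attached to every record.
#' @return List with `records` (data.frame of per-cell density records),
#'   `somata`, `pairs` (per-soma list of pair tables), `boutons`,
#'   `clusters`.
#' @export
quantify_synapses <- function(img,
                              soma_thresh = nominal_thresholds()$soma,
                              puncta_thresh = nominal_thresholds()$puncta,
                              min_particle_area = 0.05, band_width = 2,
                              min_soma_area = 30, max_soma_area = 800,
                              watershed_on = FALSE,
                              pairing = "one_to_one", infected = NULL,
                              cell_id_prefix = "cell",
                              animal_id = NA_character_) {
  somata <- segment_somata(img, "cell", intensity_thresh = soma_thresh,
                           min_area = min_soma_area, max_area = max_soma_area,
                           band_width = band_width)
  pre <- detect_puncta(img, "presyn", puncta_thresh, min_particle_area,
                       watershed_on = watershed_on)
  post <- detect_puncta(img, "postsyn", puncta_thresh, min_particle_area,
                        watershed_on = watershed_on)
  if (is.null(infected) && "infection" %in% names(img$channels))
    infected <- classify_infection(img, somata)
  recs <- list(); pair_list <- list(); bl <- list(); cl <- list()
  for (i in seq_along(somata)) {
    s <- somata[[i]]
    cls <- classify_puncta(c(pre, post), s)
    pairs <- pair_synapses(cls$boutons, cls$clusters, img$pixel_size,
                           mode = pairing)
    recs[[i]] <- density_record(
      cell_id = paste0(cell_id_prefix, i),
      group = if (!is.null(infected) && isTRUE(infected[i])) "infected"
              else "uninfected",
      n_boutons = length(cls$boutons), n_clusters = length(cls$clusters),
      pairs = pairs, perimeter_length = s$perimeter_length,
      animal_id = animal_id)
    pair_list[[i]] <- pairs
    bl[[i]] <- cls$boutons; cl[[i]] <- cls$clusters
  }
  list(records = if (length(recs)) do.call(rbind, recs) else
         density_record(character(0), character(0), integer(0), integer(0),
                        data.frame(), 1)[0, ],
       somata = somata, pairs = pair_list, boutons = bl, clusters = cl)
}

#' Optional mCherry-intensity infection classifier
#'
#' Infection status is normally a manual per-cell annotation; this helper
#' offers a reproducible automatic stand-in that calls a soma infected when
#' the mean infection-channel intensity inside its mask exceeds
#' `threshold`.
#'
#' @param img An [image_stack] with an `infection` channel.
#' @param somata List of [soma_roi] objects.
#' @param threshold Mean-intensity cutoff (a.u.).
#' @return Logical vector, one element per soma.
#' @export
classify_infection <- function(img, somata, threshold = 90) {
  ch <- get_channel(img, "infection")
  vapply(somata, function(s) mean(ch[s$mask]) > threshold, logical(1))
}
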