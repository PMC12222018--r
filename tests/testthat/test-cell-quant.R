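ps10 <- 0.1  # px area 0.01 um^2 for exact-arithmetic constructions

square_roi <- function(x0, y0, w, n = 64, id = 1, pixel_size = ps10) {
  m <- matrix(FALSE, n, n)
  m[x0:(x0 + w - 1), y0:(y0 + w - 1)] <- TRUE
  soma_roi(id, m, pixel_size = pixel_size)
}

test_that("FOS intensity over a constant region is that constant", {
  fos <- matrix(20, 64, 64)
  fos[10:30, 10:30] <- 100
  img <- image_stack(list(fos = fos), ps10)
  roi <- square_roi(10, 10, 21)
  out <- fos_intensity(img, list(roi))
  expect_equal(out$mean_intensity, 100)
})

test_that("an empty ROI list yields an empty FOS table; mismatched ROI errors", {
  img <- image_stack(list(fos = matrix(0, 64, 64)), ps10)
  expect_equal(nrow(fos_intensity(img, list())), 0)
  bad <- square_roi(2, 2, 4, n = 32)
  expect_error(fos_intensity(img, list(bad)), "match")
})

test_that("planted per-cell FOS intensities are recovered under noise", {
  tr <- image_truth(n_somata = 2, pixel_size = 1 / 0.88, soma_radius_um = 8,
                    n_pairs_per_soma = 0, n_unpaired_boutons = 0,
                    n_unpaired_clusters = 0, n_distractors = 0,
                    fos_intensity = c(120, 60), infected = c(TRUE, FALSE),
                    seed = 21)
  sim <- make_fos_image(tr, noise_sd = 5)
  somata <- segment_somata(sim$image, "cell", intensity_thresh = 90,
                           min_area = 50, max_area = 800)
  expect_length(somata, 2)
  out <- fos_intensity(sim$image, somata)
  # match recovered ROIs to planted cells by centroid x
  ord <- order(vapply(somata, function(s)
    mean(((which(s$mask) - 1) %% nrow(s$mask)) + 1), numeric(1)))
  planted_ord <- order(tr$soma_centers$x)
  npix <- vapply(somata, function(s) sum(s$mask), numeric(1))
  for (k in 1:2) {
    se <- 5 / sqrt(npix[ord[k]])
    expect_lt(abs(out$mean_intensity[ord[k]] -
                  tr$planted_fos_intensity[planted_ord[k]]), 5 * se + 0.01)
  }
})

test_that("raw particle count is signal area over single-particle area", {
  probe <- matrix(0, 64, 64)
  probe[11:26, 11:20] <- 200          # 160 px * 0.01 = 1.6 um^2
  img <- image_stack(list(probe = probe), ps10)
  roi <- square_roi(5, 5, 40)
  rec <- count_particles(img, roi, intensity_thresh = 50)
  expect_equal(rec$signal_area, 1.6)
  expect_equal(rec$raw_count, 10)     # 1.6 / 0.16
  # zero signal
  rec0 <- count_particles(image_stack(list(probe = matrix(0, 64, 64)), ps10),
                          roi, intensity_thresh = 50)
  expect_equal(rec0$raw_count, 0)
  expect_error(count_particles(img, roi, 50, single_particle_area = 0),
               "single_particle_area")
})

test_that("signal outside the ROI does not contribute to the count", {
  probe <- matrix(0, 64, 64)
  probe[11:26, 11:20] <- 200
  probe[50:60, 50:60] <- 200  # outside
  img <- image_stack(list(probe = probe), ps10)
  rec <- count_particles(img, square_roi(5, 5, 40), intensity_thresh = 50)
  expect_equal(rec$raw_count, 10)
})

test_that("planted particle counts are recovered within one particle", {
  tr <- image_truth(n_somata = 2, width = 360, height = 360,
                    pixel_size = 1 / 5.544, soma_radius_um = 8,
                    n_pairs_per_soma = 0, n_unpaired_boutons = 0,
                    n_unpaired_clusters = 0, n_distractors = 0,
                    particle_count = c(12, 25), seed = 31)
  sim <- make_fish_image(tr)
  somata <- segment_somata(sim$image, "cell", intensity_thresh = 90,
                           min_area = 50, max_area = 800)
  expect_length(somata, 2)
  counts <- vapply(somata, function(s)
    count_particles(sim$image, s, intensity_thresh = 50)$raw_count, numeric(1))
  expect_equal(sort(round(counts)), c(12, 25))
  expect_true(all(abs(sort(counts) - c(12, 25)) <= 1))
})

test_that("intensity ratios normalize per-brain means to the dimmest brain", {
  norm <- brain_normalization(c(210, 190, 95, 105), c("b1", "b1", "b2", "b2"))
  expect_equal(norm$intensity_ratio[norm$brain_id == "b2"], 1)
  expect_equal(norm$intensity_ratio[norm$brain_id == "b1"], 2)
  recs <- data.frame(cell_id = "c1", brain_id = "b1", raw_count = 8,
                     corrected_count = NA_real_)
  out <- intensity_correction(recs, norm)
  expect_equal(out$corrected_count, 4)
  # single brain: ratio 1, corrected == raw
  n1 <- brain_normalization(c(100, 120), c("b", "b"))
  expect_equal(n1$intensity_ratio, 1)
  expect_error(brain_normalization(numeric(0), character(0)), "at least one")
  expect_error(intensity_correction(
    data.frame(brain_id = "nope", raw_count = 1), norm), "absent")
})

test_that("correction is invariant to brain relabeling and global gain", {
  means <- c(100, 150, 200)
  brains <- c("a", "b", "c")
  recs <- data.frame(cell_id = paste0("c", 1:3), brain_id = brains,
                     raw_count = c(10, 15, 20))
  base <- intensity_correction(recs, brain_normalization(means, brains))
  # common multiplicative factor leaves ratios and corrections unchanged
  scaled <- intensity_correction(recs, brain_normalization(means * 7, brains))
  expect_equal(base$corrected_count, scaled$corrected_count)
  # relabeling brains permutes rows but not values
  perm <- c("c", "a", "b")
  recs2 <- recs; recs2$brain_id <- perm[match(recs$brain_id, brains)]
  out2 <- intensity_correction(recs2, brain_normalization(means, perm))
  expect_equal(out2$corrected_count, base$corrected_count)
  # ratios >= 1 so corrected never exceeds raw
  expect_true(all(base$corrected_count <= base$raw_count))
})

test_that("a brain-level staining gain is undone by the correction", {
  count_brain <- function(gain, seed) {
    tr <- image_truth(n_somata = 2, width = 360, height = 360,
                      pixel_size = 1 / 5.544, soma_radius_um = 8,
                      n_pairs_per_soma = 0, n_unpaired_boutons = 0,
                      n_unpaired_clusters = 0, n_distractors = 0,
                      particle_count = c(12, 25), seed = seed)
    sim <- make_fish_image(tr, gain = gain)
    somata <- segment_somata(sim$image, "cell", intensity_thresh = 90,
                             min_area = 50, max_area = 800)
    recs <- do.call(rbind, lapply(somata, function(s)
      count_particles(sim$image, s, intensity_thresh = 50,
                      brain_id = paste0("g", gain))))
    list(recs = recs, mean = roi_excluded_mean(sim$image, somata))
  }
  b1 <- count_brain(1, 31)
  b2 <- count_brain(1.6, 31)
  norm <- brain_normalization(c(b1$mean, b2$mean), c("g1", "g1.6"))
  expect_equal(norm$intensity_ratio, c(1, 1.6), tolerance = 0.02)
  all_recs <- intensity_correction(rbind(b1$recs, b2$recs), norm)
  gained <- all_recs$corrected_count[all_recs$brain_id == "g1.6"]
  ungained <- all_recs$corrected_count[all_recs$brain_id == "g1"]
  expect_true(all(abs(sort(gained) - sort(ungained)) <= 1))
  expect_true(all(abs(sort(gained) - c(12, 25)) <= 1.5))
})

test_that("pair ids survive the correction for paired comparisons", {
  recs <- data.frame(cell_id = c("c1", "c2"), brain_id = "b",
                     pair_id = c("p1", "p1"),
                     marker_status = c("mCherry+", "mCherry-"),
                     raw_count = c(30, 22))
  out <- intensity_correction(recs, brain_normalization(100, "b"))
  expect_equal(out$pair_id, c("p1", "p1"))
  expect_equal(out$marker_status, recs$marker_status)
})
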