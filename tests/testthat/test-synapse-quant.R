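# geometry used for exact-overlap constructions: pixel area 0.001 um^2,
# rectangular soma x:30..70, y:30..70 in a 100x100 field
ps_exact <- sqrt(0.001)

rect_soma <- function(band_width = 2) {
  m <- matrix(FALSE, 100, 100)
  m[30:70, 30:70] <- TRUE
  soma_roi(1, m, pixel_size = ps_exact, band_width = band_width)
}

test_that("bouton rule: outside centroid plus >= 0.1 um^2 perimeter overlap", {
  soma <- rect_soma()
  in_band <- block_pixels(28, 40, 5, 20, 100)    # 100 px inside the band
  outside <- block_pixels(20, 40, 8, 20, 100)    # 160 px, clear of mask/band
  expect_true(all(soma$band[in_band]))
  expect_true(!any(soma$mask[outside] | soma$band[outside]))

  p_at <- make_punctum(1, "presyn", c(outside, in_band), 100, ps_exact)
  got <- classify_puncta(list(p_at), soma)
  expect_length(got$boutons, 1)                       # overlap exactly 0.100
  expect_equal(got$boutons[[1]]$band_overlap, 0.1)

  p_below <- make_punctum(2, "presyn", c(outside, in_band[-100]), 100, ps_exact)
  expect_length(classify_puncta(list(p_below), soma)$boutons, 0)  # 0.099
})

test_that("cluster rule: inside centroid plus >= 0.2 um^2 perimeter overlap", {
  soma <- rect_soma()
  in_band <- block_pixels(28, 31, 5, 40, 100)    # 200 px in band
  interior <- block_pixels(40, 36, 8, 30, 100)   # 240 px interior, not band
  expect_true(all(soma$band[in_band]))
  expect_true(all(soma$mask[interior]) && !any(soma$band[interior]))

  p_at <- make_punctum(1, "postsyn", c(interior, in_band), 100, ps_exact)
  got <- classify_puncta(list(p_at), soma)
  expect_length(got$clusters, 1)
  expect_equal(got$clusters[[1]]$band_overlap, 0.2)

  p_below <- make_punctum(2, "postsyn", c(interior, in_band[-200]), 100, ps_exact)
  expect_length(classify_puncta(list(p_below), soma)$clusters, 0)  # 0.199
})

test_that("presyn puncta inside the soma are discarded regardless of overlap", {
  soma <- rect_soma()
  in_band <- block_pixels(28, 40, 5, 20, 100)
  interior <- block_pixels(45, 40, 10, 20, 100)
  p <- make_punctum(1, "presyn", c(in_band, interior), 100, ps_exact)
  got <- classify_puncta(list(p), soma)
  expect_length(got$boutons, 0)
  expect_length(got$clusters, 0)
})

test_that("puncta with an unknown channel role are an error", {
  soma <- rect_soma()
  p <- make_punctum(1, "probe", block_pixels(28, 40, 5, 4, 100), 100, ps_exact)
  expect_error(classify_puncta(list(p), soma), "role")
})

test_that("pairing emits pairs at >= 0.03 um^2 and drops weaker contacts", {
  b <- make_punctum(1, "presyn", block_pixels(10, 10, 40, 2, 100), 100, ps_exact)
  overlap30 <- block_pixels(10, 10, 30, 1, 100)    # 30 px = 0.03 um^2
  c_ok <- make_punctum(1, "postsyn", c(overlap30, block_pixels(10, 14, 40, 2, 100)),
                       100, ps_exact)
  got <- pair_synapses(list(b), list(c_ok), ps_exact)
  expect_equal(nrow(got), 1)
  expect_equal(got$coloc_area, 0.03)

  c_weak <- make_punctum(2, "postsyn", c(overlap30[-1], block_pixels(10, 14, 40, 2, 100)),
                         100, ps_exact)
  expect_equal(nrow(pair_synapses(list(b), list(c_weak), ps_exact)), 0)  # 0.029
})

test_that("a bouton contacting two clusters pairs with the larger overlap only", {
  b <- make_punctum(1, "presyn", block_pixels(10, 10, 80, 2, 100), 100, ps_exact)
  c1 <- make_punctum(1, "postsyn", c(block_pixels(10, 10, 60, 1, 100),
                                     block_pixels(10, 16, 30, 2, 100)), 100, ps_exact)
  c2 <- make_punctum(2, "postsyn", c(block_pixels(30, 11, 40, 1, 100),
                                     block_pixels(10, 20, 30, 2, 100)), 100, ps_exact)
  got <- pair_synapses(list(b), list(c1, c2), ps_exact)   # 0.06 vs 0.04
  expect_equal(nrow(got), 1)
  expect_equal(got$cluster_id, 1)
  expect_equal(got$coloc_area, 0.06)
  # many-to-many mode keeps both contacts
  expect_equal(nrow(pair_synapses(list(b), list(c1, c2), ps_exact,
                                  mode = "many")), 2)
})

test_that("greedy 1:1 pairing is order-invariant, unique and maximal", {
  set.seed(77)
  for (rep in 1:10) {
    boutons <- lapply(1:4, function(i)
      make_punctum(i, "presyn",
                   block_pixels(sample(5:80, 1), sample(5:80, 1), 8, 3, 100),
                   100, ps_exact))
    clusters <- lapply(1:4, function(i)
      make_punctum(i, "postsyn",
                   block_pixels(sample(5:80, 1), sample(5:80, 1), 8, 3, 100),
                   100, ps_exact))
    got <- pair_synapses(boutons, clusters, ps_exact)
    shuffled <- pair_synapses(boutons[c(3, 1, 4, 2)], clusters[c(2, 4, 1, 3)],
                              ps_exact)
    expect_equal(got[order(got$bouton_id), ],
                 shuffled[order(shuffled$bouton_id), ], ignore_attr = TRUE)
    expect_false(any(duplicated(got$bouton_id)))
    expect_false(any(duplicated(got$cluster_id)))
    # maximality: no unmatched bouton-cluster contact >= 0.03 remains
    for (b in boutons) for (cl in clusters) {
      if (b$id %in% got$bouton_id || cl$id %in% got$cluster_id) next
      expect_lt(overlap_area(b$pixels, cl$pixels, ps_exact), 0.03)
    }
    # overlap values equal the brute-force pixel oracle
    for (k in seq_len(nrow(got))) {
      bp <- boutons[[got$bouton_id[k]]]$pixels
      cp <- clusters[[got$cluster_id[k]]]$pixels
      expect_identical(got$coloc_area[k], oracle_overlap(bp, cp, ps_exact))
    }
  }
})

test_that("ties in overlap break deterministically toward the lowest id", {
  shared <- block_pixels(40, 40, 40, 1, 100)  # 0.04 um^2
  b1 <- make_punctum(1, "presyn", c(shared, block_pixels(30, 50, 10, 2, 100)),
                     100, ps_exact)
  b2 <- make_punctum(2, "presyn", c(shared, block_pixels(30, 60, 10, 2, 100)),
                     100, ps_exact)
  cl <- make_punctum(1, "postsyn", c(shared, block_pixels(60, 40, 10, 2, 100)),
                     100, ps_exact)
  got <- pair_synapses(list(b1, b2), list(cl), ps_exact)
  expect_equal(got$bouton_id, 1)
})

test_that("density is the pair count per micrometre of perimeter", {
  pairs10 <- data.frame(bouton_id = 1:10, cluster_id = 1:10,
                        coloc_area = rep(0.05, 10))
  rec <- density_record("c1", "infected", 12, 11, pairs10,
                        perimeter_length = 50)
  expect_equal(rec$density, 0.2)
  rec0 <- density_record("c2", "infected", 0, 0, pairs10[0, ],
                         perimeter_length = 50)
  expect_equal(rec0$density, 0)
  expect_error(density_record("c3", "x", 0, 0, pairs10, 0), "perimeter")
})

test_that("density change follows the ratio formula", {
  inf <- data.frame(cell_id = "a", animal_id = NA, density = 0.10)
  uni <- data.frame(cell_id = "b", animal_id = NA, density = 0.08)
  expect_equal(density_change(inf, uni, level = "cell"), 25)
  expect_equal(density_change(inf, inf, level = "cell"), 0)
  expect_error(density_change(inf[0, ], uni), "non-empty")
  zero <- data.frame(cell_id = "z", animal_id = NA, density = 0)
  expect_error(density_change(inf, zero, level = "cell"), "zero")
})

test_that("density change of any population against itself is zero", {
  pop <- make_density_population(n_cells = 25, seed = 9)
  expect_equal(density_change(pop$infected, pop$infected), 0)
  expect_equal(density_change(pop$uninfected, pop$uninfected, level = "cell"), 0)
})

test_that("per-animal and per-cell aggregation levels both recover ~+30%", {
  ests_animal <- ests_cell <- numeric(25)
  for (s in 1:25) {
    pop <- make_density_population(n_cells = 30, density_ratio = 1.30,
                                   seed = 100 + s)
    ests_animal[s] <- density_change(pop$infected, pop$uninfected)
    ests_cell[s] <- density_change(pop$infected, pop$uninfected, level = "cell")
  }
  expect_lt(abs(mean(ests_animal) - 30), 8)
  expect_lt(abs(mean(ests_cell) - 30), 8)
})

test_that("noise-free synthetic fields are recovered exactly, end to end", {
  tr <- image_truth(n_somata = 2, n_pairs_per_soma = 3,
                    n_unpaired_boutons = 2, n_unpaired_clusters = 2,
                    n_distractors = 4, infected = c(TRUE, FALSE), seed = 55)
  sim <- make_synapse_image(tr, noise_sd = 0)
  q <- quantify_synapses(sim$image)
  expect_equal(nrow(q$records), 2)
  expect_equal(sum(q$records$n_synapses), nrow(tr$planted_pairs))
  per_soma <- table(factor(tr$planted_pairs$soma, levels = 1:2))
  expect_equal(sort(q$records$n_synapses), sort(as.integer(per_soma)))
  expect_setequal(q$records$group, c("infected", "uninfected"))
})

test_that("recall and precision stay >= 0.95 at the documented noise level", {
  # noise_sd 8 against spot amplitude 200 and threshold 50 is the
  # documented operating point for exact-threshold detection
  tr <- image_truth(n_somata = 2, n_pairs_per_soma = 3,
                    n_unpaired_boutons = 2, n_unpaired_clusters = 2,
                    n_distractors = 4, seed = 77)
  sim <- make_synapse_image(tr, noise_sd = 8)
  q <- quantify_synapses(sim$image)
  planted <- nrow(tr$planted_pairs)
  detected <- sum(q$records$n_synapses)
  # with one detected set per soma and planted pairings unique, matched
  # pairs are bounded by min(planted, detected)
  expect_gte(min(detected, planted) / planted, 0.95)        # recall
  expect_gte(min(detected, planted) / max(detected, 1), 0.95)  # precision
})
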