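test_that("local contrast normalization maps constant regions to mid-gray and keeps maxima", {
  expect_true(all(normalize_local_contrast(matrix(0.7, 40, 40), 15) == 0.5))

  img <- matrix(0.2, 64, 64)
  img[30:34, 40:44] <- 0.9
  out <- normalize_local_contrast(img, 21)
  expect_equal(which(out == max(out), arr.ind = TRUE)[1, ] >= c(30, 40),
               c(row = TRUE, col = TRUE))
  expect_true(max(out) > 0.5)

  # oversized block falls back to global normalization with a message
  expect_message(normalize_local_contrast(matrix(runif(100), 10, 10), 99),
                 "global")
})

test_that("normalization is approximately idempotent on noise", {
  img <- withr::with_seed(4, matrix(runif(128 * 128), 128, 128))
  once <- normalize_local_contrast(img)
  twice <- normalize_local_contrast(once)
  expect_lt(mean(abs(twice - once)), 0.01)
})

test_that("detection finds isolated synthetic beads accurately", {
  expect_equal(nrow(detect_beads(matrix(0, 50, 50))), 0L)

  # one rendered bead, apparent diameter 10 px, no noise
  img <- matrix(0, 120, 120)
  img <- magsort:::draw_disk(img, cx = 60, cy = 45, diameter = 10,
                             intensity = 0.9)
  det <- detect_beads(img, block_size = 31)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 60), 1)
  expect_lt(abs(det$y - 45), 1)
  expect_lt(abs(det$diameter - 10) / 10, 0.15)

  # two beads 50 px apart are two components
  img2 <- magsort:::draw_disk(img, cx = 60, cy = 95, diameter = 10,
                              intensity = 0.9)
  expect_equal(nrow(detect_beads(img2, block_size = 31)), 2L)
})

test_that("detection is equivariant under integer translation", {
  img <- matrix(0, 100, 100)
  img <- magsort:::draw_disk(img, 40, 50, 9, 0.8)
  d0 <- detect_beads(img, block_size = 31)
  sh <- matrix(0, 100, 100)
  sh[11:100, 4:100] <- img[1:90, 1:97]   # shift by (dx = 3, dy = 10)
  d1 <- detect_beads(sh, block_size = 31)
  expect_equal(d1$x, d0$x + 3, tolerance = 1e-6)
  expect_equal(d1$y, d0$y + 10, tolerance = 1e-6)
})

test_that("detection recall on noise-free simulator output is complete", {
  cfg <- sim_config(n_sections = 4, field_size = c(50, 50), noise_sd = 0,
                    n_channels = 1, pose_rotation_max = 0,
                    pose_translation_max = 0, seed = 21)
  sl <- slice_volume(generate_bead_volume(cfg), cfg)
  rs <- suppressMessages(render_sections(sl))
  ideal <- pose_bead_sets(sl)
  for (sid in unique(ideal$section_id)) {
    truth <- ideal[ideal$section_id == sid, ]
    # restrict to isolated beads away from the border
    w <- cfg$field_size[1] / cfg$pixel_size
    ok <- truth$x > 10 & truth$x < w - 10 & truth$y > 10 & truth$y < w - 10
    # isolated = farther from every neighbour than the sum of radii plus a
    # margin; large enough to clear the detector's min_area
    dd <- as.matrix(dist(cbind(truth$x, truth$y)))
    diag(dd) <- Inf
    rsum <- outer(truth$diameter, truth$diameter, `+`) / 2
    ok <- ok & apply(dd - rsum, 1, min) > 6 & truth$diameter > 3.5
    truth <- truth[ok, ]
    if (nrow(truth) == 0) next
    # zero-noise imagery: a permissive threshold and a normalization block
    # matched to the spot scale (so a bright bead cannot inflate the local
    # SD under a dim one) keep every isolated bead above background
    det <- detect_beads(rs$images[[sprintf("s%03d_c1", sid)]],
                        threshold = 0.65, block_size = 21)
    nn <- vapply(seq_len(nrow(truth)), function(i) {
      min(sqrt((det$x - truth$x[i])^2 + (det$y - truth$y[i])^2))
    }, 0)
    expect_true(all(nn < 1))   # every isolated bead recovered within 1 px
  }
})

test_that("channel merging unions, collapses and commutes", {
  a <- tibble::tibble(section_id = 1L, x = c(10, 40, 70), y = c(10, 40, 70),
                      diameter = c(8, 9, 10), channel = 1L)
  b <- tibble::tibble(section_id = 1L, x = c(10.5, 90), y = c(10.2, 90),
                      diameter = c(8.4, 7), channel = 2L)

  # disjoint: pure union
  far_b <- dplyr::mutate(b, x = x + 500)
  expect_equal(nrow(merge_channels(a, far_b, radius = 4)), 5L)

  # exact copy: total collapse
  self <- merge_channels(a, dplyr::mutate(a, channel = 2L), radius = 4)
  expect_equal(nrow(self), 3L)
  expect_equal(sort(self$diameter), sort(a$diameter))

  # exactly one cross pair within radius: 3 + 2 - 1 = 4 (verified by
  # brute-force pair enumeration)
  within <- sum(outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2 < 4^2)
  expect_equal(within, 1L)
  ab <- merge_channels(a, b, radius = 4)
  expect_equal(nrow(ab), 4L)
  expect_true(all(ab$channel == "merged"))

  # commutative up to row order
  ba <- merge_channels(b, a, radius = 4)
  expect_equal(dplyr::arrange(ab, x)$x, dplyr::arrange(ba, x)$x)
  expect_equal(dplyr::arrange(ab, x)$diameter, dplyr::arrange(ba, x)$diameter)

  expect_error(merge_channels(a, dplyr::mutate(b, section_id = 2L), 4),
               "different sections")
})
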