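make_points <- function(n, seed, extent = 200) {
  withr::with_seed(seed, tibble::tibble(
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    diameter = runif(n, 4, 8)
  ))
}

test_that("constellation matching recovers a known rigid transform", {
  a <- make_points(40, seed = 1)
  b <- rigid_copy(a, theta_deg = 37, tx = 25, ty = -12)
  m <- match_point_sets(a, b)
  expect_true(m$matched)
  p <- magsort:::affine_apply(m$affine, a$x, a$y)
  rms <- sqrt(mean((p$x - b$x)^2 + (p$y - b$y)^2))
  expect_lt(rms, 0.5)
  expect_equal(nrow(m$correspondences), 40L)
})

test_that("a set matches itself with the identity transform", {
  a <- make_points(30, seed = 2)
  m <- match_point_sets(a, a)
  expect_true(m$matched)
  expect_equal(nrow(m$correspondences), nrow(a))
  expect_equal(m$correspondences$i, m$correspondences$j)
  expect_equal(m$affine[1:2, 1:2], diag(2), tolerance = 1e-6)
})

test_that("unrelated point sets are rejected with high probability", {
  fails <- vapply(1:100, function(s) {
    a <- make_points(30, seed = 1000 + s)
    b <- make_points(30, seed = 5000 + s)
    p <- match_params(seed = s)
    !match_point_sets(a, b, p)$matched
  }, TRUE)
  expect_gte(mean(fails), 0.99)
})

test_that("too few points means no geometric match, not an error", {
  a <- make_points(3, seed = 3)
  expect_false(match_point_sets(a, a)$matched)
})

test_that("pair dissimilarity: self-pair is zero, inflation counts survivors", {
  a <- make_points(35, seed = 4)
  expect_equal(bead_pair_dissimilarity(a, a), 0)

  # rigid copy with every diameter inflated by +1: dissimilarity is exactly
  # (number of surviving matches) * 1, survivors counted by brute force
  b <- rigid_copy(a, 20, 10, 5)
  b$diameter <- b$diameter + 1
  params <- match_params()
  val <- bead_pair_dissimilarity(a, b, params)
  # brute-force central box on the common frame of the aligned sets
  frame <- c(range(b$x), range(b$y))
  lox <- frame[1] + 0.2 * (frame[2] - frame[1])
  hix <- frame[1] + 0.8 * (frame[2] - frame[1])
  loy <- frame[3] + 0.2 * (frame[4] - frame[3])
  hiy <- frame[3] + 0.8 * (frame[4] - frame[3])
  m_expected <- sum(b$x >= lox & b$x <= hix & b$y >= loy & b$y <= hiy)
  # the transform is exact, so survivors of the box are the matches
  expect_equal(val, m_expected * 1)

  # empty input returns the sentinel
  empty <- a[0, ]
  expect_equal(bead_pair_dissimilarity(empty, a), params$sentinel)
})

test_that("pair dissimilarity is invariant to a rigid pose of one section", {
  sl <- small_stack()
  sets <- pose_bead_sets(sl)
  ids <- sl$ground_truth$true_order
  a <- sets[sets$section_id == ids[1], ]
  b <- sets[sets$section_id == ids[2], ]
  params <- match_params(frame_size = sl$config$field_size / sl$config$pixel_size)
  v1 <- bead_pair_dissimilarity(a, b, params)
  a2 <- rigid_copy(a, 83, 12, -7)
  v2 <- bead_pair_dissimilarity(a2, b, params)
  expect_true(v1 < params$sentinel && v2 < params$sentinel)
  expect_lt(abs(v1 - v2) / v1, 0.10)
})

test_that("sections beyond the bead span share no beads and get the sentinel", {
  # two sections cut 60 sections (3 um) apart: farther than any 2 um bead
  cfg <- sim_config(n_sections = 70, field_size = c(60, 60), seed = 8)
  sl <- slice_volume(generate_bead_volume(cfg), cfg)
  sets <- pose_bead_sets(sl)
  ids <- sl$ground_truth$true_order
  a <- sets[sets$section_id == ids[1], ]
  b <- sets[sets$section_id == ids[61], ]
  expect_length(intersect(a$bead_id, b$bead_id), 0)
  params <- match_params(frame_size = cfg$field_size / cfg$pixel_size)
  expect_equal(bead_pair_dissimilarity(a, b, params), params$sentinel)
})

test_that("the dissimilarity matrix is symmetric, zero-diagonal and seeded", {
  a <- make_points(25, seed = 6)
  two <- dplyr::bind_rows(
    dplyr::mutate(a, section_id = 1L),
    dplyr::mutate(a, section_id = 2L)
  )
  d <- build_bead_matrix(two)
  expect_equal(unclass(d), matrix(0, 2, 2, dimnames = list(1:2, 1:2)),
               ignore_attr = TRUE)

  # unrelated sections: all off-diagonal entries are the sentinel
  three <- dplyr::bind_rows(lapply(1:3, function(s) {
    dplyr::mutate(make_points(25, seed = 60 + s), section_id = s)
  }))
  params <- match_params(seed = 2)
  d3 <- build_bead_matrix(three, params)
  off <- d3[upper.tri(d3)]
  expect_true(all(off == params$sentinel))
  expect_equal(unclass(d3), t(unclass(d3)), ignore_attr = TRUE)

  # determinism under a fixed seed
  d3b <- build_bead_matrix(three, params)
  expect_identical(unclass(d3), unclass(d3b))
})

test_that("mean dissimilarity increases with cutting-index gap", {
  # high-density stack at the default configuration and seed
  cfg <- sim_config()
  sl <- slice_volume(generate_bead_volume(cfg), cfg)
  sets <- pose_bead_sets(sl)
  d <- build_bead_matrix(sets,
                         match_params(frame_size = cfg$field_size / cfg$pixel_size))
  to <- sl$ground_truth$true_order
  perm <- match(to, as.integer(colnames(d)))
  m <- unclass(d)[perm, perm]
  gap_mean <- vapply(1:10, function(g) {
    v <- m[cbind(seq_len(nrow(m) - g), seq_len(nrow(m) - g) + g)]
    mean(v[v < MAGSORT_SENTINEL])
  }, 0)
  # the summed diameter-difference signal grows with gap: strictly over
  # small gaps, and as a strong monotone trend overall (at large gaps the
  # shrinking set of shared beads adds pair-count noise to the raw sum)
  expect_true(all(diff(gap_mean[1:7]) > 0))
  expect_gt(cor(1:10, gap_mean, method = "spearman"), 0.9)
  expect_gt(gap_mean[10], 2 * gap_mean[1])
})
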