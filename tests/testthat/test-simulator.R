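test_that("bead volume sampling is Poisson, uniform, and seeded", {
  cfg <- sim_config(n_sections = 5, field_size = c(20, 20), seed = 11)

  zero <- cfg
  zero$bead_density <- 0
  expect_equal(nrow(generate_bead_volume(zero)), 0L)

  v1 <- generate_bead_volume(cfg)
  v2 <- generate_bead_volume(cfg)
  expect_identical(v1, v2)

  # calibrate density for an expected count of 200 and check the empirical
  # mean over many seeds against the Poisson standard error
  target <- 200
  vol_um3 <- prod(cfg$field_size) * diff(magsort:::block_z_range(cfg))
  cfg$bead_density <- target / vol_um3
  counts <- vapply(1:1000, function(s) {
    c2 <- cfg
    c2$seed <- s
    nrow(generate_bead_volume(c2))
  }, 0L)
  se <- sqrt(target / length(counts))
  expect_lt(abs(mean(counts) - target), 3 * se)

  expect_true(all(v1$diameter > 0))
  expect_true(all(v1$x >= 0 & v1$x <= cfg$field_size[1]))
})

test_that("sphere-slab intersection gives the correct apparent diameters", {
  cfg <- sim_config(n_sections = 60, field_size = c(10, 10),
                    bead_diameter_cv = 0, seed = 1)
  t_um <- cfg$section_thickness / 1000

  one_bead <- function(z) {
    structure(tibble::tibble(bead_id = 1L, x = 5, y = 5, z = z,
                             diameter = 2, channel = 1L),
              class = c("bead_volume", "data.frame"))
  }

  # mid-plane through the bead center: apparent diameter = true diameter
  sl <- slice_volume(one_bead(10.5 * t_um), cfg)
  eq <- sl$sections[sl$sections$cut_index == 11L, ]
  expect_equal(eq$apparent_diameter, 2, tolerance = 1e-12)

  # |z| = radius: tangent plane, bead absent
  sl2 <- slice_volume(one_bead(10.5 * t_um + 1 + 1e-9), cfg)
  expect_false(11L %in% sl2$sections$cut_index)

  # offset sweep: a fully contained 2 um bead spans 40 +/- 1 sections
  spans <- vapply(seq(0, 1, length.out = 23), function(phase) {
    sl3 <- slice_volume(one_bead((25 + phase) * t_um), cfg)
    nrow(sl3$sections)
  }, 0L)
  expect_true(all(spans >= 39 & spans <= 41))
})

test_that("bead spans are contiguous and diameters unimodal", {
  sl <- small_stack()
  by_bead <- split(sl$sections, sl$sections$bead_id)
  for (df in by_bead) {
    idx <- sort(df$cut_index)
    expect_identical(idx, seq(min(idx), max(idx)))
    d <- df$apparent_diameter[order(df$cut_index)]
    peak <- which.max(d)
    expect_true(all(diff(d[seq_len(peak)]) >= 0))
    expect_true(all(diff(d[peak:length(d)]) <= 0))
  }
  # true_order is a bijection over section ids
  expect_setequal(sl$ground_truth$true_order, seq_len(sl$config$n_sections))
})

test_that("rendering places beads at their posed positions", {
  cfg <- sim_config(n_sections = 2, field_size = c(20, 20), pixel_size = 0.25,
                    noise_sd = 0, n_channels = 1, bead_density = 0, seed = 3)
  vol <- structure(tibble::tibble(bead_id = 1L, x = 10, y = 8, z = 0.05,
                                  diameter = 2, channel = 1L),
                   class = c("bead_volume", "data.frame"))
  sl <- slice_volume(vol, cfg)
  rs <- render_sections(sl)

  for (sid in sl$ground_truth$true_order) {
    pose <- sl$ground_truth$poses
    pose <- pose[pose$section_id == sid, ]
    sec <- sl$sections[sl$sections$section_id == sid, ]
    if (nrow(sec) == 0) next
    p <- magsort:::apply_pose(sec$x, sec$y, pose$rotation_deg,
                              pose$tx_um, pose$ty_um, cfg$field_size)
    img <- rs$images[[sprintf("s%03d_c1", sid)]]
    peak <- which(img == max(img), arr.ind = TRUE)
    # brightest pixel within 1 px of the analytically transformed center
    expect_lt(min(abs(peak[, 2] - 1 - p$x / cfg$pixel_size)), 1.01)
    expect_lt(min(abs(peak[, 1] - 1 - p$y / cfg$pixel_size)), 1.01)
  }
})

test_that("rendering and the on-disk shuffle are deterministic given the seed", {
  cfg <- sim_config(n_sections = 4, field_size = c(30, 30), seed = 9)
  sl <- slice_volume(generate_bead_volume(cfg), cfg)
  r1 <- suppressMessages(render_sections(sl))
  r2 <- suppressMessages(render_sections(sl))
  expect_identical(r1$images, r2$images)
  expect_identical(r1$catalog, r2$catalog)
  # the catalog order is a permutation, not the cutting order by construction
  expect_setequal(unique(r1$catalog$section_id), sl$ground_truth$true_order)
})

test_that("rendered artifacts round-trip through disk", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_sections = 3, field_size = c(20, 20), seed = 2)
  sl <- slice_volume(generate_bead_volume(cfg), cfg)
  rs <- suppressMessages(render_sections(sl, dir = dir))
  expect_true(file.exists(file.path(dir, "catalog.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_catalog(file.path(dir, "catalog.csv"))
  expect_equal(nrow(back$catalog), nrow(rs$catalog))
  key <- names(rs$images)[1]
  # 16-bit quantization
  expect_lt(max(abs(back$images[[key]] - rs$images[[key]])), 1 / 65535 + 1e-9)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$true_order, sl$ground_truth$true_order)
})

test_that("EM texture volume correlates along the axis as configured", {
  cfg <- sim_config(n_sections = 24, field_size = c(40, 40), seed = 6)
  vol <- generate_em_volume(cfg, tile_px = 64)
  expect_identical(dim(vol), c(64L, 64L, 24L))
  v1 <- generate_em_volume(cfg, tile_px = 64)
  expect_identical(vol, v1)
  adj <- cor(as.numeric(vol[, , 1]), as.numeric(vol[, , 2]))
  far <- cor(as.numeric(vol[, , 1]), as.numeric(vol[, , 21]))
  expect_gt(adj, far)
  expect_gt(adj, 0.9)
  # correlation length shorter than one section defeats ordering: warned
  expect_warning(generate_em_volume(cfg, tile_px = 32, axial_sigma = 0.5),
                 "axial correlation")
})
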