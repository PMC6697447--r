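#' Generate a random bead volume
#'
#' Draws a Poisson number of spherical beads uniformly inside the virtual
#' block, with lognormal diameters at the configured mean and coefficient of
#' variation, and assigns each bead to a fluorescent channel.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `bead_volume` with columns `bead_id`, `x`, `y`,
#'   `z` (bead centers, μm), `diameter` (μm) and `channel`.
#' @examples
#' vol <- generate_bead_volume(sim_config(n_sections = 5, seed = 2))
#' nrow(vol)
#' @export
generate_bead_volume <- function(config) {
  validate_sim_config(config)
  zr <- block_z_range(config)
  volume_um3 <- prod(config$field_size) * diff(zr)
  withr::local_seed(config$seed)
  n <- rpois(1L, config$bead_density * volume_um3)
  # lognormal parameterized by mean m and CV c:
  # sdlog^2 = log(1 + c^2), meanlog = log(m) - sdlog^2 / 2
  sdlog <- sqrt(log(1 + config$bead_diameter_cv^2))
  meanlog <- log(config$bead_mean_diameter) - sdlog^2 / 2
  beads <- tibble(
    bead_id = seq_len(n),
    x = runif(n, 0, config$field_size[1]),
    y = runif(n, 0, config$field_size[2]),
    z = runif(n, zr[1], zr[2]),
    diameter = rlnorm(n, meanlog, sdlog),
    channel = ifelse(runif(n) < config$channel_assignment_prob, 1L, 2L)
  )
  if (config$n_channels == 1L) beads$channel <- 1L
  class(beads) <- c("bead_volume", class(beads))
  beads
}

#' Slice a bead volume into sections
#'
#' Cuts the block into `n_sections` sections of the configured thickness. A
#' bead of diameter D centered at axial offset z from a section's mid-plane
#' appears in that section iff |z| < D/2, with apparent (cross-section)
#' diameter 2 * sqrt((D/2)^2 - z^2). Each bead therefore appears in a
#' contiguous run of sections -- with 2 μm beads and 50 nm sections, around
#' forty of them. The hidden cutting order, the per-section deposition pose
#' and the per-bead section spans are returned as ground truth.
#'
#' Section ids are assigned by a seeded random permutation: as on a real
#' wafer, the label a section carries is unrelated to its cutting depth.
#'
#' @param volume A [generate_bead_volume()] result.
#' @param config The same [sim_config()].
#' @return A list of class `sliced_stack`:
#'   * `sections`: tibble with `section_id`, `cut_index`, `bead_id`, `x`, `y`
#'     (bead centers, μm, block frame), `apparent_diameter` (μm), `channel`;
#'   * `ground_truth`: list with `true_order` (section ids in cutting order),
#'     `poses` (tibble `section_id`, `rotation_deg`, `tx_um`, `ty_um`) and
#'     `bead_section_spans` (tibble `bead_id`, `first_cut_index`,
#'     `last_cut_index`).
#' @examples
#' cfg <- sim_config(n_sections = 8, seed = 3)
#' sl <- slice_volume(generate_bead_volume(cfg), cfg)
#' sl$ground_truth$true_order
#' @export
slice_volume <- function(volume, config) {
  validate_sim_config(config)
  t_um <- thickness_um(config)
  n <- config$n_sections
  mid_z <- (seq_len(n) - 0.5) * t_um

  per_section <- purrr::map(seq_len(n), function(i) {
    dz <- volume$z - mid_z[i]
    keep <- abs(dz) < volume$diameter / 2
    if (!any(keep)) {
      return(tibble(
        cut_index = integer(), bead_id = integer(),
        x = numeric(), y = numeric(),
        apparent_diameter = numeric(), channel = integer()
      ))
    }
    tibble(
      cut_index = i,
      bead_id = volume$bead_id[keep],
      x = volume$x[keep],
      y = volume$y[keep],
      apparent_diameter = 2 * sqrt((volume$diameter[keep] / 2)^2 - dz[keep]^2),
      channel = volume$channel[keep]
    )
  })
  sections <- dplyr::bind_rows(per_section)

  # deposition: random ids and poses, seeded independently of bead placement
  withr::local_seed(config$seed + 1L)
  ids <- sample.int(n)                # ids[i] = label of the i-th cut section
  rot <- runif(n, -config$pose_rotation_max, config$pose_rotation_max)
  trn <- matrix(runif(2 * n, -config$pose_translation_max,
                      config$pose_translation_max), ncol = 2)

  sections$section_id <- ids[sections$cut_index]
  sections <- dplyr::relocate(sections, "section_id")

  spans <- sections |>
    dplyr::group_by(.data$bead_id) |>
    dplyr::summarise(
      first_cut_index = min(.data$cut_index),
      last_cut_index = max(.data$cut_index),
      .groups = "drop"
    )

  ground_truth <- list(
    true_order = ids,
    poses = tibble(
      section_id = ids,
      rotation_deg = rot,
      tx_um = trn[, 1],
      ty_um = trn[, 2]
    ),
    bead_section_spans = spans
  )
  structure(list(sections = sections, ground_truth = ground_truth,
                 config = config),
            class = "sliced_stack")
}

# apply a section's deposition pose to block-frame um coordinates,
# returning um coordinates in the wafer/image frame
apply_pose <- function(x, y, rotation_deg, tx, ty, field_size) {
  th <- rotation_deg * pi / 180
  cx <- field_size[1] / 2
  cy <- field_size[2] / 2
  xr <- cos(th) * (x - cx) - sin(th) * (y - cy) + cx + tx
  yr <- sin(th) * (x - cx) + cos(th) * (y - cy) + cy + ty
  list(x = xr, y = yr)
}

#' Idealized posed bead sets (noise-free detections)
#'
#' Applies each section's deposition pose to its bead cross-sections and
#' converts to pixel coordinates, producing the point sets a perfect detector
#' would extract from the rendered imagery. Beads falling outside the imaged
#' field after posing are clipped. Useful for testing the matching and
#' ordering stages in isolation from rendering and detection.
#'
#' @param sliced A [slice_volume()] result.
#' @return A tibble with `section_id`, `x`, `y` (0-based px), `diameter` (px)
#'   and `channel`, one row per visible bead cross-section.
#' @export
pose_bead_sets <- function(sliced) {
  cfg <- sliced$config
  poses <- sliced$ground_truth$poses
  df <- dplyr::left_join(sliced$sections, poses, by = "section_id")
  p <- apply_pose(df$x, df$y, df$rotation_deg, df$tx_um, df$ty_um,
                  cfg$field_size)
  out <- tibble(
    section_id = df$section_id,
    x = p$x / cfg$pixel_size,
    y = p$y / cfg$pixel_size,
    diameter = df$apparent_diameter / cfg$pixel_size,
    channel = df$channel,
    bead_id = df$bead_id
  )
  w <- cfg$field_size[1] / cfg$pixel_size
  h <- cfg$field_size[2] / cfg$pixel_size
  dplyr::filter(out, .data$x >= 0, .data$x < w, .data$y >= 0, .data$y < h)
}
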