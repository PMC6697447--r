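# Images throughout the package are numeric matrices in [0, 1] indexed
# [row = y + 1, col = x + 1]; x/y are 0-based pixel-center coordinates.

# draw one antialiased bright disk into an image matrix (in place semantics
# via return); intensity scales with apparent cross-section area
draw_disk <- function(img, cx, cy, diameter, intensity) {
  r <- diameter / 2
  nr <- nrow(img); nc <- ncol(img)
  j0 <- max(1L, floor(cx - r) ); j1 <- min(nc, ceiling(cx + r) + 2)
  i0 <- max(1L, floor(cy - r) ); i1 <- min(nr, ceiling(cy + r) + 2)
  if (j0 > j1 || i0 > i1) return(img)
  jj <- j0:j1; ii <- i0:i1
  dx <- (jj - 1) - cx
  dy <- (ii - 1) - cy
  dist <- sqrt(outer(dy^2, dx^2, `+`))
  cov <- pmin(pmax(r - dist + 0.5, 0), 1)   # ~pixel coverage at the rim
  img[ii, jj] <- img[ii, jj] + intensity * cov
  img
}

#' Render section images and the on-disk catalog
#'
#' Draws every section's bead cross-sections as bright disks (intensity
#' proportional to apparent cross-section area) after applying the section's
#' deposition pose, one image per fluorescent channel, with additive Gaussian
#' noise. The catalog lists sections in a seeded random on-disk order, so the
#' file layout carries no trace of the cutting order -- downstream stages see
#' only what a real wafer yields, and the ground truth travels separately.
#'
#' @param sliced A [slice_volume()] result.
#' @param dir Optional output directory; when given, 16-bit grayscale TIFFs,
#'   `catalog.csv` and `ground_truth.json` are written there.
#' @return A list of class `rendered_stack` with `images` (named list
#'   `s<ID>_c<CH>` of matrices in `[0, 1]`), `catalog` (tibble `section_id`,
#'   `channel`, `image_path`, `tile_row`, `tile_col`) and `ground_truth`.
#' @examples
#' cfg <- sim_config(n_sections = 3, field_size = c(20, 20), seed = 1)
#' rs <- render_sections(slice_volume(generate_bead_volume(cfg), cfg))
#' names(rs$images)
#' @export
render_sections <- function(sliced, dir = NULL) {
  cfg <- sliced$config
  w <- round(cfg$field_size[1] / cfg$pixel_size)
  h <- round(cfg$field_size[2] / cfg$pixel_size)
  poses <- sliced$ground_truth$poses
  ref_area <- (cfg$bead_mean_diameter / cfg$pixel_size / 2)^2 * pi

  withr::local_seed(cfg$seed + 2L)
  disk_order <- sample(poses$section_id)   # on-disk shuffle

  clipped <- 0L
  images <- list()
  for (sid in disk_order) {
    sec <- dplyr::filter(sliced$sections, .data$section_id == sid)
    pose <- poses[poses$section_id == sid, ]
    p <- apply_pose(sec$x, sec$y, pose$rotation_deg, pose$tx_um, pose$ty_um,
                    cfg$field_size)
    px <- p$x / cfg$pixel_size
    py <- p$y / cfg$pixel_size
    dpx <- sec$apparent_diameter / cfg$pixel_size
    outside <- px < -dpx / 2 | px > w - 1 + dpx / 2 |
               py < -dpx / 2 | py > h - 1 + dpx / 2
    clipped <- clipped + sum(outside)
    for (ch in seq_len(cfg$n_channels)) {
      img <- matrix(0, h, w)
      idx <- which(sec$channel == ch & !outside)
      for (k in idx) {
        # brightness proportional to apparent cross-section area, capped
        inten <- min(1, (dpx[k] / 2)^2 * pi / ref_area)
        img <- draw_disk(img, px[k], py[k], dpx[k], inten)
      }
      if (cfg$noise_sd > 0) {
        img <- img + matrix(rnorm(h * w, 0, cfg$noise_sd), h, w)
      }
      images[[sprintf("s%03d_c%d", sid, ch)]] <- pmin(pmax(img, 0), 1)
    }
  }
  if (clipped > 0) {
    inform(sprintf("render_sections: %d bead cross-section(s) fell outside the field after posing and were clipped.", clipped))
  }

  catalog <- tidyr::expand_grid(
    section_id = disk_order,
    channel = seq_len(cfg$n_channels)
  ) |>
    dplyr::mutate(
      image_path = sprintf("s%03d_c%d.tif", .data$section_id, .data$channel),
      tile_row = 1L, tile_col = 1L
    )

  out <- structure(
    list(images = images, catalog = catalog,
         ground_truth = sliced$ground_truth, config = cfg),
    class = "rendered_stack"
  )
  if (!is.null(dir)) write_rendered_stack(out, dir)
  out
}

write_rendered_stack <- function(rendered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(rendered$images)) {
    tiff::writeTIFF(rendered$images[[nm]], file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16L)
  }
  write.csv(rendered$catalog, file.path(dir, "catalog.csv"),
            row.names = FALSE)
  gt <- rendered$ground_truth
  jsonlite::write_json(
    list(true_order = gt$true_order,
         poses = gt$poses,
         bead_section_spans = gt$bead_section_spans),
    file.path(dir, "ground_truth.json"),
    dataframe = "columns", auto_unbox = FALSE, digits = NA
  )
  invisible(dir)
}

#' Read a section catalog and its images
#'
#' @param catalog_path Path to a `catalog.csv` written by [render_sections()]
#'   (columns `section_id`, `channel`, `image_path`, `tile_row`, `tile_col`;
#'   image paths relative to the catalog's directory).
#' @return A list with `catalog` (tibble) and `images` (named list of
#'   matrices keyed `s<ID>_c<CH>`).
#' @export
read_catalog <- function(catalog_path) {
  catalog <- as_tibble(read.csv(catalog_path))
  base <- dirname(catalog_path)
  images <- list()
  for (i in seq_len(nrow(catalog))) {
    key <- sprintf("s%03d_c%d", catalog$section_id[i], catalog$channel[i])
    img <- tiff::readTIFF(file.path(base, catalog$image_path[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    images[[key]] <- img
  }
  list(catalog = catalog, images = images)
}
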