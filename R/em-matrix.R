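# inverse-mapping bilinear warp: M (3 x 2) maps 0-based (x, y) in `img`'s
# frame to the output frame; output pixels with no preimage are NA
warp_affine <- function(img, M, out_dim = dim(img)) {
  A <- M[1:2, 1:2]; tr <- M[3, ]
  Ainv <- solve(A)
  h <- out_dim[1]; w <- out_dim[2]
  xb <- rep(0:(w - 1L), each = h)
  yb <- rep(0:(h - 1L), times = w)
  xa <- Ainv[1, 1] * (xb - tr[1]) + Ainv[2, 1] * (yb - tr[2])
  ya <- Ainv[1, 2] * (xb - tr[1]) + Ainv[2, 2] * (yb - tr[2])
  x0 <- floor(xa); y0 <- floor(ya)
  fx <- xa - x0; fy <- ya - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= ncol(img) - 2L & y0 <= nrow(img) - 2L
  out <- rep(NA_real_, h * w)
  if (any(ok)) {
    r <- y0[ok] + 1L; c <- x0[ok] + 1L
    v00 <- img[cbind(r, c)];       v01 <- img[cbind(r, c + 1L)]
    v10 <- img[cbind(r + 1L, c)];  v11 <- img[cbind(r + 1L, c + 1L)]
    out[ok] <- (1 - fy[ok]) * ((1 - fx[ok]) * v00 + fx[ok] * v01) +
               fy[ok] * ((1 - fx[ok]) * v10 + fx[ok] * v11)
  }
  matrix(out, h, w)
}

#' Generate an EM-like correlated texture volume
#'
#' Produces a 3-D band-limited noise volume whose axial correlation length is
#' much longer than one section, so consecutive slices share texture the way
#' consecutive 50-nm sections of stained tissue share ultrastructure, while
#' distant slices decorrelate. This drives the correlation-based ordering
#' variant.
#'
#' @param config A [sim_config()] (supplies `n_sections` and `seed`).
#' @param tile_px Lateral slice size in px.
#' @param lateral_sigma Lateral Gaussian smoothing sigma (px).
#' @param axial_sigma Axial Gaussian correlation sigma, in sections; values
#'   `<= 1` trigger a warning because the ordering signal vanishes when the
#'   correlation length does not exceed the section thickness.
#' @return A numeric array `tile_px x tile_px x n_sections`, values in
#'   `[0, 1]`, slice `[, , i]` being the i-th cut section.
#' @export
generate_em_volume <- function(config, tile_px = 128, lateral_sigma = 2.5,
                               axial_sigma = 4) {
  validate_sim_config(config)
  if (axial_sigma <= 1) {
    warn("generate_em_volume: axial correlation does not exceed the section thickness; adjacent sections will not correlate.")
  }
  n <- config$n_sections
  withr::local_seed(config$seed + 3L)
  vol <- array(rnorm(tile_px * tile_px * n), c(tile_px, tile_px, n))
  # axial smoothing: band kernel across slices
  zk <- outer(seq_len(n), seq_len(n),
              function(i, j) exp(-(i - j)^2 / (2 * axial_sigma^2)))
  zk <- zk / rowSums(zk)
  flat <- matrix(vol, tile_px * tile_px, n) %*% t(zk)
  vol <- array(flat, c(tile_px, tile_px, n))
  for (i in seq_len(n)) {
    vol[, , i] <- EBImage::gblur(vol[, , i], sigma = lateral_sigma)
  }
  rng <- range(vol)
  (vol - rng[1]) / (rng[2] - rng[1])
}

#' Cut an EM volume into posed tile mosaics
#'
#' Slices the volume per section, applies each section's deposition pose
#' (the same ground-truth pose as the bead imagery, rotation about the tile
#' center plus translation) and cuts the result into a `grid` of tiles.
#' Output mosaics are keyed by section id, so their order carries no trace of
#' the cutting order.
#'
#' @param volume From [generate_em_volume()].
#' @param sliced A [slice_volume()] result supplying ground-truth ids/poses.
#' @param grid Mosaic layout `c(rows, cols)` (default one tile).
#' @return Named list (by section id) of `tile_mosaic` objects: lists with
#'   `section_id`, `grid` and `tiles` (row-major list of matrices).
#' @export
render_em_sections <- function(volume, sliced, grid = c(1L, 1L)) {
  cfg <- sliced$config
  poses <- sliced$ground_truth$poses
  d <- dim(volume)[1]
  px_per_um <- d / max(cfg$field_size)  # tile spans the field
  mosaics <- list()
  for (r in seq_len(nrow(poses))) {
    sid <- poses$section_id[r]
    cut <- match(sid, sliced$ground_truth$true_order)
    th <- poses$rotation_deg[r] * pi / 180
    c0 <- (d - 1) / 2
    # row-vector convention: p' = p %*% A + tr (matches warp_affine)
    A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    tr <- c(c0 + poses$tx_um[r] * px_per_um,
            c0 + poses$ty_um[r] * px_per_um) - as.numeric(c(c0, c0) %*% A)
    M <- rbind(A, tr)
    img <- warp_affine(volume[, , cut], M)
    img[is.na(img)] <- 0.5
    mosaics[[as.character(sid)]] <- new_tile_mosaic(sid, img, grid)
  }
  mosaics[order(as.integer(names(mosaics)))]
}

new_tile_mosaic <- function(section_id, img, grid = c(1L, 1L)) {
  gr <- as.integer(grid)
  rh <- nrow(img) %/% gr[1]; cw <- ncol(img) %/% gr[2]
  tiles <- list()
  for (i in seq_len(gr[1])) {
    for (j in seq_len(gr[2])) {
      tiles[[length(tiles) + 1L]] <-
        img[((i - 1L) * rh + 1L):(i * rh), ((j - 1L) * cw + 1L):(j * cw)]
    }
  }
  structure(list(section_id = section_id, grid = gr, tiles = tiles),
            class = "tile_mosaic")
}

#' Parameters for EM tile matching
#'
#' @param n_keypoints Strongest difference-of-Gaussians blob keypoints kept
#'   per tile.
#' @param dog_sigma Base Gaussian sigma of the blob detector (px).
#' @param box Side cap (px) of the central correlation box (default 2000;
#'   smaller tiles use their full central extent).
#' @param match [match_params()] controlling the keypoint constellation
#'   match and consensus affine fit.
#' @param sentinel Dissimilarity when no tile of a pair matches.
#' @return A named list of class `em_params`.
#' @export
em_params <- function(n_keypoints = 150L, dog_sigma = 2, box = 2000L,
                      match = match_params(inlier_tol = 3, ratio = 0.95,
                                           n_iter = 1000L),
                      sentinel = MAGSORT_SENTINEL) {
  structure(list(n_keypoints = as.integer(n_keypoints), dog_sigma = dog_sigma,
                 box = as.integer(box), match = match, sentinel = sentinel),
            class = "em_params")
}

# difference-of-Gaussians blob keypoints: local extrema of the DoG response,
# strongest first
dog_keypoints <- function(img, sigma = 2, n_max = 150L) {
  g1 <- EBImage::gblur(img, sigma = sigma)
  g2 <- EBImage::gblur(img, sigma = 1.6 * sigma)
  dog <- g1 - g2
  nr <- nrow(dog); nc <- ncol(dog)
  core <- dog[2:(nr - 1), 2:(nc - 1)]
  ismax <- ismin <- matrix(TRUE, nr - 2, nc - 2)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- dog[(2 + dy):(nr - 1 + dy), (2 + dx):(nc - 1 + dx)]
    ismax <- ismax & core > nb
    ismin <- ismin & core < nb
  }
  idx <- which(ismax | ismin, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(tibble(x = numeric(), y = numeric()))
  resp <- abs(core[idx])
  ord <- order(resp, decreasing = TRUE)[seq_len(min(n_max, length(resp)))]
  tibble(x = idx[ord, 2] - 1 + 1,   # +1: core offset, -1: 0-based
         y = idx[ord, 1] - 1 + 1)
}

central_box_idx <- function(dm, box) {
  side <- pmin(box, dm)
  r0 <- (dm[1] - side[1]) %/% 2 + 1L
  c0 <- (dm[2] - side[2]) %/% 2 + 1L
  list(rows = r0:(r0 + side[1] - 1L), cols = c0:(c0 + side[2] - 1L))
}

#' Dissimilarity of one EM tile pair
#'
#' Seeks an affine transform between the tiles by matching blob-keypoint
#' constellations with a robust consensus fit; when found, aligns tile `a`
#' onto `b` and computes the Pearson normalized cross-correlation `c` of
#' their central boxes (sides capped at `params$box` px). The tile
#' dissimilarity is `2 - c`, so identical aligned tiles score 1 and
#' contrast-inverted ones score 3.
#'
#' @param tile_a,tile_b Equal-shape numeric matrices.
#' @param params An [em_params()].
#' @param force_identity Skip alignment and correlate in place (used when the
#'   tiles are already registered).
#' @return A list `(value, matched)`; `matched = FALSE` (with the sentinel
#'   value) when no affine is found or a tile is constant.
#' @export
tile_dissimilarity <- function(tile_a, tile_b, params = em_params(),
                               force_identity = FALSE) {
  stopifnot(all(dim(tile_a) == dim(tile_b)))
  unmatched <- list(value = params$sentinel, matched = FALSE)
  if (sd(tile_a) == 0 || sd(tile_b) == 0) return(unmatched)
  if (force_identity) {
    aligned <- tile_a
  } else {
    ka <- dog_keypoints(tile_a, params$dog_sigma, params$n_keypoints)
    kb <- dog_keypoints(tile_b, params$dog_sigma, params$n_keypoints)
    m <- match_point_sets(ka, kb, params$match)
    if (!m$matched) return(unmatched)
    aligned <- warp_affine(tile_a, m$affine)
  }
  cb <- central_box_idx(dim(tile_b), params$box)
  va <- aligned[cb$rows, cb$cols]
  vb <- tile_b[cb$rows, cb$cols]
  ok <- !is.na(va)
  if (sum(ok) < 16 || sd(va[ok]) == 0 || sd(vb[ok]) == 0) return(unmatched)
  list(value = 2 - cor(va[ok], vb[ok]), matched = TRUE)
}

#' Dissimilarity of one EM section pair (tile-averaged)
#'
#' Scores each corresponding tile pair with [tile_dissimilarity()] and
#' averages over the tiles that matched; tiles that failed to match are
#' excluded as long as at least one tile matched (robustness to per-tile
#' artifacts). When no tile matches the sentinel is returned.
#'
#' @param a,b `tile_mosaic` objects with identical grids.
#' @param params An [em_params()].
#' @return A single dissimilarity value.
#' @export
section_pair_dissimilarity <- function(a, b, params = em_params()) {
  if (!all(a$grid == b$grid)) abort("section_pair_dissimilarity: mosaic grids differ.")
  res <- purrr::map(seq_along(a$tiles), function(k) {
    tile_dissimilarity(a$tiles[[k]], b$tiles[[k]], params)
  })
  vals <- vapply(res, `[[`, 0, "value")
  ok <- vapply(res, `[[`, TRUE, "matched")
  if (!any(ok)) return(params$sentinel)
  mean(vals[ok])
}

#' Build the EM dissimilarity matrix over all section pairs
#'
#' @param mosaics List of `tile_mosaic` objects (e.g. from
#'   [render_em_sections()]).
#' @param params An [em_params()].
#' @param progress Emit a progress message every 50 pairs.
#' @return A `dissimilarity_matrix` (modality `"em"`): symmetric, diagonal
#'   fixed at 0 by convention (a self-pair would score `2 - 1 = 1`, but only
#'   off-diagonal entries enter the path solver).
#' @export
build_em_matrix <- function(mosaics, params = em_params(), progress = FALSE) {
  ids <- vapply(mosaics, `[[`, 0L, "section_id")
  ord <- order(ids)
  mosaics <- mosaics[ord]; ids <- ids[ord]
  n <- length(ids)
  if (n < 2L) abort("build_em_matrix: need at least 2 sections.")
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      vals[i, j] <- vals[j, i] <-
        section_pair_dissimilarity(mosaics[[i]], mosaics[[j]], params)
      done <- done + 1L
      if (progress && done %% 50L == 0L) {
        inform(sprintf("build_em_matrix: %d/%d pairs", done,
                       n * (n - 1L) %/% 2L))
      }
    }
  }
  new_dissimilarity_matrix(vals, params$sentinel, "em", params)
}
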