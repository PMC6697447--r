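# box-filter local mean via integral images (zero-padded borders use the
# available neighbourhood only)
local_mean <- function(img, half) {
  nr <- nrow(img); nc <- ncol(img)
  ii <- rbind(0, apply(img, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  s <- ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1, c2 + 1L, drop = FALSE] -
       ii[r2 + 1L, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  s / cnt
}

#' Normalize local contrast
#'
#' Standardizes every pixel by the mean and standard deviation of its
#' surrounding `block_size` x `block_size` neighbourhood, clips at
#' `n_sd` standard deviations and rescales to `[0, 1]`, with locally constant
#' regions mapping to mid-gray (0.5). This flattens illumination gradients so
#' a single global threshold separates beads from background.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param block_size Side of the sliding neighbourhood in px (>= 3). If it
#'   exceeds the image, global normalization is used instead (with a message).
#' @param n_sd Standard deviations mapped to the output range (default 3).
#' @return A matrix of the same shape with values in `[0, 1]`.
#' @examples
#' img <- matrix(0.2, 32, 32); img[16, 16] <- 1
#' out <- normalize_local_contrast(img, block_size = 15)
#' which(out == max(out), arr.ind = TRUE)
#' @export
normalize_local_contrast <- function(image, block_size = 63, n_sd = 3) {
  stopifnot(is.matrix(image))
  if (block_size < 3) abort("`block_size` must be at least 3 px.")
  if (block_size > min(dim(image))) {
    inform("normalize_local_contrast: block exceeds image; using global normalization.")
    m <- mean(image); s <- sd(image)
    z <- if (s > 0) (image - m) / s else image * 0
  } else {
    half <- block_size %/% 2
    mu <- local_mean(image, half)
    mu2 <- local_mean(image^2, half)
    sig <- sqrt(pmax(mu2 - mu^2, 0))
    z <- ifelse(sig > 1e-6, (image - mu) / sig, 0)
  }
  pmin(pmax(z, -n_sd), n_sd) / (2 * n_sd) + 0.5
}

#' Detect beads in a contrast-normalized section image
#'
#' Thresholds the image, labels connected components, and reports one bead
#' per component at its intensity-weighted centroid. The apparent diameter is
#' the equivalent-disk diameter of the component, `2 * sqrt(area / pi)` --
#' a scalar that is directly comparable across sections, which is all the
#' diameter-difference dissimilarity needs.
#'
#' @param image Numeric matrix (raw or already normalized).
#' @param section_id Integer id recorded in the output.
#' @param channel Channel label recorded in the output.
#' @param threshold Fraction of the normalized range above which a pixel is
#'   foreground; the default 0.85 sits about two local standard deviations
#'   above the local mean after [normalize_local_contrast()].
#' @param min_area Components smaller than this many px are discarded.
#' @param normalize Apply [normalize_local_contrast()] first (default TRUE).
#' @param block_size Passed to [normalize_local_contrast()].
#' @return A tibble with `section_id`, `x`, `y` (0-based px, x = column),
#'   `diameter` (px) and `channel`; zero rows for a blank image.
#' @export
detect_beads <- function(image, section_id = 1L, channel = 1L,
                         threshold = 0.85, min_area = 4, normalize = TRUE,
                         block_size = 63) {
  norm <- if (normalize) normalize_local_contrast(image, block_size) else image
  mask <- norm > threshold
  empty <- tibble(section_id = integer(), x = numeric(), y = numeric(),
                  diameter = numeric(), channel = integer())
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(mask)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  wgt <- norm[labels > 0] - threshold      # weight by supra-threshold signal
  wgt[wgt <= 0] <- 1e-9
  area <- tabulate(lab)
  sx <- vapply(split(wgt * (idx[, 2] - 1), lab), sum, 0)
  sy <- vapply(split(wgt * (idx[, 1] - 1), lab), sum, 0)
  sw <- vapply(split(wgt, lab), sum, 0)
  keep <- area >= min_area
  if (!any(keep)) return(empty)
  tibble(
    section_id = as.integer(section_id),
    x = (sx / sw)[keep],
    y = (sy / sw)[keep],
    diameter = 2 * sqrt(area[keep] / pi),
    channel = as.integer(channel)
  )
}

#' Merge bead detections from two fluorescent channels
#'
#' Returns the union of the two point sets; cross-channel pairs closer than
#' `radius` are collapsed to a single bead at the mean position with the mean
#' diameter (the same physical bead imaged in both channels). Pairing is
#' greedy by increasing distance, each point used at most once.
#'
#' @param set_a,set_b Bead tibbles from [detect_beads()] for the same section.
#' @param radius Collapse radius in px.
#' @return A bead tibble with channel label `"merged"`.
#' @export
merge_channels <- function(set_a, set_b, radius) {
  if (nrow(set_a) > 0 && nrow(set_b) > 0 &&
      !identical(unique(set_a$section_id), unique(set_b$section_id))) {
    abort("merge_channels: the two sets come from different sections.")
  }
  na <- nrow(set_a); nb <- nrow(set_b)
  take <- function(df) tibble(section_id = df$section_id, x = df$x,
                              y = df$y, diameter = df$diameter)
  if (na == 0L || nb == 0L) {
    out <- dplyr::bind_rows(take(set_a), take(set_b))
    out$channel <- "merged"
    return(out)
  }
  d <- sqrt(outer(set_a$x, set_b$x, `-`)^2 + outer(set_a$y, set_b$y, `-`)^2)
  cand <- which(d < radius, arr.ind = TRUE)
  used_a <- logical(na); used_b <- logical(nb)
  pairs <- cand[order(d[cand]), , drop = FALSE]
  merged <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    merged[[length(merged) + 1L]] <- tibble(
      section_id = set_a$section_id[i],
      x = (set_a$x[i] + set_b$x[j]) / 2,
      y = (set_a$y[i] + set_b$y[j]) / 2,
      diameter = (set_a$diameter[i] + set_b$diameter[j]) / 2
    )
  }
  out <- dplyr::bind_rows(
    take(set_a[!used_a, , drop = FALSE]),
    take(set_b[!used_b, , drop = FALSE]),
    dplyr::bind_rows(merged)
  )
  out$channel <- "merged"
  out
}

#' Detect and merge beads across a rendered stack
#'
#' Runs [detect_beads()] on every section/channel image of a rendered stack
#' (or a list read by [read_catalog()]) and merges the channels per section.
#'
#' @param stack A `rendered_stack` or the result of [read_catalog()].
#' @param merge_radius Cross-channel collapse radius in px; default half the
#'   mean bead diameter in px when the stack carries its configuration, else
#'   4 px.
#' @inheritParams detect_beads
#' @return One tibble of beads for all sections (channel `"merged"`).
#' @export
detect_stack <- function(stack, threshold = 0.85, min_area = 4,
                         block_size = 63, merge_radius = NULL) {
  cfg <- stack$config
  if (is.null(merge_radius)) {
    merge_radius <- if (!is.null(cfg)) {
      0.5 * cfg$bead_mean_diameter / cfg$pixel_size
    } else 4
  }
  catalog <- stack$catalog
  sids <- unique(catalog$section_id)
  purrr::map_dfr(sids, function(sid) {
    chans <- sort(unique(catalog$channel[catalog$section_id == sid]))
    dets <- purrr::map(chans, function(ch) {
      img <- stack$images[[sprintf("s%03d_c%d", sid, ch)]]
      detect_beads(img, section_id = sid, channel = ch,
                   threshold = threshold, min_area = min_area,
                   block_size = block_size)
    })
    out <- dets[[1]]
    if (length(dets) > 1) {
      for (k in 2:length(dets)) out <- merge_channels(out, dets[[k]],
                                                      merge_radius)
    } else {
      out$channel <- "merged"
    }
    out
  })
}
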