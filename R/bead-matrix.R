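new_dissimilarity_matrix <- function(values, sentinel, modality, params = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, sentinel = sentinel, modality = modality,
            params = params, class = c("dissimilarity_matrix", "matrix"))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d sections (%s), sentinel %g, %d/%d finite off-diagonal pairs\n",
              nrow(x), attr(x, "modality"), attr(x, "sentinel"),
              sum(x[upper.tri(x)] < attr(x, "sentinel")),
              sum(upper.tri(x))))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Bead-based dissimilarity of one section pair
#'
#' Implements the diameter-difference dissimilarity between two sections'
#' bead sets: (1) constellation matching of the full sets -- if no geometric
#' match, the sentinel is returned; (2) the fitted affine brings set `a` into
#' `b`'s frame; (3) beads outside the central bounding box of the common
#' frame are excluded, so beads seen in only one section because of the
#' limited field of view cannot contribute; (4) the surviving sets are
#' matched again; (5) the dissimilarity is the sum over the final matches of
#' the absolute apparent-diameter differences. Physically adjacent sections
#' slice each shared bead at nearly the same latitude, so their summed
#' diameter differences are small; the sum grows with cutting distance.
#'
#' @param a,b Bead tables with columns `x`, `y`, `diameter` (px).
#' @param params A [match_params()].
#' @return A single non-negative number (the sentinel when unmatched or when
#'   either set is empty).
#' @export
bead_pair_dissimilarity <- function(a, b, params = match_params()) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(params$sentinel)
  m1 <- match_point_sets(a, b, params)
  if (!m1$matched) return(params$sentinel)

  p <- affine_apply(m1$affine, a$x, a$y)
  a2 <- tibble(x = p$x, y = p$y, diameter = a$diameter)
  b2 <- tibble(x = b$x, y = b$y, diameter = b$diameter)

  frame <- params$frame_size %||%
    c(max(a2$x, b2$x) - min(a2$x, b2$x), max(a2$y, b2$y) - min(a2$y, b2$y))
  orig <- if (is.null(params$frame_size)) {
    c(min(a2$x, b2$x), min(a2$y, b2$y))
  } else c(0, 0)
  cf <- params$central_fraction
  lo <- orig + (1 - cf) / 2 * frame
  hi <- orig + (1 + cf) / 2 * frame
  inbox <- function(df) df[df$x >= lo[1] & df$x <= hi[1] &
                           df$y >= lo[2] & df$y <= hi[2], , drop = FALSE]
  a3 <- inbox(a2); b3 <- inbox(b2)

  m2 <- match_point_sets(a3, b3, params)
  if (!m2$matched) return(params$sentinel)
  sum(abs(a3$diameter[m2$correspondences$i] -
          b3$diameter[m2$correspondences$j]))
}

#' Build the bead dissimilarity matrix over all section pairs
#'
#' Computes [bead_pair_dissimilarity()] once per unordered pair of sections
#' and mirrors it; the diagonal is zero. Rows/columns follow sorted section
#' ids (stored in `dimnames`).
#'
#' @param beads A bead table for all sections (columns `section_id`, `x`,
#'   `y`, `diameter`), e.g. from [detect_stack()] or [pose_bead_sets()].
#' @param params A [match_params()].
#' @param progress Emit a progress message every 50 pairs.
#' @return A `dissimilarity_matrix` (symmetric, non-negative, zero diagonal,
#'   sentinel entries for unmatched pairs).
#' @examples
#' cfg <- sim_config(n_sections = 4, field_size = c(30, 30), seed = 1)
#' sets <- pose_bead_sets(slice_volume(generate_bead_volume(cfg), cfg))
#' d <- build_bead_matrix(sets)
#' d[1:4, 1:4]
#' @export
build_bead_matrix <- function(beads, params = match_params(),
                              progress = FALSE) {
  ids <- sort(unique(beads$section_id))
  n <- length(ids)
  if (n < 2L) abort("build_bead_matrix: need at least 2 sections.")
  sets <- lapply(ids, function(s) beads[beads$section_id == s, , drop = FALSE])
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      vals[i, j] <- vals[j, i] <-
        bead_pair_dissimilarity(sets[[i]], sets[[j]], params)
      done <- done + 1L
      if (progress && done %% 50L == 0L) {
        inform(sprintf("build_bead_matrix: %d/%d pairs", done,
                       n * (n - 1L) %/% 2L))
      }
    }
  }
  new_dissimilarity_matrix(vals, params$sentinel, "beads", params)
}

#' Write / read a dissimilarity matrix with its metadata
#'
#' The matrix goes to `path` as a plain n x n CSV (section ids as header);
#' the sentinel, modality and matching parameters go to a JSON sidecar
#' `<path>.meta.json`.
#'
#' @param d A `dissimilarity_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly (`read_dissimilarity_matrix` returns the
#'   reconstructed `dissimilarity_matrix`).
#' @export
write_dissimilarity_matrix <- function(d, path) {
  write.csv(as.data.frame(unclass(d)), path, row.names = FALSE)
  prm <- attr(d, "params")
  jsonlite::write_json(
    list(sentinel = attr(d, "sentinel"), modality = attr(d, "modality"),
         section_ids = as.integer(colnames(d)),
         params = prm[!vapply(prm, is.null, TRUE)]),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_dissimilarity_matrix
#' @export
read_dissimilarity_matrix <- function(path) {
  vals <- as.matrix(read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  dimnames(vals) <- list(meta$section_ids, meta$section_ids)
  new_dissimilarity_matrix(vals, meta$sentinel, meta$modality, meta$params)
}
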