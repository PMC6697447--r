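#' Parameters for constellation matching and bead dissimilarity
#'
#' @param k Neighbours per local descriptor (default 4): each point is
#'   described by the distances and relative angles to its `k` nearest
#'   neighbours, a rotation/translation-invariant signature of its local
#'   bead constellation.
#' @param ratio Nearest/second-nearest descriptor distance ratio below which
#'   a candidate correspondence is kept (Lowe-style ambiguity test).
#' @param inlier_tol Residual (px) under the fitted affine below which a
#'   candidate correspondence counts as an inlier.
#' @param min_inliers Consensus correspondences required to declare a match.
#' @param n_iter Consensus-sampling iterations (fixed budget).
#' @param scale_tol Tolerated deviation of the affine's singular values from
#'   1 (sections are deposited rigidly up to slight anisotropy).
#' @param central_fraction Side fraction of the common frame kept by the
#'   central-bounding-box exclusion, which drops beads visible in only one
#'   section because of the limited field of view.
#' @param sentinel Dissimilarity assigned when no geometric match is found.
#' @param frame_size Optional `c(width, height)` of the common frame in px;
#'   when `NULL` the bounding box of the pooled points is used.
#' @param seed Seed for the consensus sampler.
#' @return A named list of class `match_params`.
#' @export
match_params <- function(k = 4L, ratio = 0.9, inlier_tol = 2,
                         min_inliers = 6L, n_iter = 300L, scale_tol = 0.2,
                         central_fraction = 0.6,
                         sentinel = MAGSORT_SENTINEL,
                         frame_size = NULL, seed = 1L) {
  structure(list(k = as.integer(k), ratio = ratio, inlier_tol = inlier_tol,
                 min_inliers = as.integer(min_inliers),
                 n_iter = as.integer(n_iter), scale_tol = scale_tol,
                 central_fraction = central_fraction, sentinel = sentinel,
                 frame_size = frame_size, seed = as.integer(seed)),
            class = "match_params")
}

# rotation/translation-invariant local descriptor per point:
# sorted distances to the k nearest neighbours plus (cos, sin) of the angles
# of neighbours 2..k relative to the nearest neighbour's direction
point_descriptors <- function(x, y, k) {
  n <- length(x)
  d2 <- outer(x, x, `-`)^2 + outer(y, y, `-`)^2
  diag(d2) <- Inf
  desc <- matrix(0, n, k + 2L * (k - 1L))
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k)]
    dist <- sqrt(d2[i, nb])
    ang <- atan2(y[nb] - y[i], x[nb] - x[i])
    rel <- ang[-1] - ang[1]
    desc[i, ] <- c(dist, cos(rel), sin(rel))
  }
  desc
}

fit_affine_ls <- function(ax, ay, bx, by) {
  X <- cbind(ax, ay, 1)
  M <- tryCatch(qr.solve(X, cbind(bx, by)), error = function(e) NULL)
  if (!is.null(M)) dimnames(M) <- NULL
  M   # 3 x 2; maps (x, y, 1) -> (x', y')
}

affine_apply <- function(M, x, y) {
  list(x = M[1, 1] * x + M[2, 1] * y + M[3, 1],
       y = M[1, 2] * x + M[2, 2] * y + M[3, 2])
}

affine_scale_ok <- function(M, scale_tol) {
  sv <- svd(M[1:2, 1:2])$d
  all(sv > 1 / (1 + scale_tol), sv < 1 + scale_tol)
}

#' Match two bead point sets by local constellation descriptors
#'
#' Builds a rotation/translation-invariant descriptor from each point's `k`
#' nearest neighbours, proposes candidate correspondences by descriptor
#' similarity with an ambiguity test, and filters them by robust consensus
#' fitting of a 2-D affine transform (seeded sampling with a fixed iteration
#' budget, least-squares refit on the consensus set). The match succeeds when
#' at least `min_inliers` correspondences agree with one affine model.
#'
#' @param a,b Data frames with columns `x`, `y` (px); typically bead tables
#'   from [detect_beads()] or [pose_bead_sets()].
#' @param params A [match_params()].
#' @return A list of class `match_result`: `matched` (logical), `affine`
#'   (3 x 2 matrix mapping `a` into `b`'s frame, or `NULL`),
#'   `correspondences` (tibble `i`, `j` of row indices into `a` and `b`),
#'   and `n_inliers`.
#' @export
match_point_sets <- function(a, b, params = match_params()) {
  k <- params$k
  na <- nrow(a); nb <- nrow(b)
  no_match <- list(matched = FALSE, affine = NULL,
                   correspondences = tibble(i = integer(), j = integer()),
                   n_inliers = 0L)
  class(no_match) <- "match_result"
  if (na < k + 1L || nb < k + 1L) return(no_match)

  da <- point_descriptors(a$x, a$y, k)
  db <- point_descriptors(b$x, b$y, k)
  # squared descriptor distances, candidates by ambiguity-tested NN
  dd <- outer(rowSums(da^2), rowSums(db^2), `+`) - 2 * tcrossprod(da, db)
  dd[dd < 0] <- 0
  best_j <- max.col(-dd)
  best_d <- dd[cbind(seq_len(na), best_j)]
  dd2 <- dd
  dd2[cbind(seq_len(na), best_j)] <- Inf
  second_d <- dd2[cbind(seq_len(na), max.col(-dd2))]
  keep <- sqrt(best_d) < params$ratio * sqrt(second_d)
  ci <- which(keep); cj <- best_j[keep]
  if (length(ci) < 3L) return(no_match)

  ax <- a$x[ci]; ay <- a$y[ci]; bx <- b$x[cj]; by <- b$y[cj]
  nc <- length(ci)
  withr::local_seed(params$seed)
  best_inl <- integer(0)
  for (it in seq_len(params$n_iter)) {
    s <- sample.int(nc, 3L)
    if (length(unique(ci[s])) < 3L || length(unique(cj[s])) < 3L) next
    M <- fit_affine_ls(ax[s], ay[s], bx[s], by[s])
    if (is.null(M) || !affine_scale_ok(M, params$scale_tol)) next
    p <- affine_apply(M, ax, ay)
    res <- sqrt((p$x - bx)^2 + (p$y - by)^2)
    inl <- which(res < params$inlier_tol)
    if (length(inl) > length(best_inl)) {
      best_inl <- inl
      if (length(best_inl) > 0.8 * nc) break
    }
  }
  if (length(best_inl) < 3L) return(no_match)

  M <- fit_affine_ls(ax[best_inl], ay[best_inl], bx[best_inl], by[best_inl])
  if (is.null(M)) return(no_match)
  p <- affine_apply(M, ax, ay)
  res <- sqrt((p$x - bx)^2 + (p$y - by)^2)
  if (sum(res < params$inlier_tol) < params$min_inliers) return(no_match)

  # final correspondences from the consensus transform over ALL points
  # (not just descriptor candidates): greedy one-to-one nearest pairs
  # within the inlier tolerance -- complete and stable across pairs
  pa <- affine_apply(M, a$x, a$y)
  dmat <- sqrt(outer(pa$x, b$x, `-`)^2 + outer(pa$y, b$y, `-`)^2)
  cand2 <- which(dmat < params$inlier_tol, arr.ind = TRUE)
  cand2 <- cand2[order(dmat[cand2]), , drop = FALSE]
  used_i <- logical(na); used_j <- logical(nb)
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(cand2))) {
    i <- cand2[k, 1]; j <- cand2[k, 2]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    ii <- c(ii, i); jj <- c(jj, j)
  }
  if (length(ii) < params$min_inliers) return(no_match)
  ord <- order(ii)
  corr <- tibble(i = unname(ii[ord]), j = unname(jj[ord]))

  # refit on the full correspondence set: averages out the sampler's choice
  # of consensus triplet, so the transform is stable across seeds
  M2 <- fit_affine_ls(a$x[corr$i], a$y[corr$i], b$x[corr$j], b$y[corr$j])
  if (!is.null(M2) && affine_scale_ok(M2, params$scale_tol)) M <- M2

  structure(list(matched = TRUE, affine = M, correspondences = corr,
                 n_inliers = nrow(corr)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("<match_result> matched, %d correspondences\n", x$n_inliers))
  } else {
    cat("<match_result> no geometric match\n")
  }
  invisible(x)
}
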