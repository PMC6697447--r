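new_section_order <- function(order, path_cost, solver, seed = NA_integer_) {
  structure(list(order = order, path_cost = path_cost, solver = solver,
                 seed = seed),
            class = "section_order")
}

#' @export
print.section_order <- function(x, ...) {
  cat(sprintf("<section_order> %d sections, path cost %g (%s solver)\n",
              length(x$order), x$path_cost, x$solver))
  cat(" ", paste(utils::head(x$order, 20), collapse = " - "),
      if (length(x$order) > 20) "..." else "", "\n")
  invisible(x)
}

order_ids <- function(order) {
  if (inherits(order, "section_order")) order$order else order
}

# colnames are character; recover integer ids when they are numeric so
# canonical orientation compares ids numerically
matrix_ids <- function(d) {
  ids <- colnames(d) %||% as.character(seq_len(nrow(d)))
  ii <- suppressWarnings(as.integer(ids))
  if (!anyNA(ii)) ii else ids
}

path_cost_of <- function(d, ids) {
  all_ids <- colnames(d) %||% as.character(seq_len(nrow(d)))
  pos <- match(as.character(ids), all_ids)
  sum(d[cbind(pos[-length(pos)], pos[-1])])
}

#' Canonical orientation of a section order
#'
#' A recovered cutting order is defined only up to reversal (nothing
#' distinguishes cutting front-to-back from back-to-front), so orders are
#' reported with the smaller terminal id first.
#'
#' @param order A vector of section ids or a `section_order`.
#' @return The same type, possibly reversed.
#' @export
canonicalize <- function(order) {
  if (inherits(order, "section_order")) {
    order$order <- canonicalize(order$order)
    return(order)
  }
  if (length(order) >= 2L && order[1] > order[length(order)]) rev(order) else order
}

#' Exact minimum-cost open tour (Held-Karp)
#'
#' Finds a minimum-cost Hamiltonian path through all sections by dynamic
#' programming over subsets (`O(2^n n^2)`), the open-path analogue of the
#' classic cycle recursion: `dp[S, j]` is the cheapest path visiting exactly
#' the set `S` and ending at `j`. Exact but exponential, hence capped at
#' `exact_limit` sections.
#'
#' @param d A `dissimilarity_matrix` (or plain symmetric matrix).
#' @param exact_limit Refuse larger problems (default 12) and point to
#'   [solve_heuristic()].
#' @return A `section_order` (canonical orientation) with the optimal
#'   `path_cost`.
#' @examples
#' m <- as.matrix(dist(c(0, 3, 1, 2)))
#' solve_exact(m)$order
#' @export
solve_exact <- function(d, exact_limit = 12L) {
  n <- nrow(d)
  if (n > exact_limit) {
    abort(sprintf("solve_exact: n = %d exceeds exact_limit = %d; use solve_heuristic().", n, exact_limit))
  }
  ids <- matrix_ids(d)
  if (n == 2L) {
    return(new_section_order(canonicalize(ids), d[1, 2], "exact"))
  }
  nS <- bitwShiftL(1L, n)
  dp <- matrix(Inf, nS, n)
  parent <- matrix(NA_integer_, nS, n)
  for (j in seq_len(n)) dp[bitwShiftL(1L, j - 1L) + 1L, j] <- 0
  for (S in seq_len(nS - 1L)) {
    members <- which(bitwAnd(S, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(members) < 1L) next
    for (j in members) {
      cur <- dp[S + 1L, j]
      if (!is.finite(cur)) next
      rest <- setdiff(seq_len(n), members)
      for (m in rest) {
        S2 <- bitwOr(S, bitwShiftL(1L, m - 1L))
        cand <- cur + d[j, m]
        if (cand < dp[S2 + 1L, m]) {
          dp[S2 + 1L, m] <- cand
          parent[S2 + 1L, m] <- j
        }
      }
    }
  }
  full <- nS - 1L
  end <- which.min(dp[full + 1L, ])
  best <- dp[full + 1L, end]
  path <- integer(n)
  S <- full; j <- end
  for (p in n:1) {
    path[p] <- j
    pj <- parent[S + 1L, j]
    S <- bitwAnd(S, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  new_section_order(canonicalize(ids[path]), best, "exact")
}

# one nearest-neighbour construction on the dummy-augmented cycle
nn_tour <- function(dd, start) {
  n <- nrow(dd)
  visited <- logical(n); tour <- integer(n)
  cur <- start; visited[cur] <- TRUE; tour[1] <- cur
  for (k in 2:n) {
    cand <- dd[cur, ]
    cand[visited] <- Inf
    cur <- which.min(cand)
    visited[cur] <- TRUE
    tour[k] <- cur
  }
  tour
}

tour_len <- function(dd, tour) {
  sum(dd[cbind(tour, c(tour[-1], tour[1]))])
}

# first-improvement 2-opt on a cycle until no improving move remains
two_opt <- function(dd, tour) {
  n <- length(tour)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(n - 1L)) {
      if (i + 2L > n) next
      a <- tour[i]; b <- tour[i + 1L]
      js <- (i + 2L):n
      if (i == 1L) js <- js[js < n]   # (1, n) edges are adjacent on the cycle
      if (length(js) == 0L) next
      cs <- tour[js]; ds <- tour[js %% n + 1L]
      delta <- dd[a, cs] + dd[cbind(b, ds)] - dd[a, b] - dd[cbind(cs, ds)]
      best <- which.min(delta)
      if (delta[best] < -1e-9) {
        j <- js[best]
        tour[(i + 1L):j] <- rev(tour[(i + 1L):j])
        improved <- TRUE
      }
    }
  }
  tour
}

#' Heuristic open tour (dummy-node closure + 2-opt)
#'
#' Converts the open-path problem to a cycle problem by adding a virtual
#' node at distance zero to every section -- any cycle through the virtual
#' node, cut at that node, is a Hamiltonian path of equal cost, so the two
#' problems share an optimum. The cycle is solved by multi-start greedy
#' nearest-neighbour construction followed by 2-opt improvement to a local
#' optimum; fully deterministic given `seed`.
#'
#' @param d A `dissimilarity_matrix` (or plain symmetric matrix).
#' @param seed Seed for the multi-start order.
#' @param n_starts Nearest-neighbour starts (default `min(n, 10)`).
#' @param tol Symmetry tolerance; larger asymmetry is an error.
#' @return A `section_order` (canonical orientation).
#' @export
solve_heuristic <- function(d, seed = 1L, n_starts = NULL, tol = 1e-8) {
  n <- nrow(d)
  if (n < 2L) abort("solve_heuristic: need at least 2 sections.")
  if (max(abs(d - t(d))) > tol * max(1, max(abs(d)))) {
    abort("solve_heuristic: matrix is asymmetric beyond tolerance.")
  }
  ids <- matrix_ids(d)
  dd <- rbind(cbind(unclass(d), 0), 0)   # dummy node n+1 at distance 0
  diag(dd) <- 0
  n_starts <- n_starts %||% min(n, 10L)
  withr::local_seed(seed)
  starts <- sample.int(n, n_starts)
  best_tour <- NULL; best_len <- Inf
  for (s in starts) {
    tour <- two_opt(dd, nn_tour(dd, s))
    len <- tour_len(dd, tour)
    if (len < best_len) {
      best_len <- len
      best_tour <- tour
    }
  }
  # cut the cycle at the dummy node -> open path
  pos <- which(best_tour == n + 1L)
  path <- c(best_tour[-seq_len(pos)], best_tour[seq_len(pos - 1L)])
  out <- new_section_order(canonicalize(ids[path]), best_len, "heuristic",
                           as.integer(seed))
  out$path_cost <- path_cost_of(d, out$order)
  out
}

#' Solve for the cutting order
#'
#' Dispatches to [solve_exact()] when the problem is small enough and to
#' [solve_heuristic()] otherwise.
#'
#' @param d A `dissimilarity_matrix`.
#' @param seed Seed for the heuristic.
#' @param exact_limit Largest n handled exactly.
#' @return A `section_order`.
#' @export
solve_order <- function(d, seed = 1L, exact_limit = 12L) {
  if (nrow(d) <= exact_limit) solve_exact(d, exact_limit)
  else solve_heuristic(d, seed)
}
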