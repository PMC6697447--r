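# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small simulated stack used across modules: 8 sections, dense beads
small_stack <- function() {
  cached("small_stack", {
    cfg <- sim_config(n_sections = 8, field_size = c(60, 60), seed = 5)
    slice_volume(generate_bead_volume(cfg), cfg)
  })
}

small_rendered <- function() {
  cached("small_rendered", suppressMessages(render_sections(small_stack())))
}

# all permutations of 1..n as a matrix (n! rows); fine up to n = 8
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    rest <- setdiff(seq_len(n), k)
    out[rows, 1] <- k
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

# brute-force minimum open-path cost over all permutations
brute_force_path <- function(d) {
  n <- nrow(d)
  P <- all_perms(n)
  cost <- rep(0, nrow(P))
  for (k in seq_len(n - 1L)) {
    cost <- cost + d[cbind(P[, k], P[, k + 1L])]
  }
  best <- which.min(cost)
  list(cost = cost[best], order = P[best, ])
}

# a rigid transform applied to a bead table (for invariance tests)
rigid_copy <- function(beads, theta_deg, tx, ty) {
  th <- theta_deg * pi / 180
  tibble::tibble(
    x = cos(th) * beads$x - sin(th) * beads$y + tx,
    y = sin(th) * beads$x + cos(th) * beads$y + ty,
    diameter = beads$diameter
  )
}

# synthetic banded matrix that mimics a simulator-derived dissimilarity
# matrix: entries grow with cutting-index gap, sentinel beyond max_gap
banded_matrix <- function(n, max_gap = 6L, noise = 0.1, seed = 1L,
                          sentinel = MAGSORT_SENTINEL) {
  withr::with_seed(seed, {
    m <- matrix(sentinel, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        g <- j - i
        if (g <= max_gap) {
          m[i, j] <- m[j, i] <- g + abs(rnorm(1, 0, noise * g))
        }
      }
    }
    diag(m) <- 0
    perm <- sample.int(n)
    m2 <- m[perm, perm]
    dimnames(m2) <- list(seq_len(n), seq_len(n))
    list(matrix = m2, true_order = order(perm))
  })
}
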