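#' @importFrom generics tidy glance
NULL

#' Tidy a recovered section order
#'
#' @param x A `section_order`.
#' @param ... Unused.
#' @return A tibble with `position` (1..n along the recovered path) and
#'   `section_id`.
#' @export
tidy.section_order <- function(x, ...) {
  tibble(position = seq_along(x$order), section_id = x$order)
}

#' One-row summary of a recovered section order
#'
#' @param x A `section_order`.
#' @param ... Unused.
#' @return A tibble with `n_sections`, `path_cost`, `solver`, `seed`.
#' @export
glance.section_order <- function(x, ...) {
  tibble(n_sections = length(x$order), path_cost = x$path_cost,
         solver = x$solver, seed = x$seed)
}

#' Tidy a link-cost report
#'
#' @param x A `link_cost_report`.
#' @param ... Unused.
#' @return A tibble with one row per link: `link`, `from`, `to` (section
#'   ids) and `cost`.
#' @export
tidy.link_cost_report <- function(x, ...) {
  tibble(link = seq_along(x$costs),
         from = x$proposed[-length(x$proposed)],
         to = x$proposed[-1],
         cost = x$costs)
}

#' One-row summary of a link-cost report
#'
#' @param x A `link_cost_report`.
#' @param ... Unused.
#' @return A tibble with `n_links`, `total_cost`, `max_cost`, `prop_zero`
#'   (fraction of links joining true neighbours) and `perfect`.
#' @export
glance.link_cost_report <- function(x, ...) {
  tibble(n_links = length(x$costs), total_cost = x$total,
         max_cost = max(x$costs), prop_zero = mean(x$costs == 0L),
         perfect = is_perfect(x))
}

#' Tidy a dissimilarity matrix
#'
#' @param x A `dissimilarity_matrix`.
#' @param ... Unused.
#' @return A long tibble with `section_a`, `section_b`, `dissimilarity` and
#'   `matched` (FALSE for sentinel pairs), upper triangle only.
#' @export
tidy.dissimilarity_matrix <- function(x, ...) {
  ids <- matrix_ids(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble(section_a = ids[ut[, 1]], section_b = ids[ut[, 2]],
         dissimilarity = x[ut],
         matched = x[ut] < attr(x, "sentinel"))
}
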