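#' Per-link costs of a proposed order against a ground truth
#'
#' For each consecutive pair of sections `(s, t)` in the proposed order, the
#' link cost is the absolute difference of their positions in the
#' ground-truth order, minus one: a link joining true neighbours costs 0, a
#' link that skips one section costs 1, and so on. An order of `n` sections
#' has `n - 1` links; the frequency of the costs summarizes how precise the
#' reordering is, and a total of 0 characterizes the true order or its
#' reversal.
#'
#' @param proposed A `section_order` or a vector of section ids.
#' @param truth The ground-truth order (vector of the same ids, cutting
#'   order).
#' @return An object of class `link_cost_report`: list with `costs`
#'   (integer, length n-1), `histogram` (named frequency table of costs),
#'   `total`, and the two orders.
#' @examples
#' link_costs(c(1, 2, 4, 3, 5, 6), 1:6)$costs
#' @export
link_costs <- function(proposed, truth) {
  p <- order_ids(proposed)
  truth <- order_ids(truth)
  if (length(p) < 2L) abort("link_costs: need at least 2 sections.")
  if (!setequal(p, truth) || length(p) != length(truth)) {
    abort("link_costs: proposed and ground-truth orders hold different section ids.")
  }
  pos <- match(p, truth)
  costs <- as.integer(abs(diff(pos)) - 1L)
  tab <- table(factor(costs, levels = sort(unique(costs))))
  structure(
    list(costs = costs,
         histogram = setNames(as.integer(tab), names(tab)),
         total = sum(costs),
         proposed = p, truth = truth),
    class = "link_cost_report"
  )
}

#' @export
print.link_cost_report <- function(x, ...) {
  cat(sprintf("<link_cost_report> %d links, total cost %d%s\n",
              length(x$costs), x$total,
              if (x$total == 0L) " (perfect up to reversal)" else ""))
  cat("  costs:", paste(x$costs, collapse = ","), "\n")
  invisible(x)
}

#' Is a recovered order perfect?
#'
#' `TRUE` iff the total link cost is zero, i.e. the proposed order is the
#' ground truth or its exact reversal.
#'
#' @param report A [link_costs()] report.
#' @return A logical scalar.
#' @export
is_perfect <- function(report) {
  report$total == 0L
}

#' Score one order against another
#'
#' Treats `order_b` as ground truth and scores `order_a` with the link-cost
#' metric -- e.g. cross-checking a bead-derived order against an EM-derived
#' one.
#'
#' @param order_a,order_b Orders over the same section ids.
#' @return A `link_cost_report`.
#' @export
compare_orders <- function(order_a, order_b) {
  link_costs(order_a, order_b)
}
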