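#' Configuration for the end-to-end order-retrieval pipeline
#'
#' Bundles the per-stage parameters. A single global `seed` fans out to the
#' stages by fixed offsets (simulation `seed`, matching `seed + 10`, solver
#' `seed + 20`, EM texture `seed + 30`), so any stage can be rerun in
#' isolation yet the whole run is reproducible from one integer.
#'
#' @param sim A [sim_config()].
#' @param match A [match_params()] for the bead dissimilarity.
#' @param em An [em_params()] for the EM dissimilarity.
#' @param modality `"beads"`, `"em"` or `"both"`.
#' @param exact_limit Largest n solved exactly; larger stacks use the
#'   seeded heuristic.
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), match = match_params(),
                            em = em_params(),
                            modality = c("beads", "em", "both"),
                            exact_limit = 12L, seed = 1L) {
  modality <- match.arg(modality)
  seed <- as.integer(seed)
  sim$seed <- seed
  match$seed <- seed + 10L
  match$frame_size <- match$frame_size %||% (sim$field_size / sim$pixel_size)
  em$match$seed <- seed + 10L
  structure(list(sim = sim, match = match, em = em, modality = modality,
                 exact_limit = as.integer(exact_limit), seed = seed),
            class = "pipeline_config")
}

#' Run the full order-retrieval pipeline
#'
#' Simulate a serial-section stack with hidden cutting order, render and
#' detect beads (and/or slice an EM texture volume), build the pairwise
#' dissimilarity matrix, recover the order by solving the open
#' traveling-salesman problem, and score the result against the simulator's
#' ground truth with the link-cost metric. The solver only ever sees the
#' shuffled imagery -- the ground truth is used exclusively for scoring.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every artifact (TIFFs,
#'   catalog, bead table, matrices, orders, report, the config itself) is
#'   written there.
#' @param progress Pass-through to the matrix builders.
#' @return A list of class `pipeline_result` with `beads`, `matrix`,
#'   `order`, `report` (per modality where applicable: `matrix_em`,
#'   `order_em`, `report_em`, `cross_report`), `ground_truth` and `config`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim = sim_config(n_sections = 6,
#'                                         field_size = c(40, 40)),
#'                        seed = 7)
#' res <- run_pipeline(cfg)
#' res$report$total
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  sim <- config$sim
  sliced <- stage("simulate", {
    vol <- generate_bead_volume(sim)
    slice_volume(vol, sim)
  })
  truth <- sliced$ground_truth$true_order
  res <- list(ground_truth = sliced$ground_truth, config = config)

  if (config$modality %in% c("beads", "both")) {
    rendered <- stage("render", render_sections(sliced, dir = out_dir))
    beads <- stage("detect", detect_stack(rendered))
    dmat <- stage("bead_dissimilarity",
                  build_bead_matrix(beads, config$match, progress = progress))
    ord <- stage("order", solve_order(dmat, seed = config$seed + 20L,
                                      exact_limit = config$exact_limit))
    res$beads <- beads
    res$matrix <- dmat
    res$order <- ord
    res$report <- stage("evaluate", link_costs(ord, truth))
  }

  if (config$modality %in% c("em", "both")) {
    emvol <- stage("simulate_em", generate_em_volume(sim))
    mosaics <- stage("render_em", render_em_sections(emvol, sliced))
    dmat_em <- stage("em_dissimilarity",
                     build_em_matrix(mosaics, config$em, progress = progress))
    ord_em <- stage("order_em", solve_order(dmat_em,
                                            seed = config$seed + 20L,
                                            exact_limit = config$exact_limit))
    res$matrix_em <- dmat_em
    res$order_em <- ord_em
    res$report_em <- stage("evaluate_em", link_costs(ord_em, truth))
  }
  if (config$modality == "both") {
    res$cross_report <- compare_orders(res$order, res$order_em)
  }

  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d sections (%s)\n",
              x$config$sim$n_sections, x$config$modality))
  if (!is.null(x$report)) {
    cat(sprintf("  bead order total link cost: %d\n", x$report$total))
  }
  if (!is.null(x$report_em)) {
    cat(sprintf("  EM order total link cost: %d\n", x$report_em$total))
  }
  invisible(x)
}

write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  jsonlite::write_json(
    list(modality = cfg$modality, seed = cfg$seed,
         exact_limit = cfg$exact_limit,
         sim = unclass(cfg$sim),
         match = cfg$match[!vapply(cfg$match, is.null, TRUE)]),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(res$beads)) {
    write.csv(res$beads, file.path(dir, "beads.csv"), row.names = FALSE)
  }
  if (!is.null(res$matrix)) {
    write_dissimilarity_matrix(res$matrix, file.path(dir, "dmat_beads.csv"))
    write_order(res$order, file.path(dir, "order_beads.json"))
    write_report(res$report, file.path(dir, "report_beads.json"))
  }
  if (!is.null(res$matrix_em)) {
    write_dissimilarity_matrix(res$matrix_em, file.path(dir, "dmat_em.csv"))
    write_order(res$order_em, file.path(dir, "order_em.json"))
    write_report(res$report_em, file.path(dir, "report_em.json"))
  }
  invisible(dir)
}

#' Write / read a section order as JSON
#'
#' @param order A `section_order`.
#' @param path JSON path.
#' @return `path` invisibly; `read_order()` returns the `section_order`.
#' @export
write_order <- function(order, path) {
  jsonlite::write_json(
    list(order = order$order, path_cost = order$path_cost,
         solver = order$solver, seed = order$seed),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_order
#' @export
read_order <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_section_order(x$order, x$path_cost, x$solver,
                    x$seed %||% NA_integer_)
}

#' Write a link-cost report as JSON
#'
#' @param report A `link_cost_report`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(costs = report$costs,
         histogram = as.list(report$histogram),
         total = report$total),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
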