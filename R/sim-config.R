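#' Simulation configuration for a synthetic serial-section stack
#'
#' Describes a virtual resin block laden with fluorescent fiducial beads that
#' is cut into ultrathin sections. Because the mean bead diameter (2 μm) far
#' exceeds the section thickness (50 nm), each bead reappears in dozens of
#' consecutive sections with a smoothly varying apparent diameter -- the
#' physical signal every downstream ordering stage relies on.
#'
#' @param n_sections Number of sections cut from the block (>= 2).
#' @param section_thickness Section thickness in nm (default 50).
#' @param bead_mean_diameter Mean bead diameter in μm (default 2).
#' @param bead_diameter_cv Coefficient of variation of the bead diameter
#'   distribution (lognormal; default 0.15).
#' @param bead_density Beads per μm^3 of magnetic-resin volume, or one of the
#'   preset strings `"high"` (0.010, the dense-bead regime) or `"low"`
#'   (0.002, the sparse regime that yields more ordering errors).
#' @param field_size Imaged field `c(width, height)` in μm.
#' @param pixel_size Pixel size in μm/px.
#' @param n_channels Number of fluorescent bead channels (1 or 2).
#' @param channel_assignment_prob Probability that a bead belongs to channel 1.
#' @param pose_rotation_max Maximum in-plane rotation magnitude in degrees a
#'   section can land with on the wafer (default 360, i.e. arbitrary pose).
#' @param pose_translation_max Maximum in-plane translation in μm (default 5).
#' @param noise_sd Additive Gaussian image noise (fraction of full scale).
#' @param seed Integer seed; all simulator output is reproducible given the
#'   seed and configuration.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_sections = 10, seed = 1)
#' cfg$bead_density
#' @export
sim_config <- function(n_sections = 30,
                       section_thickness = 50,
                       bead_mean_diameter = 2,
                       bead_diameter_cv = 0.15,
                       bead_density = "high",
                       field_size = c(80, 80),
                       pixel_size = 0.25,
                       n_channels = 2,
                       channel_assignment_prob = 0.5,
                       pose_rotation_max = 360,
                       pose_translation_max = 5,
                       noise_sd = 0.02,
                       seed = 1L) {
  if (is.character(bead_density)) {
    bead_density <- switch(match.arg(bead_density, c("high", "low")),
      high = 0.010,
      low  = 0.002
    )
  }
  cfg <- list(
    n_sections = as.integer(n_sections),
    section_thickness = section_thickness,
    bead_mean_diameter = bead_mean_diameter,
    bead_diameter_cv = bead_diameter_cv,
    bead_density = bead_density,
    field_size = as.numeric(field_size),
    pixel_size = pixel_size,
    n_channels = as.integer(n_channels),
    channel_assignment_prob = channel_assignment_prob,
    pose_rotation_max = pose_rotation_max,
    pose_translation_max = pose_translation_max,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_sections < 2L) {
    abort("`n_sections` must be at least 2.")
  }
  if (cfg$section_thickness <= 0) {
    abort("`section_thickness` must be positive (nm).")
  }
  # thickness is nm, diameter is um: beads must span multiple sections
  if (cfg$bead_mean_diameter * 1000 <= cfg$section_thickness) {
    abort("`bead_mean_diameter` (μm) must exceed `section_thickness` (nm converted); otherwise beads cannot span multiple sections.")
  }
  if (cfg$bead_density < 0) {
    abort("`bead_density` must be non-negative.")
  }
  if (length(cfg$field_size) != 2L || any(cfg$field_size <= 0)) {
    abort("`field_size` must be two positive lengths (μm).")
  }
  if (cfg$pixel_size <= 0) {
    abort("`pixel_size` must be positive.")
  }
  if (!cfg$n_channels %in% c(1L, 2L)) {
    abort("`n_channels` must be 1 or 2.")
  }
  if (cfg$channel_assignment_prob < 0 || cfg$channel_assignment_prob > 1) {
    abort("`channel_assignment_prob` must lie in [0, 1].")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d sections x %g nm; beads %g um (CV %g), %g /um^3\n",
              x$n_sections, x$section_thickness, x$bead_mean_diameter,
              x$bead_diameter_cv, x$bead_density))
  cat(sprintf("  field %g x %g um at %g um/px, %d channel(s), seed %d\n",
              x$field_size[1], x$field_size[2], x$pixel_size,
              x$n_channels, x$seed))
  invisible(x)
}

# section thickness in um
thickness_um <- function(cfg) cfg$section_thickness / 1000

# axial extent of the sliced block in um, with margin so beads whose spans
# straddle the first/last section are represented
block_z_range <- function(cfg) {
  margin <- cfg$bead_mean_diameter * (1 + 3 * cfg$bead_diameter_cv)
  c(-margin, cfg$n_sections * thickness_um(cfg) + margin)
}
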