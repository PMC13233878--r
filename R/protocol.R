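#' Rake and sample geometry
#'
#' Planar geometry of a square sample mounted on four multi-tine rakes.
#' The rakes pierce the sample a distance `apron` from each edge, so the
#' gauge region spanned by opposing rake lines has side
#' `side - 2 * apron`. Tines are evenly spaced along each rake line,
#' centered, with a half-spacing end margin. Tine count and diameter
#' are figure-derived defaults and configurable.
#'
#' @param side Sample edge length, mm.
#' @param apron Rake-to-edge distance, mm.
#' @param tine_diameter Tine (hole) diameter, mm.
#' @param tines_per_edge Number of tines per rake.
#' @param thickness Sample thickness, mm.
#' @param effective_width Width used to convert stress to force in the
#'   homogeneous model; defaults to the gauge length `side - 2 * apron`
#'   (the rake-spanned strip).
#' @return An object of class `rake_geometry`.
#' @examples
#' rake_geometry(thickness = 2.0)
#' @export
rake_geometry <- function(side = 5.2, apron = 1.0, tine_diameter = 0.3,
                          tines_per_edge = 5, thickness = 2.0,
                          effective_width = NULL) {
  stopifnot(side > 0, apron >= 0, tine_diameter > 0, tines_per_edge >= 1,
            thickness > 0)
  if (side <= 2 * apron) stop("side must exceed 2 * apron")
  span <- side - 2 * apron
  spacing <- span / tines_per_edge
  if (tine_diameter >= spacing)
    stop("tines do not fit: tine_diameter >= spacing within the gauge span")
  if (is.null(effective_width)) effective_width <- span
  structure(list(side = side, apron = apron, tine_diameter = tine_diameter,
                 tines_per_edge = tines_per_edge, tine_spacing = spacing,
                 thickness = thickness, effective_width = effective_width),
            class = "rake_geometry")
}

#' Gauge length of a rake geometry
#'
#' Initial inter-rake distance `side - 2 * apron`, the reference length
#' for the engineering strain definition.
#'
#' @param geom A [rake_geometry()].
#' @return Gauge length in mm.
#' @export
gauge_length <- function(geom) {
  stopifnot(inherits(geom, "rake_geometry"))
  geom$side - 2 * geom$apron
}

#' @export
print.rake_geometry <- function(x, ...) {
  cat(sprintf(
    "Rake geometry: %.2f x %.2f mm sample, apron %.2f mm, %d tines/edge (d = %.2f mm), t = %.3f mm\n",
    x$side, x$side, x$apron, x$tines_per_edge, x$tine_diameter, x$thickness))
  invisible(x)
}

#' Equi-biaxial loading protocol
#'
#' Monotone displacement ramp to `max_strain` engineering strain applied
#' simultaneously on both axes, recorded at `points_per_direction`
#' equally spaced strain levels from zero to the maximum (inclusive), for
#' `2 * points_per_direction` force values in total. Engineering strain
#' is rake displacement divided by the initial inter-rake gauge length.
#'
#' @param max_strain Target engineering strain (default 0.5).
#' @param rate Strain rate in percent per second (default 2.5); used to
#'   time-stamp the sampling instants.
#' @param points_per_direction Recorded samples per loading direction
#'   (default 25).
#' @return An object of class `loading_protocol` with the sampled strain
#'   schedule in `$strains` and matching times (s) in `$times`.
#' @export
loading_protocol <- function(max_strain = 0.5, rate = 2.5,
                             points_per_direction = 25) {
  stopifnot(max_strain > 0, rate > 0, points_per_direction >= 2)
  strains <- max_strain * (0:(points_per_direction - 1)) / (points_per_direction - 1)
  times <- strains / (rate / 100)
  structure(list(max_strain = max_strain, rate = rate,
                 points_per_direction = as.integer(points_per_direction),
                 strains = strains, times = times,
                 duration = max_strain / (rate / 100)),
            class = "loading_protocol")
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat(sprintf(
    "Equi-biaxial ramp to %.0f%% strain at %.2f %%/s; %d points/direction (n = %d)\n",
    100 * x$max_strain, x$rate, x$points_per_direction,
    2L * x$points_per_direction))
  invisible(x)
}

#' Force curve container
#'
#' A tidy record of the sampled biaxial force response: one row per
#' sampling instant and direction, axial block first. The full 50-value
#' force vector used by the calibration objective is recovered with
#' [force_vector()].
#'
#' @param displacements Rake displacements at the sampling instants, mm
#'   (one value per instant, identical for both axes under the
#'   equi-biaxial protocol).
#' @param forces_axial,forces_circ Forces in mN, one per instant.
#' @param times Sampling times in s (optional).
#' @return A data frame of class `force_curve` with columns `direction`,
#'   `time`, `displacement`, `force`.
#' @export
force_curve <- function(displacements, forces_axial, forces_circ,
                        times = NULL) {
  p <- length(displacements)
  stopifnot(length(forces_axial) == p, length(forces_circ) == p)
  if (is.unsorted(displacements)) stop("displacements must be non-decreasing")
  if (is.null(times)) times <- rep(NA_real_, p)
  out <- data.frame(
    direction = rep(c("axial", "circumferential"), each = p),
    time = rep(times, 2),
    displacement = rep(displacements, 2),
    force = c(forces_axial, forces_circ))
  class(out) <- c("force_curve", "data.frame")
  out
}

#' Extract the ordered force vector from a force curve
#'
#' @param curve A [force_curve()].
#' @return Numeric vector, axial forces first then circumferential.
#' @export
force_vector <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  c(curve$force[curve$direction == "axial"],
    curve$force[curve$direction == "circumferential"])
}

#' @export
print.force_curve <- function(x, ...) {
  p <- sum(x$direction == "axial")
  cat(sprintf("Force curve: %d points/direction, peak axial %.3g mN, peak circumferential %.3g mN\n",
              p, max(x$force[x$direction == "axial"]),
              max(x$force[x$direction == "circumferential"])))
  invisible(x)
}
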