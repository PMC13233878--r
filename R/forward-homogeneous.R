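#' Homogeneous-deformation forward model of the equi-biaxial test
#'
#' Fast analytic forward map from HGO parameters to the sampled force
#' response, assuming the gauge region deforms homogeneously: at each
#' sampled strain `eps` both in-plane stretches are `1 + eps` and the
#' force per direction is the first Piola--Kirchhoff stress times the
#' undeformed cross-section `thickness * effective_width`. Stresses in
#' kPa with lengths in mm give forces directly in mN.
#'
#' This is the default forward map for surrogate training; the finite
#' element model ([fe_forward()]) resolves the rake boundary conditions
#' when fidelity matters.
#'
#' @param params An [hgo_params()] object or length-4 numeric vector.
#' @param geom A [rake_geometry()] (supplies thickness, gauge and
#'   effective width).
#' @param protocol A [loading_protocol()].
#' @param form Energy form, see [hgo_strain_energy()].
#' @param a0 Reference fiber direction, default axial.
#' @return A [force_curve()] with `2 * points_per_direction` force values.
#' @examples
#' fc <- homogeneous_forward(hgo_params(0.12, 0.122, 6.6, 0.07),
#'                           rake_geometry(thickness = 2), loading_protocol())
#' head(fc)
#' @export
homogeneous_forward <- function(params, geom, protocol = loading_protocol(),
                                form = "standard", a0 = c(1, 0)) {
  params <- as_hgo_params(params)
  stopifnot(inherits(geom, "rake_geometry"), inherits(protocol, "loading_protocol"))
  lam <- 1 + protocol$strains
  if (any(lam <= 0)) stop("protocol produces inadmissible stretches")
  S <- hgo_plane_stress(params, lam, lam, form = form, a0 = a0)
  area <- geom$thickness * geom$effective_width   # mm^2
  L0 <- gauge_length(geom)
  force_curve(displacements = protocol$strains * L0,
              forces_axial = S$P11 * area,
              forces_circ = S$P22 * area,
              times = protocol$times)
}

# 50-vector forward map used by surrogate training and calibration:
# (C10, k1, k2, kappa) and thickness -> force vector (axial then circ).
forward_map_homogeneous <- function(theta, thickness, geom = rake_geometry(),
                                    protocol = loading_protocol(),
                                    form = "standard") {
  g <- geom
  g$thickness <- thickness
  force_vector(homogeneous_forward(as_hgo_params(theta), g, protocol, form))
}

# analytic Jacobian of the homogeneous force map wrt (C10, k1, k2, kappa),
# standard energy form, axial fibers. Rows follow the force vector
# (axial block then circumferential), columns the four parameters.
# Supplying this to the least-squares solver resolves the narrow
# C10-(k1, k2) valley that finite differencing cannot (the matrix term
# contributes ~1e-5 of the force at stiff corners of the space).
forward_jac_homogeneous <- function(theta, thickness, geom = rake_geometry(),
                                    protocol = loading_protocol()) {
  p <- as_hgo_params(theta)
  lam <- 1 + protocol$strains
  l3sq <- 1 / (lam * lam)^2
  I1 <- 2 * lam^2 + l3sq
  I4 <- lam^2
  kap <- p$kappa
  E <- kap * (I1 - 3) + (1 - 3 * kap) * (I4 - 1)
  act <- as.numeric(E > 0)
  ex <- exp(pmin(p$k2 * E^2, 250)) * act
  g <- p$k1 * E * ex                       # dU/dE
  dE_dkap <- (I1 - 3) - 3 * (I4 - 1)
  dg_dk1 <- E * ex
  dg_dk2 <- p$k1 * E^3 * ex
  dg_dkap <- p$k1 * ex * (1 + 2 * p$k2 * E^2) * dE_dkap
  # psi1 = C10 + g*kap ; psi4 = g*(1 - 3*kap)
  a <- lam - l3sq / lam                    # P11 = 2 psi1 a + 2 psi4 lam
  area <- thickness * geom$effective_width
  dP11 <- cbind(C10 = 2 * a,
                k1 = 2 * a * dg_dk1 * kap + 2 * lam * dg_dk1 * (1 - 3 * kap),
                k2 = 2 * a * dg_dk2 * kap + 2 * lam * dg_dk2 * (1 - 3 * kap),
                kappa = 2 * a * (g + kap * dg_dkap) +
                  2 * lam * (dg_dkap * (1 - 3 * kap) - 3 * g))
  dP22 <- cbind(C10 = 2 * a,               # equibiaxial: same geometric factor
                k1 = 2 * a * dg_dk1 * kap,
                k2 = 2 * a * dg_dk2 * kap,
                kappa = 2 * a * (g + kap * dg_dkap))
  rbind(dP11, dP22) * area
}
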