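#' HGO material parameters
#'
#' Container for the four constitutive parameters of the
#' Holzapfel--Gasser--Ogden (HGO) anisotropic hyperelastic model: an
#' isotropic neo-Hookean matrix term of stiffness `C10` and one
#' dispersed fiber family with stiffness `k1`, exponential nonlinearity
#' `k2` and dispersion `kappa`.
#'
#' @param C10 Matrix stiffness, kPa. Must be positive.
#' @param k1 Fiber stiffness, kPa. Non-negative.
#' @param k2 Fiber exponential nonlinearity, dimensionless. Non-negative.
#' @param kappa Fiber dispersion, dimensionless. `0` means perfectly
#'   aligned fibers, `1/3` an isotropic fiber distribution; values must
#'   lie in `[0, 1/3]`.
#'
#' @return An object of class `hgo_params` (a named list).
#' @examples
#' hgo_params(C10 = 0.12, k1 = 0.122, k2 = 6.6, kappa = 0.07)
#' @export
hgo_params <- function(C10, k1 = 0, k2 = 0, kappa = 0) {
  stopifnot(is.numeric(C10), length(C10) == 1L,
            is.numeric(k1), length(k1) == 1L,
            is.numeric(k2), length(k2) == 1L,
            is.numeric(kappa), length(kappa) == 1L)
  if (!is.finite(C10) || C10 <= 0) stop("C10 must be positive (kPa)")
  if (!is.finite(k1) || k1 < 0) stop("k1 must be non-negative (kPa)")
  if (!is.finite(k2) || k2 < 0) stop("k2 must be non-negative")
  if (!is.finite(kappa) || kappa < 0 || kappa > 1 / 3 + 1e-12)
    stop("kappa must lie in [0, 1/3]")
  structure(list(C10 = C10, k1 = k1, k2 = k2, kappa = min(kappa, 1 / 3)),
            class = "hgo_params")
}

#' @export
print.hgo_params <- function(x, ...) {
  cat("HGO parameters: C10 =", format(x$C10), "kPa, k1 =", format(x$k1),
      "kPa, k2 =", format(x$k2), ", kappa =", format(x$kappa), "\n")
  invisible(x)
}

#' Coerce a numeric vector to HGO parameters
#'
#' @param x Numeric vector of length 4, ordered `(C10, k1, k2, kappa)`,
#'   or an existing `hgo_params` object (returned unchanged).
#' @return An `hgo_params` object.
#' @export
as_hgo_params <- function(x) {
  if (inherits(x, "hgo_params")) return(x)
  stopifnot(is.numeric(x), length(x) == 4L)
  hgo_params(x[[1]], x[[2]], x[[3]], x[[4]])
}

#' Planar deformation state under incompressibility
#'
#' Describes a homogeneous deformation with principal in-plane stretches
#' `lambda1` (axial) and `lambda2` (circumferential). The through-thickness
#' stretch defaults to `1 / (lambda1 * lambda2)` so that `J = det F = 1`;
#' total and deviatoric invariants then coincide.
#'
#' @param lambda1,lambda2 In-plane stretches, dimensionless, positive.
#' @param lambda3 Thickness stretch; defaults to the incompressible value.
#' @param a0 Unit reference fiber direction in the plane, length-2 vector.
#'   Defaults to the axial axis `c(1, 0)`.
#' @return An object of class `deformation_state`.
#' @export
deformation_state <- function(lambda1, lambda2,
                              lambda3 = 1 / (lambda1 * lambda2),
                              a0 = c(1, 0)) {
  stopifnot(is.numeric(lambda1), is.numeric(lambda2), is.numeric(lambda3))
  if (any(c(lambda1, lambda2, lambda3) <= 0))
    stop("stretches must be positive")
  if (length(a0) != 2L || abs(sqrt(sum(a0^2)) - 1) > 1e-8)
    stop("a0 must be a unit vector of length 2")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 a0 = as.numeric(a0)),
            class = "deformation_state")
}

#' First and fourth invariants of a deformation state
#'
#' For a principal-stretch state with in-plane fiber direction `a0`,
#' `I1bar = lambda1^2 + lambda2^2 + lambda3^2` and
#' `I4bar = a0 . C a0` (the squared stretch along the fiber direction).
#' Under `J = 1` these equal the deviatoric invariants.
#'
#' @param state A [deformation_state()].
#' @return Named numeric vector `c(I1bar = , I4bar = )`.
#' @export
hgo_invariants <- function(state) {
  stopifnot(inherits(state, "deformation_state"))
  a <- state$a0
  I1 <- state$lambda1^2 + state$lambda2^2 + state$lambda3^2
  I4 <- a[1]^2 * state$lambda1^2 + a[2]^2 * state$lambda2^2
  c(I1bar = I1, I4bar = I4)
}

# fiber strain-like exponent argument; form switches between the standard
# GOH expression E = kappa (I1-3) + (1-3 kappa)(I4-1), squared as a whole
# in the exponent, and the squared-i4 variant that squares only (I4-1).
hgo_exponent_terms <- function(params, I1, I4, form) {
  kap <- params$kappa
  if (form == "standard") {
    E <- kap * (I1 - 3) + (1 - 3 * kap) * (I4 - 1)
    list(arg = params$k2 * pmax(E, 0)^2, E = E)
  } else {
    E <- kap * (I1 - 3) + (1 - 3 * kap) * (I4 - 1)^2
    list(arg = params$k2 * pmax(E, 0), E = E)
  }
}

#' HGO strain-energy density
#'
#' Evaluates the strain-energy density
#' \deqn{U = C_{10}(\bar I_1 - 3) + \frac{k_1}{2 k_2}\left[e^{k_2 E^2} - 1\right]}
#' with \eqn{E = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_4 - 1)} in the
#' default `"standard"` (GOH/ABAQUS) form. The `"squared-i4"` form instead
#' uses the exponent
#' \eqn{k_2[\kappa(\bar I_1-3) + (1-3\kappa)(\bar I_4-1)^2]}.
#' The fiber term is tension-only: it contributes only when the fiber
#' strain-like quantity is positive. The `k2 = 0` limit is handled by the
#' series limit `k1/2 * E^2` of the standard form.
#'
#' @param params An [hgo_params()] object.
#' @param state A [deformation_state()].
#' @param form `"standard"` (whole bracket squared in the exponent) or
#'   `"squared-i4"` (only `(I4bar - 1)` squared).
#' @return Energy density in kPa.
#' @export
hgo_strain_energy <- function(params, state, form = c("standard", "squared-i4")) {
  form <- match.arg(form)
  params <- as_hgo_params(params)
  inv <- hgo_invariants(state)
  I1 <- inv[["I1bar"]]; I4 <- inv[["I4bar"]]
  iso <- params$C10 * (I1 - 3)
  et <- hgo_exponent_terms(params, I1, I4, form)
  if (params$k1 == 0) return(unname(iso))
  fib <- if (params$k2 > 0) {
    params$k1 / (2 * params$k2) * (exp(et$arg) - 1)
  } else if (form == "standard") {
    params$k1 / 2 * pmax(et$E, 0)^2
  } else {
    params$k1 / 2 * pmax(et$E, 0)
  }
  unname(iso + fib)
}

# Scalar derivatives dU/dI1, dU/dI4 shared by all stress evaluations.
# Vectorized over I1, I4. exp argument clamped to avoid overflow in
# intermediate Newton states far outside the admissible range.
hgo_dpsi <- function(params, I1, I4, form = "standard", clamp = 250) {
  C10 <- params$C10; k1 <- params$k1; k2 <- params$k2; kap <- params$kappa
  if (form == "standard") {
    E <- kap * (I1 - 3) + (1 - 3 * kap) * (I4 - 1)
    act <- E > 0
    ex <- exp(pmin(k2 * E^2, clamp))
    g <- ifelse(act, k1 * E * ex, 0)    # dU/dE, works for k2 = 0 too
    list(dI1 = C10 + g * kap, dI4 = g * (1 - 3 * kap))
  } else {
    E <- kap * (I1 - 3) + (1 - 3 * kap) * (I4 - 1)^2
    act <- E > 0
    h <- if (k2 > 0) exp(pmin(k2 * E, clamp)) else 1
    gg <- ifelse(act, k1 / 2 * h, 0)    # dU/dE
    list(dI1 = C10 + gg * kap, dI4 = gg * (1 - 3 * kap) * 2 * (I4 - 1))
  }
}

# First Piola-Kirchhoff stress for a general in-plane deformation gradient
# under incompressible plane stress (lambda3 = 1 / det F2d, sigma33 = 0).
# Vectorized over the F components. a0 is the reference fiber direction.
# Internal: used by both the homogeneous and FE forward models.
pk1_plane <- function(params, F11, F12, F21, F22, form = "standard",
                      a0 = c(1, 0)) {
  J2 <- F11 * F22 - F12 * F21
  C11 <- F11^2 + F21^2
  C22 <- F12^2 + F22^2
  C12 <- F11 * F12 + F21 * F22
  l3sq <- 1 / J2^2
  I1 <- C11 + C22 + l3sq
  c1 <- a0[1]; s1 <- a0[2]
  I4 <- c1^2 * C11 + 2 * c1 * s1 * C12 + s1^2 * C22
  d <- hgo_dpsi(params, I1, I4, form)
  # dI1/dF = 2F - 2 J2^-2 F^-T ;  dI4/dF = 2 F a0 (x) a0
  cc <- 2 * d$dI1
  cf <- 2 * d$dI1 * l3sq / J2
  Fa1 <- F11 * c1 + F12 * s1          # F a0, row 1
  Fa2 <- F21 * c1 + F22 * s1
  q <- 2 * d$dI4
  list(P11 = cc * F11 - cf * F22 + q * Fa1 * c1,
       P12 = cc * F12 + cf * F21 + q * Fa1 * s1,
       P21 = cc * F21 + cf * F12 + q * Fa2 * c1,
       P22 = cc * F22 - cf * F11 + q * Fa2 * s1)
}

#' In-plane stresses under incompressible plane stress
#'
#' Analytic first Piola--Kirchhoff and Cauchy stresses for a homogeneous
#' biaxial deformation with principal stretches `lambda1`, `lambda2`,
#' thickness stretch `1/(lambda1 lambda2)` and zero out-of-plane Cauchy
#' stress (the hydrostatic pressure is eliminated analytically).
#' Vectorized over the stretches.
#'
#' @param params An [hgo_params()] object (or length-4 numeric vector).
#' @param lambda1,lambda2 In-plane stretches (axial, circumferential).
#' @param form Energy form, see [hgo_strain_energy()].
#' @param a0 Reference fiber direction, default axial.
#' @return A data frame of class `stress_result` with columns `lambda1`,
#'   `lambda2`, `P11`, `P22`, `sigma11`, `sigma22`, `energy` (kPa).
#' @export
hgo_plane_stress <- function(params, lambda1, lambda2,
                             form = c("standard", "squared-i4"),
                             a0 = c(1, 0)) {
  form <- match.arg(form)
  params <- as_hgo_params(params)
  stopifnot(length(lambda1) == length(lambda2))
  if (any(lambda1 <= 0) || any(lambda2 <= 0))
    stop("stretches must be positive")
  if (length(a0) != 2L || abs(sqrt(sum(a0^2)) - 1) > 1e-8)
    stop("a0 must be a unit vector of length 2")
  z <- rep(0, length(lambda1))
  P <- pk1_plane(params, lambda1, z, z, lambda2, form, a0)
  en <- vapply(seq_along(lambda1), function(i)
    hgo_strain_energy(params,
                      deformation_state(lambda1[i], lambda2[i], a0 = a0),
                      form),
    numeric(1))
  out <- data.frame(lambda1 = lambda1, lambda2 = lambda2,
                    P11 = P$P11, P22 = P$P22,
                    sigma11 = P$P11 * lambda1, sigma22 = P$P22 * lambda2,
                    energy = en)
  class(out) <- c("stress_result", "data.frame")
  out
}

#' Numerical stress oracle by central differences
#'
#' Independent check of [hgo_plane_stress()]: differentiates the strain
#' energy numerically with the incompressibility constraint
#' `lambda3 = 1/(lambda1 lambda2)` substituted, so that
#' `P11 = dU/dlambda1` and `P22 = dU/dlambda2`. Intended for tests; the
#' analytic path never calls this.
#'
#' @inheritParams hgo_plane_stress
#' @param h Relative step for the central difference (default `1e-6`).
#' @return A data frame like [hgo_plane_stress()] (without Cauchy columns
#'   recomputed; they follow from `P lambda`).
#' @export
numerical_stress_oracle <- function(params, lambda1, lambda2, h = 1e-6,
                                    form = c("standard", "squared-i4"),
                                    a0 = c(1, 0)) {
  form <- match.arg(form)
  params <- as_hgo_params(params)
  stopifnot(length(lambda1) == length(lambda2), h > 0)
  U <- function(l1, l2) hgo_strain_energy(params,
                                          deformation_state(l1, l2, a0 = a0),
                                          form)
  n <- length(lambda1)
  P11 <- P22 <- numeric(n)
  for (i in seq_len(n)) {
    h1 <- h * max(1, abs(lambda1[i]))
    h2 <- h * max(1, abs(lambda2[i]))
    P11[i] <- (U(lambda1[i] + h1, lambda2[i]) - U(lambda1[i] - h1, lambda2[i])) / (2 * h1)
    P22[i] <- (U(lambda1[i], lambda2[i] + h2) - U(lambda1[i], lambda2[i] - h2)) / (2 * h2)
  }
  data.frame(lambda1 = lambda1, lambda2 = lambda2, P11 = P11, P22 = P22,
             sigma11 = P11 * lambda1, sigma22 = P22 * lambda2)
}

#' Effective small-strain Young's modulus from the matrix stiffness
#'
#' For an incompressible neo-Hookean matrix the shear modulus is
#' `mu = 2 C10`, hence the effective Young's modulus `E = 3 mu = 6 C10`.
#'
#' @param C10 Matrix stiffness in kPa (scalar or vector).
#' @return Effective modulus in kPa.
#' @export
effective_modulus <- function(C10) {
  stopifnot(is.numeric(C10), all(C10 > 0))
  6 * C10
}
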