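# shared fixtures: reference parameter sets and small protocols

# trachea reference sample #3 (calibrated values used as ground truth)
trachea3 <- function() hgo_params(C10 = 0.12, k1 = 0.122, k2 = 6.6, kappa = 0.07)

# cohort-mean tracheal parameter set
trachea_mean <- function() hgo_params(C10 = 0.53, k1 = 0.17, k2 = 6.1, kappa = 0.08)

std_geom <- function(t = 2.0) rake_geometry(thickness = t)

# reduced protocols keep FE tests fast
short_protocol <- function(max_strain = 0.15, pts = 4)
  loading_protocol(max_strain = max_strain, points_per_direction = pts)

# random admissible parameter draw within the surrogate space
random_params <- function() {
  sp <- parameter_space()
  u <- stats::runif(5)
  x <- sp$lower + u * (sp$upper - sp$lower)
  list(params = hgo_params(x[[1]], x[[2]], x[[3]], x[[4]]), thickness = x[[5]])
}

# independent computation of the pooled NRMSE definition
nrmse_direct <- function(pred, ref) sqrt(sum((pred - ref)^2) / sum(ref^2)) * 100

# independent direct coding of the strain-energy formula (kept deliberately
# naive; used to cross-check hgo_strain_energy)
energy_direct <- function(C10, k1, k2, kappa, l1, l2, form = "standard") {
  l3 <- 1 / (l1 * l2)
  I1 <- l1^2 + l2^2 + l3^2
  I4 <- l1^2
  Eq <- if (form == "standard") {
    (kappa * (I1 - 3) + (1 - 3 * kappa) * (I4 - 1))^2
  } else {
    kappa * (I1 - 3) + (1 - 3 * kappa) * (I4 - 1)^2
  }
  C10 * (I1 - 3) + k1 / (2 * k2) * (exp(k2 * Eq) - 1)
}
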