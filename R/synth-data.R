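#' Force-dependent measurement noise model
#'
#' Additive Gaussian noise whose standard deviation is a floor plus a
#' fraction of the true force magnitude:
#' `sd(F) = sd_floor + prop_frac * |F|`. The defaults (5 mN floor, 1%
#' proportional) make readings below 30 mN noise-dominated while large
#' forces stay proportionally accurate, matching the reliability tiers
#' of the weighting scheme.
#'
#' @param sd_floor Noise floor, mN.
#' @param prop_frac Proportional standard-deviation fraction.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sd_floor = 5, prop_frac = 0.01) {
  stopifnot(sd_floor >= 0, prop_frac >= 0)
  structure(list(sd_floor = sd_floor, prop_frac = prop_frac),
            class = "noise_model")
}

noise_sd <- function(noise, force) noise$sd_floor + noise$prop_frac * abs(force)

apply_noise <- function(noise, force) {
  if (noise$sd_floor == 0 && noise$prop_frac == 0) return(force)
  force + stats::rnorm(length(force), 0, noise_sd(noise, force))
}

#' Synthesize one biaxial experiment file
#'
#' Emulates a recorded test: 10 preconditioning cycles (triangular
#' up-down ramps at 95% amplitude -- present so cycle extraction sees
#' realistic input; no softening is modeled) followed by the measurement
#' ramp to full strain, densely sampled in time. Forces come from the
#' homogeneous forward model; optional noise is added per sample. A JSON
#' sidecar stores the ground truth: generating parameters, thickness,
#' the noiseless protocol-sampled force curve and the true cycle
#' boundaries.
#'
#' @param params [hgo_params()] or length-4 vector; must lie within the
#'   calibration bounds.
#' @param geom A [rake_geometry()] (supplies the thickness).
#' @param protocol A [loading_protocol()].
#' @param noise A [noise_model()]; use `noise_model(0, 0)` for a
#'   noiseless record.
#' @param seed Integer seed for the noise draws.
#' @param path Output CSV path; the sidecar takes `<path>.json`.
#' @param n_precondition Number of preconditioning cycles (default 10).
#' @param dt Sampling interval of the dense record, s (default 0.4).
#' @param region Region label stored in the sidecar.
#' @return The path, invisibly; attributes `sidecar` gives the JSON path.
#' @export
synthesize_experiment <- function(params, geom, protocol = loading_protocol(),
                                  noise = noise_model(), seed = 1L,
                                  path = tempfile(fileext = ".csv"),
                                  n_precondition = 10L, dt = 0.4,
                                  region = NA_character_) {
  params <- as_hgo_params(params)
  stopifnot(inherits(geom, "rake_geometry"), inherits(protocol, "loading_protocol"),
            inherits(noise, "noise_model"), n_precondition >= 0, dt > 0)
  dur <- protocol$duration
  ramp_n <- max(2L, ceiling(dur / dt))
  # one triangular cycle at amplitude `amp` (fraction of max strain)
  cycle_strain <- function(amp) {
    up <- seq(0, amp * protocol$max_strain, length.out = ramp_n + 1L)
    c(up, rev(up[-length(up)])[-ramp_n])   # up then down, open end
  }
  # measurement ramp carries the protocol's sampling strains exactly, so
  # resampling a noiseless record is an identity
  ramp <- sort(c(seq(0, protocol$max_strain, length.out = ramp_n + 1L),
                 protocol$strains))
  ramp <- ramp[c(TRUE, diff(ramp) > 1e-12)]   # drop float-level duplicates
  pre_strains <- rep(cycle_strain(0.95), n_precondition)
  strains <- c(pre_strains, ramp)
  t0 <- if (n_precondition > 0) length(pre_strains) * dt else 0
  times <- c(seq_len(length(pre_strains)) * dt - dt,
             t0 + ramp / (protocol$rate / 100))
  nrec <- length(strains)
  L0 <- gauge_length(geom)
  lam <- 1 + strains
  S <- hgo_plane_stress(params, lam, lam)
  area <- geom$thickness * geom$effective_width
  Fax <- S$P11 * area
  Fci <- S$P22 * area
  noisy <- withr_seed(seed, {
    list(ax = apply_noise(noise, Fax), ci = apply_noise(noise, Fci))
  })
  d <- data.frame(time = times,
                  disp_axial = strains * L0, disp_circ = strains * L0,
                  force_axial = noisy$ax, force_circ = noisy$ci)
  rec <- structure(list(data = d, thickness = geom$thickness, region = region,
                        sample_id = basename(path), cycles = NULL),
                   class = "biaxial_record")
  write_biaxial_csv(rec, path)
  # ground truth sidecar
  truth_curve <- force_vector(homogeneous_forward(params, geom, protocol))
  cyc_len <- length(cycle_strain(0.95))
  boundaries <- if (n_precondition > 0)
    cumsum(rep(cyc_len, n_precondition)) else integer(0)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    params = unclass(params), thickness = geom$thickness,
    region = region, seed = seed,
    noise = unclass(noise), n_precondition = n_precondition,
    cycle_boundaries = boundaries,
    noiseless_forces = truth_curve,
    protocol = list(max_strain = protocol$max_strain, rate = protocol$rate,
                    points_per_direction = protocol$points_per_direction)),
    sidecar, digits = NA, auto_unbox = TRUE)
  attr(path, "sidecar") <- sidecar
  invisible(path)
}

#' Cohort specification for synthetic studies
#'
#' Per-region parameter means and standard deviations emulating the
#' measured airway cohort: trachea `C10` 0.53 +/- 0.25 kPa, `k1`
#' 0.17 +/- 0.30 kPa, `k2` 6.1 +/- 2.0, `kappa` 0.08 +/- 0.01; left
#' bronchus 0.60 +/- 0.22, 0.17 +/- 0.32, 5.7 +/- 2.7, 0.07 +/- 0.03;
#' right bronchus 0.46 +/- 0.13, 0.13 +/- 0.23, 5.0 +/- 2.0,
#' 0.07 +/- 0.03. Draws are truncated to the surrogate training space
#' so every synthetic sample is calibratable there; thickness is uniform
#' in 1.24--2.84 mm.
#'
#' @param regions Named list of lists with `mean` and `sd` vectors
#'   (`C10, k1, k2, kappa`).
#' @param n_per_region Samples per region (named or single number).
#' @param thickness_range Length-2 thickness bounds, mm.
#' @param space [parameter_space()] used to truncate the draws.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(
    regions = list(
      trachea = list(mean = c(C10 = 0.53, k1 = 0.17, k2 = 6.1, kappa = 0.08),
                     sd = c(C10 = 0.25, k1 = 0.30, k2 = 2.0, kappa = 0.01)),
      left_bronchus = list(mean = c(C10 = 0.60, k1 = 0.17, k2 = 5.7, kappa = 0.07),
                           sd = c(C10 = 0.22, k1 = 0.32, k2 = 2.7, kappa = 0.03)),
      right_bronchus = list(mean = c(C10 = 0.46, k1 = 0.13, k2 = 5.0, kappa = 0.07),
                            sd = c(C10 = 0.13, k1 = 0.23, k2 = 2.0, kappa = 0.03))),
    n_per_region = c(trachea = 16L, left_bronchus = 15L, right_bronchus = 15L),
    thickness_range = c(1.24, 2.84),
    space = parameter_space(), seed = 1L) {
  stopifnot(length(regions) >= 1, all(thickness_range > 0),
            thickness_range[1] < thickness_range[2])
  if (length(n_per_region) == 1L)
    n_per_region <- stats::setNames(rep(as.integer(n_per_region), length(regions)),
                                    names(regions))
  for (rg in regions)
    stopifnot(all(c("C10", "k1", "k2", "kappa") %in% names(rg$mean)),
              all(rg$sd >= 0))
  structure(list(regions = regions, n_per_region = n_per_region,
                 thickness_range = thickness_range, space = space,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated-normal draw by rejection within [lo, hi]; warns when the
# acceptance rate drops below 50%
rtruncnorm_vec <- function(n, mean, sd, lo, hi, label = "") {
  if (all(sd == 0)) return(matrix(rep(pmin(pmax(mean, lo), hi), each = n), n))
  out <- matrix(NA_real_, n, length(mean))
  total <- 0L; accepted <- 0L
  for (j in seq_along(mean)) {
    got <- 0L
    while (got < n) {
      m <- max(n - got, 8L)
      x <- stats::rnorm(m, mean[j], sd[j])
      total <- total + m
      okx <- x[x >= lo[j] & x <= hi[j]]
      accepted <- accepted + length(okx)
      take <- min(length(okx), n - got)
      if (take > 0) out[got + seq_len(take), j] <- okx[seq_len(take)]
      got <- got + take
      if (total > 10000L * n) stop("truncation bounds reject nearly all draws")
    }
  }
  if (accepted < total / 2)
    warning(sprintf("truncation rejected >50%% of parameter draws%s",
                    if (nzchar(label)) paste0(" for ", label) else ""))
  out
}

#' Generate a synthetic cohort of experiment files
#'
#' Draws per-region HGO parameters from truncated normal distributions,
#' uniform thicknesses, and writes one experiment CSV (plus ground-truth
#' sidecar) per sample together with a `manifest.csv` mapping file names
#' to the generating parameters.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if missing).
#' @param protocol A [loading_protocol()].
#' @param noise A [noise_model()].
#' @param geom Base [rake_geometry()] (thickness is overridden per sample).
#' @return The manifest as a data frame (invisibly); written to
#'   `dir/manifest.csv`.
#' @export
generate_cohort <- function(spec, dir, protocol = loading_protocol(),
                            noise = noise_model(), geom = rake_geometry()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lo <- spec$space$lower[1:4]; hi <- spec$space$upper[1:4]
  rows <- list()
  k <- 0L
  for (rg in names(spec$regions)) {
    n <- spec$n_per_region[[rg]]
    mu <- spec$regions[[rg]]$mean; sdv <- spec$regions[[rg]]$sd
    draws <- withr_seed(spec$seed + match(rg, names(spec$regions)), {
      th <- stats::runif(n, spec$thickness_range[1], spec$thickness_range[2])
      P <- rtruncnorm_vec(n, mu, sdv, lo, hi, label = rg)
      list(P = P, th = th)
    })
    for (i in seq_len(n)) {
      k <- k + 1L
      fname <- sprintf("%s_%02d.csv", rg, i)
      g <- geom; g$thickness <- draws$th[i]
      synthesize_experiment(draws$P[i, ], g, protocol, noise,
                            seed = spec$seed * 10000L + k,
                            path = file.path(dir, fname), region = rg)
      rows[[k]] <- data.frame(file = fname, region = rg,
                              C10 = draws$P[i, 1], k1 = draws$P[i, 2],
                              k2 = draws$P[i, 3], kappa = draws$P[i, 4],
                              thickness = draws$th[i])
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
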