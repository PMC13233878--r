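#' Column dialect for biaxial test exports
#'
#' Describes how to read a delimited biaxial record: column names for
#' time, per-axis displacement and force, the delimiter, and the units
#' used in the file. Units are normalized to s / mm / mN on read.
#'
#' @param time,disp_axial,disp_circ,force_axial,force_circ Column names.
#' @param sep Field delimiter.
#' @param force_unit `"mN"` or `"N"`.
#' @param disp_unit `"mm"` or `"m"`.
#' @return A list of class `biaxial_dialect`.
#' @export
biaxial_dialect <- function(time = "time_s",
                            disp_axial = "disp_axial_mm",
                            disp_circ = "disp_circ_mm",
                            force_axial = "force_axial_mN",
                            force_circ = "force_circ_mN",
                            sep = ",", force_unit = c("mN", "N"),
                            disp_unit = c("mm", "m")) {
  structure(list(time = time, disp_axial = disp_axial, disp_circ = disp_circ,
                 force_axial = force_axial, force_circ = force_circ,
                 sep = sep, force_unit = match.arg(force_unit),
                 disp_unit = match.arg(disp_unit)),
            class = "biaxial_dialect")
}

#' Read a biaxial test record from delimited text
#'
#' @param path File path.
#' @param dialect A [biaxial_dialect()] describing the column map and units.
#' @param thickness Specimen thickness in mm (may also be supplied later).
#' @param region Optional region label (e.g. `"trachea"`).
#' @param sample_id Optional sample identifier.
#' @return An object of class `biaxial_record`: `$data` (data frame with
#'   columns `time`, `disp_axial`, `disp_circ`, `force_axial`,
#'   `force_circ`, normalized units), plus metadata fields.
#' @export
read_biaxial_csv <- function(path, dialect = biaxial_dialect(),
                             thickness = NA_real_, region = NA_character_,
                             sample_id = NA_character_) {
  stopifnot(inherits(dialect, "biaxial_dialect"))
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- unlist(dialect[c("time", "disp_axial", "disp_circ",
                           "force_axial", "force_circ")])
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  d <- data.frame(time = raw[[dialect$time]],
                  disp_axial = raw[[dialect$disp_axial]],
                  disp_circ = raw[[dialect$disp_circ]],
                  force_axial = raw[[dialect$force_axial]],
                  force_circ = raw[[dialect$force_circ]])
  if (any(!is.finite(as.matrix(d)))) stop("non-finite values in record")
  if (is.unsorted(d$time, strictly = TRUE))
    stop("time must be strictly increasing")
  if (dialect$force_unit == "N") {
    d$force_axial <- d$force_axial * 1000
    d$force_circ <- d$force_circ * 1000
  }
  if (dialect$disp_unit == "m") {
    d$disp_axial <- d$disp_axial * 1000
    d$disp_circ <- d$disp_circ * 1000
  }
  structure(list(data = d, thickness = thickness, region = region,
                 sample_id = sample_id, cycles = NULL),
            class = "biaxial_record")
}

#' Write a biaxial record in the package's CSV dialect
#'
#' @param record A `biaxial_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biaxial_csv <- function(record, path) {
  stopifnot(inherits(record, "biaxial_record"))
  d <- record$data
  names(d) <- c("time_s", "disp_axial_mm", "disp_circ_mm",
                "force_axial_mN", "force_circ_mN")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.biaxial_record <- function(x, ...) {
  cat(sprintf("Biaxial record: %d samples over %.1f s, t = %s mm, region = %s\n",
              nrow(x$data), diff(range(x$data$time)),
              format(x$thickness), x$region))
  invisible(x)
}

# cycle segmentation: a loading cycle ends when displacement returns
# below `frac` of its running peak. A cycle starts at the minimum-
# displacement row of the low plateau preceding its rise (latest such
# row on ties), so the zero-displacement sample belongs to its cycle.
detect_cycles <- function(disp, frac = 0.02) {
  peak <- max(disp)
  low <- disp <= frac * peak
  n <- length(disp)
  starts <- integer(0); ends <- integer(0)
  in_cycle <- FALSE
  run_start <- 1L
  for (i in seq_len(n)) {
    if (!in_cycle && !low[i]) {
      run <- run_start:max(run_start, i - 1L)
      cand <- run[disp[run] <= min(disp[run]) + 1e-12]
      starts <- c(starts, cand[length(cand)])
      in_cycle <- TRUE
    } else if (in_cycle && low[i]) {
      ends <- c(ends, i)
      in_cycle <- FALSE
      run_start <- i
    }
  }
  if (in_cycle) ends <- c(ends, n)
  cbind(start = starts, end = ends)
}

#' Isolate the recorded test cycle after preconditioning
#'
#' Splits the record into loading cycles (displacement rising from and
#' returning to below 2% of its peak) and keeps the final one -- the
#' measurement ramp recorded after the preconditioning cycles.
#'
#' @param record A `biaxial_record`.
#' @param n_precondition Number of preconditioning cycles expected before
#'   the test cycle (default 10). With `n_precondition = 0` and a
#'   single-ramp record the record is returned unchanged.
#' @return A `biaxial_record` containing only the final cycle, with time
#'   rebased to start at zero.
#' @export
extract_test_cycle <- function(record, n_precondition = 10) {
  stopifnot(inherits(record, "biaxial_record"), n_precondition >= 0)
  d <- record$data
  cyc <- detect_cycles(pmax(d$disp_axial, d$disp_circ))
  if (nrow(cyc) < n_precondition + 1)
    stop(sprintf("record has %d cycles; need at least %d (preconditioning + test)",
                 nrow(cyc), n_precondition + 1))
  if (n_precondition == 0 && nrow(cyc) == 1) return(record)
  keep <- cyc[nrow(cyc), ]
  out <- record
  out$data <- d[keep["start"]:keep["end"], , drop = FALSE]
  out$data$time <- out$data$time - out$data$time[1]
  rownames(out$data) <- NULL
  out$cycles <- cyc
  out
}

#' Resample a record onto the 50-point protocol
#'
#' Linearly interpolates each direction's force onto the protocol's
#' sampling displacements (strain times gauge length), producing the
#' axial-first force vector consumed by the calibration objective.
#' Displacement-based interpolation makes the result independent of the
#' recorded rate.
#'
#' @param record A `biaxial_record` spanning the full ramp (use
#'   [extract_test_cycle()] first for multi-cycle records).
#' @param geom A [rake_geometry()] giving the gauge length.
#' @param protocol A [loading_protocol()].
#' @return A [force_curve()].
#' @export
resample_to_protocol <- function(record, geom, protocol = loading_protocol()) {
  stopifnot(inherits(record, "biaxial_record"), inherits(geom, "rake_geometry"),
            inherits(protocol, "loading_protocol"))
  L0 <- gauge_length(geom)
  targets <- protocol$strains * L0
  d <- record$data
  # use the loading branch up to peak displacement
  up_a <- seq_len(which.max(d$disp_axial))
  up_c <- seq_len(which.max(d$disp_circ))
  if (max(d$disp_axial) < max(targets) - 1e-9 ||
      max(d$disp_circ) < max(targets) - 1e-9)
    stop("record does not span the full protocol ramp")
  # rule = 2 extends constantly below the record's first displacement
  # (the zero-displacement sample of records that begin marginally above 0)
  fa <- stats::approx(d$disp_axial[up_a], d$force_axial[up_a], xout = targets,
                      ties = mean, rule = 2)$y
  fc <- stats::approx(d$disp_circ[up_c], d$force_circ[up_c], xout = targets,
                      ties = mean, rule = 2)$y
  force_curve(displacements = targets, forces_axial = fa, forces_circ = fc,
              times = protocol$times)
}

#' Convert a force curve to engineering stress--strain
#'
#' First Piola--Kirchhoff (engineering) stress is force divided by the
#' undeformed cross-section `thickness * effective width`; engineering
#' strain is displacement divided by the gauge length. With force in mN
#' and lengths in mm the stress is in kPa.
#'
#' @param curve A [force_curve()].
#' @param geom A [rake_geometry()].
#' @return A data frame of class `stress_strain_curve` with columns
#'   `direction`, `strain`, `stress`.
#' @export
to_stress_strain <- function(curve, geom) {
  stopifnot(inherits(curve, "force_curve"), inherits(geom, "rake_geometry"))
  if (geom$thickness <= 0) stop("thickness must be positive")
  area <- geom$thickness * geom$effective_width
  out <- data.frame(direction = curve$direction,
                    strain = curve$displacement / gauge_length(geom),
                    stress = curve$force / area)
  class(out) <- c("stress_strain_curve", "data.frame")
  out
}

# slope and R^2 of a least-squares line through (x, y)
linfit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  res <- y - my - slope * (x - mx)
  syy <- sum((y - my)^2)
  r2 <- if (syy < 1e-24) NA_real_ else 1 - sum(res^2) / syy
  c(slope = slope, r2 = r2, sse = sum(res^2))
}

#' Initial and ultimate moduli from a bilinear stress--strain curve
#'
#' Fits the characteristic bilinear response of strain-stiffening
#' tissue by a least-squares change-point segmentation: for every
#' admissible break index the curve is split into a low-strain and a
#' terminal window (each at least `min_pts` points, sharing the break
#' point) fitted by straight lines, and the break minimizing the total
#' squared error is selected. The initial modulus is the low-window
#' slope and the ultimate modulus the terminal-window slope; each
#' window's fit must reach `R^2 >=` `r2_min`, otherwise that modulus is
#' `NA` and the result is flagged. A perfectly straight curve yields
#' identical moduli (any break fits exactly).
#'
#' @param curve A `stress_strain_curve` (one direction) or a data frame
#'   with `strain` and `stress` columns in monotone loading order.
#' @param r2_min Minimum per-window fit R-squared (default 0.9).
#' @param min_pts Minimum points per window (default 5).
#' @return A list with `initial`, `ultimate` (kPa), the fitted `windows`
#'   (row index ranges), per-window `r2`, and `flagged`.
#' @export
bilinear_moduli <- function(curve, r2_min = 0.9, min_pts = 5) {
  stopifnot(all(c("strain", "stress") %in% names(curve)))
  strain <- curve$strain; stress <- curve$stress
  if (length(unique(curve$direction)) > 1)
    stop("supply a single direction; split the curve first")
  if (is.unsorted(strain)) stop("strain must be in monotone loading order")
  n <- length(strain)
  if (n < 2 * min_pts - 1)
    stop(sprintf("need at least %d points for two %d-point windows",
                 2 * min_pts - 1, min_pts))
  breaks <- seq(min_pts, n - min_pts + 1L)
  best <- NULL
  for (k in breaks) {
    lo <- linfit(strain[1:k], stress[1:k])
    hi <- linfit(strain[k:n], stress[k:n])
    # scale-free quality: the worse of the two per-window R^2 values (a
    # flat window fits a line perfectly and counts as 1). Maximizing the
    # minimum balances the regimes, so the huge terminal stresses do not
    # drown out the low-strain window
    q <- min(if (is.na(lo[["r2"]])) 1 else lo[["r2"]],
             if (is.na(hi[["r2"]])) 1 else hi[["r2"]])
    if (is.null(best) || q > best$q + 1e-12)
      best <- list(k = k, lo = lo, hi = hi, q = q)
  }
  ok_lo <- is.na(best$lo[["r2"]]) || best$lo[["r2"]] >= r2_min
  ok_hi <- is.na(best$hi[["r2"]]) || best$hi[["r2"]] >= r2_min
  list(initial = if (ok_lo) best$lo[["slope"]] else NA_real_,
       ultimate = if (ok_hi) best$hi[["slope"]] else NA_real_,
       windows = list(initial = c(from = 1L, to = best$k),
                      ultimate = c(from = best$k, to = n)),
       r2 = c(initial = unname(best$lo[["r2"]]),
              ultimate = unname(best$hi[["r2"]])),
       flagged = !ok_lo || !ok_hi)
}
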