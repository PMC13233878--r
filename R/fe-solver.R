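# Total-Lagrangian plane-stress membrane solver for quadratic triangles.
# Incompressibility is condensed analytically (lambda3 = 1/det F2d, zero
# out-of-plane Cauchy stress via pressure elimination), so the only
# unknowns are the in-plane displacements.

# 3-point Gauss rule on the reference triangle (degree 2, exact for the
# TRI6 stiffness of an affine element)
.tri6_gauss <- list(pts = rbind(c(1 / 6, 1 / 6), c(2 / 3, 1 / 6), c(1 / 6, 2 / 3)),
                    w = rep(1 / 6, 3))

# shape-function derivatives wrt (L1, L2) with L3 = 1 - L1 - L2
tri6_dshape <- function(L1, L2) {
  L3 <- 1 - L1 - L2
  list(dxi  = c(4 * L1 - 1, 0, -(4 * L3 - 1), 4 * L2, -4 * L2, 4 * (L3 - L1)),
       deta = c(0, 4 * L2 - 1, -(4 * L3 - 1), 4 * L1, 4 * (L3 - L2), -4 * L1))
}

# per-Gauss-point reference gradients, weights, scatter indices and the
# constant shape-gradient products used by the tangent assembly
fe_precompute <- function(mesh) {
  conn <- mesh$conn; ne <- nrow(conn)
  Xe <- matrix(mesh$nodes[conn, 1], ne, 6)
  Ye <- matrix(mesh$nodes[conn, 2], ne, 6)
  gp <- lapply(1:3, function(g) {
    d <- tri6_dshape(.tri6_gauss$pts[g, 1], .tri6_gauss$pts[g, 2])
    J11 <- c(Xe %*% d$dxi);  J12 <- c(Ye %*% d$dxi)
    J21 <- c(Xe %*% d$deta); J22 <- c(Ye %*% d$deta)
    detJ <- J11 * J22 - J12 * J21
    if (any(detJ <= 0)) stop("degenerate element in mesh (non-positive Jacobian)")
    dNx <- matrix(0, ne, 6); dNy <- matrix(0, ne, 6)
    for (a in 1:6) {
      dNx[, a] <- ( J22 * d$dxi[a] - J12 * d$deta[a]) / detJ
      dNy[, a] <- (-J21 * d$dxi[a] + J11 * d$deta[a]) / detJ
    }
    dN <- list(dNx, dNy)
    G <- lapply(1:2, function(k) lapply(1:2, function(l) {
      m <- matrix(0, ne, 36)
      cc <- 0
      for (b in 1:6) for (a in 1:6) {
        cc <- cc + 1
        m[, cc] <- dN[[k]][, a] * dN[[l]][, b]
      }
      m
    }))
    list(dNx = dNx, dNy = dNy, w = .tri6_gauss$w[g] * detJ, G = G)
  })
  dofs <- matrix(0L, ne, 12)
  dofs[, seq(1, 11, 2)] <- 2L * conn - 1L
  dofs[, seq(2, 12, 2)] <- 2L * conn
  list(gp = gp, dofs = dofs,
       rows = as.vector(dofs[, rep(1:12, times = 12)]),
       cols = as.vector(dofs[, rep(1:12, each = 12)]),
       ne = ne, ndof = 2L * nrow(mesh$nodes), conn = conn)
}

fe_def_grad <- function(p, UX, UY) {
  list(F11 = 1 + rowSums(UX * p$dNx), F12 = rowSums(UX * p$dNy),
       F21 = rowSums(UY * p$dNx),     F22 = 1 + rowSums(UY * p$dNy))
}

# assembled internal force vector
fe_internal_force <- function(pc, u, params, thickness, form = "standard",
                              a0 = c(1, 0)) {
  conn <- pc$conn; ne <- pc$ne
  UX <- matrix(u[2 * conn - 1], ne, 6)
  UY <- matrix(u[2 * conn], ne, 6)
  FE <- matrix(0, ne, 12)
  for (g in 1:3) {
    p <- pc$gp[[g]]
    Fg <- fe_def_grad(p, UX, UY)
    P <- pk1_plane(params, Fg$F11, Fg$F12, Fg$F21, Fg$F22, form, a0)
    wt <- p$w * thickness
    for (a in 1:6) {
      FE[, 2 * a - 1] <- FE[, 2 * a - 1] + (P$P11 * p$dNx[, a] + P$P12 * p$dNy[, a]) * wt
      FE[, 2 * a]     <- FE[, 2 * a]     + (P$P21 * p$dNx[, a] + P$P22 * p$dNy[, a]) * wt
    }
  }
  ag <- rowsum(as.vector(FE), as.vector(pc$dofs))
  fint <- numeric(pc$ndof)
  fint[as.integer(rownames(ag))] <- ag[, 1]
  fint
}

# consistent tangent by central differencing of the PK1 stress wrt F at
# each Gauss point (cheap: the material law is evaluated vectorized)
fe_tangent <- function(pc, u, params, thickness, form = "standard",
                       a0 = c(1, 0), h = 1e-6) {
  conn <- pc$conn; ne <- pc$ne
  UX <- matrix(u[2 * conn - 1], ne, 6)
  UY <- matrix(u[2 * conn], ne, 6)
  Kel <- matrix(0, ne, 144)
  comps <- c("F11", "F12", "F21", "F22")
  for (g in 1:3) {
    p <- pc$gp[[g]]
    Fg <- fe_def_grad(p, UX, UY)
    wt <- p$w * thickness
    A <- vector("list", 16)     # A[(ik-1)*4 + jl] = dP_ik/dF_jl * wt
    for (jl in 1:4) {
      Fp <- Fg; Fp[[comps[jl]]] <- Fp[[comps[jl]]] + h
      Fm <- Fg; Fm[[comps[jl]]] <- Fm[[comps[jl]]] - h
      Pp <- pk1_plane(params, Fp$F11, Fp$F12, Fp$F21, Fp$F22, form, a0)
      Pm <- pk1_plane(params, Fm$F11, Fm$F12, Fm$F21, Fm$F22, form, a0)
      for (ik in 1:4)
        A[[(ik - 1) * 4 + jl]] <- (Pp[[ik]] - Pm[[ik]]) * (wt / (2 * h))
    }
    for (i in 1:2) for (j in 1:2) {
      blk <- matrix(0, ne, 36)
      for (k in 1:2) for (l in 1:2) {
        ik <- (i - 1) * 2 + k; jl <- (j - 1) * 2 + l
        blk <- blk + A[[(ik - 1) * 4 + jl]] * p$G[[k]][[l]]
      }
      cc <- 0
      for (b in 1:6) for (a in 1:6) {
        cc <- cc + 1
        col <- (2 * (b - 1) + j - 1) * 12 + 2 * (a - 1) + i
        Kel[, col] <- Kel[, col] + blk[, cc]
      }
    }
  }
  Matrix::sparseMatrix(i = pc$rows, j = pc$cols, x = as.vector(Kel),
                       dims = c(pc$ndof, pc$ndof))
}

# Dirichlet data for the two mesh kinds at full load
fe_boundary <- function(mesh, dmax) {
  fixed <- c(2L * mesh$left - 1L, 2L * mesh$bottom)
  vals <- rep(0, length(fixed))
  if (mesh$kind == "rake") {
    for (h in seq_along(mesh$hole_nodes)) {
      hn <- mesh$hole_nodes[[h]]
      if (mesh$which_dir[h] == 2L) {          # top rake: uy driven, ux held
        fixed <- c(fixed, 2L * hn, 2L * hn - 1L)
        vals <- c(vals, rep(dmax, length(hn)), rep(0, length(hn)))
      } else {                                 # right rake: ux driven, uy held
        fixed <- c(fixed, 2L * hn - 1L, 2L * hn)
        vals <- c(vals, rep(dmax, length(hn)), rep(0, length(hn)))
      }
    }
    ax_dofs <- unlist(lapply(which(mesh$which_dir == 1L),
                             function(h) 2L * mesh$hole_nodes[[h]] - 1L))
    ci_dofs <- unlist(lapply(which(mesh$which_dir == 2L),
                             function(h) 2L * mesh$hole_nodes[[h]]))
  } else {
    fixed <- c(fixed, 2L * mesh$right - 1L, 2L * mesh$top)
    vals <- c(vals, rep(dmax, length(mesh$right)), rep(dmax, length(mesh$top)))
    ax_dofs <- 2L * mesh$right - 1L
    ci_dofs <- 2L * mesh$top
  }
  keep <- !duplicated(fixed)
  list(fixed = fixed[keep], vals = vals[keep],
       ax_dofs = ax_dofs, ci_dofs = ci_dofs)
}

#' Finite element forward model of the biaxial test
#'
#' Incremental total-Lagrangian Newton solution of the quarter-symmetry
#' plane-stress membrane model. The prescribed rake (or edge)
#' displacement is ramped through the protocol's sampling instants; at
#' each converged instant the reaction force is summed over the driven
#' degrees of freedom and doubled for quarter symmetry. Newton uses a
#' backtracking line search on the residual norm, factorization reuse,
#' and adaptive load-step bisection; divergence is reported with the
#' failing load factor.
#'
#' @param mesh A `quarter_mesh` from [build_quarter_mesh()] or
#'   [build_square_mesh()].
#' @param params An [hgo_params()] object.
#' @param protocol A [loading_protocol()]; its sampled strains set both
#'   the load steps and the reported curve.
#' @param form Energy form, see [hgo_strain_energy()].
#' @param a0 Reference fiber direction.
#' @param tol Residual 2-norm convergence tolerance (mN).
#' @param max_iter Newton iterations per load level.
#' @param fields If `TRUE` (default) return nodal displacements and
#'   element Green--Lagrange strains at full load.
#' @return An object of class `fe_result`: `curve` (a [force_curve()]),
#'   and, with `fields = TRUE`, `u` (nodes x 2 displacements, mm) and
#'   `strain` (elements x 3 Green strain components E11, E22, E12 plus
#'   magnitude, Gauss-point averaged).
#' @export
fe_forward <- function(mesh, params, protocol = loading_protocol(),
                       form = "standard", a0 = c(1, 0),
                       tol = 1e-6, max_iter = 40, fields = TRUE) {
  stopifnot(inherits(mesh, "quarter_mesh"), inherits(protocol, "loading_protocol"))
  params <- as_hgo_params(params)
  thickness <- mesh$geom$thickness
  dmax_half <- protocol$max_strain * mesh$gauge_half  # per-rake, quarter model
  pc <- fe_precompute(mesh)
  bc <- fe_boundary(mesh, dmax_half)
  free <- setdiff(seq_len(pc$ndof), bc$fixed)

  lam_levels <- protocol$strains / protocol$max_strain  # load factors in (0, 1]
  lam_levels <- lam_levels[lam_levels > 0]
  u <- numeric(pc$ndof)
  f_ax <- f_ci <- numeric(length(lam_levels))
  lam_done <- 0
  for (s in seq_along(lam_levels)) {
    lam_target <- lam_levels[s]
    dlam <- lam_target - lam_done
    while (lam_done < lam_target - 1e-12) {
      lam_try <- min(lam_done + dlam, lam_target)
      u_try <- u
      u_try[bc$fixed] <- lam_try * bc$vals
      ok <- FALSE
      LU <- NULL
      rn_prev <- Inf
      for (it in seq_len(max_iter)) {
        r <- fe_internal_force(pc, u_try, params, thickness, form, a0)[free]
        rn <- sqrt(sum(r^2))
        if (is.finite(rn) && rn < tol) { ok <- TRUE; break }
        if (!is.finite(rn)) break
        if (is.null(LU) || rn > 0.5 * rn_prev) {
          K <- fe_tangent(pc, u_try, params, thickness, form, a0)
          LU <- tryCatch(Matrix::lu(K[free, free]), error = function(e) NULL)
          if (is.null(LU)) break
        }
        du <- tryCatch(as.vector(Matrix::solve(LU, -r)), error = function(e) NULL)
        if (is.null(du) || any(!is.finite(du))) break
        rn_prev <- rn
        alpha <- 1
        for (bt in 1:10) {
          u_new <- u_try
          u_new[free] <- u_try[free] + alpha * du
          rn2 <- sqrt(sum(fe_internal_force(pc, u_new, params, thickness,
                                            form, a0)[free]^2))
          if (is.finite(rn2) && (rn2 < rn || alpha < 1e-2)) break
          alpha <- alpha / 2
        }
        u_try <- u_new
      }
      if (ok) {
        u <- u_try
        lam_done <- lam_try
        dlam <- min(dlam * 2, max(lam_target - lam_done, dlam))
      } else {
        dlam <- dlam / 2
        if (dlam < 1e-5)
          stop(sprintf("Newton solver diverged at load factor %.5f (strain %.4f)",
                       lam_try, lam_try * protocol$max_strain))
      }
    }
    fint <- fe_internal_force(pc, u, params, thickness, form, a0)
    f_ax[s] <- 2 * sum(fint[bc$ax_dofs])
    f_ci[s] <- 2 * sum(fint[bc$ci_dofs])
  }

  has0 <- protocol$strains[1] == 0
  forces_ax <- if (has0) c(0, f_ax) else f_ax
  forces_ci <- if (has0) c(0, f_ci) else f_ci
  curve <- force_curve(displacements = protocol$strains * 2 * mesh$gauge_half,
                       forces_axial = forces_ax, forces_circ = forces_ci,
                       times = protocol$times)
  out <- list(curve = curve, mesh = mesh, params = params)
  if (fields) {
    out$u <- matrix(u, ncol = 2, byrow = TRUE)
    out$strain <- fe_green_strain(pc, u)
  }
  class(out) <- "fe_result"
  out
}

# Gauss-point-averaged Green-Lagrange strain per element
fe_green_strain <- function(pc, u) {
  conn <- pc$conn; ne <- pc$ne
  UX <- matrix(u[2 * conn - 1], ne, 6)
  UY <- matrix(u[2 * conn], ne, 6)
  E11 <- E22 <- E12 <- 0
  for (g in 1:3) {
    Fg <- fe_def_grad(pc$gp[[g]], UX, UY)
    E11 <- E11 + (Fg$F11^2 + Fg$F21^2 - 1) / 2
    E22 <- E22 + (Fg$F12^2 + Fg$F22^2 - 1) / 2
    E12 <- E12 + (Fg$F11 * Fg$F12 + Fg$F21 * Fg$F22) / 2
  }
  E11 <- E11 / 3; E22 <- E22 / 3; E12 <- E12 / 3
  cbind(E11 = E11, E22 = E22, E12 = E12,
        magnitude = sqrt(E11^2 + E22^2 + 2 * E12^2))
}

#' @export
print.fe_result <- function(x, ...) {
  cat("FE biaxial simulation result\n")
  print(x$curve)
  invisible(x)
}

#' Mesh convergence study on the rake model
#'
#' Runs [fe_forward()] at successive refinement levels and reports the
#' peak axial force against element count. Convergence is declared when
#' the relative change between successive levels falls below `tol`.
#'
#' @param geom A [rake_geometry()].
#' @param params An [hgo_params()] object.
#' @param protocol A [loading_protocol()]; a reduced-strain protocol
#'   keeps the study fast.
#' @param levels Integer vector of at least 3 refinement levels.
#' @param tol Relative-change convergence threshold (default 0.01).
#' @return A data frame with columns `level`, `elements`, `peak_force`
#'   (mN) and `rel_change`; attribute `converged` gives the first level
#'   meeting the criterion (NA if none), attribute `oscillatory` flags
#'   non-monotone |change| sequences.
#' @export
mesh_convergence <- function(geom, params, protocol = loading_protocol(),
                             levels = 1:3, tol = 0.01) {
  stopifnot(inherits(geom, "rake_geometry"))
  if (length(levels) < 3) stop("at least 3 refinement levels are required")
  peak <- elems <- numeric(length(levels))
  for (i in seq_along(levels)) {
    mesh <- build_quarter_mesh(geom, refinement = levels[i])
    elems[i] <- nrow(mesh$conn)
    res <- fe_forward(mesh, params, protocol, fields = FALSE)
    peak[i] <- max(force_vector(res$curve))
  }
  rel <- c(NA, abs(diff(peak)) / abs(peak[-length(peak)]))
  out <- data.frame(level = levels, elements = elems, peak_force = peak,
                    rel_change = rel)
  idx <- which(rel < tol)
  attr(out, "converged") <- if (length(idx)) levels[min(idx)] else NA_integer_
  d <- rel[-1]
  attr(out, "oscillatory") <- length(d) >= 2 && any(diff(d) > tol)
  out
}
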