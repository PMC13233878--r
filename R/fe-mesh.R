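#' Quarter-symmetry mesh of the rake-mounted sample
#'
#' Builds a conforming quadratic-triangle (6-node) mesh of one quarter of
#' the square sample, with the rake tines represented as circular holes
#' along the two loaded rake lines, mirroring the kinematic-coupling
#' idealization of the physical rakes. The mesh is generated on a graded
#' tensor grid (fine spacing near the rake lines and tine positions,
#' coarse elsewhere); triangles whose centroid falls inside a hole are
#' removed and nearby nodes are projected radially onto the hole circle,
#' so hole boundaries are polygonal approximations of the circles with
#' curved (projected) midside nodes.
#'
#' The quarter domain is `[0, side/2]^2` with the sample center at the
#' origin; the symmetry edges are `x = 0` and `y = 0`. Tines on the top
#' rake line move in `+y` (circumferential), tines on the right rake line
#' in `+x` (axial).
#'
#' @param geom A [rake_geometry()].
#' @param refinement Integer refinement level (>= 1). Each level shrinks
#'   the target spacings by a factor 0.8; element count increases
#'   strictly with level.
#' @return An object of class `quarter_mesh`: nodes (mm), 6-node
#'   connectivity, hole centers/radius, per-hole boundary node sets and
#'   reference points, symmetry-edge node sets.
#' @export
build_quarter_mesh <- function(geom, refinement = 3) {
  stopifnot(inherits(geom, "rake_geometry"),
            refinement >= 1, refinement == round(refinement))
  half <- geom$side / 2
  r <- geom$tine_diameter / 2
  gh <- half - geom$apron
  span <- geom$side - 2 * geom$apron
  spacing <- geom$tine_spacing
  xt <- seq(-span / 2 + spacing / 2, span / 2 - spacing / 2,
            length.out = geom$tines_per_edge)
  xt <- xt[xt > -1e-9]
  if (gh - r <= 0 || gh + r >= half || any(xt + r > half))
    stop("tine layout is geometrically infeasible for this geometry")
  centers <- rbind(cbind(xt, gh), cbind(gh, xt))
  which_dir <- c(rep(2L, length(xt)), rep(1L, length(xt)))

  # fine spacing near holes never exceeds ~r/2.4 so every hole boundary
  # (including half-holes on the symmetry axes) is resolved at level 1
  hf <- min(0.1, r / 2.4) * 0.8^(refinement - 1)
  hc <- 0.4 * 0.8^(refinement - 1)
  xs <- graded_lines(half, c(xt, gh), band = r + 2 * hf, hf = hf, hc = hc)
  mesh <- carve_tri6(xs, centers, r)

  tolc <- 1e-9
  d <- dist_to_centers(mesh$nodes, centers)
  hole_nodes <- lapply(seq_len(nrow(centers)), function(h)
    which(abs(d$d - r) < 1e-7 & d$h == h))
  if (any(vapply(hole_nodes, length, 1L) == 0L))
    stop("mesh too coarse to resolve the tine holes; increase refinement")
  structure(list(
    nodes = mesh$nodes, conn = mesh$conn,
    centers = centers, radius = r, which_dir = which_dir,
    ref_points = centers, hole_nodes = hole_nodes,
    left = which(abs(mesh$nodes[, 1]) < tolc),
    bottom = which(abs(mesh$nodes[, 2]) < tolc),
    gauge_half = gh, geom = geom, refinement = refinement,
    kind = "rake"), class = "quarter_mesh")
}

#' Quarter-symmetry mesh of a hole-free square
#'
#' Uniform quadratic-triangle mesh of one quarter of a square of side
#' equal to the gauge length, for the idealized variant where uniform
#' displacements are applied directly along the sample edges. The exact
#' solution of this problem is the homogeneous equi-biaxial deformation,
#' which makes it the analytic oracle for the finite element solver.
#'
#' @param geom A [rake_geometry()]; the square side is `gauge_length(geom)`.
#' @param nx Number of grid cells per edge of the quarter domain.
#' @return A `quarter_mesh` object with `kind = "square"`.
#' @export
build_square_mesh <- function(geom, nx = 6) {
  stopifnot(inherits(geom, "rake_geometry"), nx >= 1)
  half <- gauge_length(geom) / 2
  xs <- seq(0, half, length.out = nx + 1)
  mesh <- carve_tri6(xs, centers = NULL, r = 0)
  tolc <- 1e-9
  structure(list(
    nodes = mesh$nodes, conn = mesh$conn,
    centers = NULL, radius = 0, which_dir = integer(0),
    ref_points = NULL, hole_nodes = list(),
    left = which(abs(mesh$nodes[, 1]) < tolc),
    bottom = which(abs(mesh$nodes[, 2]) < tolc),
    right = which(abs(mesh$nodes[, 1] - half) < tolc),
    top = which(abs(mesh$nodes[, 2] - half) < tolc),
    gauge_half = half, geom = geom, refinement = NA_integer_,
    kind = "square"), class = "quarter_mesh")
}

#' @export
print.quarter_mesh <- function(x, ...) {
  cat(sprintf("Quarter mesh (%s): %d quadratic triangles, %d nodes, %d holes\n",
              x$kind, nrow(x$conn), nrow(x$nodes), length(x$hole_nodes)))
  invisible(x)
}

# graded 1D grid: coarse spacing hc overall, fine spacing hf in bands of
# half-width `band` around each entry of fine_at
graded_lines <- function(half, fine_at, band, hf, hc) {
  pts <- seq(0, half, by = hc)
  for (cx in fine_at)
    pts <- c(pts, seq(max(0, cx - band), min(half, cx + band), by = hf))
  pts <- sort(unique(c(pts, half)))
  pts <- pts[c(TRUE, diff(pts) > hf / 2)]
  if (abs(pts[length(pts)] - half) > 1e-12) pts <- c(pts, half)
  pts
}

dist_to_centers <- function(pts, centers) {
  if (is.null(centers) || nrow(centers) == 0L)
    return(list(d = rep(Inf, nrow(pts)), h = rep(NA_integer_, nrow(pts))))
  d <- matrix(Inf, nrow(pts), nrow(centers))
  for (h in seq_len(nrow(centers)))
    d[, h] <- sqrt((pts[, 1] - centers[h, 1])^2 + (pts[, 2] - centers[h, 2])^2)
  list(d = apply(d, 1, min), h = apply(d, 1, which.min))
}

# structured grid -> carve holes -> snap -> quadratic midside nodes
carve_tri6 <- function(xs, centers, r) {
  nx <- length(xs) - 1L
  cid <- function(i, j) (j - 1L) * (nx + 1L) + i
  corners <- cbind(rep(xs, nx + 1), rep(xs, each = nx + 1))
  i <- rep(seq_len(nx), nx); j <- rep(seq_len(nx), each = nx)
  tris <- rbind(cbind(cid(i, j), cid(i + 1L, j), cid(i + 1L, j + 1L)),
                cbind(cid(i, j), cid(i + 1L, j + 1L), cid(i, j + 1L)))
  if (!is.null(centers) && r > 0) {
    cen <- (corners[tris[, 1], ] + corners[tris[, 2], ] + corners[tris[, 3], ]) / 3
    tris <- tris[dist_to_centers(cen, centers)$d > r, , drop = FALSE]
    dn <- dist_to_centers(corners, centers)
    for (k in which(dn$d < r - 1e-12)) {
      h <- dn$h[k]
      v <- corners[k, ] - centers[h, ]
      nv <- sqrt(sum(v^2))
      corners[k, ] <- if (nv < 1e-12) centers[h, ] + c(r, 0)
                      else centers[h, ] + v * (r / nv)
    }
  }
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(corners)); remap[used] <- seq_along(used)
  corners <- corners[used, , drop = FALSE]
  tris <- matrix(remap[tris], ncol = 3)
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  uk <- unique(key)
  eid <- match(key, uk)
  first <- !duplicated(eid)
  ord <- order(eid[first])
  e1 <- edges[first, 1][ord]; e2 <- edges[first, 2][ord]
  mids <- (corners[e1, ] + corners[e2, ]) / 2
  if (!is.null(centers) && r > 0) {
    dn1 <- dist_to_centers(corners, centers)
    onc <- abs(dn1$d - r) < 1e-7
    for (k in which(onc[e1] & onc[e2] & (dn1$h[e1] == dn1$h[e2]))) {
      h <- dn1$h[e1[k]]
      v <- mids[k, ] - centers[h, ]
      nv <- sqrt(sum(v^2))
      if (nv > 1e-12) mids[k, ] <- centers[h, ] + v * (r / nv)
    }
  }
  nodes <- rbind(corners, mids)
  conn <- cbind(tris, nrow(corners) + matrix(eid, nrow(tris), 3))
  list(nodes = nodes, conn = conn)
}

#' Export a mesh (and optional fields) as legacy ASCII VTK
#'
#' Writes an unstructured-grid file with quadratic triangle cells
#' (VTK cell type 22) for inspection in ParaView or similar viewers.
#'
#' @param mesh A `quarter_mesh`.
#' @param path Output file path (`.vtk`).
#' @param point_data Optional named list of per-node vectors (scalars) or
#'   two-column matrices (vectors, padded to 3D).
#' @param cell_data Optional named list of per-element scalar vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = NULL, cell_data = NULL) {
  stopifnot(inherits(mesh, "quarter_mesh"))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$conn)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "biaxfit quarter mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 7L * ne), con)
  # VTK quadratic triangle node order matches (corners, midsides 12/23/31)
  writeLines(apply(mesh$conn - 1L, 1, function(rw)
    paste(c(6L, rw), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("22", ne), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10g %.10g 0", v[, 1], v[, 2]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", v), con)
      }
    }
  }
  if (!is.null(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}
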