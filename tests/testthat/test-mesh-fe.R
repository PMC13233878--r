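test_that("quarter mesh is structurally valid at a coarse level", {
  m <- build_quarter_mesh(std_geom(), refinement = 1)
  expect_s3_class(m, "quarter_mesh")
  expect_gt(nrow(m$conn), 0)
  expect_equal(length(m$hole_nodes), nrow(m$centers))
  expect_equal(length(m$hole_nodes), 6)   # 3 top + 3 right in the quarter
  # symmetry sets sit on the axes, hole sets on their circles
  expect_true(all(abs(m$nodes[m$left, 1]) < 1e-9))
  expect_true(all(abs(m$nodes[m$bottom, 2]) < 1e-9))
  for (h in seq_along(m$hole_nodes)) {
    d <- sqrt(rowSums(sweep(m$nodes[m$hole_nodes[[h]], , drop = FALSE],
                            2, m$centers[h, ], "-")^2))
    expect_true(all(abs(d - m$radius) < 1e-6))
  }
  # each hole maps to exactly one reference point
  expect_equal(nrow(m$ref_points), length(m$hole_nodes))
  # conforming: every midside node appears where its edge does (shared ids)
  expect_true(max(m$conn) <= nrow(m$nodes))
})

test_that("element count increases strictly with refinement", {
  counts <- vapply(1:3, function(l)
    nrow(build_quarter_mesh(std_geom(), refinement = l)$conn), numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("hole perimeters carry at least 8 nodes at the default refinement", {
  m <- build_quarter_mesh(std_geom())
  expect_true(all(vapply(m$hole_nodes, length, 1L) >= 8L))
})

test_that("infeasible tine layouts are rejected", {
  expect_error(build_quarter_mesh(rake_geometry(apron = 0.1)), "infeasible")
})

test_that("FE on a hole-free square reproduces the homogeneous solution", {
  g <- std_geom()
  p <- trachea3()
  prot <- loading_protocol(max_strain = 0.5, points_per_direction = 6)
  res <- fe_forward(build_square_mesh(g, nx = 4), p, prot)
  hom <- force_vector(homogeneous_forward(p, g, prot))
  fe <- force_vector(res$curve)
  nz <- hom != 0
  expect_lt(max(abs(fe[nz] - hom[nz]) / abs(hom[nz])), 0.01)
  # zero-displacement sample carries zero reaction
  expect_equal(fe[!nz], hom[!nz])
})

test_that("FE forces scale linearly with thickness", {
  p <- hgo_params(0.5, 0.2, 3, 0.05)
  prot <- short_protocol(0.2, 3)
  f1 <- force_vector(fe_forward(build_square_mesh(std_geom(1.24), nx = 3),
                                p, prot, fields = FALSE)$curve)
  f2 <- force_vector(fe_forward(build_square_mesh(std_geom(2.48), nx = 3),
                                p, prot, fields = FALSE)$curve)
  expect_equal(f2, 2 * f1, tolerance = 1e-5)
})

test_that("rotating the fiber by 90 degrees swaps the FE force curves", {
  p <- trachea3()
  prot <- short_protocol(0.2, 3)
  mesh <- build_square_mesh(std_geom(), nx = 3)
  f1 <- force_vector(fe_forward(mesh, p, prot, fields = FALSE)$curve)
  f2 <- force_vector(fe_forward(mesh, p, prot, a0 = c(0, 1),
                                fields = FALSE)$curve)
  expect_equal(f1[1:3], f2[4:6], tolerance = 1e-6)
  expect_equal(f1[4:6], f2[1:3], tolerance = 1e-6)
})

test_that("isotropic rake model is direction-symmetric to solver tolerance", {
  m <- build_quarter_mesh(std_geom(), refinement = 2)
  res <- fe_forward(m, hgo_params(0.5), short_protocol(0.1, 2), fields = FALSE)
  fv <- force_vector(res$curve)
  expect_equal(fv[1:2], fv[3:4], tolerance = 1e-4)
})

test_that("rake and square-edge boundary conditions differ notably", {
  p <- trachea3()
  prot <- short_protocol(0.15, 3)
  rake <- force_vector(fe_forward(build_quarter_mesh(std_geom(), 1), p, prot,
                                  fields = FALSE)$curve)
  unif <- force_vector(homogeneous_forward(p, std_geom(), prot))
  nz <- unif != 0
  # responses differ by far more than solver/mesh tolerance
  expect_gt(max(abs(rake[nz] - unif[nz]) / abs(unif[nz])), 0.10)
})

test_that("mesh convergence study reports shrinking changes and flags", {
  expect_error(mesh_convergence(std_geom(), hgo_params(0.5), levels = 1),
               "3 refinement levels")
  tab <- mesh_convergence(std_geom(), hgo_params(0.5),
                          protocol = short_protocol(0.1, 2), levels = 1:3)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$elements) > 0))
  d <- tab$rel_change[-1]
  expect_true(all(diff(d) < 0))            # |change| decreasing under refinement
  conv <- attr(tab, "converged")
  if (!is.na(conv)) {
    # by construction, the first converged level changed < 1% from its predecessor
    expect_lt(tab$rel_change[tab$level == conv], 0.01)
  }
})

test_that("meshes and FE fields export as legacy VTK", {
  g <- std_geom()
  mesh <- build_square_mesh(g, nx = 3)
  res <- fe_forward(mesh, hgo_params(0.5), short_protocol(0.1, 2))
  path <- tempfile(fileext = ".vtk")
  write_vtk(mesh, path, point_data = list(displacement = res$u),
            cell_data = list(strain_magnitude = res$strain[, "magnitude"]))
  lines <- readLines(path)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_equal(sum(grepl("^POINTS", lines)), 1)
  np <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE), " ")[[1]][2])
  expect_equal(np, nrow(mesh$nodes))
  expect_equal(sum(lines == "22"), nrow(mesh$conn))   # quadratic triangles
  expect_equal(sum(grepl("^VECTORS displacement", lines)), 1)
  expect_equal(sum(grepl("^SCALARS strain_magnitude", lines)), 1)
})
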