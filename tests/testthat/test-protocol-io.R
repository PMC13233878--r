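test_that("synthetic files round-trip exactly through the CSV dialect", {
  g <- std_geom(1.8)
  path <- tempfile(fileext = ".csv")
  synthesize_experiment(trachea3(), g, noise = noise_model(0, 0), path = path)
  rec <- read_biaxial_csv(path, thickness = 1.8)
  rec2path <- tempfile(fileext = ".csv")
  write_biaxial_csv(rec, rec2path)
  expect_identical(readLines(path), readLines(rec2path))
})

test_that("records with shuffled rows or missing columns are rejected", {
  path <- tempfile(fileext = ".csv")
  synthesize_experiment(trachea3(), std_geom(), noise = noise_model(0, 0),
                        path = path, n_precondition = 0)
  d <- utils::read.csv(path)
  set.seed(1)
  utils::write.csv(d[sample(nrow(d)), ], path, row.names = FALSE)
  expect_error(read_biaxial_csv(path), "increasing")
  utils::write.csv(d[, -2], path, row.names = FALSE)
  expect_error(read_biaxial_csv(path), "missing columns")
})

test_that("unit dialects normalize newton files to millinewtons", {
  path <- tempfile(fileext = ".csv")
  synthesize_experiment(trachea3(), std_geom(), noise = noise_model(0, 0),
                        path = path, n_precondition = 0)
  rec_mN <- read_biaxial_csv(path)
  d <- utils::read.csv(path)
  d$force_axial_mN <- d$force_axial_mN / 1000
  d$force_circ_mN <- d$force_circ_mN / 1000
  utils::write.csv(d, path, row.names = FALSE)
  rec_N <- read_biaxial_csv(path, biaxial_dialect(force_unit = "N"))
  expect_equal(rec_N$data$force_axial, rec_mN$data$force_axial, tolerance = 1e-12)
})

test_that("the final test cycle is isolated from preconditioning", {
  g <- std_geom()
  path <- tempfile(fileext = ".csv")
  synthesize_experiment(trachea3(), g, noise = noise_model(0, 0), path = path,
                        n_precondition = 10)
  rec <- read_biaxial_csv(path, thickness = 2)
  cut <- extract_test_cycle(rec, n_precondition = 10)
  expect_lt(nrow(cut$data), nrow(rec$data) / 10)
  expect_equal(max(cut$data$disp_axial), max(rec$data$disp_axial))
  expect_equal(cut$data$time[1], 0)
  expect_error(extract_test_cycle(rec, n_precondition = 30), "cycles")
  # single-ramp record with n = 0 passes through unchanged
  path1 <- tempfile(fileext = ".csv")
  synthesize_experiment(trachea3(), g, noise = noise_model(0, 0), path = path1,
                        n_precondition = 0)
  rec1 <- read_biaxial_csv(path1, thickness = 2)
  expect_identical(extract_test_cycle(rec1, 0)$data, rec1$data)
})

test_that("detected cycle boundaries match the generator ground truth", {
  g <- std_geom()
  path <- tempfile(fileext = ".csv")
  synthesize_experiment(trachea3(), g, noise = noise_model(0, 0), path = path,
                        n_precondition = 10)
  truth <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rec <- read_biaxial_csv(path, thickness = 2)
  cut <- extract_test_cycle(rec, n_precondition = 10)
  cyc <- cut$cycles
  expect_equal(nrow(cyc), 11)
  # each annotated boundary (end of a preconditioning cycle) is recovered
  # within one sample
  expect_true(all(abs(cyc[-nrow(cyc), "end"] - truth$cycle_boundaries) <= 1))
})

test_that("resampling is exact on-grid and accurate off-grid", {
  g <- std_geom()
  prot <- loading_protocol()
  path <- tempfile(fileext = ".csv")
  synthesize_experiment(trachea3(), g, prot, noise_model(0, 0), path = path,
                        n_precondition = 0, dt = 0.05)
  rec <- read_biaxial_csv(path, thickness = 2)
  fc <- resample_to_protocol(rec, g, prot)
  truth <- force_vector(homogeneous_forward(trachea3(), g, prot))
  fv <- force_vector(fc)
  expect_length(fv, 50)
  nz <- truth != 0
  expect_lt(max(abs(fv[nz] - truth[nz]) / abs(truth[nz])), 0.005)
  # a half-rate record still resamples to the full 50-value contract
  slow <- loading_protocol(rate = 1.25)
  path2 <- tempfile(fileext = ".csv")
  synthesize_experiment(trachea3(), g, slow, noise_model(0, 0), path = path2,
                        n_precondition = 0)
  fc2 <- resample_to_protocol(read_biaxial_csv(path2, thickness = 2), g, prot)
  expect_length(force_vector(fc2), 50)
  # a short record cannot span the ramp
  shortp <- loading_protocol(max_strain = 0.3)
  path3 <- tempfile(fileext = ".csv")
  synthesize_experiment(trachea3(), g, shortp, noise_model(0, 0), path = path3,
                        n_precondition = 0)
  expect_error(resample_to_protocol(read_biaxial_csv(path3, thickness = 2),
                                    g, prot), "span")
})

test_that("stress conversion is linear in thickness and needs a thickness", {
  curve <- homogeneous_forward(trachea_mean(), std_geom(2))
  s2 <- to_stress_strain(curve, std_geom(2))
  s4 <- to_stress_strain(curve, std_geom(4))
  expect_equal(s4$stress, s2$stress / 2, tolerance = 1e-12)
  g0 <- std_geom(2); g0$thickness <- 0
  expect_error(to_stress_strain(curve, g0), "thickness")
})

test_that("bilinear moduli recover known slopes", {
  strain <- seq(0, 0.5, length.out = 26)
  knee <- 0.3
  stress <- ifelse(strain <= knee, 15 * strain,
                   15 * knee + 400 * (strain - knee))
  bl <- bilinear_moduli(data.frame(strain = strain, stress = stress))
  expect_lt(abs(bl$initial - 15) / 15, 0.02)
  expect_lt(abs(bl$ultimate - 400) / 400, 0.02)
  expect_false(bl$flagged)
  # straight line: both moduli equal the single slope
  ln <- bilinear_moduli(data.frame(strain = strain, stress = 42 * strain))
  expect_equal(ln$initial, 42, tolerance = 1e-8)
  expect_equal(ln$ultimate, 42, tolerance = 1e-8)
})

test_that("HGO curves are strain-stiffening: ultimate exceeds initial modulus", {
  g <- std_geom()
  p <- hgo_params(0.5, 0.3, 2.5, 0.07)   # moderate stiffening: bilinear regimes exist
  ss <- to_stress_strain(homogeneous_forward(p, g), g)
  ax <- ss[ss$direction == "axial", ]
  bl <- bilinear_moduli(ax)
  expect_false(bl$flagged)
  expect_gt(bl$ultimate, bl$initial)
})
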