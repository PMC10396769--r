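test_that("zero load yields zero displacement and stress", {
  mesh <- make_bar_mesh(c(10, 10, 20), 5)
  mat <- uniform_materials(mesh)
  lc <- build_load_case(mesh, list(tip = c(0, 0, 0)))
  res <- solve_linear_elasticity(mesh, mat, lc)
  expect_true(all(res$displacements == 0))
  expect_true(all(res$von_mises == 0))
})

test_that("uniaxial bar reproduces the closed-form stress and deflection", {
  # nu = 0 and consistent traction loading: the field is exactly uniform
  mesh <- make_bar_mesh(c(10, 10, 100), 5)
  mat <- uniform_materials(mesh, E = 1000, nu = 0)
  lc <- build_traction_load(mesh, "tip", c(0, 0, -5))  # 5 MPa over 100 mm2
  res <- solve_linear_elasticity(mesh, mat, lc)
  expect_equal(max(res$von_mises), 5, tolerance = 0.02)     # F/A
  expect_equal(mean(res$stress[, 3]), 5, tolerance = 1e-9)  # tension
  tip_dz <- mean(res$displacements[mesh$nsets$tip, 3])
  expect_equal(tip_dz, -0.5, tolerance = 0.02)              # FL/EA
  # global force balance at the fixed boundary
  expect_lt(max(abs(colSums(res$reactions) + c(0, 0, -500))), 1e-8 * 500)
  expect_lt(res$residual, 1e-8)
})

test_that("patch test: imposed linear field gives constant strain", {
  mesh <- make_bar_mesh(c(10, 10, 30), 5)
  mat <- uniform_materials(mesh, E = 2500, nu = 0.3)
  A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, -2e-3, 5e-4, 2e-4, 1e-4, 8e-4),
              3, 3)
  surf <- mesh_surface_nodes(mesh)
  lc <- list(forces = matrix(0, nrow(mesh$nodes), 3), fixed_nodes = surf,
             fixed_values = mesh$nodes[surf, ] %*% t(A))
  res <- solve_linear_elasticity(mesh, mat, lc)
  As <- (A + t(A)) / 2
  expected <- c(diag(As), 2 * As[1, 2], 2 * As[2, 3], 2 * As[3, 1])
  expect_lt(max(abs(sweep(res$strain, 2, expected))), 1e-12)
})

test_that("solution is exactly linear in the load", {
  mesh <- make_bar_mesh(c(10, 10, 50), 5)
  mat <- uniform_materials(mesh)
  lc1 <- build_load_case(mesh, list(tip = c(30, -20, -100)))
  lc2 <- build_load_case(mesh, list(tip = 2 * c(30, -20, -100)))
  r1 <- solve_linear_elasticity(mesh, mat, lc1)
  r2 <- solve_linear_elasticity(mesh, mat, lc2)
  expect_equal(r2$displacements, 2 * r1$displacements, tolerance = 1e-12)
  expect_equal(r2$von_mises, 2 * r1$von_mises, tolerance = 1e-12)
})

test_that("bar stress error shrinks monotonically under refinement", {
  # bending-dominated case so the discretisation error is visible
  stresses <- vapply(c(10, 5, 2.5), function(h) {
    mesh <- make_bar_mesh(c(10, 10, 100), h)
    mat <- uniform_materials(mesh, E = 1000, nu = 0.3)
    lc <- build_load_case(mesh, list(tip = c(200, 0, 0)))
    max(solve_linear_elasticity(mesh, mat, lc)$von_mises)
  }, numeric(1))
  expect_true(all(diff(stresses) > 0))  # stiffer coarse mesh underpredicts
})

test_that("singular systems report missing constraints", {
  mesh <- make_bar_mesh(c(10, 10, 20), 5)
  mat <- uniform_materials(mesh)
  lc <- list(forces = matrix(0, nrow(mesh$nodes), 3),
             fixed_nodes = integer(0))
  expect_error(build_load_case(mesh, list(tip = c(0, 0, 1)),
                               fixed = integer(0)),
               class = "paosim_config_error")
  lc_bad <- list(forces = matrix(0, nrow(mesh$nodes), 3),
                 fixed_nodes = 1L)  # a single point cannot stop rotation
  expect_error(solve_linear_elasticity(mesh, mat, lc_bad),
               class = "paosim_solver_error")
})

test_that("von Mises and principal strain closed forms", {
  expect_equal(von_mises_stress(c(100, 0, 0, 0, 0, 0)), 100)
  expect_equal(von_mises_stress(c(50, 50, 50, 0, 0, 0)), 0)  # hydrostatic
  expect_equal(von_mises_stress(c(0, 0, 0, 10, 0, 0)), 10 * sqrt(3))
  ps <- principal_strains(c(0.01, -0.002, 0.003, 0, 0, 0))
  expect_equal(ps[1, ], c(0.01, 0.003, -0.002))
  # pure engineering shear gamma: principal strains +-gamma/2
  ps2 <- principal_strains(c(0, 0, 0, 0.004, 0, 0))
  expect_equal(ps2[1, ], c(0.002, 0, -0.002), tolerance = 1e-12)
})

test_that("load distribution reproduces force and moment resultants", {
  mesh <- generate_pelvis_mesh(geometry_spec("IS", target_edge_size = 6))
  # single-node region takes the entire force
  mesh$nsets$one <- mesh$nsets$couple_joint[1]
  lc1 <- build_load_case(mesh, list(one = c(3, -4, 12)))
  expect_equal(lc1$forces[mesh$nsets$one, ], c(3, -4, 12))
  expect_equal(sum(lc1$forces != 0), 3)
  # zero force gives an all-zero case
  lc0 <- build_load_case(mesh, list(couple_joint = c(0, 0, 0)))
  expect_true(all(lc0$forces == 0))
  # random region: nodal sums match force, moments match about centroid
  set.seed(9)
  Fv <- stats::rnorm(3, 0, 200)
  Mv <- stats::rnorm(3, 0, 500)
  lc <- build_load_case(mesh, list(couple_abductor = list(force = Fv,
                                                          moment = Mv)))
  ids <- mesh$nsets$couple_abductor
  expect_equal(colSums(lc$forces[ids, ]), Fv, tolerance = 1e-9)
  ctr <- colMeans(mesh$nodes[ids, ])
  mom <- c(0, 0, 0)
  for (i in ids) {
    mom <- mom + paosim:::cross3(mesh$nodes[i, ] - ctr, lc$forces[i, ])
  }
  expect_equal(mom, Mv, tolerance = 1e-6)
  expect_error(build_load_case(mesh, list(nowhere = c(1, 0, 0))),
               class = "paosim_mapping_error")
})

test_that("frame transforms round-trip and rotate load vectors", {
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  fr <- load_frame(Rz, origin = c(10, 20, 0))
  v <- c(100, -50, 30)
  expect_equal(frame_transform(fr, frame_transform(fr, v), inverse = TRUE),
               v, tolerance = 1e-12)
  mesh <- make_bar_mesh(c(10, 10, 20), 5)
  lc <- build_load_case(mesh, list(tip = v), frame = fr)
  expect_equal(colSums(lc$forces), drop(Rz %*% v), tolerance = 1e-9)
  expect_error(load_frame(matrix(1, 3, 3)), class = "paosim_config_error")
})

test_that("field results serialise to legacy VTK", {
  mesh <- make_bar_mesh(c(10, 10, 20), 5)
  mat <- uniform_materials(mesh)
  res <- solve_linear_elasticity(mesh, mat,
                                 build_load_case(mesh,
                                                 list(tip = c(0, 0, -50))))
  path <- file.path(tempdir(), "field.vtk")
  write_field_vtk(res, path)
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("^VECTORS displacement", lines)))
  expect_true(any(grepl("^SCALARS von_mises", lines)))
})
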