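test_that("mean peak stress matches the sort-based oracle", {
  expect_equal(as.numeric(p100_mean(rep(7.5, 300))), 7.5)
  expect_equal(as.numeric(p100_mean(c(rep(10, 100), rep(0, 900)))), 10)
  set.seed(21)
  x <- stats::rexp(5000, 1 / 40)
  expect_equal(as.numeric(p100_mean(x)),
               mean(sort(x, decreasing = TRUE)[1:100]))
  # homogeneity of degree one
  expect_equal(as.numeric(p100_mean(3 * x)), 3 * as.numeric(p100_mean(x)))
  # fewer than 100 values: use all and flag
  short <- p100_mean(c(1, 2, 3))
  expect_equal(as.numeric(short), 2)
  expect_true(attr(short, "truncated"))
  expect_error(p100_mean(numeric(0)), class = "paosim_input_error")
})

test_that("weighted mean stress follows the phase-peak weighting", {
  p100 <- c(10, 20, 30, 40, 50, 60, 70, 80)
  expect_equal(wmv_s100(p100, rep(3, 8)), mean(p100))
  w <- rep(0, 8); w[3] <- 5
  expect_equal(wmv_s100(p100, w), p100[3])
  set.seed(4)
  a <- stats::runif(8, 10, 200); b <- stats::runif(8, 1, 50)
  expect_equal(wmv_s100(a, b), sum(a * b / sum(b)))
  # convex combination bounds
  expect_gte(wmv_s100(a, b), min(a))
  expect_lte(wmv_s100(a, b), max(a))
  expect_error(wmv_s100(a, rep(0, 8)), class = "paosim_input_error")
  expect_error(wmv_s100(a, -b), class = "paosim_input_error")
})

test_that("convergence protocol reproduces the worked refinement table", {
  table_stress <- c("4" = 213.9, "3.5" = 209.4, "3" = 206.1,
                    "2.5" = 205.3, "2" = 205.3)
  factory <- function(size) table_stress[[as.character(size)]]
  rep <- run_mesh_convergence(factory, start = 4, step = 0.5, tol = 1)
  expect_equal(round(rep$variation_pct[2], 1), 2.1)
  expect_equal(round(rep$variation_pct[3], 1), 1.6)
  expect_lt(rep$variation_pct[4], 1)
  expect_equal(attr(rep, "selected_size"), 2.5)
  expect_true(attr(rep, "converged"))
  # one confirmation refinement is recorded past the selected size
  expect_equal(rep$size_mm, c(4, 3.5, 3, 2.5, 2))
  # constant sequence selects the first refinement
  rep2 <- run_mesh_convergence(function(s) 100, start = 4, step = 0.5,
                               tol = 1)
  expect_equal(attr(rep2, "selected_size"), 3.5)
  # never converging reports failure above the floor
  rep3 <- run_mesh_convergence(function(s) s * 100, start = 4, step = 1,
                               tol = 0.001, floor = 1)
  expect_false(attr(rep3, "converged"))
  expect_error(run_mesh_convergence(function(s) 1, start = 1, step = 2),
               class = "paosim_config_error")
})

test_that("bar convergence reaches the closed-form stress", {
  factory <- function(h) {
    mesh <- make_bar_mesh(c(10, 10, 100), h)
    mat <- uniform_materials(mesh, E = 1000, nu = 0)
    lc <- build_traction_load(mesh, "tip", c(0, 0, -5))
    res <- solve_linear_elasticity(mesh, mat, lc)
    structure(max(res$von_mises), n_elements = nrow(mesh$elements))
  }
  rep <- run_mesh_convergence(factory, start = 10, step = 2.5, tol = 1,
                              floor = 2.5)
  expect_true(attr(rep, "converged"))
  expect_equal(rep$max_von_mises, rep(5, nrow(rep)), tolerance = 1e-9)
  expect_true(all(diff(rep$n_elements) > 0))
})

test_that("uniform bar yields within one increment of the analytic load", {
  mesh <- make_bar_mesh(c(10, 10, 100), 5)
  E <- 1000; A <- 100; eps_lim <- 0.0073
  mat <- uniform_materials(mesh, E = E, nu = 0)
  lc <- build_traction_load(mesh, "tip", c(0, 0, -5))  # 500 N base load
  analytic <- eps_lim * E * A  # 730 N
  for (del in c(FALSE, TRUE)) {
    yl <- compute_yield_load(mesh, mat, lc, increment = 10,
                             delete_failed = del, body_mass = 65)
    expect_false(yl$capped)
    expect_lte(abs(yl$yield_load_N - analytic), 10, label = paste(del))
    expect_equal(yl$yield_load_bw * 65 * 9.81, yl$yield_load_N,
                 tolerance = 1e-12)
  }
})

test_that("infinite strain limits cap out with no failed elements", {
  mesh <- make_bar_mesh(c(10, 10, 50), 5)
  mat <- uniform_materials(mesh, E = 1000, nu = 0)
  lc <- build_load_case(mesh, list(tip = c(0, 0, -200)))
  yl <- compute_yield_load(mesh, mat, lc,
                           limits = c(tensile = Inf, compressive = Inf),
                           delete_failed = FALSE)
  expect_true(yl$capped)
  expect_length(yl$failed_elements, 0)
  expect_true(is.na(yl$yield_load_N))
})

test_that("linear shortcut equals the quantile-scaling oracle", {
  # graded stiffness: elements fail progressively
  mesh <- make_bar_mesh(c(10, 10, 100), 5)
  ne <- nrow(mesh$elements)
  mat <- uniform_materials(mesh, E = 1000, nu = 0)
  set.seed(5)
  mat$E <- stats::runif(ne, 600, 1600)
  lc <- build_load_case(mesh, list(tip = c(60, 0, -400)))
  res <- solve_linear_elasticity(mesh, mat, lc)
  yl <- compute_yield_load(mesh, mat, lc, increment = 10,
                           fail_fraction = 0.02, delete_failed = FALSE)
  # oracle: scale the base strains so the 2%-volume quantile hits a limit
  vols <- abs(paosim:::tet_volumes(mesh$nodes, mesh$elements))
  a_t <- ifelse(res$principal_strain[, 1] > 0,
                0.0073 / res$principal_strain[, 1], Inf)
  a_c <- ifelse(res$principal_strain[, 3] < 0,
                0.0104 / (-res$principal_strain[, 3]), Inf)
  al <- pmin(a_t, a_c)
  ord <- order(al)
  astar <- al[ord[which(cumsum(vols[ord]) / sum(vols) >= 0.02)[1]]]
  F0 <- sqrt(sum(colSums(lc$forces)^2))
  expected <- max(F0 + 10 * ceiling((astar * F0 - F0) / 10 - 1e-9), F0)
  expect_equal(yl$yield_load_N, expected)
  # failed volume fraction is non-decreasing in load
  expect_true(all(diff(yl$iterations$failed_fraction) >= 0))
})

test_that("phase stress summary aggregates all eight load cases", {
  tr <- generate_gait_trial(local_noiseless_profile("postop"))
  ida <- run_ida(normalize_to_cycle(tr))
  mesh <- generate_pelvis_mesh(geometry_spec("IS", target_edge_size = 8))
  mat <- assign_materials(mesh, generate_density_field(mesh, seed = 1))
  lcs <- lapply(1:8, function(i) {
    build_load_case(mesh, phase_loads(ida$phase_summary[i, ]), phase = i)
  })
  ss <- phase_stress_summary(mesh, mat, lcs)
  expect_equal(ss$phase, 1:8)
  expect_true(all(ss$p100 <= ss$peak))
  wmv <- attr(ss, "wmv")
  expect_gte(wmv, min(ss$p100))
  expect_lte(wmv, max(ss$p100))
})
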