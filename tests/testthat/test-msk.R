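test_that("strength scaling follows the mass/height/lean-mass ratios", {
  expect_equal(scale_strength(1000), 1000)          # identity case
  expect_equal(scale_strength(1000, k_m = 1.2, k_L = 1.1,
                              R_fat_subject = 0.3, R_fat_generic = 0.25),
               1000 * (1.2 / 1.1) * (0.2 / 0.25))
  expect_equal(scale_strength(2000, k_m = 1.3),
               2 * scale_strength(1000, k_m = 1.3))  # linear in F0
  expect_error(scale_strength(1000, R_fat_subject = 0.5),
               class = "paosim_domain_error")
  expect_error(scale_strength(1000, k_L = 0), class = "paosim_domain_error")
})

test_that("attachment morphing recovers affine landmark maps", {
  G <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  P <- matrix(stats::runif(15), 5, 3)
  # identical landmarks leave points unchanged
  out <- morph_attachments(P, G, G)
  expect_equal(out, P, ignore_attr = TRUE, tolerance = 1e-12)
  # uniform scaling scales the points
  out2 <- morph_attachments(P, G, 1.1 * G)
  expect_equal(out2, 1.1 * P, ignore_attr = TRUE, tolerance = 1e-12)
  # random invertible affine map is recovered to machine precision
  set.seed(1)
  A <- matrix(stats::rnorm(9), 3, 3) + diag(3)
  b <- c(0.3, -0.2, 0.5)
  S <- G %*% t(A) + matrix(b, 5, 3, byrow = TRUE)
  out3 <- morph_attachments(P, G, S)
  expect_equal(out3, P %*% t(A) + matrix(b, nrow(P), 3, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(attr(out3, "A"), A, tolerance = 1e-10)
  # coplanar landmarks are a rank error
  Gc <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(morph_attachments(P, Gc, Gc), class = "paosim_rank_error")
})

test_that("cylinder wrapping: straight, closed-form, and dense oracle", {
  # cylinder far away: straight-line path
  m <- muscle_element("m", "flexor", c(1, 0, 0), c(2, 0, 0), 100,
                      wrap = list(point = c(0, 5, 0), axis = c(0, 0, 1),
                                  radius = 0.5))
  w <- wrap_path(m)
  expect_false(w$wrapped)
  expect_equal(w$length, 1)
  # diametrically opposite points on the surface, same height: pi * R
  m2 <- muscle_element("m2", "flexor", c(0.03, 0, 0), c(-0.03, 0, 0), 100,
                       wrap = list(point = c(0, 0, 0), axis = c(0, 0, 1),
                                   radius = 0.03))
  expect_equal(wrap_path(m2)$length, pi * 0.03, tolerance = 1e-12)
  # generic obstructed case vs numeric shortest-path oracle
  wr <- list(point = c(0, 0, 0), axis = c(0, 0, 1), radius = 0.02)
  o <- c(0.05, 0.01, 0.04)
  i <- c(-0.06, -0.005, -0.03)
  m3 <- muscle_element("m3", "flexor", o, i, 100, wrap = wr)
  w3 <- wrap_path(m3)
  expect_true(w3$wrapped)
  oracle <- function(par) {
    # two surface points (theta, z); straight-tangent + surface geodesic
    p1 <- c(0.02 * cos(par[1]), 0.02 * sin(par[1]), par[2])
    p2 <- c(0.02 * cos(par[3]), 0.02 * sin(par[3]), par[4])
    dth <- abs(atan2(sin(par[3] - par[1]), cos(par[3] - par[1])))
    sqrt(sum((o - p1)^2)) + sqrt((0.02 * dth)^2 + (par[4] - par[2])^2) +
      sqrt(sum((p2 - i)^2))
  }
  th_o <- atan2(o[2], o[1]); th_i <- atan2(i[2], i[1])
  fit <- stats::optim(c(th_o + 0.5, o[3] / 2, th_i - 0.5, i[3] / 2), oracle,
                      method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(w3$length - fit$value), 1e-6)  # metres
  expect_lte(w3$length, fit$value + 1e-9)      # ours is the shortest
  # endpoint inside the cylinder is a geometry error
  m4 <- muscle_element("m4", "flexor", c(0.005, 0, 0.05), c(0, 0.05, -0.05),
                       100, wrap = wr)
  expect_error(wrap_path(m4), class = "paosim_geometry_error")
})

test_that("inverse dynamics satisfies the static and degenerate cases", {
  massless <- list(leg_mass = 0, hip_height = 0.9, com_offset = 0.4,
                   inertia = 0)
  # zero load, zero acceleration, massless: zero moments
  idm <- inverse_dynamics(make_cycle(), segment = massless)
  expect_true(all(abs(idm[, c("moment_x_Nm", "moment_y_Nm",
                              "moment_z_Nm")]) < 1e-12))
  # vertical force W at horizontal lever d: frontal-plane moment = W * d
  W <- 650; d <- 0.08
  grf <- cbind(0, 0, rep(W, 101))
  grm <- cbind(rep(d * W, 101), 0, 0)  # encodes the lateral lever
  idm2 <- inverse_dynamics(make_cycle(grf = grf, grm = grm),
                           segment = massless)
  expect_equal(idm2$moment_x_Nm, rep(-d * W, 101), tolerance = 1e-9)
  expect_true(all(abs(idm2$moment_y_Nm) < 1e-9))
  expect_error(inverse_dynamics(make_cycle()[, 1:4]),
               class = "paosim_input_error")
})

test_that("inverse dynamics matches an independent Newton-Euler oracle", {
  tr <- generate_gait_trial(local_noiseless_profile("postop"))
  cur <- normalize_to_cycle(tr)
  seg <- default_segment_params(65)
  idm <- inverse_dynamics(cur, 65, seg)
  # independent implementation: explicit loops, own differentiation
  tt <- cur$cycle_pct / 100 * attr(cur, "cycle_duration_s")
  d2 <- function(y) {
    n <- length(y); h <- tt[2] - tt[1]
    out <- c(NA, (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / h^2, NA)
    out[1] <- out[2]; out[n] <- out[n - 1]
    out
  }
  deg <- pi / 180
  com <- matrix(0, 101, 3)
  for (i in 1:101) {
    R <- paosim:::rot_z(cur$angle_transverse_deg[i] * deg) %*%
      paosim:::rot_x(cur$angle_frontal_deg[i] * deg) %*%
      paosim:::rot_y(cur$angle_sagittal_deg[i] * deg)
    com[i, ] <- R %*% c(0, 0, -seg$com_offset)
  }
  acc <- apply(com, 2, d2)
  alpha <- cbind(d2(cur$angle_frontal_deg * deg),
                 d2(cur$angle_sagittal_deg * deg),
                 d2(cur$angle_transverse_deg * deg))
  for (i in c(1, 20, 51, 80, 101)) {
    Fg <- c(cur$grf_x_N[i], cur$grf_y_N[i], cur$grf_z_N[i])
    Mg <- c(cur$grm_x_Nm[i], cur$grm_y_Nm[i], cur$grm_z_Nm[i])
    m_ext <- paosim:::cross3(c(0, 0, -seg$hip_height), Fg) + Mg +
      paosim:::cross3(com[i, ], c(0, 0, -seg$leg_mass * 9.81))
    expected <- seg$inertia * alpha[i, ] +
      seg$leg_mass * paosim:::cross3(com[i, ], acc[i, ]) - m_ext
    got <- c(idm$moment_x_Nm[i], idm$moment_y_Nm[i], idm$moment_z_Nm[i])
    expect_equal(got, expected, tolerance = 1e-8)
  }
})

test_that("recruitment reproduces forced, symmetric and closed-form cases", {
  # single muscle forced by the equality constraint
  f <- recruit_muscles(list(C = matrix(0.05, 1, 1), r = 10, N = 1000,
                            p = 3))
  expect_equal(as.numeric(f), 200, tolerance = 1e-8)
  # two identical muscles share the load equally
  f2 <- recruit_muscles(list(C = matrix(0.05, 1, 2), r = 10,
                             N = c(800, 800), p = 3))
  expect_equal(f2[1], f2[2], tolerance = 1e-8)
  expect_equal(sum(0.05 * f2), 10, tolerance = 1e-8)
  # equal arms, N1 = 2 N2, p = 3: f1/f2 = 2^(3/2)
  f3 <- recruit_muscles(list(C = matrix(0.05, 1, 2), r = 10,
                             N = c(1000, 500), p = 3))
  expect_equal(f3[1] / f3[2], 2^1.5, tolerance = 1e-6)
  # numeric-optimizer oracle on the same problem
  obj <- function(f1) (f1 / 1000)^3 + ((10 / 0.05 - f1) / 500)^3
  opt <- stats::optimize(obj, c(0, 200), tol = 1e-12)
  expect_equal(f3[1], opt$minimum, tolerance = 1e-6)
})

test_that("recruitment KKT residual, reordering and load-scaling behave", {
  set.seed(3)
  mus <- default_hip_muscles()
  pr <- build_recruitment_problem(mus, c(15, -30, 5))
  f <- recruit_muscles(pr)
  expect_lt(max(abs(pr$C %*% f - pr$r)), 1e-6 * (1 + max(abs(pr$r))))
  expect_true(all(f >= 0))
  # invariant to muscle reordering
  idx <- sample(length(mus))
  pr2 <- pr
  pr2$C <- pr$C[, idx]; pr2$N <- pr$N[idx]; pr2$names <- pr$names[idx]
  f2 <- recruit_muscles(pr2)
  expect_equal(as.numeric(f2), as.numeric(f)[idx], tolerance = 1e-6)
  # scaling the demand keeps the active set and scales the equilibrium
  pr3 <- pr; pr3$r <- 2.5 * pr$r
  f3 <- recruit_muscles(pr3)
  expect_equal(which(f3 > 1e-9), which(f > 1e-9))
  expect_equal(as.numeric(pr$C %*% f3), as.numeric(2.5 * pr$r),
               tolerance = 1e-6)
  # minimality: random feasible perturbations only increase the objective
  Z <- MASS::Null(t(pr$C))
  objective <- function(ff) sum((ff / pr$N)^3)
  for (k in 1:20) {
    dz <- Z %*% stats::rnorm(ncol(Z), 0, 5)
    fp <- as.numeric(f) + dz
    if (all(fp >= 0)) {
      expect_gte(objective(fp), objective(as.numeric(f)) - 1e-9)
    }
  }
})

test_that("equal-arm recruitment follows the N^(p/(p-1)) allocation", {
  set.seed(11)
  for (n in 2:5) {
    N <- stats::runif(n, 300, 1500)
    f <- recruit_muscles(list(C = matrix(0.04, 1, n), r = 12, N = N, p = 3))
    ratios <- as.numeric(f) / N^(3 / 2)
    expect_lt(diff(range(ratios)) / mean(ratios), 1e-6)
  }
})

test_that("infeasible demands raise an informative error", {
  # both muscles push the same way; a negative demand is unreachable
  expect_error(
    recruit_muscles(list(C = matrix(c(0.05, 0.03), 1, 2), r = -10,
                         N = c(1000, 1000), p = 3)),
    class = "paosim_infeasible_error")
  expect_error(
    recruit_muscles(list(C = matrix(0.05, 1, 1), r = 10, N = 1000, p = 1)),
    class = "paosim_config_error")
})

test_that("hip reaction force closes the balance", {
  # no muscles, no loads
  h0 <- hip_reaction_force(numeric(0), matrix(0, 3, 0), c(0, 0, 0), 70)
  expect_equal(h0$vector, c(0, 0, 0))
  expect_equal(h0$bw, 0)
  # single-leg-stance toy: supported weight (5/6) BW at lever 0.10 m,
  # vertical abductor with 0.05 m arm; static balance closed form
  mass <- 72; W <- (5 / 6) * mass * 9.81
  f_abd <- W * 0.10 / 0.05
  h <- hip_reaction_force(f_abd, matrix(c(0, 0, 1), 3, 1),
                          external = c(0, 0, W), body_mass = mass)
  expect_equal(h$vector, c(0, 0, -(W + f_abd)))
  expect_equal(h$bw, (W + f_abd) / (mass * 9.81), tolerance = 1e-12)
  # linearity in the loads
  h2 <- hip_reaction_force(2 * f_abd, matrix(c(0, 0, 1), 3, 1),
                           external = c(0, 0, 2 * W), body_mass = mass)
  expect_equal(h2$vector, 2 * h$vector)
})

test_that("muscle group curves sum the member forces in BW", {
  groups <- c("extensor", "abductor", "abductor", "adductor")
  forces <- rbind(c(10, 20, 30, 40), c(0, 0, 0, 0))
  gf <- group_muscle_forces(forces, groups, body_mass = 65)
  bw <- 65 * 9.81
  expect_equal(gf$abductor, c(50, 0) / bw)
  expect_equal(gf$extensor, c(10, 0) / bw)
  expect_equal(gf$flexor, c(0, 0))
  expect_error(group_muscle_forces(forces, c(groups[-4], "spine"), 65),
               class = "paosim_config_error")
  # single-group model: group curve equals the total muscle force
  gf1 <- group_muscle_forces(matrix(c(5, 7), 2, 1), "flexor", 65)
  expect_equal(gf1$flexor, c(5, 7) / bw)
})

test_that("full trial analysis produces equilibrium at every sample", {
  tr <- generate_gait_trial(local_noiseless_profile("healthy"))
  ida <- run_ida(normalize_to_cycle(tr))
  pr <- build_recruitment_problem(ida$muscles, c(0, 0, 0))
  r_all <- as.matrix(ida$samples[, c("moment_x_Nm", "moment_y_Nm",
                                     "moment_z_Nm")])
  resid <- abs(pr$C %*% t(ida$muscle_forces) - t(r_all))
  expect_true(all(resid <= 1e-6 * (1 + max(abs(r_all)))))
  expect_true(all(ida$muscle_forces >= 0))
  expect_equal(nrow(ida$phase_summary), 8)
})
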