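test_that("cycle normalization resamples onto 101 points correctly", {
  # constant signal stays constant
  n <- 180
  tt <- seq(0, 1.2, length.out = n)
  tr <- tibble::tibble(time_s = tt,
                       angle_sagittal_deg = rep(7, n),
                       angle_frontal_deg = seq(0, 10, length.out = n),
                       angle_transverse_deg = sin(tt),
                       grf_x_N = 0, grf_y_N = 0, grf_z_N = 0,
                       grm_x_Nm = 0, grm_y_Nm = 0, grm_z_Nm = 0)
  attr(tr, "body_mass") <- 70
  attr(tr, "events") <- c(heel_strike_1 = 0, toe_off = 0.744,
                          heel_strike_2 = 1.2)
  cur <- normalize_to_cycle(tr)
  expect_equal(nrow(cur), 101)
  expect_true(all(cur$angle_sagittal_deg == 7))
  # linear ramp in time becomes a linear ramp in cycle percent
  expect_equal(cur$angle_frontal_deg, seq(0, 10, length.out = 101),
               tolerance = 1e-12)
  # input already on the 101-point uniform grid is reproduced exactly
  tt2 <- seq(0, 1.2, length.out = 101)
  tr2 <- tr[rep(1, 101), ]
  tr2$time_s <- tt2
  tr2$angle_transverse_deg <- sin(3 * tt2)
  attr(tr2, "events") <- attr(tr, "events")
  attr(tr2, "body_mass") <- 70
  cur2 <- normalize_to_cycle(tr2)
  expect_equal(cur2$angle_transverse_deg, tr2$angle_transverse_deg,
               tolerance = 1e-12)
  # fewer than two heel strikes is an event error
  attr(tr, "events") <- c(heel_strike_1 = 0, toe_off = 0.744)
  expect_error(normalize_to_cycle(tr), class = "paosim_event_error")
})

test_that("normalization preserves extrema of smooth signals", {
  tr <- generate_gait_trial(local_noiseless_profile("healthy"),
                            n_samples = 400)
  cur <- normalize_to_cycle(tr)
  for (col in c("angle_sagittal_deg", "grf_z_N")) {
    rng <- max(tr[[col]]) - min(tr[[col]])
    expect_lt(abs(max(cur[[col]]) - max(tr[[col]])), 0.01 * rng)
    expect_lt(abs(min(cur[[col]]) - min(tr[[col]])), 0.01 * rng)
  }
})

test_that("RLA phase set is an ordered partition of the cycle", {
  ph <- rla_phases()
  expect_equal(nrow(ph), 8)
  expect_equal(ph$start[1], 0)
  expect_equal(ph$end[8], 100)
  expect_equal(ph$start[-1], ph$end[-8])  # disjoint + covering
  expect_equal(phase_at(ph, 55), 5)      # pre-swing
  expect_equal(phase_at(ph, c(0, 1.9, 2, 100)), c(1, 1, 2, 8))
  # overridden boundaries are honoured
  ph2 <- rla_phases(c(0, 5, 15, 30, 50, 60, 75, 90, 100))
  expect_equal(phase_at(ph2, 55), 5)
  expect_equal(ph2$end[1], 5)
  expect_error(rla_phases(c(0, 2, 12, 31, 50, 62, 75, 87, 99)),
               class = "paosim_config_error")
  cur <- make_cycle()
  expect_s3_class(segment_rla_phases(cur), "paosim_phase_set")
})

test_that("medoid selection matches exhaustive search", {
  set.seed(42)
  curves <- lapply(1:7, function(i) stats::rnorm(101))
  X <- paosim:::curve_feature_matrix(curves)
  D <- as.matrix(stats::dist(X))
  for (k in 1:4) {
    expect_equal(select_typical_trials(curves, k),
                 brute_force_medoids(D, k), info = paste("k =", k))
  }
  # k = 1 is the distance-sum minimiser
  expect_equal(select_typical_trials(curves, 1),
               unname(which.min(rowSums(D))))
  # k = n is the identity selection
  expect_equal(cluster_subjects_by_hrf(curves, 7), 1:7)
  expect_error(select_typical_trials(curves, 8),
               class = "paosim_parameter_error")
})

test_that("well-separated curve families are each represented", {
  set.seed(7)
  fam <- function(mu) lapply(1:4, function(i) mu + stats::rnorm(101, 0, .1))
  curves <- c(fam(rep(0, 101)), fam(sin(seq(0, 2 * pi, length.out = 101)) *
                                      5), fam(rep(10, 101)))
  sel <- select_typical_trials(curves, 3)
  expect_length(sel, 3)
  expect_equal(sort(ceiling(sel / 4)), 1:3)  # one medoid per family
  # two HRF families, high-peak vs flat
  hrf <- c(lapply(1:3, function(i) 3 * sin(seq(0, pi, length.out = 101)) +
                    stats::rnorm(101, 0, .05)),
           lapply(1:3, function(i) rep(1.2, 101) +
                    stats::rnorm(101, 0, .05)))
  sel2 <- cluster_subjects_by_hrf(hrf, 2)
  expect_length(sel2, 2)
  expect_equal(sort(ceiling(sel2 / 3)), 1:2)
})

test_that("five trials reduce to three distinct typical representatives", {
  prof <- cohort_profile("postop", noise_sd = 0.03)
  trials <- lapply(1:5, function(s) generate_gait_trial(prof, seed = s))
  curves <- lapply(trials, normalize_to_cycle)
  sel <- select_typical_trials(curves, 3)
  expect_length(unique(sel), 3)
  expect_true(all(sel %in% 1:5))
})

test_that("range of motion and HRF peak extraction", {
  # sinusoid of amplitude A has RoM 2A
  pct <- seq(0, 100, length.out = 101)
  cur <- make_cycle(sag = 12 * sin(2 * pi * pct / 100))
  s <- extract_rom_and_peaks(cur)
  expect_equal(s$rom_sagittal_deg, 24, tolerance = 1e-9)
  # monotone HRF curve: no second peak
  mono <- extract_rom_and_peaks(seq(0.5, 3, length.out = 101))
  expect_true(mono$second_peak_flat)
  expect_true(is.na(mono$hrf_peak2_bw))
  # synthetic M-curve with known bump heights
  h <- 1 + 1.8 * exp(-(pct - 15)^2 / 40) + 1.2 * exp(-(pct - 48)^2 / 40)
  pk <- extract_rom_and_peaks(h)
  expect_equal(pk$hrf_peak1_bw, max(h[pct < 35]), tolerance = 1e-12)
  expect_equal(pk$hrf_peak1_pct, 15, tolerance = 1)
  expect_equal(pk$hrf_peak2_bw, max(h[pct > 35 & pct < 62]),
               tolerance = 1e-12)
  expect_false(pk$second_peak_flat)
})
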