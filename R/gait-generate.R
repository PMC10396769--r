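.paosim_cache <- new.env(parent = emptyenv())

#' Define a cohort profile for synthetic gait generation
#'
#' Encodes the group-level gait statistics the generator reproduces:
#' body mass, scaling ratios, the target first/second hip-reaction-force
#' peaks (body-weight multiples, mean and SD across trials), per-plane
#' range-of-motion targets, and the waveform noise level. Defaults for the
#' pre- and postoperative groups carry the reported group statistics
#' (postoperative initial peak 3.12 +/- 1.41 BW, preoperative second peak
#' 2.11 +/- 1.03 BW, and the per-plane ranges of motion); healthy defaults
#' are representative normal-gait values with a balanced M-shaped reaction
#' curve.
#'
#' @param group `"healthy"`, `"preop"` or `"postop"`.
#' @param body_mass Body mass, kg.
#' @param body_height_ratio Subject/generic height ratio `k_L`.
#' @param fat_ratio Body-fat ratio in `[0, 0.5)`.
#' @param hrf_peak1_mean,hrf_peak1_sd First-peak target, BW.
#' @param hrf_peak2_mean,hrf_peak2_sd Second-peak target, BW.
#' @param rom_targets Named numeric: per-plane range of motion, degrees
#'   (`sagittal`, `frontal`, `transverse`).
#' @param noise_sd Waveform noise as a fraction of each signal's amplitude.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A `paosim_cohort_profile` list.
#' @export
cohort_profile <- function(group = c("healthy", "preop", "postop"),
                           body_mass = 65, body_height_ratio = 1,
                           fat_ratio = NULL,
                           hrf_peak1_mean = NULL, hrf_peak1_sd = NULL,
                           hrf_peak2_mean = NULL, hrf_peak2_sd = NULL,
                           rom_targets = NULL, noise_sd = 0.02, seed = 1L) {
  if (is.character(group) && !all(group %in% c("healthy", "preop",
                                               "postop"))) {
    stop_paosim(sprintf("unknown cohort group '%s'", group[1]),
                "paosim_config_error")
  }
  group <- match.arg(group)
  def <- switch(group,
    healthy = list(fat = 0.25, p1 = 2.90, s1 = 0.40, p2 = 2.80, s2 = 0.40,
                   rom = c(sagittal = 45.0, frontal = 16.0,
                           transverse = 16.0),
                   widths = c(0.30, 0.30)),
    preop = list(fat = 0.28, p1 = 2.60, s1 = 0.90, p2 = 2.11, s2 = 1.03,
                 rom = c(sagittal = 37.6, frontal = 11.5, transverse = 8.4),
                 widths = c(0.26, 0.36)),
    postop = list(fat = 0.28, p1 = 3.12, s1 = 1.41, p2 = 2.00, s2 = 0.80,
                  rom = c(sagittal = 35.5, frontal = 14.3,
                          transverse = 13.6),
                  widths = c(0.20, 0.36)))
  prof <- list(group = group,
               body_mass = body_mass,
               body_height_ratio = body_height_ratio,
               fat_ratio = fat_ratio %||% def$fat,
               hrf_peak1_mean = hrf_peak1_mean %||% def$p1,
               hrf_peak1_sd = hrf_peak1_sd %||% def$s1,
               hrf_peak2_mean = hrf_peak2_mean %||% def$p2,
               hrf_peak2_sd = hrf_peak2_sd %||% def$s2,
               rom_targets = rom_targets %||% def$rom,
               hump_widths = def$widths,
               noise_sd = noise_sd, seed = as.integer(seed))
  if (prof$body_mass <= 0) {
    stop_paosim("body mass must be positive", "paosim_config_error")
  }
  if (prof$fat_ratio < 0 || prof$fat_ratio >= 0.5) {
    stop_paosim("fat ratio must lie in [0, 0.5)", "paosim_config_error")
  }
  sds <- c(prof$hrf_peak1_sd, prof$hrf_peak2_sd)
  if (any(sds < 0) || prof$hrf_peak1_mean <= 0 || prof$hrf_peak2_mean <= 0) {
    stop_paosim("peak means must be positive and SDs non-negative",
                "paosim_config_error")
  }
  class(prof) <- "paosim_cohort_profile"
  prof
}

# raised-cosine bump with compact support |u - c| < w
.bump <- function(u, c, w) {
  ifelse(abs(u - c) < w, cos(pi * (u - c) / (2 * w))^2, 0)
}

# deterministic trial waveform for given hump scales (c1, c2), no noise
.gait_template <- function(profile, n_samples, c1, c2) {
  Tcyc <- 1.1
  stance <- 0.62
  tt <- seq(0, Tcyc, length.out = n_samples)
  s <- tt / Tcyc
  u <- pmin(s / stance, 1)
  in_stance <- s <= stance
  rom <- profile$rom_targets
  ang_sag <- 5 + rom[["sagittal"]] / 2 * cos(2 * pi * (s - 0.9))
  ang_fro <- 2 + rom[["frontal"]] / 2 * sin(2 * pi * (s - 0.05))
  ang_tra <- rom[["transverse"]] / 2 * sin(2 * pi * (s - 0.30))
  bwN <- profile$body_mass * .g
  w <- profile$hump_widths
  blk <- function(z, x, y, cop) {
    Fz <- z * in_stance
    Fx <- x * in_stance
    Fy <- y * in_stance
    grm <- t(vapply(seq_along(s), function(i) {
      cross3(cop, c(Fx[i], Fy[i], Fz[i]))
    }, numeric(3)))
    list(F = cbind(Fx, Fy, Fz) * bwN, M = grm * bwN)
  }
  b1 <- blk(.bump(u, 0.25, w[1]), -0.03 * .bump(u, 0.22, 0.18),
            0.04 * .bump(u, 0.25, 0.20), c(0.02, -0.06, 0))
  b2 <- blk(.bump(u, 0.78, w[2]), 0.03 * .bump(u, 0.80, 0.18),
            0.04 * .bump(u, 0.78, 0.20), c(-0.03, -0.06, 0))
  base <- blk(0.70 * sin(pi * u) * in_stance, 0 * u, 0 * u,
              c(0.00, -0.04, 0))
  cb <- (c1 + c2) / 2
  F <- c1 * b1$F + c2 * b2$F + cb * base$F
  M <- c1 * b1$M + c2 * b2$M + cb * base$M
  out <- tibble::tibble(time_s = tt,
                        angle_sagittal_deg = ang_sag,
                        angle_frontal_deg = ang_fro,
                        angle_transverse_deg = ang_tra,
                        grf_x_N = F[, 1], grf_y_N = F[, 2], grf_z_N = F[, 3],
                        grm_x_Nm = M[, 1], grm_y_Nm = M[, 2],
                        grm_z_Nm = M[, 3])
  attr(out, "body_mass") <- profile$body_mass
  attr(out, "events") <- c(heel_strike_1 = 0, toe_off = stance * Tcyc,
                           heel_strike_2 = Tcyc)
  attr(out, "group") <- profile$group
  class(out) <- c("paosim_gait_trial", class(out))
  out
}

#' Hip-reaction-force cycle curve for one trial
#'
#' Convenience wrapper: normalizes a trial to the gait cycle, runs the
#' musculoskeletal stage, and returns the HRF magnitude curve in BW (101
#' samples).
#'
#' @param trial A `paosim_gait_trial`.
#' @param muscles,p Passed to [run_ida()].
#' @return Numeric vector of 101 HRF values in body-weight multiples.
#' @export
trial_hrf <- function(trial, muscles = default_hip_muscles(), p = 3) {
  curves <- normalize_to_cycle(trial)
  ida <- run_ida(curves, muscles = muscles, p = p)
  ida$samples$hrf_bw
}

.template_peaks <- function(profile, n_samples, c1, c2) {
  tr <- .gait_template(profile, n_samples, c1, c2)
  pk <- extract_rom_and_peaks(trial_hrf(tr))
  p2 <- pk$hrf_peak2_bw
  if (is.na(p2)) {
    # flat second peak: use the late-stance level so calibration can lift it
    hrf <- trial_hrf(tr)
    pct <- seq(0, 100, length.out = length(hrf))
    p2 <- max(hrf[pct >= 40 & pct <= 62])
  }
  c(pk$hrf_peak1_bw, p2)
}

.calibrate_profile <- function(profile, n_samples) {
  key <- paste(profile$group, profile$body_mass, profile$body_height_ratio,
               profile$fat_ratio, profile$hrf_peak1_mean,
               profile$hrf_peak2_mean,
               paste(profile$rom_targets, collapse = ","),
               paste(profile$hump_widths, collapse = ","),
               n_samples, sep = "|")
  hit <- .paosim_cache[[key]]
  if (!is.null(hit)) return(hit)
  target <- c(profile$hrf_peak1_mean, profile$hrf_peak2_mean)
  cc <- c(1, 1)
  for (it in 1:5) {
    pk <- .template_peaks(profile, n_samples, cc[1], cc[2])
    ratio <- target / pk
    cc <- cc * ratio
    if (max(abs(ratio - 1)) < 5e-3) break
  }
  .paosim_cache[[key]] <- cc
  cc
}

#' Generate a synthetic gait trial
#'
#' Produces one gait cycle of hip angles (three planes), ground reaction
#' force and moment, and heel-strike/toe-off events for a cohort profile.
#' Waveforms are sums of raised-cosine bumps per signal: the vertical GRF
#' has the double-hump stance shape and is exactly zero in swing. The two
#' hump amplitudes are calibrated (through the package's own
#' musculoskeletal stage) so that the downstream hip-reaction-force curve
#' attains the profile's first/second peak targets; per-trial peak targets
#' are drawn from the profile's mean/SD, giving the group its reported
#' between-trial spread. Generation is deterministic for a fixed profile
#' and seed.
#'
#' @param profile A `paosim_cohort_profile`.
#' @param n_samples Number of time samples (>= 50).
#' @param seed Optional seed override (defaults to `profile$seed`).
#' @return A `paosim_gait_trial` tibble with attributes `body_mass`,
#'   `events`, `group`, `seed`, `peak_targets_bw`.
#' @export
generate_gait_trial <- function(profile, n_samples = 101L, seed = NULL) {
  stopifnot(inherits(profile, "paosim_cohort_profile"))
  if (n_samples < 50) {
    stop_paosim("n_samples must be at least 50", "paosim_config_error")
  }
  seed <- as.integer(seed %||% profile$seed)
  cc0 <- .calibrate_profile(profile, n_samples)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t1 <- max(stats::rnorm(1, profile$hrf_peak1_mean, profile$hrf_peak1_sd),
            0.3)
  t2 <- max(stats::rnorm(1, profile$hrf_peak2_mean, profile$hrf_peak2_sd),
            0.3)
  cc <- cc0 * c(t1 / profile$hrf_peak1_mean, t2 / profile$hrf_peak2_mean)
  # one correction step against the measured noiseless response
  pk <- .template_peaks(profile, n_samples, cc[1], cc[2])
  cc <- cc * pmax(pmin(c(t1, t2) / pk, 2), 0.5)
  out <- .gait_template(profile, n_samples, cc[1], cc[2])
  if (profile$noise_sd > 0) {
    # band-limited noise: white noise convolved with a Gaussian kernel and
    # rescaled, so that kinematic noise stays differentiable (angles are
    # double-differentiated downstream) as it would after standard low-pass
    # filtering of motion-capture data
    smooth_noise <- function(n, sd_target, tau) {
      k <- stats::dnorm(seq(-3 * tau, 3 * tau), 0, tau)
      k <- k / sum(k)
      e <- stats::rnorm(n + 6 * tau, 0, 1)
      e <- as.numeric(stats::filter(e, k, sides = 2))
      e <- e[(3 * tau + 1):(3 * tau + n)]
      e[is.na(e)] <- 0
      if (stats::sd(e) > 0) e <- e / stats::sd(e)
      e * sd_target
    }
    for (col in gait_signal_cols()) {
      amp <- max(out[[col]]) - min(out[[col]])
      if (amp == 0) next
      tau <- if (grepl("^angle", col)) 8L else 3L
      e <- smooth_noise(n_samples, profile$noise_sd * amp, tau)
      if (grepl("^gr", col)) e <- e * ifelse(out[[col]] != 0, 1, 0)
      out[[col]] <- out[[col]] + e
    }
  }
  attr(out, "seed") <- seed
  attr(out, "peak_targets_bw") <- c(peak1 = t1, peak2 = t2)
  out
}

#' Write / read a gait trial as CSV plus JSON sidecar
#'
#' The CSV holds the time series (time plus the columns of
#' [gait_signal_cols()]); the JSON sidecar (same path with extension
#' `.json`) holds body mass, events, group and seed.
#'
#' @param trial A `paosim_gait_trial`.
#' @param path CSV file path.
#' @return `read_gait_trial()` returns the reconstructed trial.
#' @export
write_gait_trial <- function(trial, path) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  side <- list(body_mass = attr(trial, "body_mass"),
               events = as.list(attr(trial, "events")),
               group = attr(trial, "group"),
               seed = attr(trial, "seed"))
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gait_trial
#' @export
read_gait_trial <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  if (any(diff(df$time_s) <= 0)) {
    stop_paosim("trial time must be strictly increasing",
                "paosim_input_error")
  }
  attr(df, "body_mass") <- side$body_mass
  attr(df, "events") <- unlist(side$events)
  attr(df, "group") <- side$group
  attr(df, "seed") <- side$seed
  class(df) <- c("paosim_gait_trial", class(df))
  df
}
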