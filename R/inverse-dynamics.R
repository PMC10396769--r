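rot_y <- function(th) {
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
}
rot_x <- function(th) {
  matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
         byrow = TRUE)
}
rot_z <- function(th) {
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# second time derivative by central differences, one-sided at the ends
second_deriv <- function(y, t) {
  n <- length(y)
  d2 <- numeric(n)
  if (n < 3) return(d2)
  h <- t[2] - t[1]
  d2[2:(n - 1)] <- (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / h^2
  d2[1] <- d2[2]
  d2[n] <- d2[n - 1]
  d2
}

#' Default stance-limb segment parameters
#'
#' Anthropometric constants for the lumped stance-leg segment: mass
#' fraction, hip height, centre-of-mass offset and radius-of-gyration
#' fraction (standard gait-analysis segment tables).
#'
#' @param body_mass Body mass, kg.
#' @param hip_height Hip-centre height above the force plate, m.
#' @return List of segment parameters.
#' @export
default_segment_params <- function(body_mass, hip_height = 0.9) {
  leg_mass <- 0.161 * body_mass
  leg_len <- hip_height
  list(leg_mass = leg_mass,
       hip_height = hip_height,
       com_offset = 0.45 * leg_len,     # below the hip, along the segment
       inertia = leg_mass * (0.35 * leg_len)^2)
}

#' Net hip moments by inverse dynamics
#'
#' Newton-Euler balance on a simplified stance-limb linkage: the leg is a
#' single rigid segment rotating about the hip with the recorded hip
#' angles; ground reaction force and moment are applied at the plate
#' origin (directly below the hip), gravity and inertia of the segment are
#' included with central-difference accelerations. Returns the net hip
#' moment the muscles must produce at each cycle sample.
#'
#' @param curves A `paosim_gait_cycle` (must include GRF/GRM and angles).
#' @param body_mass Body mass in kg (defaults to the curves' attribute).
#' @param segment Segment parameters (see [default_segment_params()]).
#' @return Tibble: `cycle_pct`, `moment_x_Nm`, `moment_y_Nm`,
#'   `moment_z_Nm`, plus the segment state used (`com_x/y/z_m`,
#'   `acc_x/y/z`).
#' @export
inverse_dynamics <- function(curves, body_mass = NULL, segment = NULL) {
  need <- c("grf_x_N", "grf_y_N", "grf_z_N")
  if (!all(need %in% names(curves))) {
    stop_paosim("curves lack ground reaction force columns",
                "paosim_input_error")
  }
  body_mass <- body_mass %||% attr(curves, "body_mass")
  if (is.null(body_mass)) {
    stop_paosim("body mass is required", "paosim_input_error")
  }
  segment <- segment %||% default_segment_params(body_mass)
  Tcyc <- attr(curves, "cycle_duration_s") %||% 1.1
  n <- nrow(curves)
  tt <- curves$cycle_pct / 100 * Tcyc
  d2r <- pi / 180
  sag <- curves$angle_sagittal_deg * d2r
  fro <- curves$angle_frontal_deg * d2r
  tra <- curves$angle_transverse_deg * d2r
  com0 <- c(0, 0, -segment$com_offset)
  p_hip <- c(0, 0, segment$hip_height)
  com <- t(vapply(seq_len(n), function(i) {
    drop(rot_z(tra[i]) %*% rot_x(fro[i]) %*% rot_y(sag[i]) %*% com0)
  }, numeric(3)))
  acc <- apply(com, 2, second_deriv, t = tt)
  alpha <- cbind(second_deriv(fro, tt), second_deriv(sag, tt),
                 second_deriv(tra, tt))
  mlg <- segment$leg_mass
  I <- segment$inertia
  grf <- cbind(curves$grf_x_N, curves$grf_y_N, curves$grf_z_N)
  grm <- if (all(c("grm_x_Nm", "grm_y_Nm", "grm_z_Nm") %in% names(curves))) {
    cbind(curves$grm_x_Nm, curves$grm_y_Nm, curves$grm_z_Nm)
  } else matrix(0, n, 3)
  M <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    m_ext <- cross3(-p_hip, grf[i, ]) + grm[i, ] +
      cross3(com[i, ], c(0, 0, -mlg * .g))
    M[i, ] <- I * alpha[i, ] + mlg * cross3(com[i, ], acc[i, ]) - m_ext
  }
  tibble::tibble(cycle_pct = curves$cycle_pct,
                 moment_x_Nm = M[, 1], moment_y_Nm = M[, 2],
                 moment_z_Nm = M[, 3],
                 com_x_m = com[, 1], com_y_m = com[, 2], com_z_m = com[, 3],
                 acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3])
}

#' Hip joint reaction force closing the force balance
#'
#' The hip reaction is the contact force that closes the force balance at
#' the joint: `HRF = -(sum_i f_i u_i + F_external + F_inertial)`, reported
#' as a vector in N and as magnitude in body-weight multiples.
#'
#' @param f Muscle force vector, N.
#' @param lines 3 x n matrix of unit lines of action (at the insertion,
#'   pointing from femur toward pelvis).
#' @param external External force on the limb (GRF plus segment gravity),
#'   N, length 3.
#' @param body_mass Body mass, kg.
#' @param inertial Inertial force term (`-m a`), N.
#' @return List: `vector` (N), `magnitude_N`, `bw`.
#' @export
hip_reaction_force <- function(f, lines, external = c(0, 0, 0),
                               body_mass = 70, inertial = c(0, 0, 0)) {
  tot <- if (length(f) > 0) drop(lines %*% f) else c(0, 0, 0)
  v <- -(tot + external + inertial)
  mag <- sqrt(sum(v^2))
  list(vector = v, magnitude_N = mag, bw = mag / (body_mass * .g))
}

#' Sum muscle forces by functional group
#'
#' @param forces Matrix (n_samples x n_muscles) of muscle forces in N.
#' @param groups Character vector of group labels per muscle.
#' @param body_mass Body mass (kg) for body-weight normalisation.
#' @return Tibble (n_samples x groups) of group force sums in BW.
#' @export
group_muscle_forces <- function(forces, groups, body_mass) {
  lv <- c("extensor", "flexor", "abductor", "adductor")
  if (!all(groups %in% lv)) {
    stop_paosim(sprintf("unknown muscle group label(s): %s",
                        paste(setdiff(groups, lv), collapse = ", ")),
                "paosim_config_error")
  }
  bw <- body_mass * .g
  out <- tibble::tibble(.rows = nrow(forces))
  for (g in lv) {
    sel <- groups == g
    out[[g]] <- if (any(sel)) {
      rowSums(forces[, sel, drop = FALSE]) / bw
    } else rep(0, nrow(forces))
  }
  out
}

#' Run the full inverse-dynamics + recruitment analysis on one gait cycle
#'
#' Chains [inverse_dynamics()], [recruit_muscles()] at every cycle sample,
#' [hip_reaction_force()] and [group_muscle_forces()], then aggregates over
#' the Rancho Los Amigos phases. This is the per-trial musculoskeletal
#' stage of the pipeline; its phase aggregates feed the finite-element
#' load cases.
#'
#' @param curves A `paosim_gait_cycle`.
#' @param body_mass Body mass, kg (defaults to the curves' attribute).
#' @param muscles Muscle set (default [default_hip_muscles()]).
#' @param p Recruitment exponent.
#' @param phases Phase table from [rla_phases()].
#' @param segment Optional segment parameter override.
#' @return A `paosim_ida` object: list with `samples` (tibble: cycle_pct,
#'   net moments, HRF vector in N, `hrf_bw`, group forces in BW),
#'   `muscle_forces` (n x muscles matrix, N), `phase_summary` (per-phase
#'   means incl. HRF vector and per-group pelvis-side force vectors in N),
#'   `muscles`, `body_mass`.
#' @export
run_ida <- function(curves, body_mass = NULL, muscles = default_hip_muscles(),
                    p = 3, phases = rla_phases(), segment = NULL) {
  body_mass <- body_mass %||% attr(curves, "body_mass")
  idm <- inverse_dynamics(curves, body_mass, segment)
  segment <- segment %||% default_segment_params(body_mass)
  n <- nrow(curves)
  nm <- length(muscles)
  pr0 <- build_recruitment_problem(muscles, c(0, 0, 0), p = p)
  groups <- vapply(muscles, `[[`, "", "group")
  forces <- matrix(0, n, nm,
                   dimnames = list(NULL, vapply(muscles, `[[`, "", "name")))
  hrf_vec <- matrix(0, n, 3)
  hrf_bw <- numeric(n)
  grf <- cbind(curves$grf_x_N, curves$grf_y_N, curves$grf_z_N)
  lam <- NULL
  for (i in seq_len(n)) {
    pr <- pr0
    pr$r <- c(idm$moment_x_Nm[i], idm$moment_y_Nm[i], idm$moment_z_Nm[i])
    f <- recruit_muscles(pr, lambda0 = lam)
    lam_try <- attr(f, "lambda")
    # warm start only helps when it is finite and nonzero
    lam <- if (all(is.finite(lam_try)) && any(lam_try != 0)) lam_try else NULL
    forces[i, ] <- f
    ext <- grf[i, ] + c(0, 0, -segment$leg_mass * .g)
    inert <- -segment$leg_mass * c(idm$acc_x[i], idm$acc_y[i], idm$acc_z[i])
    h <- hip_reaction_force(as.numeric(f), pr0$lines, ext, body_mass, inert)
    hrf_vec[i, ] <- h$vector
    hrf_bw[i] <- h$bw
  }
  gf <- group_muscle_forces(forces, groups, body_mass)
  samples <- tibble::tibble(cycle_pct = curves$cycle_pct,
                            moment_x_Nm = idm$moment_x_Nm,
                            moment_y_Nm = idm$moment_y_Nm,
                            moment_z_Nm = idm$moment_z_Nm,
                            hrf_x_N = hrf_vec[, 1], hrf_y_N = hrf_vec[, 2],
                            hrf_z_N = hrf_vec[, 3], hrf_bw = hrf_bw)
  samples <- dplyr::bind_cols(samples, gf)
  ph_id <- phase_at(phases, samples$cycle_pct)
  # pelvis-side force vectors: each muscle pulls its pelvic attachment
  # toward the femur (-u per unit force); the joint contact pushes with -HRF
  U <- pr0$lines
  pelvis_group <- array(0, dim = c(n, 4, 3),
                        dimnames = list(NULL, c("extensor", "flexor",
                                                "abductor", "adductor"),
                                        NULL))
  for (g in seq_along(dimnames(pelvis_group)[[2]])) {
    gl <- dimnames(pelvis_group)[[2]][g]
    sel <- which(groups == gl)
    if (length(sel) > 0) {
      for (k in 1:3) {
        pelvis_group[, g, k] <-
          -forces[, sel, drop = FALSE] %*% U[k, sel]
      }
    }
  }
  ph_list <- lapply(seq_len(nrow(phases)), function(ip) {
    sel <- ph_id == ip
    row <- tibble::tibble(phase = phases$phase[ip], name = phases$name[ip],
                          hrf_bw = mean(samples$hrf_bw[sel]),
                          hrf_x_N = mean(samples$hrf_x_N[sel]),
                          hrf_y_N = mean(samples$hrf_y_N[sel]),
                          hrf_z_N = mean(samples$hrf_z_N[sel]))
    for (gl in c("extensor", "flexor", "abductor", "adductor")) {
      row[[paste0(gl, "_bw")]] <- mean(gf[[gl]][sel])
      gi <- match(gl, dimnames(pelvis_group)[[2]])
      for (k in 1:3) {
        row[[paste0(gl, "_", c("x", "y", "z")[k], "_N")]] <-
          mean(pelvis_group[sel, gi, k])
      }
    }
    row
  })
  out <- list(samples = samples, muscle_forces = forces,
              phase_summary = dplyr::bind_rows(ph_list),
              muscles = muscles, body_mass = body_mass,
              lines = U, groups = groups)
  class(out) <- "paosim_ida"
  out
}

#' @export
print.paosim_ida <- function(x, ...) {
  cat("Inverse dynamics + recruitment result:",
      nrow(x$samples), "samples,", ncol(x$muscle_forces), "muscles\n")
  pk <- extract_rom_and_peaks(x)
  cat(sprintf("HRF peak 1: %.2f BW at %.0f%%", pk$hrf_peak1_bw,
              pk$hrf_peak1_pct))
  if (!pk$second_peak_flat) {
    cat(sprintf("; peak 2: %.2f BW at %.0f%%\n", pk$hrf_peak2_bw,
                pk$hrf_peak2_pct))
  } else cat("; second peak flat\n")
  invisible(x)
}

#' @export
tidy.paosim_ida <- function(x, ...) x$samples

#' @export
glance.paosim_ida <- function(x, ...) {
  pk <- extract_rom_and_peaks(x)
  tibble::tibble(hrf_peak1_bw = pk$hrf_peak1_bw,
                 hrf_peak2_bw = pk$hrf_peak2_bw,
                 second_peak_flat = pk$second_peak_flat,
                 max_phase = x$phase_summary$phase[
                   which.max(x$phase_summary$hrf_bw)],
                 body_mass = x$body_mass)
}
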