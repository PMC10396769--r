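#' Gait signal column names
#'
#' Canonical column order for gait trial / cycle tables: three-plane hip
#' angles (deg), ground reaction force (N) and moment (N m) components.
#' @return Character vector of signal column names.
#' @export
gait_signal_cols <- function() {
  c("angle_sagittal_deg", "angle_frontal_deg", "angle_transverse_deg",
    "grf_x_N", "grf_y_N", "grf_z_N", "grm_x_Nm", "grm_y_Nm", "grm_z_Nm")
}

#' Normalize a gait trial to the 0-100% gait cycle
#'
#' Resamples every signal of a trial by linear interpolation onto 101
#' uniformly spaced points spanning one full gait cycle (heel strike to the
#' next heel strike of the same foot). Sample 0 is at heel strike.
#'
#' @param trial A `paosim_gait_trial` tibble (see [generate_gait_trial()] or
#'   [read_gait_trial()]); needs at least two heel-strike events.
#' @return A `paosim_gait_cycle` tibble with `cycle_pct` (0..100) and the
#'   columns of [gait_signal_cols()]; carries `body_mass`, `events`,
#'   `cycle_duration_s`, `source_rate_hz` attributes.
#' @export
normalize_to_cycle <- function(trial) {
  ev <- attr(trial, "events")
  hs <- sort(ev[grepl("^heel_strike", names(ev))])
  if (length(hs) < 2) {
    stop_paosim("trial needs two successive heel strikes to define a cycle",
                "paosim_event_error")
  }
  t0 <- hs[[1]]; t1 <- hs[[2]]
  if (!(min(trial$time_s) <= t0 && max(trial$time_s) >= t1)) {
    stop_paosim("heel-strike events outside the recorded time range",
                "paosim_event_error")
  }
  tq <- seq(t0, t1, length.out = 101L)
  sig <- intersect(gait_signal_cols(), names(trial))
  out <- tibble::tibble(cycle_pct = seq(0, 100, length.out = 101L))
  for (s in sig) {
    out[[s]] <- stats::approx(trial$time_s, trial[[s]], xout = tq,
                              rule = 2)$y
  }
  dt <- diff(trial$time_s)
  attr(out, "body_mass") <- attr(trial, "body_mass")
  attr(out, "events") <- ev
  attr(out, "cycle_duration_s") <- t1 - t0
  attr(out, "source_rate_hz") <- 1 / stats::median(dt)
  attr(out, "group") <- attr(trial, "group")
  class(out) <- c("paosim_gait_cycle", class(out))
  out
}

#' Rancho Los Amigos phase table
#'
#' The eight functional phases of the gait cycle as half-open percent
#' intervals (the last interval is closed at 100). Boundaries default to the
#' standard Rancho Los Amigos values and are configurable.
#'
#' @param boundaries Numeric vector of 9 increasing breakpoints starting at
#'   0 and ending at 100.
#' @return A `paosim_phase_set` tibble: `phase` (1-8), `name`, `start`,
#'   `end` (percent of cycle).
#' @examples
#' rla_phases()
#' @export
rla_phases <- function(boundaries = c(0, 2, 12, 31, 50, 62, 75, 87, 100)) {
  if (length(boundaries) != 9 || any(diff(boundaries) <= 0) ||
      boundaries[1] != 0 || boundaries[9] != 100) {
    stop_paosim("boundaries must be 9 increasing values from 0 to 100",
                "paosim_config_error")
  }
  nm <- c("initial contact", "loading response", "midstance",
          "terminal stance", "pre-swing", "initial swing", "midswing",
          "terminal swing")
  out <- tibble::tibble(phase = 1:8, name = nm,
                        start = boundaries[1:8], end = boundaries[2:9])
  class(out) <- c("paosim_phase_set", class(out))
  out
}

#' Segment a normalized gait cycle into RLA phases
#'
#' Returns the phase partition applicable to a set of cycle curves; the
#' boundaries come from configuration, the curves only validate the domain.
#'
#' @param curves A `paosim_gait_cycle` (validated, not otherwise used for
#'   the default boundary table).
#' @param boundaries Passed to [rla_phases()].
#' @return A `paosim_phase_set` tibble.
#' @export
segment_rla_phases <- function(curves,
                               boundaries = c(0, 2, 12, 31, 50, 62, 75, 87,
                                              100)) {
  stopifnot(inherits(curves, "paosim_gait_cycle") || is.data.frame(curves))
  rla_phases(boundaries)
}

#' Phase label at a cycle percent
#'
#' @param phases A `paosim_phase_set`.
#' @param pct Numeric vector of cycle percents in [0, 100].
#' @return Integer phase ids (1-8).
#' @examples
#' phase_at(rla_phases(), 55)  # pre-swing
#' @export
phase_at <- function(phases, pct) {
  if (any(pct < 0 | pct > 100)) {
    stop_paosim("percent must lie in [0, 100]", "paosim_input_error")
  }
  i <- findInterval(pct, c(phases$start, 100), rightmost.closed = TRUE)
  pmin(pmax(i, 1L), nrow(phases))
}

# ---- medoid clustering ------------------------------------------------

# z-score each signal column across observations, concatenate into one
# feature vector per curve set; constant signals contribute zeros.
curve_feature_matrix <- function(curves_list) {
  mats <- lapply(curves_list, function(cc) {
    if (is.data.frame(cc)) {
      cols <- setdiff(names(cc), "cycle_pct")
      unlist(cc[cols], use.names = FALSE)
    } else {
      as.numeric(cc)
    }
  })
  len <- unique(vapply(mats, length, integer(1)))
  if (length(len) != 1) {
    stop_paosim("curves must share a common sampling", "paosim_input_error")
  }
  X <- do.call(rbind, mats)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

# exact k-medoid search when the enumeration is small, PAM otherwise
medoid_indices <- function(D, k, exhaustive_limit = 5000) {
  n <- nrow(D)
  if (k > n) {
    stop_paosim("k exceeds the number of curves", "paosim_parameter_error")
  }
  if (k == n) return(seq_len(n))
  if (choose(n, k) <= exhaustive_limit) {
    best <- NULL
    best_cost <- Inf
    sets <- utils::combn(n, k)
    for (j in seq_len(ncol(sets))) {
      med <- sets[, j]
      cost <- sum(apply(D[, med, drop = FALSE], 1, min))
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best <- med
      }
    }
    sort(best)
  } else {
    fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
    sort(as.integer(fit$id.med))
  }
}

#' Select typical gait trials by medoid clustering
#'
#' Partitions repeated trials of one subject into `k` clusters on the
#' Euclidean distance between z-scored concatenated signal curves and
#' returns each cluster's medoid index — the "typical" trials carried into
#' the musculoskeletal simulation. For small inputs the medoid set is found
#' by exact enumeration; larger inputs use PAM.
#'
#' @param trials List of `paosim_gait_cycle` tibbles (or plain numeric
#'   vectors of equal length).
#' @param k Number of representatives (default 3).
#' @return Sorted integer indices of the selected trials.
#' @export
select_typical_trials <- function(trials, k = 3L) {
  if (length(trials) < k || k < 1) {
    stop_paosim("need at least k trials and k >= 1", "paosim_parameter_error")
  }
  X <- curve_feature_matrix(trials)
  D <- as.matrix(stats::dist(X))
  medoid_indices(D, as.integer(k))
}

#' Select representative subjects by their hip-reaction-force curves
#'
#' Applies the same medoid logic to per-subject HRF cycle curves (101
#' samples, body-weight units) to screen the subjects carried into finite-
#' element modeling.
#'
#' @param hrf_curves List of numeric vectors (101 samples each) or a matrix
#'   with one row per subject.
#' @param k Number of representative subjects.
#' @return Sorted integer indices of the representatives.
#' @export
cluster_subjects_by_hrf <- function(hrf_curves, k = 2L) {
  if (is.matrix(hrf_curves)) {
    hrf_curves <- lapply(seq_len(nrow(hrf_curves)),
                         function(i) hrf_curves[i, ])
  }
  if (length(hrf_curves) < k || k < 1) {
    stop_paosim("need at least k curves and k >= 1",
                "paosim_parameter_error")
  }
  X <- curve_feature_matrix(hrf_curves)
  D <- as.matrix(stats::dist(X))
  medoid_indices(D, as.integer(k))
}

# ---- range of motion and HRF peaks ------------------------------------

local_maxima_idx <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Range of motion and hip-reaction-force peak summary
#'
#' For angle curves, reports the per-plane range of motion (max minus min,
#' degrees). For an inverse-dynamics result (or a bare HRF curve in
#' body-weight units), reports the first and second stance peaks of the HRF
#' magnitude. The second peak is a stance local maximum after
#' `second_peak_after` percent of the cycle that exceeds the inter-peak
#' minimum by at least `min_prominence_bw`; when none qualifies the curve
#' is flagged flat (`peak2 = NA`), the pattern seen when the second peak
#' disappears postoperatively.
#'
#' @param x A `paosim_gait_cycle`, a `paosim_ida` result, or a numeric
#'   101-sample HRF curve in BW.
#' @param stance_end Percent of cycle at toe-off (default 62).
#' @param second_peak_after Earliest percent for the second peak (35).
#' @param min_prominence_bw Prominence threshold in BW (0.02).
#' @return A one-row tibble with any of `rom_sagittal_deg`,
#'   `rom_frontal_deg`, `rom_transverse_deg`, `hrf_peak1_bw`,
#'   `hrf_peak1_pct`, `hrf_peak2_bw`, `hrf_peak2_pct`, `second_peak_flat`.
#' @export
extract_rom_and_peaks <- function(x, stance_end = 62, second_peak_after = 35,
                                  min_prominence_bw = 0.02) {
  out <- tibble::tibble(.rows = 1)
  hrf <- NULL
  pct <- seq(0, 100, length.out = 101L)
  if (inherits(x, "paosim_ida")) {
    hrf <- x$samples$hrf_bw
    pct <- x$samples$cycle_pct
  } else if (is.numeric(x) && is.null(dim(x))) {
    hrf <- as.numeric(x)
    pct <- seq(0, 100, length.out = length(hrf))
  }
  if (is.data.frame(x)) {
    for (pl in c("sagittal", "frontal", "transverse")) {
      col <- paste0("angle_", pl, "_deg")
      if (col %in% names(x)) {
        out[[paste0("rom_", pl, "_deg")]] <- max(x[[col]]) - min(x[[col]])
      }
    }
    if ("hrf_bw" %in% names(x)) {
      hrf <- x$hrf_bw
      pct <- x$cycle_pct
    }
  }
  if (!is.null(hrf)) {
    st <- pct <= stance_end
    y <- hrf[st]
    p <- pct[st]
    im <- local_maxima_idx(y)
    # initial peak: the largest stance local maximum in the early window
    early <- im[p[im] < second_peak_after]
    i1 <- if (length(early) > 0) early[which.max(y[early])] else which.max(y)
    out$hrf_peak1_bw <- y[i1]
    out$hrf_peak1_pct <- p[i1]
    cand <- im[p[im] >= second_peak_after & im > i1]
    flat <- TRUE
    if (length(cand) > 0) {
      i2 <- cand[which.max(y[cand])]
      valley <- min(y[i1:i2])
      if (y[i2] - valley >= min_prominence_bw) {
        out$hrf_peak2_bw <- y[i2]
        out$hrf_peak2_pct <- p[i2]
        flat <- FALSE
      }
    }
    if (flat) {
      out$hrf_peak2_bw <- NA_real_
      out$hrf_peak2_pct <- NA_real_
    }
    out$second_peak_flat <- flat
  }
  out
}
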