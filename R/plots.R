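#' @export
autoplot.paosim_gait_trial <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(intersect(gait_signal_cols(),
                                                      names(object))),
                              names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Synthetic gait trial")
}

#' @export
autoplot.paosim_gait_cycle <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(intersect(gait_signal_cols(),
                                                      names(object))),
                              names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle_pct, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = "gait cycle (%)", y = NULL,
                  title = "Normalized gait cycle")
}

#' @export
autoplot.paosim_ida <- function(object, ...) {
  s <- object$samples
  long <- tidyr::pivot_longer(
    s[, c("cycle_pct", "hrf_bw", "extensor", "flexor", "abductor",
          "adductor")],
    -"cycle_pct", names_to = "series", values_to = "bw")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle_pct, .data$bw,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gait cycle (%)", y = "force (BW)",
                  colour = NULL,
                  title = "Hip reaction force and muscle group forces")
}

#' @export
autoplot.paosim_convergence <- function(object, ...) {
  df <- tibble::as_tibble(object)
  sel <- attr(object, "selected_size")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$size_mm,
                                        .data$max_von_mises)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "edge size (mm)", y = "max von Mises (MPa)",
                  title = "Mesh convergence")
  if (!is.na(sel)) {
    p <- p + ggplot2::geom_vline(xintercept = sel, linetype = 2)
  }
  p
}

#' @export
autoplot.paosim_yield <- function(object, ...) {
  ggplot2::ggplot(object$iterations,
                  ggplot2::aes(.data$load_N,
                               100 * .data$failed_fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 100 * object$fail_fraction,
                        linetype = 2) +
    ggplot2::labs(x = "applied load (N)", y = "failed volume (%)",
                  title = "Incremental failure analysis")
}

#' @export
autoplot.paosim_fixation_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$fixation, .data$yield_load_bw)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "fixation layout", y = "yield load (BW)",
                  title = "Yield load by fixation layout")
}

#' @export
autoplot.paosim_comparison <- function(object, ...) {
  df <- tibble::tibble(
    group = rep(object$labels, c(length(object$samples$a),
                                 length(object$samples$b))),
    p100 = c(object$samples$a, object$samples$b))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$p100)) +
    ggplot2::geom_boxplot() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "mean peak stress (MPa)",
                  title = "High-stress-phase comparison")
}

#' Plot a hip-reaction-force cycle curve
#'
#' @param hrf Numeric vector (101 samples) of HRF in BW, or a matrix with
#'   one curve per row.
#' @param labels Optional curve labels.
#' @return A ggplot object.
#' @export
plot_hrf_curves <- function(hrf, labels = NULL) {
  if (is.null(dim(hrf))) hrf <- matrix(hrf, nrow = 1)
  labels <- labels %||% paste0("curve", seq_len(nrow(hrf)))
  df <- tibble::tibble(
    curve = rep(labels, each = ncol(hrf)),
    cycle_pct = rep(seq(0, 100, length.out = ncol(hrf)), nrow(hrf)),
    bw = as.vector(t(hrf)))
  ggplot2::ggplot(df, ggplot2::aes(.data$cycle_pct, .data$bw,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gait cycle (%)", y = "HRF (BW)", colour = NULL)
}
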