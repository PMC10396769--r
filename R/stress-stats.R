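#' Mean of the largest integration-point von Mises stresses
#'
#' `p100_mean()` computes the mean peak stress: the average of the `n_top`
#' (default 100) largest von Mises values over all integration points of a
#' solved field. When fewer than `n_top` values exist, all values are used
#' and the result is flagged via the `"truncated"` attribute.
#'
#' @param von_mises Numeric vector of von Mises stresses (MPa) at
#'   integration points.
#' @param n_top Number of top values to average (default 100).
#' @return Scalar mean peak stress in MPa, with attribute `truncated`
#'   (logical) when fewer than `n_top` values were available.
#' @examples
#' p100_mean(c(rep(10, 100), rep(0, 900)))
#' @export
p100_mean <- function(von_mises, n_top = 100L) {
  if (length(von_mises) == 0) {
    stop_paosim("empty stress field", "paosim_input_error")
  }
  k <- min(n_top, length(von_mises))
  top <- sort(von_mises, decreasing = TRUE)[seq_len(k)]
  out <- mean(top)
  if (k < n_top) attr(out, "truncated") <- TRUE
  out
}

#' Phase-peak-weighted mean stress across the gait cycle
#'
#' Combines the per-phase mean peak stresses into a single weighted mean,
#' weighting each phase by its peak stress relative to the sum of peaks:
#' `WMV = sum_i p100_i * (p_i / S_p)` with `S_p = sum_i p_i`.
#'
#' @param p100 Numeric vector of per-phase mean peak stresses (MPa),
#'   typically 8 gait phases.
#' @param peaks Numeric vector of per-phase peak stresses `p_i` (MPa), same
#'   length, all `>= 0` with positive sum.
#' @return Scalar weighted mean stress in MPa.
#' @examples
#' wmv_s100(c(10, 20, 30), c(1, 1, 1))  # plain mean
#' @export
wmv_s100 <- function(p100, peaks) {
  stopifnot(length(p100) == length(peaks))
  if (any(peaks < 0)) {
    stop_paosim("phase peaks must be non-negative", "paosim_input_error")
  }
  sp <- sum(peaks)
  if (sp <= 0) {
    stop_paosim("sum of phase peaks is zero; weights are degenerate",
                "paosim_input_error")
  }
  sum(p100 * peaks / sp)
}

#' Run a mesh-convergence study
#'
#' Implements the refinement protocol used to pick the working mesh size:
#' starting from `start` mm the edge size is reduced by `step` mm, the model
#' is re-solved, and the variation rate
#' `100 * |sigma_prev - sigma_curr| / sigma_prev` of the maximum von Mises
#' stress is tracked. The first size whose variation falls below `tol`
#' percent is selected; one extra confirmation refinement is recorded when
#' the size floor allows.
#'
#' @param case_factory Function `size_mm -> max von Mises stress (MPa)`
#'   (typically wraps mesh generation + FE solve; may also look up a
#'   precomputed table).
#' @param start Initial edge size, mm.
#' @param step Refinement decrement, mm; `0 < step < start`.
#' @param tol Variation-rate threshold in percent (default 1).
#' @param floor Smallest admissible edge size, mm.
#' @return A `paosim_convergence` object: tibble of
#'   (`size_mm`, `n_elements`, `max_von_mises`, `variation_pct`) plus
#'   attributes `selected_size` and `converged`.
#' @export
run_mesh_convergence <- function(case_factory, start = 4, step = 0.5,
                                 tol = 1, floor = 0.5) {
  if (!(start > step && step > 0)) {
    stop_paosim("need start > step > 0", "paosim_config_error")
  }
  sizes <- numeric()
  stresses <- numeric()
  nelems <- numeric()
  rates <- numeric()
  selected <- NA_real_
  size <- start
  while (size >= floor - 1e-12) {
    s <- case_factory(size)
    n_el <- attr(s, "n_elements") %||% NA_real_
    sizes <- c(sizes, size)
    stresses <- c(stresses, as.numeric(s))
    nelems <- c(nelems, n_el)
    i <- length(sizes)
    if (i == 1) {
      rates <- c(rates, NA_real_)
    } else {
      rates <- c(rates, 100 * abs(stresses[i - 1] - stresses[i]) /
                   stresses[i - 1])
      if (is.na(selected) && rates[i] < tol) {
        selected <- size
        # one confirmation refinement, then stop
        if (size - step >= floor - 1e-12) {
          s2 <- case_factory(size - step)
          sizes <- c(sizes, size - step)
          stresses <- c(stresses, as.numeric(s2))
          nelems <- c(nelems, attr(s2, "n_elements") %||% NA_real_)
          rates <- c(rates, 100 * abs(stresses[i] - as.numeric(s2)) /
                       stresses[i])
        }
        break
      }
    }
    size <- size - step
  }
  out <- tibble::tibble(size_mm = sizes, n_elements = nelems,
                        max_von_mises = stresses, variation_pct = rates)
  attr(out, "selected_size") <- selected
  attr(out, "converged") <- !is.na(selected)
  attr(out, "tol_pct") <- tol
  class(out) <- c("paosim_convergence", class(out))
  out
}

#' @export
print.paosim_convergence <- function(x, ...) {
  cat("Mesh convergence study (tol", attr(x, "tol_pct"), "%)\n")
  NextMethod()
  if (isTRUE(attr(x, "converged"))) {
    cat("Selected mesh size:", attr(x, "selected_size"), "mm\n")
  } else {
    cat("Did not converge above the size floor\n")
  }
  invisible(x)
}

#' @export
glance.paosim_convergence <- function(x, ...) {
  tibble::tibble(selected_size = attr(x, "selected_size"),
                 converged = attr(x, "converged"),
                 n_steps = nrow(x),
                 final_stress = x$max_von_mises[nrow(x)])
}
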