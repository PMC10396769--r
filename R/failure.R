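#' Incremental yield-load prediction by the principal-strain criterion
#'
#' Starting from the applied gait-phase load, the load case is scaled
#' upward in fixed increments (default 10 N on the total applied force).
#' An element fails when its maximum principal strain exceeds the tensile
#' limit or its minimum principal strain exceeds the compressive limit in
#' magnitude; the run stops when the failed element volume reaches
#' `fail_fraction` of the bone volume (screws excluded), and that load is
#' the construct's yield load. With `delete_failed = TRUE` failed elements
#' are removed (stiffness knocked down to a negligible value) and the
#' system re-solved, letting damage redistribute load; the protocol steps
#' between failure events using the linearity of the current configuration.
#' With `delete_failed = FALSE` the base solution is scaled analytically
#' (the linear shortcut, equivalent to iterating without deletion).
#'
#' @param mesh A `paosim_tet_mesh`.
#' @param materials A `paosim_material_field`.
#' @param loadcase A `paosim_load_case` (the maximum-load gait phase).
#' @param limits Named strain limits: `tensile`, `compressive` (positive
#'   magnitudes; defaults 0.73% and 1.04%, standard bone yield strains).
#' @param increment Load increment, N.
#' @param fail_fraction Failed-volume stop fraction of bone volume.
#' @param delete_failed Remove failed elements and re-solve.
#' @param load_cap Maximum load, N (default 40x the base load); reaching it
#'   returns a capped result instead of an error.
#' @param body_mass Optional body mass (kg) to report the yield load in
#'   body-weight multiples.
#' @return A `paosim_yield` object: `yield_load_N`, `yield_load_bw`,
#'   `iterations` (tibble: load_N, failed_fraction, n_failed),
#'   `failed_elements`, `limits`, `capped`, `base_load_N`.
#' @export
compute_yield_load <- function(mesh, materials, loadcase,
                               limits = c(tensile = 0.0073,
                                          compressive = 0.0104),
                               increment = 10, fail_fraction = 0.01,
                               delete_failed = TRUE, load_cap = NULL,
                               body_mass = NULL) {
  stopifnot(limits[["tensile"]] > 0, limits[["compressive"]] > 0,
            increment > 0)
  ftot <- colSums(loadcase$forces)
  F0 <- sqrt(sum(ftot^2))
  if (F0 <= 0) {
    stop_paosim("load case has zero resultant force; cannot scale",
                "paosim_input_error")
  }
  load_cap <- load_cap %||% (40 * F0)
  vols <- abs(tet_volumes(mesh$nodes, mesh$elements))
  is_screw <- materials$is_screw
  bone <- which(!is_screw)
  Vbone <- sum(vols[bone])
  crit_alpha <- function(ps) {
    # per-element load multiplier at which the strain criterion is first hit
    a_t <- ifelse(ps[, 1] > 0, limits[["tensile"]] / ps[, 1], Inf)
    a_c <- ifelse(ps[, 3] < 0, limits[["compressive"]] / (-ps[, 3]), Inf)
    pmin(a_t, a_c)
  }
  snap_up <- function(load) F0 + increment * ceiling((load - F0) / increment
                                                     - 1e-9)
  mk_result <- function(yield, iters, failed, capped) {
    structure(list(yield_load_N = yield,
                   yield_load_bw = if (!is.null(body_mass)) {
                     yield / (body_mass * .g)
                   } else NA_real_,
                   iterations = iters, failed_elements = failed,
                   limits = limits, capped = capped, base_load_N = F0,
                   delete_failed = delete_failed,
                   fail_fraction = fail_fraction),
              class = "paosim_yield")
  }
  if (!delete_failed) {
    res <- solve_linear_elasticity(mesh, materials, loadcase)
    al <- crit_alpha(res$principal_strain[bone, , drop = FALSE])
    ord <- order(al)
    cum <- cumsum(vols[bone][ord]) / Vbone
    hit <- which(cum >= fail_fraction)
    if (length(hit) == 0 || !is.finite(al[ord[hit[1]]]) ||
        al[ord[hit[1]]] * F0 > load_cap) {
      iters <- tibble::tibble(load_N = load_cap,
                              failed_fraction = sum(vols[bone][
                                is.finite(al) & al * F0 <= load_cap]) /
                                Vbone,
                              n_failed = sum(is.finite(al) &
                                               al * F0 <= load_cap))
      return(mk_result(NA_real_, iters, integer(), TRUE))
    }
    alpha_star <- al[ord[hit[1]]]
    yield <- max(snap_up(alpha_star * F0), F0)
    loads <- seq(F0, yield, by = increment)
    iters <- tibble::tibble(
      load_N = loads,
      failed_fraction = vapply(loads, function(L) {
        sum(vols[bone][al <= L / F0]) / Vbone
      }, numeric(1)),
      n_failed = vapply(loads, function(L) sum(al <= L / F0), integer(1)))
    failed <- bone[al <= yield / F0]
    return(mk_result(yield, iters, failed, FALSE))
  }
  # deletion mode: event-driven stepping with re-solve after each failure
  mat <- materials
  failed <- integer()
  failed_vol <- 0
  L <- F0
  iters <- list()
  repeat {
    res <- solve_linear_elasticity(mesh, mat, loadcase)
    alive <- setdiff(bone, failed)
    ps <- res$principal_strain[alive, , drop = FALSE]
    al <- crit_alpha(ps)
    new_fail <- alive[al <= L / F0 + 1e-12]
    if (length(new_fail) > 0) {
      failed <- c(failed, new_fail)
      failed_vol <- failed_vol + sum(vols[new_fail])
      mat$E[new_fail] <- 1e-3
      iters[[length(iters) + 1]] <-
        tibble::tibble(load_N = L, failed_fraction = failed_vol / Vbone,
                       n_failed = length(failed))
      if (failed_vol / Vbone >= fail_fraction) {
        return(mk_result(L, dplyr::bind_rows(iters), sort(failed), FALSE))
      }
      next  # cascade check at the same load with the damaged stiffness
    }
    iters[[length(iters) + 1]] <-
      tibble::tibble(load_N = L, failed_fraction = failed_vol / Vbone,
                     n_failed = length(failed))
    a_next <- min(al)
    if (!is.finite(a_next) || a_next * F0 > load_cap) {
      return(mk_result(NA_real_, dplyr::bind_rows(iters), sort(failed),
                       TRUE))
    }
    L <- max(L + increment, snap_up(a_next * F0))
  }
}

#' @export
print.paosim_yield <- function(x, ...) {
  if (x$capped) {
    cat("Yield not reached below the load cap;",
        sprintf("failed fraction %.3g%% at %.0f N\n",
                100 * max(x$iterations$failed_fraction),
                max(x$iterations$load_N)))
  } else {
    cat(sprintf("Yield load: %.0f N", x$yield_load_N))
    if (!is.na(x$yield_load_bw)) {
      cat(sprintf(" (%.2f BW)", x$yield_load_bw))
    }
    cat(sprintf("; %d failed elements, base load %.0f N\n",
                length(x$failed_elements), x$base_load_N))
  }
  invisible(x)
}

#' @export
tidy.paosim_yield <- function(x, ...) x$iterations

#' @export
glance.paosim_yield <- function(x, ...) {
  tibble::tibble(yield_load_N = x$yield_load_N,
                 yield_load_bw = x$yield_load_bw,
                 base_load_N = x$base_load_N,
                 n_failed = length(x$failed_elements),
                 capped = x$capped)
}

#' Per-phase stress summary and weighted mean stress for one solved model
#'
#' Solves the eight gait-phase load cases for one fixation model and
#' summarises the integration-point von Mises field per phase: the peak
#' stress `p_i`, the mean of the top 100 values, and the phase-peak
#' weighted mean stress across the cycle.
#'
#' @param mesh,materials Model definition.
#' @param loadcases List of 8 `paosim_load_case` objects (phases 1-8).
#' @return A `paosim_stress_summary`: tibble (phase, peak, p100) with
#'   attributes `wmv` and `s_p`; the solved fields are attached as
#'   attribute `results`.
#' @export
phase_stress_summary <- function(mesh, materials, loadcases) {
  rows <- vector("list", length(loadcases))
  results <- vector("list", length(loadcases))
  for (i in seq_along(loadcases)) {
    res <- solve_linear_elasticity(mesh, materials, loadcases[[i]])
    results[[i]] <- res
    rows[[i]] <- tibble::tibble(
      phase = loadcases[[i]]$phase %||% i,
      peak = max(res$von_mises),
      p100 = as.numeric(p100_mean(res$von_mises)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "wmv") <- wmv_s100(out$p100, out$peak)
  attr(out, "s_p") <- sum(out$peak)
  attr(out, "results") <- results
  class(out) <- c("paosim_stress_summary", class(out))
  out
}

#' Compare screw fixation layouts on the same synthetic geometry
#'
#' Runs the finite-element stage for a set of fixation layouts on the same
#' parametric hemipelvis geometry and phase loads: per-phase peak-stress
#' statistics, the weighted mean stress, and the yield load at the
#' maximum-load gait phase. Yield loads use the linear (no-deletion)
#' protocol by default so that all layouts are screened under identical,
#' inexpensive conditions; the damage-redistribution protocol is available
#' via `delete_failed = TRUE`.
#'
#' @param ida A `paosim_ida` result whose phase aggregates supply the
#'   loads (typically from a postoperative trial).
#' @param layouts Character vector of fixation codes.
#' @param couple_muscles Apply muscle-group forces in addition to the
#'   joint contact force.
#' @param target_edge_size Mesh edge size, mm.
#' @param delete_failed Passed to [compute_yield_load()].
#' @param density_args,material_args Optional overrides passed to
#'   [generate_density_field()] / [assign_materials()].
#' @param seed Seed for the density field.
#' @return A `paosim_fixation_comparison`: tibble with one row per layout
#'   (`fixation`, `wmv`, `p100_phase2`..`p100_phase4`, `max_phase`,
#'   `yield_load_N`, `yield_load_bw`, `n_elements`); per-layout details in
#'   attribute `details`.
#' @export
compare_fixation_layouts <- function(ida,
                                     layouts = c("IS", "TS", "2S-a", "2S-b",
                                                 "2S-c", "2S-d", "2S-e"),
                                     couple_muscles = TRUE,
                                     target_edge_size = 5,
                                     delete_failed = FALSE,
                                     density_args = list(),
                                     material_args = list(),
                                     seed = 1L) {
  stopifnot(inherits(ida, "paosim_ida"))
  ph <- ida$phase_summary
  max_phase <- ph$phase[which.max(ph$hrf_bw)]
  rows <- list()
  details <- list()
  for (fx in layouts) {
    spec <- geometry_spec(fx, target_edge_size = target_edge_size,
                          seed = seed)
    mesh <- generate_pelvis_mesh(spec)
    hu <- do.call(generate_density_field,
                  c(list(mesh = mesh, seed = seed), density_args))
    mat <- do.call(assign_materials, c(list(mesh = mesh, hu = hu),
                                       material_args))
    lcs <- lapply(seq_len(nrow(ph)), function(i) {
      build_load_case(mesh, phase_loads(ph[i, ], couple_muscles),
                      phase = ph$phase[i])
    })
    ss <- phase_stress_summary(mesh, mat, lcs)
    yl <- compute_yield_load(mesh, mat, lcs[[max_phase]],
                             delete_failed = delete_failed,
                             body_mass = ida$body_mass)
    rows[[fx]] <- tibble::tibble(
      fixation = fx, wmv = attr(ss, "wmv"),
      p100_phase2 = ss$p100[ss$phase == 2],
      p100_phase3 = ss$p100[ss$phase == 3],
      p100_phase4 = ss$p100[ss$phase == 4],
      max_phase = max_phase,
      yield_load_N = yl$yield_load_N,
      yield_load_bw = yl$yield_load_bw,
      n_elements = nrow(mesh$elements))
    details[[fx]] <- list(stress = ss, yield = yl, mesh = mesh)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "details") <- details
  attr(out, "couple_muscles") <- couple_muscles
  class(out) <- c("paosim_fixation_comparison", class(out))
  out
}

#' Regional load set for one gait phase
#'
#' Translates a phase-aggregate row of [run_ida()] into the named force
#' list consumed by [build_load_case()]: the joint contact patch receives
#' the reaction to the hip force, and (when coupling is on) each muscle
#' group's patch receives the group's pelvis-side resultant.
#'
#' @param phase_row One row of `ida$phase_summary`.
#' @param couple_muscles Include the muscle group forces.
#' @return Named list of force vectors, N.
#' @export
phase_loads <- function(phase_row, couple_muscles = TRUE) {
  loads <- list(couple_joint = -c(phase_row$hrf_x_N, phase_row$hrf_y_N,
                                  phase_row$hrf_z_N))
  if (couple_muscles) {
    for (g in c("extensor", "flexor", "abductor", "adductor")) {
      loads[[paste0("couple_", g)]] <-
        c(phase_row[[paste0(g, "_x_N")]], phase_row[[paste0(g, "_y_N")]],
          phase_row[[paste0(g, "_z_N")]])
    }
  }
  loads
}
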