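#' Compare peak-stress samples between two fixation groups
#'
#' Two-group comparison of mean peak stresses at the high-stress gait
#' phases (2-4): difference of group means, its standard
#' error, the 95% confidence interval, and the one-way ANOVA F statistic
#' and p value.
#'
#' @param group_a,group_b Numeric vectors of per-phase mean peak stresses
#'   (MPa), at least 2 values each.
#' @param labels Character vector of the two group names.
#' @return A `paosim_comparison` object.
#' @export
compare_fixations <- function(group_a, group_b,
                              labels = c("groupA", "groupB")) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2) {
    stop_paosim("need at least 2 samples per group",
                "paosim_sample_size_error")
  }
  diff <- mean(a) - mean(b)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tcrit <- stats::qt(0.975, na + nb - 2)
  ci <- diff + c(-1, 1) * tcrit * se
  dat <- data.frame(y = c(a, b),
                    g = factor(rep(labels, c(na, nb)), levels = labels))
  if (sp2 == 0) {
    Fv <- if (diff == 0) 0 else Inf
    pv <- if (diff == 0) 1 else 0
  } else {
    an <- stats::anova(stats::aov(y ~ g, data = dat))
    Fv <- an$`F value`[1]
    pv <- an$`Pr(>F)`[1]
  }
  structure(list(labels = labels, samples = list(a = a, b = b),
                 difference = diff, se = se, ci = ci, f = Fv, p = pv),
            class = "paosim_comparison")
}

#' @export
print.paosim_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: difference of means %.3g MPa (SE %.3g)\n",
              x$labels[1], x$labels[2], x$difference, x$se))
  cat(sprintf("95%% CI [%.3g, %.3g]; F = %.3g, p = %.3g\n",
              x$ci[1], x$ci[2], x$f, x$p))
  invisible(x)
}

#' @export
tidy.paosim_comparison <- function(x, ...) {
  tibble::tibble(contrast = paste(x$labels, collapse = " vs "),
                 difference = x$difference, se = x$se,
                 conf.low = x$ci[1], conf.high = x$ci[2],
                 statistic = x$f, p.value = x$p)
}

#' @export
glance.paosim_comparison <- function(x, ...) tidy(x)

#' Default demonstration run configuration
#'
#' A small cohort configuration exercising every pipeline stage: healthy
#' and postoperative profiles, a handful of trials each, typical-trial
#' selection, the musculoskeletal stage, and the finite-element fixation
#' comparison on the postoperative loads.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return A `paosim_run_config` list.
#' @export
default_run_config <- function(out_dir = tempfile("paosim_run_"),
                               seed = 1L) {
  structure(list(
    profiles = list(list(group = "healthy"), list(group = "postop")),
    n_trials = 5L, k_typical = 3L,
    fixations = c("IS", "TS"),
    couple_muscles = TRUE,
    target_edge_size = 6,
    recruitment_p = 3,
    phase_boundaries = c(0, 2, 12, 31, 50, 62, 75, 87, 100),
    failure = list(tensile = 0.0073, compressive = 0.0104,
                   increment = 10, fail_fraction = 0.01,
                   delete_failed = FALSE),
    out_dir = out_dir, seed = as.integer(seed)),
    class = "paosim_run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with the fields of [default_run_config()].
#' @return A `paosim_run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  base <- unclass(default_run_config())
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  if (length(base$profiles) > 0 && !is.null(names(base$profiles[[1]]))) {
    base$profiles <- lapply(base$profiles, as.list)
  }
  structure(base, class = "paosim_run_config")
}

#' Run the cohort-scale co-simulation pipeline
#'
#' Executes the full chain for each cohort profile: synthetic gait trials,
#' cycle normalization, typical-trial selection by medoid clustering,
#' inverse dynamics with muscle recruitment, and range-of-motion / peak
#' summaries. When fixation layouts are configured, the postoperative
#' phase loads drive the finite-element comparison (eight load cases per
#' layout), peak-stress statistics and yield loads, and the
#' high-stress-phase group comparison between the first two layouts. All
#' artifacts are written under the configured output directory and listed
#' in the returned manifest; the run is reproducible per seed.
#'
#' @param config A `paosim_run_config` (see [default_run_config()]) or a
#'   path to a JSON configuration.
#' @return The manifest (list), invisibly also written as
#'   `manifest.json`.
#' @export
run_cohort_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phases <- rla_phases(config$phase_boundaries)
  files <- character()
  log <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  wrap_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_paosim(sprintf("stage '%s' failed: %s", stage,
                          conditionMessage(e)), "paosim_stage_error")
    })
  }
  group_summaries <- list()
  idas <- list()
  for (pi in seq_along(config$profiles)) {
    prof <- wrap_stage("profiles",
                       do.call(cohort_profile, config$profiles[[pi]]))
    g <- prof$group
    log("simulate-gait", sprintf("group %s: %d trials", g, config$n_trials))
    trials <- wrap_stage("simulate-gait", lapply(seq_len(config$n_trials),
      function(i) generate_gait_trial(prof, seed = config$seed + i)))
    curves <- wrap_stage("process-gait", lapply(trials, normalize_to_cycle))
    typical <- wrap_stage("process-gait",
                          select_typical_trials(curves,
                                                k = config$k_typical))
    log("process-gait", sprintf("typical trials: %s",
                                paste(typical, collapse = ", ")))
    ida <- wrap_stage("run-ida",
                      run_ida(curves[[typical[1]]], muscles =
                                default_hip_muscles(),
                              p = config$recruitment_p, phases = phases))
    idas[[g]] <- ida
    pk <- extract_rom_and_peaks(ida)
    rom <- extract_rom_and_peaks(curves[[typical[1]]])
    f_trial <- file.path(out_dir, sprintf("trial_%s_typical.csv", g))
    write_gait_trial(trials[[typical[1]]], f_trial)
    f_ida <- file.path(out_dir, sprintf("ida_%s.csv", g))
    utils::write.csv(ida$samples, f_ida, row.names = FALSE)
    f_phase <- file.path(out_dir, sprintf("ida_%s_phases.json", g))
    jsonlite::write_json(ida$phase_summary, f_phase, digits = NA,
                         dataframe = "rows")
    files <- c(files, f_trial, sub("\\.csv$", ".json", f_trial), f_ida,
               f_phase)
    group_summaries[[g]] <- c(
      list(group = g, typical_trials = typical),
      as.list(dplyr::bind_cols(rom[setdiff(names(rom), names(pk))], pk)))
  }
  fe_summary <- NULL
  comparison <- NULL
  if (length(config$fixations) > 0) {
    src <- if ("postop" %in% names(idas)) "postop" else names(idas)[1]
    log("build-fe", sprintf("fixations %s on %s loads",
                            paste(config$fixations, collapse = "/"), src))
    cmp <- wrap_stage("solve-fe", compare_fixation_layouts(
      idas[[src]], layouts = config$fixations,
      couple_muscles = isTRUE(config$couple_muscles),
      target_edge_size = config$target_edge_size,
      delete_failed = isTRUE(config$failure$delete_failed),
      seed = config$seed))
    f_cmp <- file.path(out_dir, "fixation_comparison.csv")
    utils::write.csv(as.data.frame(cmp), f_cmp, row.names = FALSE)
    files <- c(files, f_cmp)
    fe_summary <- lapply(seq_len(nrow(cmp)), function(i) {
      list(fixation = cmp$fixation[i], n_load_cases = nrow(phases),
           wmv = cmp$wmv[i], yield_load_N = cmp$yield_load_N[i],
           yield_load_bw = cmp$yield_load_bw[i])
    })
    if (nrow(cmp) >= 2) {
      p100_of <- function(i) unlist(cmp[i, c("p100_phase2", "p100_phase3",
                                             "p100_phase4")])
      comparison <- wrap_stage("compare", compare_fixations(
        p100_of(2), p100_of(1), labels = cmp$fixation[2:1]))
      f_stat <- file.path(out_dir, "high_stress_comparison.json")
      jsonlite::write_json(tidy(comparison), f_stat, digits = NA,
                           dataframe = "rows")
      files <- c(files, f_stat)
    }
  } else {
    log("build-fe", "no fixation layouts configured; skipping FE stage")
  }
  manifest <- list(
    seed = config$seed,
    groups = unname(group_summaries),
    fe = fe_summary,
    comparison = if (!is.null(comparison)) {
      as.list(tidy(comparison))
    } else NULL,
    files = basename(files))
  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log("run-all", sprintf("manifest written to %s", f_manifest))
  invisible(manifest)
}
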