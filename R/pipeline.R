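#' Pipeline configuration
#'
#' One validated configuration list drives the simulate / fit / report
#' pipeline; unknown keys are rejected so typos cannot silently fall
#' back to defaults. All randomness flows from the single `seed` (the
#' generator derives per-subject streams from it; the bootstrap uses
#' `seed + 1`).
#'
#' @param seed Root seed.
#' @param n_per_arm,doses,run_times,pk_times Design overrides, see
#'   [trial_design()].
#' @param n_boot Bootstrap replicates for stage-2 standard errors.
#' @param alpha Significance threshold for the dynamics comparison.
#' @param out Output directory for [simulate_study()] /
#'   [fit_study()] file products (`NULL`: no files written).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_per_arm = 12, doses = c(100, 200),
                         run_times = 0:8, pk_times = 0:7, n_boot = 500,
                         alpha = 0.01, out = NULL) {
  cfg <- list(seed = as.integer(seed), n_per_arm = n_per_arm,
              doses = doses, run_times = run_times, pk_times = pk_times,
              n_boot = n_boot, alpha = alpha, out = out)
  structure(cfg, class = "study_config")
}

validate_config <- function(...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
}

config_design <- function(config) {
  trial_design(n_per_arm = config$n_per_arm, doses = config$doses,
               run_times = config$run_times, pk_times = config$pk_times,
               seed = config$seed)
}

#' Simulate a study to disk (or memory)
#'
#' Generates the synthetic trial for a configuration and, when
#' `config$out` is set, writes the CSV bundle via [write_trial()].
#'
#' @param config A [study_config()].
#' @param ... Must be empty (unknown keys are rejected).
#' @return The `hcvr_trial`, invisibly when written to disk.
#' @export
simulate_study <- function(config = study_config(), ...) {
  validate_config(...)
  trial <- generate_trial(config_design(config))
  if (!is.null(config$out)) {
    write_trial(trial, config$out)
    message("trial written to ", config$out)
    return(invisible(trial))
  }
  trial
}

# fit every HCVR run of a trial; returns the per-run estimate table
fit_all_runs <- function(trial, constants = physiology_constants()) {
  keys <- dplyr::distinct(trial$runs, .data$subject_id, .data$run_time_h)
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    mins <- trial$runs[trial$runs$subject_id == keys$subject_id[i] &
                         trial$runs$run_time_h == keys$run_time_h[i], ]
    rec <- run_record(mins[, c("minute", "ve_l_min", "petco2_mmhg",
                               "pico2_mmhg")],
                      subject_id = keys$subject_id[i],
                      run_time = keys$run_time_h[i])
    ft <- tryCatch(fit_run(rec, constants), error = function(e) NULL)
    rows[[i]] <- if (is.null(ft)) {
      tibble::tibble(subject_id = keys$subject_id[i],
                     run_time_h = keys$run_time_h[i],
                     baseline_ve = NA_real_, resting_petco2 = NA_real_,
                     vrt = NA_real_, slope_s = NA_real_, ve55 = NA_real_,
                     apneic_threshold = NA_real_, rss = NA_real_,
                     converged = FALSE, flagged = TRUE)
    } else {
      tibble::tibble(subject_id = keys$subject_id[i],
                     run_time_h = keys$run_time_h[i],
                     baseline_ve = ft$estimates$baseline_ve,
                     resting_petco2 = ft$estimates$resting_petco2,
                     vrt = ft$estimates$vrt,
                     slope_s = ft$estimates$slope_s,
                     ve55 = ft$ve55,
                     apneic_threshold = ft$apneic_threshold,
                     rss = ft$rss, converged = ft$converged,
                     flagged = ft$flagged)
    }
  }
  dplyr::bind_rows(rows)
}

biomarker_series <- function(run_fits, column) {
  tibble::tibble(subject_id = run_fits$subject_id,
                 time_h = run_fits$run_time_h,
                 value = run_fits[[column]])
}

#' Fit the full analysis pipeline to a trial
#'
#' Runs the complete analysis: population PK fit, per-run HCVR fits,
#' effect-compartment EMAX fits per biomarker (with the resting-class
#' biomarkers — resting ventilation, resting PCO2, recruitment
#' threshold — sharing one C50 and h1/2), population summaries of the
#' pre-drug biomarkers, potency ratios, the dose-effect comparison
#' between arms, and the shared-vs-separate dynamics test.
#'
#' @param trial An `hcvr_trial` (from [generate_trial()] /
#'   [read_trial()]) or a directory path.
#' @param config A [study_config()].
#' @param constants A [physiology_constants()] object.
#' @return A list of class `hcvr_study_fit` with components `pk`,
#'   `run_fits`, `pd` (list of `pd_fit`s), `baseline` (population
#'   summary at t = 0), `potency`, `dose_effect`, `dynamics_test`,
#'   `recovery` (estimate-vs-truth table when the trial carries truth).
#' @export
fit_study <- function(trial, config = study_config(),
                      constants = physiology_constants()) {
  if (is.character(trial)) trial <- read_trial(trial)
  stopifnot(inherits(trial, "hcvr_trial"))

  pk_data <- dplyr::left_join(trial$pk_samples,
                              trial$subjects[, c("subject_id", "dose_mg",
                                                 "weight_kg")],
                              by = c("subject_id", "dose_mg", "weight_kg"))
  pk <- fit_pk_population(pk_data, n_boot = config$n_boot,
                          seed = config$seed + 1L)

  run_fits <- fit_all_runs(trial, constants)

  subj_cl <- dplyr::left_join(trial$subjects, pk$subjects,
                              by = "subject_id")
  cp_fns <- pk_conc_fns(subj_cl, pk$params)

  sig <- setNames(study_truth()$biomarkers$sigma,
                  study_truth()$biomarkers$biomarker)
  rest_w <- 1 / sig[c("resting_ve", "resting_petco2", "vrt")]^2
  ok <- run_fits[!run_fits$flagged & run_fits$converged, ]
  # the EMAX layer needs each subject's pre-drug point: drop subjects
  # whose t = 0 run was flagged (e.g. slope pinned at zero)
  has_t0 <- unique(ok$subject_id[ok$run_time_h == 0])
  ok <- ok[ok$subject_id %in% has_t0, ]
  # ... and at least five usable time points per subject
  counts <- table(ok$subject_id)
  ok <- ok[ok$subject_id %in% names(counts)[counts >= 5], ]

  pd_rest_shared <- fit_pd_biomarker(
    list(resting_ve = biomarker_series(ok, "baseline_ve"),
         resting_petco2 = biomarker_series(ok, "resting_petco2"),
         vrt = biomarker_series(ok, "vrt")),
    cp_fns, direction = c("depressed", "elevated", "elevated"),
    weights = unname(rest_w))
  pd_rest_sep <- list(
    resting_ve = fit_pd_biomarker(biomarker_series(ok, "baseline_ve"),
                                  cp_fns, "depressed",
                                  weights = unname(rest_w[1])),
    resting_petco2 = fit_pd_biomarker(biomarker_series(ok, "resting_petco2"),
                                      cp_fns, "elevated",
                                      weights = unname(rest_w[2])),
    vrt = fit_pd_biomarker(biomarker_series(ok, "vrt"), cp_fns, "elevated",
                           weights = unname(rest_w[3])))
  pd_slope <- fit_pd_biomarker(biomarker_series(ok, "slope_s"), cp_fns,
                               "depressed")
  pd_ve55 <- fit_pd_biomarker(biomarker_series(ok, "ve55"), cp_fns,
                              "depressed")

  dynamics_test <- compare_dynamics(pd_rest_shared,
                                    unname(pd_rest_sep),
                                    alpha = config$alpha)

  base <- run_fits[run_fits$run_time_h == 0 & !run_fits$flagged, ]
  baseline <- population_summary(
    tidyr::pivot_longer(
      base[, c("subject_id", "baseline_ve", "resting_petco2", "vrt",
               "slope_s", "ve55")],
      -"subject_id", names_to = "parameter", values_to = "value"),
    B = max(config$n_boot, 200), seed = config$seed + 1L,
    sigma = sig[c("resting_ve", "resting_petco2", "vrt", "slope_s",
                  "ve55")] |>
      setNames(c("baseline_ve", "resting_petco2", "vrt", "slope_s",
                 "ve55")))

  potency <- potency_ratios(c(resting = pd_rest_shared$c50,
                              slope = pd_slope$c50,
                              ve55 = pd_ve55$c50))

  dose_effect <- tryCatch(
    dose_effect_by_arm(trial, run_fits, cp_fns, config),
    error = function(e) NULL)

  recovery <- NULL
  if (!is.null(trial$run_truth)) {
    truth0 <- trial$run_truth[trial$run_truth$run_time_h == 0, ]
    tr_med <- vapply(c("baseline_ve", "resting_petco2", "vrt", "slope_s",
                       "ve55"), function(p) median(truth0[[p]]), 0)
    est_med <- setNames(baseline$estimate, baseline$parameter)[names(tr_med)]
    recovery <- tibble::tibble(parameter = names(tr_med),
                               truth_median = unname(tr_med),
                               estimate = unname(est_med),
                               rel_dev = unname((est_med - tr_med) / tr_med))
  }

  fit <- structure(
    list(pk = pk, run_fits = run_fits,
         pd = list(resting_shared = pd_rest_shared,
                   resting_separate = pd_rest_sep,
                   slope = pd_slope, ve55 = pd_ve55),
         baseline = baseline, potency = potency,
         dose_effect = dose_effect, dynamics_test = dynamics_test,
         recovery = recovery, config = config),
    class = "hcvr_study_fit")
  if (!is.null(config$out)) {
    write_study_fit(fit, config$out)
  }
  fit
}

# per-arm peak-effect comparison using each arm's own PD fits and the
# arm's median-weight concentration curve
dose_effect_by_arm <- function(trial, run_fits, cp_fns, config) {
  doses <- sort(unique(trial$subjects$dose_mg))
  if (length(doses) < 2) stop("need two dose arms", call. = FALSE)
  arm_fits <- lapply(doses, function(d) {
    ids <- trial$subjects$subject_id[trial$subjects$dose_mg == d]
    ok <- run_fits[run_fits$subject_id %in% ids & !run_fits$flagged &
                     run_fits$converged, ]
    ok <- ok[ok$subject_id %in% ok$subject_id[ok$run_time_h == 0], ]
    cnt <- table(ok$subject_id)
    ok <- ok[ok$subject_id %in% names(cnt)[cnt >= 5], ]
    cp_arm <- cp_fns[as.character(ids)]
    sig <- setNames(study_truth()$biomarkers$sigma,
                    study_truth()$biomarkers$biomarker)
    rest_w <- 1 / sig[c("resting_ve", "resting_petco2", "vrt")]^2
    rest <- fit_pd_biomarker(
      list(resting_ve = biomarker_series(ok, "baseline_ve"),
           resting_petco2 = biomarker_series(ok, "resting_petco2"),
           vrt = biomarker_series(ok, "vrt")),
      cp_arm, direction = c("depressed", "elevated", "elevated"),
      weights = unname(rest_w))
    slope <- fit_pd_biomarker(biomarker_series(ok, "slope_s"), cp_arm,
                              "depressed")
    ve55 <- fit_pd_biomarker(biomarker_series(ok, "ve55"), cp_arm,
                             "depressed")
    med_id <- ids[which.min(abs(trial$subjects$weight_kg[
      trial$subjects$dose_mg == d] -
        median(trial$subjects$weight_kg[trial$subjects$dose_mg == d])))]
    cp_med <- cp_fns[[as.character(med_id)]]
    list(
      resting_ve = list(c50 = rest$c50, h_half = rest$h_half,
                        direction = "depressed", cp_fn = cp_med),
      resting_petco2 = list(c50 = rest$c50, h_half = rest$h_half,
                            direction = "elevated", cp_fn = cp_med),
      vrt = list(c50 = rest$c50, h_half = rest$h_half,
                 direction = "elevated", cp_fn = cp_med),
      slope_s = list(c50 = slope$c50, h_half = slope$h_half,
                     direction = "depressed", cp_fn = cp_med),
      ve55 = list(c50 = ve55$c50, h_half = ve55$h_half,
                  direction = "depressed", cp_fn = cp_med))
  })
  dose_effect_table(arm_fits[[1]], arm_fits[[2]])
}

write_study_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  table1 <- study_parameter_table(fit)
  utils::write.csv(table1, file.path(dir, "table1.csv"), row.names = FALSE)
  if (!is.null(fit$dose_effect)) {
    utils::write.csv(fit$dose_effect, file.path(dir, "fig4f.csv"),
                     row.names = FALSE)
  }
  if (!is.null(fit$recovery)) {
    utils::write.csv(fit$recovery, file.path(dir, "recovery_report.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = fit$config$seed,
         package_version = as.character(utils::packageVersion("hcvr"))),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Population parameter table of a fitted study
#'
#' Combines the pre-drug biomarker summaries with the EMAX potency and
#' hysteresis estimates into one table shaped like a standard PD
#' parameter report (estimate, SE, omega2, %CV, sigma).
#'
#' @param fit An `hcvr_study_fit`.
#' @return A tibble.
#' @export
study_parameter_table <- function(fit) {
  stopifnot(inherits(fit, "hcvr_study_fit"))
  base <- fit$baseline
  pd_rows <- tibble::tibble(
    parameter = c("c50_resting", "h_half_resting", "c50_slope",
                  "h_half_slope", "c50_ve55", "h_half_ve55"),
    estimate = c(fit$pd$resting_shared$c50, fit$pd$resting_shared$h_half,
                 fit$pd$slope$c50, fit$pd$slope$h_half,
                 fit$pd$ve55$c50, fit$pd$ve55$h_half),
    se = NA_real_, omega2 = NA_real_, cv_percent = NA_real_,
    sigma = NA_real_, n_subjects = length(unique(fit$run_fits$subject_id)))
  dplyr::bind_rows(tibble::as_tibble(base), pd_rows)
}

#' @export
print.hcvr_study_fit <- function(x, ...) {
  cat("Fitted HCVR PK/PD study\n\n")
  cat(sprintf("Population CL: %.1f L/h (omega2 %.3f)\n",
              x$pk$params$cl, x$pk$params$omega2_cl))
  cat(sprintf("%d/%d runs fitted cleanly\n\n",
              sum(!x$run_fits$flagged), nrow(x$run_fits)))
  cat("Pre-drug biomarkers (population medians):\n")
  print(as.data.frame(x$baseline), digits = 3)
  cat(sprintf("\nPotency: C50 resting %.3g, slope %.3g, ve55 %.3g mg/L\n",
              x$pd$resting_shared$c50, x$pd$slope$c50, x$pd$ve55$c50))
  print(as.data.frame(x$potency), digits = 3)
  cat(sprintf("\nDynamics test (shared vs separate resting class): LR %.2f, df %d, p %.3g\n",
              x$dynamics_test$statistic, x$dynamics_test$df,
              x$dynamics_test$p_value))
  invisible(x)
}

#' Human-readable report of a fitted study
#'
#' Renders the parameter table, potency ratios, dose-effect ordering
#' and the dynamics-test outcome as text; sections missing from a
#' partial fit are skipped with a warning line rather than an error.
#'
#' @param fit An `hcvr_study_fit` (possibly partial).
#' @return Character vector of report lines, invisibly; the report is
#'   also printed.
#' @export
report_study <- function(fit) {
  lines <- c("HCVR opioid PK/PD study report",
             strrep("=", 40))
  add <- function(...) lines <<- c(lines, ...)
  if (!is.null(fit$baseline)) {
    add("", "Pre-drug biomarkers (median [bootstrap SE], omega2, %CV):")
    for (i in seq_len(nrow(fit$baseline))) {
      b <- fit$baseline[i, ]
      add(sprintf("  %-16s %8.3g [%.2g]  omega2 %.3f  CV %.0f%%",
                  b$parameter, b$estimate, b$se, b$omega2, b$cv_percent))
    }
  } else add("", "! baseline section unavailable")
  if (!is.null(fit$pd)) {
    add("", "Effect-compartment EMAX estimates:")
    add(sprintf("  resting class: C50 %.3g mg/L, h1/2 %.2g h",
                fit$pd$resting_shared$c50, fit$pd$resting_shared$h_half))
    add(sprintf("  slope:         C50 %.3g mg/L, h1/2 %.2g h",
                fit$pd$slope$c50, fit$pd$slope$h_half))
    add(sprintf("  ve55:          C50 %.3g mg/L, h1/2 %.2g h",
                fit$pd$ve55$c50, fit$pd$ve55$h_half))
  } else add("", "! PD section unavailable")
  if (!is.null(fit$potency)) {
    add("", "Potency ratios (resting C50 / other):")
    for (i in seq_len(nrow(fit$potency))) {
      add(sprintf("  %-16s %.3g (reported as %g)",
                  fit$potency$comparison[i], fit$potency$ratio[i],
                  fit$potency$rounded[i]))
    }
  } else add("", "! potency section unavailable")
  if (!is.null(fit$dose_effect)) {
    add("", "Dose effect (peak fractional effect, high vs low arm):")
    for (i in seq_len(nrow(fit$dose_effect))) {
      d <- fit$dose_effect[i, ]
      add(sprintf("  %-16s %.2f -> %.2f (+%.1f points)", d$biomarker,
                  d$peak_effect_low, d$peak_effect_high, d$percent_change))
    }
    add(paste("  ordering:",
              paste(fit$dose_effect$biomarker, collapse = " > ")))
  } else add("", "! dose-effect section unavailable")
  if (!is.null(fit$dynamics_test)) {
    add("", sprintf(
      "Dynamics: shared vs separate resting-class fit, LR %.2f (df %d), p = %.3g%s",
      fit$dynamics_test$statistic, fit$dynamics_test$df,
      fit$dynamics_test$p_value,
      if (fit$dynamics_test$significant) " (significant)" else ""))
  } else add("", "! dynamics section unavailable")
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' One full recovery experiment at the reference truth
#'
#' Simulates the complete trial at the reference parameter set, fits
#' the entire pipeline, and returns the quantities used by the
#' recovery analysis: the population PK clearance, the pre-drug
#' biomarker medians, and the EMAX potency/hysteresis estimates.
#'
#' @param seed Trial seed.
#' @param n_per_arm Subjects per arm.
#' @param n_boot Bootstrap replicates (kept small here; SEs are not the
#'   focus of recovery).
#' @return A named list of scalars plus the full `hcvr_study_fit`.
#' @export
run_recovery <- function(seed, n_per_arm = 12, n_boot = 200) {
  cfg <- study_config(seed = seed, n_per_arm = n_per_arm, n_boot = n_boot)
  trial <- generate_trial(config_design(cfg))
  fit <- fit_study(trial, cfg)
  base <- setNames(fit$baseline$estimate, fit$baseline$parameter)
  list(
    cl = fit$pk$params$cl,
    baseline_ve = unname(base["baseline_ve"]),
    resting_petco2 = unname(base["resting_petco2"]),
    vrt = unname(base["vrt"]),
    slope_s = unname(base["slope_s"]),
    ve55 = unname(base["ve55"]),
    c50_ve55 = fit$pd$ve55$c50,
    c50_slope = fit$pd$slope$c50,
    c50_resting = fit$pd$resting_shared$c50,
    h_half_resting = fit$pd$resting_shared$h_half,
    ordering_ok = fit$pd$ve55$c50 < fit$pd$slope$c50 &&
      fit$pd$slope$c50 < fit$pd$resting_shared$c50,
    fit = fit)
}
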