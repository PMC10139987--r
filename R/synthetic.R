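#' Synthetic trial design
#'
#' Describes the layout of the respiratory study being emulated: two
#' oral dose arms, one pre-dose HCVR run plus hourly runs for 8 h, and
#' hourly plasma samples from 0 to 7 h. Body weight is drawn from a
#' normal distribution truncated to the study's printed range.
#'
#' @param n_per_arm Subjects per dose arm.
#' @param doses Oral doses, mg (one arm per dose).
#' @param run_times HCVR run start times, h since dosing; must include 0.
#' @param pk_times Plasma sampling times, h.
#' @param weight_mean,weight_sd,weight_range Body-weight distribution,
#'   kg (normal, truncated).
#' @param seed Root seed; every subject's random stream is derived from
#'   it.
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = 12, doses = c(100, 200),
                         run_times = 0:8, pk_times = 0:7,
                         weight_mean = 74, weight_sd = 10,
                         weight_range = c(57, 103), seed = 1L) {
  if (n_per_arm < 1) stop("`n_per_arm` must be >= 1", call. = FALSE)
  if (!0 %in% run_times) {
    stop("`run_times` must include 0 (the pre-drug control run)",
         call. = FALSE)
  }
  structure(
    list(n_per_arm = as.integer(n_per_arm), doses = doses,
         run_times = sort(run_times), pk_times = sort(pk_times),
         weight_mean = weight_mean, weight_sd = weight_sd,
         weight_range = weight_range, seed = as.integer(seed)),
    class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "Trial design: %d subjects/arm x doses (%s mg), %d HCVR runs, %d PK samples, seed %d\n",
    x$n_per_arm, paste(x$doses, collapse = ", "), length(x$run_times),
    length(x$pk_times), x$seed))
  invisible(x)
}

# deterministic per-subject sub-seed below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483629 + 1)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Generate one synthetic subject
#'
#' Draws the subject's individual truth (log-normal deviations using
#' the omega2 entries of the reference set), simulates noisy plasma
#' samples, and simulates every HCVR run through the closed-loop CO2
#' model with the subject's time-varying biomarkers: at each run's
#' start time the four primitive biomarkers are scaled by their
#' effect-compartment EMAX factor (resting ventilation and slope
#' depressed; resting PCO2 and recruitment threshold elevated, the
#' three resting-class biomarkers sharing one C50 draw), run-level
#' jitter is added with the within-subject sigma, and 1-min
#' ventilation noise is applied (SD 0.44 L/min at rest, scaling with
#' ventilation). Drug effect is held constant within a run.
#'
#' @param design A [trial_design()] object.
#' @param truth Population truth as from [study_truth()].
#' @param dose_mg The subject's arm (oral dose, mg).
#' @param subject_id Identifier.
#' @param seed Subject-level seed.
#' @param constants A [physiology_constants()] object.
#' @param protocol A [forcing_protocol()] object.
#' @param noise Logical; `FALSE` switches off all residual noise and
#'   jitter (truth trajectories only).
#' @return A list with `subject` (one-row tibble), `pk_samples`,
#'   `runs` (minute-level tibble across runs), `run_truth` (per-run
#'   true biomarkers), and `truth` (subject-level parameters).
#' @export
generate_subject <- function(design, truth, dose_mg, subject_id,
                             seed, constants = physiology_constants(),
                             protocol = forcing_protocol(),
                             noise = TRUE) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  bm <- truth$biomarkers
  pdt <- truth$pd
  get_bm <- function(name, col) bm[[col]][bm$biomarker == name]
  get_pd <- function(class, col) pdt[[col]][pdt$pd_class == class]

  vd <- constants$vd
  for (attempt in 1:10) {
    weight <- rtruncnorm1(design$weight_mean, design$weight_sd,
                          design$weight_range[1], design$weight_range[2])
    cl_i <- truth$pk$cl * exp(rnorm(1, 0, sqrt(truth$pk$omega2_cl)))
    b0_i <- get_bm("resting_ve", "baseline") *
      exp(rnorm(1, 0, sqrt(get_bm("resting_ve", "omega2"))))
    p0_i <- get_bm("resting_petco2", "baseline") *
      exp(rnorm(1, 0, sqrt(get_bm("resting_petco2", "omega2"))))
    vrt_i <- get_bm("vrt", "baseline") *
      exp(rnorm(1, 0, sqrt(get_bm("vrt", "omega2"))))
    s_i <- get_bm("slope_s", "baseline") *
      exp(rnorm(1, 0, sqrt(get_bm("slope_s", "omega2"))))
    c50_rest_i <- get_pd("resting", "c50") *
      exp(rnorm(1, 0, sqrt(get_pd("resting", "omega2_c50"))))
    c50_slope_i <- get_pd("slope", "c50") *
      exp(rnorm(1, 0, sqrt(get_pd("slope", "omega2_c50"))))
    if (b0_i > vd + 0.5) break
    if (attempt == 10) {
      stop("could not draw a feasible subject (resting ventilation ",
           "repeatedly at or below dead space)", call. = FALSE)
    }
  }
  hh_rest <- get_pd("resting", "h_half")
  hh_slope <- get_pd("slope", "h_half")

  pk_i <- truth$pk
  pk_i$cl <- cl_i
  cp_fn <- pk_conc_fn(pk_i, dose_mg, weight)

  # plasma samples with proportional noise
  cp <- pk_conc(pk_i, dose_mg, weight, design$pk_times)
  if (noise) {
    cp <- cp * (1 + rnorm(length(cp), 0, sqrt(truth$pk$sigma2_prop)))
  }
  cp <- pmax(cp, 0)
  pk_samples <- tibble::tibble(
    subject_id = subject_id, dose_mg = dose_mg, weight_kg = weight,
    time_h = design$pk_times, conc_mg_l = cp)

  # effect-site concentrations at run starts
  tr <- design$run_times
  ce_rest <- ce_values(cp_fn, hh_rest, tr)
  ce_slope <- ce_values(cp_fn, hh_slope, tr)
  f_rest_dep <- c50_rest_i / (c50_rest_i + ce_rest)
  f_rest_ele <- (c50_rest_i + ce_rest) / c50_rest_i
  f_slope <- c50_slope_i / (c50_slope_i + ce_slope)

  sig <- setNames(bm$sigma, bm$biomarker)
  runs <- vector("list", length(tr))
  run_truth <- vector("list", length(tr))
  for (j in seq_along(tr)) {
    b0_t <- b0_i * f_rest_dep[j]
    p0_t <- p0_i * f_rest_ele[j]
    vrt_t <- vrt_i * f_rest_ele[j]
    s_t <- s_i * f_slope[j]
    if (noise) {
      for (attempt in 1:20) {
        b0_r <- b0_t + rnorm(1, 0, sig[["resting_ve"]])
        if (b0_r > vd + 0.3) break
      }
      p0_r <- max(p0_t + rnorm(1, 0, sig[["resting_petco2"]]), 20)
      vrt_r <- max(vrt_t + rnorm(1, 0, sig[["vrt"]]), 25)
      s_r <- max(s_t + rnorm(1, 0, sig[["slope_s"]]), 0.05)
    } else {
      b0_r <- max(b0_t, vd + 0.3)
      p0_r <- p0_t; vrt_r <- vrt_t; s_r <- max(s_t, 0.05)
    }
    hc <- hcvr_parameters(b0_r, p0_r, vrt_r, s_r, run_time = tr[j])
    sim <- simulate_run(hc, constants, protocol)
    mins <- sim$minutes
    if (noise) {
      mins$ve_l_min <- mins$ve_l_min +
        rnorm(nrow(mins), 0, 0.44 * mins$ve_l_min / b0_r)
      mins$ve_l_min <- pmax(mins$ve_l_min, 0)
    }
    runs[[j]] <- dplyr::mutate(mins, subject_id = subject_id,
                               run_time_h = tr[j], .before = 1)
    run_truth[[j]] <- tibble::tibble(
      subject_id = subject_id, run_time_h = tr[j],
      baseline_ve = b0_r, resting_petco2 = p0_r, vrt = vrt_r,
      slope_s = s_r,
      ve55 = b0_r + s_r * hinge(55 - vrt_r, constants$delta))
  }

  list(
    subject = tibble::tibble(subject_id = subject_id, dose_mg = dose_mg,
                             weight_kg = weight),
    pk_samples = pk_samples,
    runs = dplyr::bind_rows(runs),
    run_truth = dplyr::bind_rows(run_truth),
    truth = list(subject_id = subject_id, weight_kg = weight, cl = cl_i,
                 baseline_ve = b0_i, resting_petco2 = p0_i, vrt = vrt_i,
                 slope_s = s_i, c50_resting = c50_rest_i,
                 c50_slope = c50_slope_i, h_half_resting = hh_rest,
                 h_half_slope = hh_slope, dose_mg = dose_mg))
}

#' Generate a complete synthetic trial
#'
#' Runs [generate_subject()] for every subject of the design (one arm
#' per dose, `n_per_arm` subjects each). Subject-level seeds are
#' derived deterministically from the design seed, so a fixed seed
#' reproduces the dataset exactly.
#'
#' @inheritParams generate_subject
#' @return A list of class `hcvr_trial`: `subjects`, `pk_samples`,
#'   `runs` (all minute-level records), `run_truth`, `truth`
#'   (per-subject truth list), `design`.
#' @export
#' @examples
#' \donttest{
#' trial <- generate_trial(trial_design(n_per_arm = 1, seed = 7))
#' }
generate_trial <- function(design = trial_design(),
                           truth = study_truth(),
                           constants = physiology_constants(),
                           protocol = forcing_protocol(),
                           noise = TRUE) {
  stopifnot(inherits(design, "trial_design"))
  arms <- rep(design$doses, each = design$n_per_arm)
  n <- length(arms)
  ids <- sprintf("S%02d", seq_len(n))
  subj <- vector("list", n)
  for (i in seq_len(n)) {
    subj[[i]] <- generate_subject(
      design, truth, dose_mg = arms[i], subject_id = ids[i],
      seed = derive_seed(design$seed, i), constants = constants,
      protocol = protocol, noise = noise)
  }
  structure(
    list(subjects = dplyr::bind_rows(lapply(subj, `[[`, "subject")),
         pk_samples = dplyr::bind_rows(lapply(subj, `[[`, "pk_samples")),
         runs = dplyr::bind_rows(lapply(subj, `[[`, "runs")),
         run_truth = dplyr::bind_rows(lapply(subj, `[[`, "run_truth")),
         truth = lapply(subj, `[[`, "truth"),
         design = design),
    class = "hcvr_trial")
}

#' @export
print.hcvr_trial <- function(x, ...) {
  cat(sprintf(
    "Synthetic HCVR trial: %d subjects, %d runs, %d PK samples (seed %d)\n",
    nrow(x$subjects),
    nrow(dplyr::distinct(x$runs, .data$subject_id, .data$run_time_h)),
    nrow(x$pk_samples), x$design$seed))
  invisible(x)
}

#' Write a trial to a directory of delimited text files
#'
#' Writes `subjects.csv`, `pk_samples.csv`, one `runs/<subject>_t<run>.csv`
#' per HCVR run, `truth.json`, and `manifest.json` (seed and package
#' version).
#'
#' @param trial An `hcvr_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "hcvr_trial"))
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$pk_samples, file.path(dir, "pk_samples.csv"),
                   row.names = FALSE)
  runs <- split(trial$runs,
                list(trial$runs$subject_id, trial$runs$run_time_h),
                drop = TRUE)
  for (r in runs) {
    f <- file.path(dir, "runs",
                   sprintf("%s_t%g.csv", r$subject_id[1], r$run_time_h[1]))
    utils::write.csv(r, f, row.names = FALSE)
  }
  jsonlite::write_json(
    list(run_truth = trial$run_truth, truth = trial$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = trial$design$seed,
         n_per_arm = trial$design$n_per_arm,
         doses = trial$design$doses,
         package_version = as.character(utils::packageVersion("hcvr"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a trial written by [write_trial()]
#'
#' @param dir Directory containing the CSV bundle.
#' @return An `hcvr_trial` (truth restored from `truth.json` when
#'   present; otherwise `NULL`).
#' @export
read_trial <- function(dir) {
  subjects <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "subjects.csv")))
  pk <- tibble::as_tibble(utils::read.csv(file.path(dir, "pk_samples.csv")))
  files <- list.files(file.path(dir, "runs"), full.names = TRUE,
                      pattern = "\\.csv$")
  if (length(files) == 0) stop("no run files under ", dir, call. = FALSE)
  runs <- dplyr::bind_rows(lapply(files, function(f) {
    tibble::as_tibble(utils::read.csv(f))
  }))
  runs <- dplyr::arrange(runs, .data$subject_id, .data$run_time_h,
                         .data$minute)
  truth <- NULL
  run_truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
    run_truth <- tibble::as_tibble(tj$run_truth)
    truth <- tj$truth
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  design <- trial_design(n_per_arm = manifest$n_per_arm,
                         doses = manifest$doses,
                         run_times = sort(unique(runs$run_time_h)),
                         pk_times = sort(unique(pk$time_h)),
                         seed = manifest$seed)
  structure(
    list(subjects = subjects, pk_samples = pk, runs = runs,
         run_truth = run_truth, truth = truth, design = design),
    class = "hcvr_trial")
}

#' Generate a PK-only synthetic study
#'
#' Draws the PK side of the trial only: per-subject weight and
#' log-normal clearance, then hourly plasma samples with proportional
#' noise. Used for clearance-recovery experiments where the HCVR runs
#' are not needed.
#'
#' @inheritParams generate_subject
#' @param design A [trial_design()] object.
#' @param truth Population truth as from [study_truth()].
#' @return A tibble with columns `subject_id`, `dose_mg`, `weight_kg`,
#'   `time_h`, `conc_mg_l`, plus a `cl_true` attribute table.
#' @export
generate_pk_study <- function(design = trial_design(),
                              truth = study_truth(), noise = TRUE) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  arms <- rep(design$doses, each = design$n_per_arm)
  rows <- vector("list", length(arms))
  truth_rows <- vector("list", length(arms))
  for (i in seq_along(arms)) {
    set.seed(derive_seed(design$seed, i))
    weight <- rtruncnorm1(design$weight_mean, design$weight_sd,
                          design$weight_range[1], design$weight_range[2])
    cl_i <- truth$pk$cl * exp(rnorm(1, 0, sqrt(truth$pk$omega2_cl)))
    p <- truth$pk
    p$cl <- cl_i
    conc <- pk_conc(p, arms[i], weight, design$pk_times)
    if (noise) {
      conc <- conc * (1 + rnorm(length(conc), 0, sqrt(truth$pk$sigma2_prop)))
    }
    id <- sprintf("S%02d", i)
    rows[[i]] <- tibble::tibble(
      subject_id = id, dose_mg = arms[i], weight_kg = weight,
      time_h = design$pk_times, conc_mg_l = pmax(conc, 0))
    truth_rows[[i]] <- tibble::tibble(subject_id = id, cl_true = cl_i)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "cl_true") <- dplyr::bind_rows(truth_rows)
  out
}
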