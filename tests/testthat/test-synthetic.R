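test_that("the default design yields the full study layout", {
  d <- trial_design()
  expect_equal(d$n_per_arm, 12L)
  expect_equal(length(d$doses) * d$n_per_arm, 24)
  # 24 x 9 runs, 24 x 8 plasma samples
  expect_equal(24 * length(d$run_times), 216)
  expect_equal(24 * length(d$pk_times), 192)
  expect_error(trial_design(run_times = 1:8), "pre-drug")
})

test_that("a one-subject-per-arm design yields two subjects", {
  trial <- generate_trial(trial_design(n_per_arm = 1, seed = 3))
  expect_equal(nrow(trial$subjects), 2)
  expect_setequal(trial$subjects$dose_mg, c(100, 200))
})

test_that("a fixed seed reproduces the dataset exactly; seeds differ", {
  t1 <- generate_trial(trial_design(n_per_arm = 1, seed = 8))
  t2 <- generate_trial(trial_design(n_per_arm = 1, seed = 8))
  t3 <- generate_trial(trial_design(n_per_arm = 1, seed = 9))
  expect_identical(t1$runs, t2$runs)
  expect_identical(t1$pk_samples, t2$pk_samples)
  expect_false(identical(t1$runs$ve_l_min, t3$runs$ve_l_min))
  # identical schema regardless of seed
  expect_identical(names(t1$runs), names(t3$runs))
})

test_that("without variability or drug effect every run equals the deterministic baseline", {
  truth <- study_truth()
  truth$biomarkers$omega2 <- 0
  truth$biomarkers$sigma <- 0
  truth$pk$omega2_cl <- 0
  subj <- generate_subject(trial_design(), truth, dose_mg = 1e-6,
                           subject_id = "Z", seed = 42, noise = FALSE)
  base <- simulate_run(ref_hcvr())$minutes
  for (tt in unique(subj$runs$run_time_h)) {
    mins <- subj$runs[subj$runs$run_time_h == tt, ]
    expect_equal(mins$ve_l_min, base$ve_l_min, tolerance = 1e-6)
    expect_equal(mins$petco2_mmhg, base$petco2_mmhg, tolerance = 1e-5)
  }
})

test_that("the generated trajectories show the hysteresis pattern of the slope vs resting class", {
  truth <- study_truth()
  truth$biomarkers$omega2 <- 0
  truth$pk$omega2_cl <- 0
  truth$pd$omega2_c50 <- 0
  subj <- generate_subject(trial_design(), truth, dose_mg = 200,
                           subject_id = "A", seed = 1, noise = FALSE)
  tr <- subj$run_truth
  rel_s <- tr$slope_s / tr$slope_s[tr$run_time_h == 0]
  rel_ve <- tr$baseline_ve / tr$baseline_ve[tr$run_time_h == 0]
  # at ~2 h the slope is already depressed while resting ventilation is
  # still near control, and the resting nadir comes later
  expect_lt(rel_s[tr$run_time_h == 2], 0.75)
  expect_gt(rel_ve[tr$run_time_h == 2], 0.8)
  expect_gte(tr$run_time_h[which.min(rel_ve)],
             tr$run_time_h[which.min(rel_s)])
  # resting PCO2 and threshold are elevated under drug
  expect_gt(max(tr$resting_petco2), tr$resting_petco2[1])
  expect_gt(max(tr$vrt), tr$vrt[1])
})

test_that("between-subject clearance variability matches its log-normal target", {
  truth <- study_truth()
  pkd <- generate_pk_study(trial_design(n_per_arm = 500, seed = 77),
                           truth, noise = FALSE)
  cls <- attr(pkd, "cl_true")$cl_true
  cv_emp <- 100 * sd(cls) / mean(cls)
  expect_lt(abs(cv_emp - compute_cv(0.06)) / compute_cv(0.06), 0.05)
})

test_that("resting minutes of the pre-drug run average to the subject's baseline", {
  trial <- tiny_trial()
  tr0 <- trial$run_truth[trial$run_truth$run_time_h == 0, ]
  # restrict to dog-leg subjects: when the threshold sits at or below
  # resting PCO2 the realized resting ventilation legitimately exceeds
  # the baseline parameter
  tr0 <- tr0[tr0$vrt > tr0$resting_petco2 + 1, ]
  for (id in tr0$subject_id) {
    mins <- trial$runs[trial$runs$subject_id == id &
                         trial$runs$run_time_h == 0, ]
    rest <- mins$ve_l_min[mins$pico2_mmhg < 1][1:6]
    b0 <- tr0$baseline_ve[tr0$subject_id == id]
    expect_lt(abs(mean(rest) - b0), 3.5 * 0.44 / sqrt(6))
  }
})

test_that("a written trial reads back identically", {
  trial <- generate_trial(trial_design(n_per_arm = 1, seed = 13))
  dir <- file.path(tempdir(), "trial13")
  write_trial(trial, dir)
  back <- read_trial(dir)
  expect_equal(as.data.frame(back$subjects), as.data.frame(trial$subjects))
  expect_equal(as.data.frame(back$pk_samples),
               as.data.frame(trial$pk_samples))
  expect_equal(
    as.data.frame(dplyr::arrange(back$runs, subject_id,
                                 run_time_h, minute)),
    as.data.frame(dplyr::arrange(trial$runs, subject_id,
                                 run_time_h, minute)),
    tolerance = 1e-12)
  expect_equal(back$design$seed, 13L)
  unlink(dir, recursive = TRUE)
})

test_that("infeasible subjects are redrawn rather than emitted", {
  # force an (almost) apneic population: baseline near dead space
  truth <- study_truth()
  truth$biomarkers$baseline[truth$biomarkers$biomarker == "resting_ve"] <- 1.0
  expect_error(
    generate_subject(trial_design(), truth, 100, "X", seed = 2),
    "feasible")
})
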