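test_that("the %CV formula is monotone, zero at zero, and inverts exactly", {
  expect_equal(compute_cv(0), 0)
  om <- seq(0, 1, 0.01)
  expect_true(all(diff(compute_cv(om)) > 0))
  cv <- compute_cv(om)
  expect_equal(cv_to_omega2(cv), om, tolerance = 1e-12)
  expect_error(compute_cv(-0.1), "non-negative")
})

test_that("equal potencies give a unit ratio", {
  pr <- potency_ratios(c(resting = 0.5, slope = 0.5, ve55 = 0.5))
  expect_equal(pr$ratio, c(1, 1))
  expect_error(potency_ratios(c(resting = 0.5, slope = 0.5)), "ve55")
})

test_that("bootstrap SE of the median matches its asymptotic value", {
  set.seed(42)
  x <- rnorm(100)
  se <- bootstrap_se(x, B = 1000, seed = 3)
  expect_lt(abs(se - 1.2533 / sqrt(100)), 0.03)
  # degenerate all-equal input
  expect_equal(bootstrap_se(rep(2.5, 10), B = 200, seed = 1), 0)
  # determinism under a fixed seed
  expect_identical(bootstrap_se(x, B = 500, seed = 11),
                   bootstrap_se(x, B = 500, seed = 11))
  expect_error(bootstrap_se(x[1:4], B = 200), "6 subjects")
  expect_error(bootstrap_se(x, B = 100), "at least 200")
})

test_that("population summaries are permutation-invariant in subject order", {
  set.seed(5)
  est <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:10), each = 2),
    parameter = rep(c("slope_s", "baseline_ve"), 10),
    value = c(rbind(2.5 * exp(rnorm(10, 0, 0.3)),
                    8.3 * exp(rnorm(10, 0, 0.15)))))
  s1 <- population_summary(est, B = 200, seed = 2)
  s2 <- population_summary(est[sample(nrow(est)), ], B = 200, seed = 2)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(s1$omega2 >= 0))
  expect_equal(s1$cv_percent, compute_cv(s1$omega2))
})

test_that("identical arms produce zero dose effect", {
  cp <- hcvr:::pk_conc_fn(pk_parameters(), 200, 70)
  arm <- list(
    slope_s = list(c50 = 0.23, h_half = 0.6, direction = "depressed",
                   cp_fn = cp),
    resting_ve = list(c50 = 0.81, h_half = 1.3, direction = "depressed",
                      cp_fn = cp))
  out <- dose_effect_table(arm, arm)
  expect_equal(out$percent_change, c(0, 0))
})

test_that("a biomarker missing from one arm is dropped with a warning", {
  cp1 <- hcvr:::pk_conc_fn(pk_parameters(), 100, 70)
  cp2 <- hcvr:::pk_conc_fn(pk_parameters(), 200, 70)
  low <- list(slope_s = list(c50 = 0.23, h_half = 0.6,
                             direction = "depressed", cp_fn = cp1))
  high <- list(slope_s = list(c50 = 0.23, h_half = 0.6,
                              direction = "depressed", cp_fn = cp2),
               vrt = list(c50 = 0.81, h_half = 1.3,
                          direction = "elevated", cp_fn = cp2))
  expect_warning(out <- dose_effect_table(low, high), "omitted")
  expect_equal(nrow(out), 1)
  expect_gt(out$percent_change, 0) # the higher dose hits harder
})

test_that("the CO2-stimulated biomarkers carry the largest dose effect", {
  # the slope and VE55 potencies sit closest to the achieved
  # effect-site concentrations, so their peak effects grow most
  # between the arms; the resting class, with its high C50, moves
  # least per extra milligram
  cp1 <- hcvr:::pk_conc_fn(pk_parameters(), 100, 70)
  cp2 <- hcvr:::pk_conc_fn(pk_parameters(), 200, 70)
  arm <- function(cp) list(
    resting_ve = list(c50 = 0.81, h_half = 1.3, direction = "depressed",
                      cp_fn = cp),
    resting_petco2 = list(c50 = 0.81, h_half = 1.3,
                          direction = "elevated", cp_fn = cp),
    vrt = list(c50 = 0.81, h_half = 1.3, direction = "elevated",
               cp_fn = cp),
    slope_s = list(c50 = 0.23, h_half = 0.6, direction = "depressed",
                   cp_fn = cp),
    ve55 = list(c50 = 0.08, h_half = 0.9, direction = "depressed",
                cp_fn = cp))
  out <- dose_effect_table(arm(cp1), arm(cp2))
  expect_setequal(out$biomarker[1:2], c("slope_s", "ve55"))
})
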