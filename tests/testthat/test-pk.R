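test_that("degenerate one-compartment case matches the closed-form infusion solution", {
  # independent oracle: one-compartment zero-order infusion,
  # C(Tabs) = (Dose/(Tabs*CL)) * (1 - exp(-(CL/V1)*Tabs))
  p1 <- pk_parameters(v1 = 90, v2 = 0, cl = 197, cl2 = 0, tabs = 1.2)
  got <- simulate_concentration(p1, 200, 70, 1.2)$conc_mg_l
  expected <- (200 / (1.2 * 197)) * (1 - exp(-(197 / 90) * 1.2))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("no drug appears before ingestion and the profile is continuous", {
  p <- pk_parameters()
  conc <- simulate_concentration(p, 200, 70, seq(0, 4, 0.01),
                                 dose_time = 1)$conc_mg_l
  expect_true(all(conc[seq(0, 4, 0.01) <= 1] == 0))
  expect_lt(max(abs(diff(conc))), 0.02) # no jumps on a 0.01-h grid
})

test_that("total eliminated mass equals the administered dose (quadrature oracle)", {
  tt <- seq(0, 48, 0.002)
  cc <- simulate_concentration(pk_parameters(), 200, 70, tt)$conc_mg_l
  eliminated <- sum(197 * (head(cc, -1) + tail(cc, -1)) / 2 * diff(tt))
  expect_equal(eliminated, 200, tolerance = 0.005)
})

test_that("kinetics are linear: doubling the dose doubles the profile", {
  tt <- seq(0, 12, 0.25)
  c100 <- simulate_concentration(pk_parameters(), 100, 70, tt)$conc_mg_l
  c200 <- simulate_concentration(pk_parameters(), 200, 70, tt)$conc_mg_l
  expect_equal(c200, 2 * c100, tolerance = 1e-12)
})

test_that("analytic solution agrees with a numerical ODE integration", {
  p <- pk_parameters()
  w <- 70
  f <- w / 70
  rhs <- function(t, y, parms) {
    r0 <- if (t > 0 && t <= p$tabs) 200 / p$tabs else 0
    v1 <- p$v1 * f; v2 <- p$v2 * f; cl <- p$cl * f; cl2 <- p$cl2 * f
    c1 <- y[1] / v1; c2 <- y[2] / v2
    list(c(r0 - cl * c1 - cl2 * (c1 - c2), cl2 * (c1 - c2)))
  }
  tt <- seq(0, 10, 0.1)
  num <- deSolve::lsoda(c(a1 = 0, a2 = 0), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  analytic <- simulate_concentration(p, 200, w, tt)$conc_mg_l
  expect_equal(num[, "a1"] / (p$v1 * f), analytic, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("washout is strictly decreasing in the one-compartment degenerate case", {
  p1 <- pk_parameters(v1 = 90, v2 = 0, cl = 197, cl2 = 0, tabs = 1.2)
  tt <- seq(1.2, 24, 0.1)
  cc <- simulate_concentration(p1, 200, 70, tt)$conc_mg_l
  expect_true(all(diff(cc) < 0))
})

test_that("parameter and precondition guards fire", {
  expect_error(pk_parameters(v1 = -1), "positive")
  expect_error(simulate_concentration(pk_parameters(), -5, 70, 0:4),
               "dose_mg")
  few <- tibble::tibble(time_h = 1:3, conc_mg_l = c(0.1, 0.2, 0.1))
  expect_error(fit_pk_individual(few, 200, 70, pk_parameters()),
               "at least 5")
})

test_that("individual fit recovers truth from noise-free data (init perturbed x1.5)", {
  truth <- pk_parameters()
  samp <- simulate_concentration(truth, 200, 70, seq(0.25, 8, 0.25))
  init <- pk_parameters(v1 = 90 * 1.5, v2 = 557 * 1.5, cl = 197 * 1.5,
                        cl2 = 726 * 1.5, tabs = 1.2 * 1.5)
  fit <- fit_pk_individual(samp, 200, 70, init)
  est <- tidy(fit)$estimate
  expect_equal(signif(est, 4), c(90, 557, 197, 726, 1.2), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("individual CL is recovered within 15% under 12% proportional noise", {
  truth <- pk_parameters()
  cls <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    conc <- hcvr:::pk_conc(truth, 200, 70, 0:7) *
      (1 + rnorm(8, 0, sqrt(0.015)))
    samp <- tibble::tibble(time_h = 0:7, conc_mg_l = pmax(conc, 0))
    fit <- fit_pk_individual(samp, 200, 70, pk_parameters(
      v1 = 120, v2 = 400, cl = 150, cl2 = 500, tabs = 1))
    fit$params$cl
  }, 0)
  expect_lt(abs(median(cls) - 197) / 197, 0.15)
})

test_that("population fit recovers structure exactly with zero between-subject variance and no noise", {
  design <- trial_design(n_per_arm = 4, seed = 5)
  truth <- study_truth()
  truth$pk$omega2_cl <- 0
  pkd <- generate_pk_study(design, truth, noise = FALSE)
  fit <- fit_pk_population(pkd, n_boot = 200)
  expect_lt(var(log(fit$subjects$cl)), 0.01)
  expect_equal(fit$params$cl, 197, tolerance = 0.01)
})

test_that("population two-stage fit is reproducible and reports bootstrap SEs", {
  pkd <- generate_pk_study(trial_design(seed = 21))
  f1 <- fit_pk_population(pkd, n_boot = 200, seed = 9)
  f2 <- fit_pk_population(pkd, n_boot = 200, seed = 9)
  expect_identical(tidy(f1), tidy(f2))
  expect_true(all(is.finite(f1$se)))
  expect_gt(f1$se[["cl"]], 0)
})

test_that("between-subject variance of CL is recovered within a factor of two", {
  om <- vapply(1:5, function(s) {
    pkd <- generate_pk_study(trial_design(seed = 400 + s))
    fit_pk_population(pkd, n_boot = 200)$params$omega2_cl
  }, 0)
  expect_gt(median(om), 0.03)
  expect_lt(median(om), 0.12)
})
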