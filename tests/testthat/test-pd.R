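# a simple reference concentration curve reused across PD tests
ref_cp <- function(dose = 200) hcvr:::pk_conc_fn(pk_parameters(), dose, 70)

test_that("effect-site concentration halves a constant input after one half-life", {
  ce <- effect_site_concentration(function(t) rep(1, length(t)), 0.9,
                                  c(0.9, 1.8, 2.7))
  expect_equal(ce$ce_mg_l, c(0.5, 0.75, 0.875), tolerance = 1e-6)
})

test_that("effect site collapses onto plasma as the half-life vanishes", {
  cp <- ref_cp()
  tt <- seq(0, 8, 0.05)
  ce <- effect_site_concentration(cp, 1e-6, tt, dt = 0.002)$ce_mg_l
  expect_lt(max(abs(ce - cp(tt))), 1e-3 * max(cp(tt)))
})

test_that("effect site lags plasma: its peak comes later and lower", {
  cp <- ref_cp()
  tt <- seq(0, 8, 0.01)
  ce <- effect_site_concentration(cp, 0.9, tt)$ce_mg_l
  expect_gt(tt[which.max(ce)], tt[which.max(cp(tt))])
  expect_lt(max(ce), max(cp(tt)))
})

test_that("EMAX forms hit their landmark values", {
  dep <- pd_parameters(8.3, 0.81, 1.3)
  expect_equal(emax_effect(dep, 0), 8.3)
  expect_equal(emax_effect(dep, 0.81), 8.3 / 2) # value drops by 50% at C50
  expect_equal(emax_effect(dep, 3 * 0.81), 8.3 / 4)
  ele <- pd_parameters(41, 0.81, 1.3, direction = "elevated")
  expect_equal(emax_effect(ele, 0), 41)
  expect_equal(emax_effect(ele, 0.81), 82)
  # bounded / monotone
  ce <- seq(0, 20, 0.1)
  expect_true(all(diff(emax_effect(dep, ce)) < 0))
  expect_true(all(emax_effect(dep, ce) > 0 &
                    emax_effect(dep, ce) <= 8.3))
  expect_true(all(diff(emax_effect(ele, ce)) > 0))
})

make_series <- function(c50, h_half, e0 = 37.1, n_subj = 8, sd = 0,
                        seed = 1, direction = "depressed") {
  set.seed(seed)
  tt <- 0:8
  cps <- list()
  rows <- list()
  for (i in seq_len(n_subj)) {
    dose <- if (i <= n_subj / 2) 100 else 200
    cp <- ref_cp(dose)
    id <- sprintf("P%02d", i)
    cps[[id]] <- cp
    ce <- hcvr:::ce_values(cp, h_half, tt)
    g <- hcvr:::emax_shape(ce, c50, 1, direction)
    rows[[i]] <- tibble::tibble(subject_id = id, time_h = tt,
                                value = e0 * g + rnorm(length(tt), 0, sd))
  }
  list(series = dplyr::bind_rows(rows), cps = cps)
}

test_that("zero-noise EMAX series are recovered essentially exactly", {
  dat <- make_series(0.23, 0.6)
  fit <- fit_pd_biomarker(dat$series, dat$cps, "depressed")
  expect_equal(fit$c50, 0.23, tolerance = 1e-3)
  expect_equal(fit$h_half, 0.6, tolerance = 1e-3)
  expect_equal(unique(round(fit$e0$e0, 4)), 37.1)
})

test_that("C50 and hysteresis are recovered under realistic noise", {
  ests <- t(vapply(1:5, function(s) {
    dat <- make_series(0.08, 0.9, sd = 3.46, seed = 100 + s, n_subj = 12)
    fit <- fit_pd_biomarker(dat$series, dat$cps, "depressed")
    c(fit$c50, fit$h_half)
  }, c(0, 0)))
  expect_lt(abs(median(ests[, 1]) - 0.08) / 0.08, 0.5)
  expect_lt(abs(median(ests[, 2]) - 0.9), 0.3)
})

test_that("a flat series without drug signal is flagged at the potency bound", {
  set.seed(4)
  tt <- 0:8
  cps <- setNames(lapply(1:6, function(i) ref_cp(200)), paste0("P", 1:6))
  ser <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(subject_id = paste0("P", i), time_h = tt,
                   value = 8.3 + rnorm(9, 0, 0.05))
  }))
  fit <- fit_pd_biomarker(ser, cps, "depressed")
  expect_true(fit$boundary)
})

test_that("input guards on the biomarker series hold", {
  dat <- make_series(0.23, 0.6, n_subj = 4)
  expect_error(fit_pd_biomarker(dat$series, dat$cps, "depressed"),
               "6 subjects")
  dat8 <- make_series(0.23, 0.6)
  no_t0 <- dat8$series[dat8$series$time_h > 0, ]
  expect_error(fit_pd_biomarker(no_t0, dat8$cps, "depressed"), "t = 0")
})

test_that("identical fits give a zero likelihood-ratio statistic", {
  dat <- make_series(0.81, 1.3, e0 = 8.3, sd = 0.2, seed = 7)
  fit <- fit_pd_biomarker(dat$series, dat$cps, "depressed")
  out <- compare_dynamics(fit, fit)
  expect_equal(out$statistic, 0)
  expect_false(out$significant)
})

test_that("clearly distinct dynamics are detected with high power", {
  rej <- vapply(1:10, function(s) {
    a <- make_series(0.81, 1.3, e0 = 8.3, sd = 0.3, seed = 200 + s)
    b <- make_series(0.08, 0.9, e0 = 37.1, sd = 1.5, seed = 300 + s)
    shared <- fit_pd_biomarker(
      list(x = a$series, y = b$series), a$cps,
      direction = c("depressed", "depressed"),
      weights = c(1 / 0.3^2, 1 / 1.5^2))
    sep <- list(
      fit_pd_biomarker(a$series, a$cps, "depressed", weights = 1 / 0.3^2),
      fit_pd_biomarker(b$series, b$cps, "depressed", weights = 1 / 1.5^2))
    compare_dynamics(shared, sep)$significant
  }, TRUE)
  expect_gte(mean(rej), 0.8)
})

test_that("non-nested model comparisons are rejected", {
  dat <- make_series(0.81, 1.3, e0 = 8.3)
  small <- make_series(0.81, 1.3, e0 = 8.3, n_subj = 6)
  f1 <- fit_pd_biomarker(dat$series, dat$cps, "depressed")
  f2 <- fit_pd_biomarker(small$series, small$cps, "depressed")
  expect_error(compare_dynamics(f1, f2), "not nested")
})
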