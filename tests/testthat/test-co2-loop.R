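test_that("hinge matches its closed forms and limits", {
  expect_equal(hinge(0, 0.1), 0.1 * log(2), tolerance = 1e-12)
  expect_equal(hinge(10, 0.1), 10, tolerance = 1e-6)
  expect_lt(hinge(-10, 0.1), 1e-40)
  # overflow safety and monotonicity
  x <- seq(-1000, 1000, length.out = 4001)
  h <- hinge(x, 0.1)
  expect_true(all(is.finite(h)))
  expect_true(all(diff(h) >= 0))
  # reduces to max(0, x) within delta * log(2) for every delta
  for (d in c(1, 0.1, 0.01)) {
    expect_lte(max(abs(hinge(x, d) - pmax(0, x))), d * log(2) + 1e-12)
  }
  expect_error(hinge(1, 0), "delta")
})

test_that("ventilation law is flat below threshold and linear above", {
  hc <- ref_hcvr()
  expect_equal(ventilation_from_brain_pco2(hc, 44 - 10), 8.3,
               tolerance = 1e-6)
  expect_equal(ventilation_from_brain_pco2(hc, 55),
               8.3 + 2.5 * hinge(11, 0.1), tolerance = 1e-9)
  flat <- hcvr_parameters(8.3, 41, 44, 0)
  expect_equal(ventilation_from_brain_pco2(flat, c(30, 45, 60)),
               rep(8.3, 3))
})

test_that("metabolic CO2 production calibration inverts the steady state", {
  expect_equal(calibrate_vco2(8.3, 41), 266.5 / 115, tolerance = 1e-12)
  expect_error(calibrate_vco2(1.0, 41), "dead-space")
  # limit: ventilation just above dead space -> production ~ 0
  expect_lt(calibrate_vco2(1.8 + 1e-8, 41), 1e-7)
  # round trip to 1e-10
  ss <- closed_loop_steady_state(ref_hcvr())
  expect_equal(ss$arterial_pco2, 41, tolerance = 1e-10)
  expect_equal(ss$ve, 8.3, tolerance = 1e-10)
})

test_that("closed-loop steady state satisfies the metabolic hyperbola to 1e-8", {
  cons <- physiology_constants()
  hc <- ref_hcvr()
  vco2 <- calibrate_vco2(8.3, 41, cons)
  cons2 <- physiology_constants(vco2 = vco2)
  for (pico2 in c(0, 10, 25, 40)) {
    ss <- closed_loop_steady_state(hc, cons2, inspired_pco2 = pico2)
    lhs <- (ss$ve - cons$vd) * (ss$arterial_pco2 - pico2)
    rhs <- cons$lambda1 * cons$lambda2 * vco2
    expect_lt(abs(lhs - rhs) / rhs, 1e-8)
    expect_gte(ss$venous_pco2, ss$arterial_pco2)
  }
})

test_that("raising inspired PCO2 raises steady-state PaCO2 and ventilation", {
  hc <- ref_hcvr()
  grid <- seq(0, 46, by = 2)
  out <- lapply(grid, function(p) closed_loop_steady_state(hc, inspired_pco2 = p))
  pa <- vapply(out, `[[`, 0, "arterial_pco2")
  ve <- vapply(out, `[[`, 0, "ve")
  expect_true(all(diff(pa) > 0))
  # above the recruitment threshold ventilation strictly rises too
  above <- pa > 44
  expect_true(all(diff(ve[above]) > 0))
})

test_that("an apneic parameter set yields an explicit no-solution result", {
  # baseline below dead space with no chemoreflex: no feasible state
  hc <- hcvr_parameters(1.0, 41, 44, 0)
  cons <- physiology_constants(vco2 = 2)
  ss <- closed_loop_steady_state(hc, cons)
  expect_false(ss$feasible)
  expect_true(is.na(ss$arterial_pco2))
})

test_that("zero-increment protocol keeps the loop at its resting equilibrium", {
  prot <- forcing_protocol(increments = 1e-9, resting_duration = 3,
                           step_duration = 4, max_total = 30)
  run <- simulate_run(ref_hcvr(), protocol = prot)
  expect_lt(max(abs(run$minutes$ve_l_min - 8.3)), 1e-3)
  expect_lt(max(abs(run$minutes$petco2_mmhg - 41)), 1e-3)
})

test_that("protocol cap drops the last end-tidal step once", {
  p <- forcing_protocol()
  expect_equal(p$increments, c(4.5, 9, 13.5))
  expect_true(p$last_step_dropped)
  p2 <- forcing_protocol(resting_duration = 4, step_duration = 4)
  expect_equal(length(p2$increments), 4)
  expect_error(forcing_protocol(increments = c(9, 4.5)), "increasing")
})

test_that("end-tidal forcing reaches each plateau within 0.5 mmHg of target", {
  run <- ref_run()
  mins <- run$minutes
  targets <- 41 + c(4.5, 9, 13.5)
  plateaus <- c(mean(mins$petco2_mmhg[mins$minute %in% 11:12]),
                mean(mins$petco2_mmhg[mins$minute %in% 18:19]),
                mean(mins$petco2_mmhg[mins$minute %in% 25:26]))
  expect_true(all(abs(plateaus - targets) < 0.5))
})

test_that("long CO2 steps settle onto the static HCVR line", {
  # with steps long enough for the brain compartment to equilibrate the
  # final-2-min means must lie on baseline + S * (PETCO2 - VRT)
  prot <- forcing_protocol(increments = c(4.5, 9, 13.5),
                           resting_duration = 6, step_duration = 20,
                           max_total = 120)
  run <- simulate_run(ref_hcvr(), protocol = prot)
  mins <- run$minutes
  for (k in 1:3) {
    idx <- (6 + 20 * k - 2):(6 + 20 * k - 1)
    ve <- mean(mins$ve_l_min[mins$minute %in% idx])
    pet <- mean(mins$petco2_mmhg[mins$minute %in% idx])
    line <- 8.3 + 2.5 * hinge(pet - 44, 0.1)
    expect_lt(abs(ve - line) / line, 0.02)
  }
})

test_that("1-min averages are stable under grid refinement", {
  run1 <- ref_run()
  run2 <- simulate_run(ref_hcvr(), dt_out = 0.5)
  expect_equal(run2$minutes$ve_l_min, run1$minutes$ve_l_min,
               tolerance = 1e-3)
})

test_that("brain-tissue PCO2 is a first-order lag with half-time tau*log(2)", {
  # idealized end-tidal clamp: arterial PCO2 stepped from 41 to 51
  cons <- physiology_constants()
  hc <- ref_hcvr()
  vco2 <- calibrate_vco2(8.3, 41, cons)
  times <- seq(0, 12, by = 1 / 600)
  forcing <- cbind(c(0, 2, 12), c(41, 51, 51))
  sol <- hcvr:::integrate_clamped(hc, cons, vco2, forcing, times,
                                  y0 = c(pv = 41 + 115 * vco2 / 4, pbr = 41))
  pbr <- sol[, "pbr"]
  t_half <- times[min(which(pbr >= 46))] - 2
  expect_equal(t_half, 2.5 * log(2), tolerance = 0.01 * 2.5 * log(2))
})

test_that("simulation started at the fixed point stays there (mass conservation)", {
  cons <- physiology_constants()
  hc <- ref_hcvr()
  prot <- forcing_protocol(increments = 1e-9, resting_duration = 10,
                           step_duration = 1, max_total = 30)
  run <- simulate_run(hc, cons, prot)
  drift <- max(abs(run$fine$petco2_mmhg[run$fine$time_min <= 10] - 41))
  expect_lt(drift, 1e-6)
})

test_that("physiology constants enforce the lambda coupling", {
  cons <- physiology_constants(lambda0 = 0.2)
  expect_equal(cons$lambda2, 20)
  expect_error(physiology_constants(valv = -3), "positive")
})
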