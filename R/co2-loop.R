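#' Per-run HCVR parameters
#'
#' The four parameters that describe one hypercapnic ventilatory
#' response run: resting (poikilocapnic) ventilation, resting end-tidal
#' PCO2, the ventilatory recruitment threshold (VRT), and the slope of
#' the linear limb (S). Ventilation follows
#' `VE = baseline_ve + S * hinge(brain_pco2 - vrt, delta)`.
#'
#' @param baseline_ve Resting ventilation, L/min (>= 0).
#' @param resting_petco2 Resting end-tidal PCO2, mmHg.
#' @param vrt Ventilatory recruitment threshold, mmHg.
#' @param slope_s HCVR slope, L min^-1 mmHg^-1 (>= 0).
#' @param run_time Hours since dosing (0 = pre-drug control).
#' @return A list of class `hcvr_parameters`. When `vrt` falls below
#'   `resting_petco2` a diagnostic flag `vrt_below_resting` is set
#'   (reported, not enforced).
#' @export
#' @examples
#' hcvr_parameters(8.3, 41, 44, 2.5)
hcvr_parameters <- function(baseline_ve, resting_petco2, vrt, slope_s,
                            run_time = 0) {
  if (baseline_ve < 0) stop("`baseline_ve` must be >= 0", call. = FALSE)
  if (slope_s < 0) stop("`slope_s` must be >= 0", call. = FALSE)
  if (resting_petco2 <= 0) stop("`resting_petco2` must be positive", call. = FALSE)
  structure(
    list(baseline_ve = baseline_ve, resting_petco2 = resting_petco2,
         vrt = vrt, slope_s = slope_s, run_time = run_time,
         vrt_below_resting = vrt < resting_petco2),
    class = "hcvr_parameters")
}

#' @export
print.hcvr_parameters <- function(x, ...) {
  cat(sprintf(
    "HCVR parameters (t = %g h): VE %.2f L/min, PETCO2 %.1f mmHg, VRT %.1f mmHg, S %.2f L/min/mmHg%s\n",
    x$run_time, x$baseline_ve, x$resting_petco2, x$vrt, x$slope_s,
    if (isTRUE(x$vrt_below_resting)) "  [VRT below resting PETCO2]" else ""))
  invisible(x)
}

#' Ventilation implied by a brain-tissue PCO2
#'
#' The hinge ventilation law `baseline_ve + S * hinge(brain_pco2 - vrt)`,
#' clamped at zero.
#'
#' @param hcvr An [hcvr_parameters()] object.
#' @param brain_pco2 Brain-tissue (effect-site) PCO2, mmHg (vectorized).
#' @param constants A [physiology_constants()] object (supplies `delta`).
#' @return Ventilation, L/min.
#' @export
ventilation_from_brain_pco2 <- function(hcvr, brain_pco2,
                                        constants = physiology_constants()) {
  stopifnot(inherits(hcvr, "hcvr_parameters"))
  pmax(0, hcvr$baseline_ve +
         hcvr$slope_s * hinge(brain_pco2 - hcvr$vrt, constants$delta))
}

#' Calibrate metabolic CO2 production from a resting baseline
#'
#' At the closed-loop steady state with zero inspired CO2 the metabolic
#' hyperbola gives `VCO2 = (VE - VD) * PaCO2 / (lambda1 * lambda2)`.
#' This inverts the steady state so that [closed_loop_steady_state()]
#' with the returned value reproduces the supplied resting pair exactly.
#'
#' @param baseline_ve Resting ventilation, L/min; must exceed dead-space
#'   ventilation.
#' @param baseline_pco2 Resting arterial/end-tidal PCO2, mmHg.
#' @param constants A [physiology_constants()] object.
#' @return CO2 production in model units.
#' @export
#' @examples
#' calibrate_vco2(8.3, 41)  # 266.5 / 115
calibrate_vco2 <- function(baseline_ve, baseline_pco2,
                           constants = physiology_constants()) {
  if (baseline_ve <= constants$vd) {
    stop("resting ventilation must exceed dead-space ventilation; ",
         "an apneic baseline cannot be calibrated", call. = FALSE)
  }
  (baseline_ve - constants$vd) * baseline_pco2 /
    (constants$lambda1 * constants$lambda2)
}

#' Closed-loop steady state of the chemoreflex system
#'
#' Solves the algebraic fixed point of the lung, tissue and brain CO2
#' balances with the hinge ventilation law at a constant inspired PCO2.
#' The solution satisfies the metabolic hyperbola
#' `(VE - VD) * (PaCO2 - PICO2) = lambda1 * lambda2 * VCO2`.
#'
#' @param hcvr An [hcvr_parameters()] object.
#' @param constants A [physiology_constants()] object. If `vco2` is
#'   `NULL` it is calibrated from the resting pair in `hcvr`.
#' @param inspired_pco2 Inspired PCO2, mmHg.
#' @return A one-row tibble: `arterial_pco2`, `venous_pco2`,
#'   `brain_pco2`, `end_tidal_pco2` (= arterial), `inspired_pco2`, `ve`,
#'   `feasible`. If no fixed point with positive alveolar ventilation
#'   exists (apnea), `feasible` is `FALSE` and the state columns are `NA`.
#' @export
#' @examples
#' closed_loop_steady_state(hcvr_parameters(8.3, 41, 44, 2.5))
closed_loop_steady_state <- function(hcvr,
                                     constants = physiology_constants(),
                                     inspired_pco2 = 0) {
  stopifnot(inherits(hcvr, "hcvr_parameters"))
  vco2 <- constants$vco2 %||%
    calibrate_vco2(hcvr$baseline_ve, hcvr$resting_petco2, constants)
  k <- constants$lambda1 * constants$lambda2 * vco2
  vd <- constants$vd
  ve_at <- function(pa) {
    hcvr$baseline_ve + hcvr$slope_s * hinge(pa - hcvr$vrt, constants$delta)
  }
  f <- function(pa) {
    max(ve_at(pa) - vd, 0) * (pa - inspired_pco2) - k
  }
  upper <- 500
  no_solution <- tibble::tibble(
    arterial_pco2 = NA_real_, venous_pco2 = NA_real_, brain_pco2 = NA_real_,
    end_tidal_pco2 = NA_real_, inspired_pco2 = inspired_pco2, ve = NA_real_,
    feasible = FALSE)
  if (f(upper) <= 0) return(no_solution)
  root <- stats::uniroot(f, lower = inspired_pco2 + 1e-9, upper = upper,
                         tol = .Machine$double.eps^0.75)
  pa <- root$root
  # polish with a few Newton steps for 1e-8 relative residual
  for (i in 1:4) {
    h <- max(1e-7, 1e-8 * pa)
    fp <- (f(pa + h) - f(pa - h)) / (2 * h)
    if (!is.finite(fp) || fp == 0) break
    pa <- pa - f(pa) / fp
  }
  ve <- ve_at(pa)
  if (ve <= vd) return(no_solution)
  tibble::tibble(
    arterial_pco2 = pa,
    venous_pco2 = pa + constants$lambda2 * vco2 / constants$q,
    brain_pco2 = pa,
    end_tidal_pco2 = pa,
    inspired_pco2 = inspired_pco2,
    ve = ve,
    feasible = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parameter vector handed to the compiled right-hand sides
co2_parms <- function(hcvr, constants, vco2,
                      kp = 5, ki = 5, pimax = 100, tau_target = 0.15,
                      protocol = NULL) {
  inc <- rep(0, 4)
  restd <- 0; stepd <- 1; nstep <- 0
  if (!is.null(protocol)) {
    ninc <- length(protocol$increments)
    inc[seq_len(min(ninc, 4))] <- protocol$increments[seq_len(min(ninc, 4))]
    restd <- protocol$resting_duration
    stepd <- protocol$step_duration
    nstep <- ninc
  }
  c(constants$valv, constants$vd, constants$vts, constants$q,
    constants$lambda1, constants$lambda2, vco2, constants$tau,
    constants$delta, hcvr$baseline_ve, hcvr$slope_s, hcvr$vrt,
    kp, ki, pimax, restd, stepd, nstep, hcvr$resting_petco2, tau_target,
    inc)
}

#' Simulate one HCVR run under dynamic end-tidal forcing
#'
#' Forward-simulates the closed-loop system from its resting steady
#' state (zero inspired CO2). A proportional-integral controller steers
#' end-tidal PCO2 to the protocol targets by adjusting inspired PCO2,
#' clipped at zero; this reproduces the idealized effect of dynamic
#' end-tidal forcing, not any particular forcing software. Integration
#' uses an adaptive stiff-capable solver (lsoda, rtol 1e-8, atol 1e-10)
#' with dense output on a `dt_out`-second grid; the 1-min table contains
#' arithmetic means of the grid points in each minute.
#'
#' @param hcvr An [hcvr_parameters()] object.
#' @param constants A [physiology_constants()] object; `vco2 = NULL`
#'   triggers calibration from the resting pair.
#' @param protocol A [forcing_protocol()] object.
#' @param dt_out Output grid spacing, s.
#' @param kp,ki Controller gains (mmHg inspired per mmHg error; per-min
#'   integral gain).
#' @return A list of class `hcvr_run`: `fine` (tibble `time_min`,
#'   `ve_l_min`, `petco2_mmhg`, `pico2_mmhg`, `brain_pco2_mmhg`),
#'   `minutes` (tibble `minute`, `ve_l_min`, `petco2_mmhg`,
#'   `pico2_mmhg`), plus the inputs used.
#' @export
#' @examples
#' run <- simulate_run(hcvr_parameters(8.3, 41, 44, 2.5))
#' head(run$minutes)
simulate_run <- function(hcvr, constants = physiology_constants(),
                         protocol = forcing_protocol(), dt_out = 1,
                         kp = 8, ki = 5) {
  stopifnot(inherits(hcvr, "hcvr_parameters"),
            inherits(protocol, "forcing_protocol"))
  vco2 <- constants$vco2 %||%
    calibrate_vco2(hcvr$baseline_ve, hcvr$resting_petco2, constants)
  ss <- closed_loop_steady_state(hcvr, replace_vco2(constants, vco2), 0)
  if (!ss$feasible) {
    stop("no feasible resting steady state for this parameter set",
         call. = FALSE)
  }
  parms <- co2_parms(hcvr, constants, vco2, kp = kp, ki = ki,
                     protocol = protocol)
  total <- protocol$total_duration
  times <- seq(0, total, by = dt_out / 60)
  y0 <- c(pa = ss$arterial_pco2, pv = ss$venous_pco2, pbr = ss$brain_pco2,
          z = 0)
  sol <- deSolve::lsoda(
    y = y0, times = times, func = "co2_closed", parms = parms,
    dllname = "hcvr", initfunc = "co2_init", nout = 2,
    outnames = c("ve", "pico2"), rtol = 1e-8, atol = 1e-10,
    maxsteps = 20000)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed in simulate_run; final state: ",
         paste(round(sol[nrow(sol), ], 4), collapse = ", "), call. = FALSE)
  }
  fine <- tibble::tibble(
    time_min = sol[, "time"],
    ve_l_min = sol[, "ve"],
    petco2_mmhg = sol[, "pa"],
    pico2_mmhg = sol[, "pico2"],
    brain_pco2_mmhg = sol[, "pbr"])
  minutes <- minute_average(fine, dt_out, total)
  structure(
    list(fine = fine, minutes = minutes, hcvr = hcvr, constants = constants,
         protocol = protocol, vco2 = vco2, dt_out = dt_out),
    class = "hcvr_run")
}

replace_vco2 <- function(constants, vco2) {
  constants$vco2 <- vco2
  constants
}

# 1-min block averages aligned to run start
minute_average <- function(fine, dt_out, total) {
  per_min <- round(60 / dt_out)
  n_min <- floor(total)
  mins <- integer(0); ve <- pet <- pic <- numeric(0)
  for (m in seq_len(n_min) - 1L) {
    idx <- (m * per_min + 1):(m * per_min + per_min)
    mins <- c(mins, m)
    ve <- c(ve, mean(fine$ve_l_min[idx]))
    pet <- c(pet, mean(fine$petco2_mmhg[idx]))
    pic <- c(pic, mean(fine$pico2_mmhg[idx]))
  }
  tibble::tibble(minute = mins, ve_l_min = ve, petco2_mmhg = pet,
                 pico2_mmhg = pic)
}

#' @export
print.hcvr_run <- function(x, ...) {
  cat(sprintf(
    "Simulated HCVR run: %.0f min, %d one-minute averages, VE %.2f-%.2f L/min\n",
    max(x$fine$time_min), nrow(x$minutes), min(x$minutes$ve_l_min),
    max(x$minutes$ve_l_min)))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.hcvr_run <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$fine[, c("time_min", "ve_l_min", "petco2_mmhg", "pico2_mmhg")],
    -"time_min", names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = "Simulated HCVR run under end-tidal forcing")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# driven-mode integration: inspired PCO2 prescribed; used by fit_run and
# by open-loop tests. pico2 is a 2-column matrix (time_min, value).
integrate_driven <- function(hcvr, constants, vco2, pico2, times,
                             y0, interp = c("linear", "constant")) {
  interp <- match.arg(interp)
  parms <- co2_parms(hcvr, constants, vco2)
  sol <- deSolve::lsoda(
    y = y0, times = times, func = "co2_driven", parms = parms,
    dllname = "hcvr", initfunc = "co2_init", initforc = "co2_forc",
    forcings = pico2,
    fcontrol = list(method = interp, rule = 2, f = 0),
    nout = 2, outnames = c("ve", "pico2"),
    rtol = 1e-8, atol = 1e-10, maxsteps = 20000)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed in driven-mode integration", call. = FALSE)
  }
  sol
}

# arterial PCO2 prescribed (idealized end-tidal clamp); returns lsoda matrix
integrate_clamped <- function(hcvr, constants, vco2, pa_forcing, times, y0) {
  parms <- co2_parms(hcvr, constants, vco2)
  sol <- deSolve::lsoda(
    y = y0, times = times, func = "co2_clamped", parms = parms,
    dllname = "hcvr", initfunc = "co2_init", initforc = "co2_forc",
    forcings = pa_forcing,
    fcontrol = list(method = "constant", rule = 2, f = 0),
    nout = 2, outnames = c("ve", "pa"),
    rtol = 1e-8, atol = 1e-10, maxsteps = 20000)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed in clamped-mode integration", call. = FALSE)
  }
  sol
}
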