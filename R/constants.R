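#' Fixed and estimated constants of the CO2 chemoreflex loop
#'
#' Bundles the physiological constants that parameterize the lung and
#' tissue CO2 mass balances and the brain-tissue (effect-site) PCO2 lag.
#' The blood CO2 dissociation relation is taken as linear,
#' `P = lambda0 * C`, and the derived constants are `lambda1` (lung
#' transfer constant, approximately q * P_BW / lambda0 / 100) and
#' `lambda2 = 100 * lambda0` (tissue production constant); `lambda2` is
#' always recomputed from `lambda0` so the pair cannot drift apart.
#'
#' @param lambda0 Slope of the blood CO2 pressure/content relation,
#'   mmHg per (mL CO2 / 100 mL blood).
#' @param lambda1 Lung transfer constant, dimensionless.
#' @param valv Alveolar volume, L.
#' @param vd Dead-space ventilation, L/min.
#' @param vts Apparent tissue CO2 distribution volume, L.
#' @param q Cardiac output, L/min.
#' @param tau Brain-tissue PCO2 time constant, min.
#' @param delta Hinge smoothness, mmHg.
#' @param vco2 Metabolic CO2 production in model units, or `NULL` to
#'   calibrate later from a resting baseline (see [calibrate_vco2()]).
#'
#' @return A list of class `physiology_constants`.
#' @seealso [calibrate_vco2()], [closed_loop_steady_state()], [simulate_run()]
#' @export
#' @examples
#' physiology_constants()
physiology_constants <- function(lambda0 = 0.115, lambda1 = 10,
                                 valv = 3, vd = 1.8, vts = 10, q = 4,
                                 tau = 2.5, delta = 0.1, vco2 = NULL) {
  vals <- c(lambda0 = lambda0, lambda1 = lambda1, valv = valv, vd = vd,
            vts = vts, q = q, tau = tau, delta = delta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physiology constants must be finite and strictly positive",
         call. = FALSE)
  }
  if (!is.null(vco2) && (!is.finite(vco2) || vco2 <= 0)) {
    stop("`vco2` must be strictly positive when supplied", call. = FALSE)
  }
  structure(
    list(lambda0 = lambda0, lambda1 = lambda1, lambda2 = 100 * lambda0,
         valv = valv, vd = vd, vts = vts, q = q, tau = tau, delta = delta,
         vco2 = vco2),
    class = "physiology_constants"
  )
}

#' @export
print.physiology_constants <- function(x, ...) {
  cat("CO2 loop physiology constants\n")
  cat(sprintf("  lambda0 %.3f  lambda1 %.1f  lambda2 %.1f\n",
              x$lambda0, x$lambda1, x$lambda2))
  cat(sprintf("  VALV %.1f L  VD %.1f L/min  VTS %.1f L  Q %.1f L/min\n",
              x$valv, x$vd, x$vts, x$q))
  cat(sprintf("  tau %.2f min  delta %.2f mmHg  VCO2 %s\n",
              x$tau, x$delta,
              if (is.null(x$vco2)) "(calibrated per use)" else
                sprintf("%.4f model units", x$vco2)))
  invisible(x)
}

#' Smooth hinge (softplus) function
#'
#' `hinge(x, delta) = delta * log(1 + exp(x / delta))`, a smooth,
#' monotone approximation to `max(0, x)` that the ventilation law uses
#' to switch on the CO2 response above the recruitment threshold. The
#' implementation is overflow-safe for large `|x| / delta`, and
#' `|hinge(x, delta) - max(0, x)| <= delta * log(2)` for all `x`.
#'
#' @param x Input, mmHg (vectorized).
#' @param delta Smoothness scale, mmHg; must be positive.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' hinge(0, 0.1)   # 0.1 * log(2)
#' hinge(10, 0.1)  # ~10
hinge <- function(x, delta = 0.1) {
  if (!is.finite(delta) || delta <= 0) {
    stop("`delta` must be strictly positive", call. = FALSE)
  }
  z <- x / delta
  out <- numeric(length(z))
  hi <- z > 30
  lo <- z < -30
  mid <- !hi & !lo
  out[hi] <- x[hi]
  out[lo] <- delta * exp(z[lo])
  out[mid] <- delta * log1p(exp(z[mid]))
  out
}

#' Dynamic end-tidal forcing protocol
#'
#' Describes one hypercapnic ventilatory response (HCVR) run: a resting
#' (poikilocapnic) phase without added CO2 followed by stepped end-tidal
#' PCO2 targets above the resting level. If the full protocol would
#' exceed `max_total` minutes, the last step is dropped (once), mirroring
#' the study procedure of omitting the +18 mmHg step when a run would
#' run long.
#'
#' @param increments End-tidal PCO2 targets above resting PETCO2, mmHg,
#'   strictly increasing.
#' @param resting_duration Resting-phase duration, min.
#' @param step_duration Duration of each CO2 step, min.
#' @param max_total Cap on total run duration, min, used only to decide
#'   whether the last step is dropped.
#' @return A list of class `forcing_protocol` with the retained
#'   increments and the total duration.
#' @export
#' @examples
#' forcing_protocol()  # default drops the +18 mmHg step
forcing_protocol <- function(increments = c(4.5, 9, 13.5, 18),
                             resting_duration = 6, step_duration = 7,
                             max_total = 20) {
  if (length(increments) < 1 || any(diff(increments) <= 0)) {
    stop("`increments` must be non-empty and strictly increasing", call. = FALSE)
  }
  if (resting_duration <= 0 || step_duration <= 0) {
    stop("durations must be positive", call. = FALSE)
  }
  dropped <- FALSE
  if (length(increments) > 1 &&
      resting_duration + length(increments) * step_duration > max_total) {
    increments <- increments[-length(increments)]
    dropped <- TRUE
  }
  structure(
    list(increments = increments,
         resting_duration = resting_duration,
         step_duration = step_duration,
         max_total = max_total,
         last_step_dropped = dropped,
         total_duration = resting_duration + length(increments) * step_duration),
    class = "forcing_protocol"
  )
}

#' @export
print.forcing_protocol <- function(x, ...) {
  cat(sprintf(
    "End-tidal forcing protocol: %.0f min rest + %d steps x %.0f min (+%s mmHg)%s\n",
    x$resting_duration, length(x$increments), x$step_duration,
    paste(x$increments, collapse = ", "),
    if (x$last_step_dropped) " [last step dropped]" else ""))
  invisible(x)
}

#' Reference population parameter set
#'
#' The reference ("truth") parameter set used by the synthetic-study
#' generator and the recovery experiments: population pharmacokinetic
#' parameters of oral tapentadol, pre-drug HCVR biomarker medians with
#' between-subject variances (omega2, variance of the log parameter) and
#' within-subject standard deviations (sigma), and the effect-compartment
#' EMAX parameters (potency C50 on the mg/L concentration scale and
#' hysteresis half-life h1/2) for the resting-class biomarkers and the
#' HCVR slope. V̇E55 rows are reference values for comparison only: the
#' generator never applies a drug effect to V̇E55 directly, it emerges
#' from the four primitive biomarkers.
#'
#' @return A list with components `pk` (a [pk_parameters()] object),
#'   `biomarkers` (tibble: baseline medians, omega2, sigma, direction),
#'   and `pd` (tibble: C50, omega2 of C50, h1/2 per dynamics class).
#' @export
#' @examples
#' study_truth()$biomarkers
study_truth <- function() {
  list(
    pk = pk_parameters(v1 = 90, v2 = 557, cl = 197, cl2 = 726, tabs = 1.2,
                       sigma2_prop = 0.015, omega2_cl = 0.06),
    biomarkers = tibble::tibble(
      biomarker = c("resting_ve", "resting_petco2", "vrt", "slope_s", "ve55"),
      baseline  = c(8.3, 41, 44, 2.5, 37.1),
      omega2    = c(0.017, 0.007, 0.005, 0.134, 0.121),
      sigma     = c(0.44, 1.50, 1.90, 0.49, 3.46),
      direction = c("depressed", "elevated", "elevated", "depressed", "depressed"),
      pd_class  = c("resting", "resting", "resting", "slope", "ve55")
    ),
    pd = tibble::tibble(
      pd_class   = c("resting", "slope", "ve55"),
      c50        = c(0.81, 0.23, 0.08),
      omega2_c50 = c(0.066, 0.589, 0.105),
      h_half     = c(1.3, 0.6, 0.9)
    )
  )
}
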