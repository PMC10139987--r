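#' Assemble a run record for fitting
#'
#' A run record holds the 1-min averaged channels of one HCVR run:
#' ventilation, end-tidal PCO2 and inspired PCO2, plus identifiers. A
#' fine-grained inspired-PCO2 trace can be attached when available (the
#' simulator provides one); otherwise the fit reconstructs inspired
#' PCO2 as a per-minute staircase, which preserves each minute's
#' average exactly.
#'
#' @param minutes Data frame with columns `minute`, `ve_l_min`,
#'   `petco2_mmhg`, `pico2_mmhg`; minutes must be contiguous from 0.
#' @param subject_id Subject identifier.
#' @param run_time Hours since dosing.
#' @param fine_pico2 Optional two-column matrix or data frame
#'   (`time_min`, `pico2_mmhg`) of the fine inspired-PCO2 trace.
#' @return A list of class `run_record`.
#' @export
run_record <- function(minutes, subject_id = NA_character_, run_time = 0,
                       fine_pico2 = NULL) {
  minutes <- tibble::as_tibble(minutes)
  need <- c("minute", "ve_l_min", "petco2_mmhg", "pico2_mmhg")
  if (!all(need %in% names(minutes))) {
    stop("`minutes` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.integer(minutes$minute),
                 seq_len(nrow(minutes)) - 1L)) {
    stop("minutes must be contiguous starting at 0", call. = FALSE)
  }
  structure(list(minutes = minutes, subject_id = subject_id,
                 run_time = run_time, fine_pico2 = fine_pico2),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("HCVR run record: subject %s, t = %g h, %d minutes\n",
              x$subject_id, x$run_time, nrow(x$minutes)))
  invisible(x)
}

# controller output is discontinuous at protocol phase boundaries; a
# sampled trace smears the jump across one sample interval under linear
# interpolation. Re-sharpen: where adjacent samples differ by a lot,
# pin the pre-jump value just before the later sample.
sharpen_jumps <- function(forcing, threshold = 5) {
  t <- forcing[, 1]; v <- forcing[, 2]
  j <- which(abs(diff(v)) > threshold)
  if (length(j) > 0) {
    t <- c(t, t[j + 1] - 1e-9)
    v <- c(v, v[j])
    o <- order(t)
    t <- t[o]; v <- v[o]
  }
  cbind(t, v)
}

# reconstruct a staircase inspired-PCO2 trace from 1-min averages: the
# recorded value is held constant over its minute, except that a minute
# sandwiched between two distinct plateaus is modelled as a jump from
# the left to the right plateau at the within-minute time that
# preserves the minute's average.
reconstruct_pico2 <- function(minute, v, jump = 3) {
  n <- length(v)
  ts <- numeric(0)
  vs <- numeric(0)
  for (m in seq_len(n)) {
    is_trans <- FALSE
    if (m > 1 && m < n) {
      l <- v[m - 1]; r <- v[m + 1]
      if (abs(r - l) > jump &&
          (v[m] - min(l, r)) > 0.05 * abs(r - l) &&
          (max(l, r) - v[m]) > 0.05 * abs(r - l)) {
        theta <- min(max((r - v[m]) / (r - l), 0), 1)
        ts <- c(ts, minute[m], minute[m] + theta)
        vs <- c(vs, l, r)
        is_trans <- TRUE
      }
    }
    if (!is_trans) {
      ts <- c(ts, minute[m])
      vs <- c(vs, v[m])
    }
  }
  cbind(ts, vs)
}

as_run_record <- function(record) {
  if (inherits(record, "run_record")) return(record)
  if (inherits(record, "hcvr_run")) {
    return(run_record(
      record$minutes,
      run_time = record$hcvr$run_time,
      fine_pico2 = cbind(record$fine$time_min, record$fine$pico2_mmhg)))
  }
  if (is.data.frame(record)) return(run_record(record))
  stop("cannot interpret `record` as a run record", call. = FALSE)
}

# segment CO2-step minutes into protocol steps; a new step starts at a
# large jump in the inspired channel (the forcing command moves much
# faster than within-step drift)
detect_steps <- function(minutes, co2_on, jump = 6) {
  idx <- which(co2_on)
  if (length(idx) == 0) return(list())
  pic <- minutes$pico2_mmhg
  segs <- list()
  cur <- idx[1]
  for (i in idx[-1]) {
    if (i == cur[length(cur)] + 1 &&
        pic[i] - pic[cur[length(cur)]] < jump) {
      cur <- c(cur, i)
    } else {
      segs[[length(segs) + 1]] <- cur
      cur <- i
    }
  }
  segs[[length(segs) + 1]] <- cur
  segs
}

#' Fit the kinetic forward model to one HCVR run
#'
#' Estimates the four per-run HCVR parameters (resting ventilation,
#' resting end-tidal PCO2, ventilatory recruitment threshold, slope) by
#' nonlinear least squares of the CO2 kinetic forward model driven by
#' the recorded inspired PCO2, fitted jointly to the 1-min ventilation
#' and end-tidal PCO2 series (the end-tidal channel identifies resting
#' PETCO2, which the ventilation series alone constrains only weakly). Starting values are data-driven: the resting pair
#' from the pre-CO2 minutes, the slope from an ordinary regression of
#' the last-2-min step means on end-tidal PCO2, and the threshold from
#' that line's intersection with resting ventilation.
#'
#' @param record A `run_record`, an `hcvr_run` (simulator output), or a
#'   minutes data frame.
#' @param constants A [physiology_constants()] object.
#' @param co2_threshold Inspired PCO2 (mmHg) above which a minute counts
#'   as a CO2 step minute.
#' @param w_ve,w_pet Residual scales (L/min, mmHg) of the ventilation
#'   and end-tidal channels in the joint objective.
#' @return A list of class `hcvr_fit`: `estimates`
#'   (an [hcvr_parameters()] object), `ve55`, `apneic_threshold`,
#'   `fitted` (tibble of observed and fitted minute ventilation and the
#'   fitted brain PCO2), `rss`, `converged`, `flagged`, `message`.
#' @export
fit_run <- function(record, constants = physiology_constants(),
                    co2_threshold = 1, w_ve = 0.44, w_pet = 0.5) {
  record <- as_run_record(record)
  minutes <- record$minutes
  n_min <- nrow(minutes)
  # CO2 administration is judged relative to the resting inspired level
  # so that estimates stay equivariant under a shift of all PCO2
  # channels (room air carries a trace of CO2)
  pico2_floor <- min(minutes$pico2_mmhg)
  co2_on <- minutes$pico2_mmhg >= pico2_floor + co2_threshold
  rest_idx <- which(!co2_on & cumsum(co2_on) == 0) # leading resting block
  if (length(rest_idx) < 3) {
    stop("need at least 3 resting minutes before CO2 administration",
         call. = FALSE)
  }
  segs <- detect_steps(minutes, co2_on)
  if (length(segs) < 2) {
    stop("insufficient excitation: need at least 2 CO2 steps", call. = FALSE)
  }

  vd <- constants$vd
  pi_rest <- mean(minutes$pico2_mmhg[rest_idx])
  b0_init <- mean(minutes$ve_l_min[rest_idx])
  p0_init <- mean(minutes$petco2_mmhg[rest_idx])
  step_means <- t(vapply(segs, function(ix) {
    tail_ix <- tail(ix, 2)
    c(ve = mean(minutes$ve_l_min[tail_ix]),
      pet = mean(minutes$petco2_mmhg[tail_ix]))
  }, c(ve = 0, pet = 0)))
  s_init <- {
    fit <- stats::lm.fit(cbind(1, step_means[, "pet"]), step_means[, "ve"])
    unname(fit$coefficients[2])
  }
  if (!is.finite(s_init) || s_init < 0.05) s_init <- 0.1
  a_init <- mean(step_means[, "ve"]) - s_init * mean(step_means[, "pet"])
  vrt_init <- (b0_init - a_init) / s_init
  if (!is.finite(vrt_init)) vrt_init <- p0_init + 3
  vrt_init <- min(max(vrt_init, p0_init - 2), 58)
  b0_init <- max(b0_init, vd + 0.5)

  # inspired-PCO2 driving signal
  if (!is.null(record$fine_pico2)) {
    forcing <- sharpen_jumps(as.matrix(record$fine_pico2))
    interp <- "linear"
  } else {
    forcing <- reconstruct_pico2(minutes$minute, minutes$pico2_mmhg)
    interp <- "constant"
  }
  times <- seq(0, n_min, by = 1 / 60)
  per_min <- 60
  ve_obs <- minutes$ve_l_min
  pet_obs <- minutes$petco2_mmhg

  minute_means <- function(x) {
    vapply(seq_len(n_min) - 1L, function(m) {
      mean(x[(m * per_min + 1):(m * per_min + per_min)])
    }, 0)
  }
  predict_minutes <- function(b0, p0, vrt, s) {
    hc <- list(baseline_ve = b0, resting_petco2 = p0, vrt = vrt,
               slope_s = s, run_time = record$run_time)
    class(hc) <- "hcvr_parameters"
    vco2 <- (b0 - vd) * max(p0 - pi_rest, 1) /
      (constants$lambda1 * constants$lambda2)
    y0 <- c(pa = p0, pv = p0 + constants$lambda2 * vco2 / constants$q,
            pbr = p0)
    sol <- integrate_driven(hc, constants, vco2, forcing, times, y0,
                            interp = interp)
    list(ve = minute_means(sol[, "ve"]),
         pet = minute_means(sol[, "pa"]),
         pbr = minute_means(sol[, "pbr"]))
  }

  unpack <- function(theta) {
    list(b0 = vd + exp(theta[1]), p0 = exp(theta[2]),
         vrt = exp(theta[3]), s = exp(theta[4]))
  }
  # joint objective over the ventilation and end-tidal channels:
  # the end-tidal channel anchors resting PETCO2 (and, through the CO2
  # kinetics, the VRT), which ventilation alone constrains only weakly
  resid_fn <- function(theta) {
    p <- unpack(theta)
    pred <- tryCatch(predict_minutes(p$b0, p$p0, p$vrt, p$s),
                     error = function(e) list(ve = rep(1e4, n_min),
                                              pet = rep(1e4, n_min)))
    c((pred$ve - ve_obs) / w_ve, (pred$pet - pet_obs) / w_pet)
  }
  theta0 <- c(log(b0_init - vd), log(p0_init), log(vrt_init), log(s_init))
  # physiologic boxes keep the search away from degenerate runaways
  # (e.g. a threshold far above the tested range with an exploding
  # slope when a run never recruits the CO2 response)
  lower <- log(c(0.05, 15, 20, 1e-3))
  upper <- log(c(60, 80, 75, 50))
  theta0 <- pmin(pmax(theta0, lower), upper)
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12,
                                         ptol = 1e-12, epsfcn = 1e-8))
  p <- unpack(fit$par)
  est <- hcvr_parameters(p$b0, p$p0, p$vrt, p$s, run_time = record$run_time)
  pred <- predict_minutes(p$b0, p$p0, p$vrt, p$s)
  converged <- fit$info %in% 1:4
  # a threshold estimated beyond the tested end-tidal range means the
  # run never recruited the CO2 response: slope and threshold are then
  # unidentified and the run is reported but flagged
  flagged <- !converged || p$s < 0.01 || p$s > 25 ||
    p$vrt > max(pet_obs) + 4
  structure(
    list(estimates = est,
         ve55 = compute_ve55(est, constants$delta),
         apneic_threshold = compute_apneic_threshold(est, constants$delta),
         fitted = tibble::tibble(minute = minutes$minute,
                                 ve_obs = ve_obs, ve_fit = pred$ve,
                                 brain_pco2 = pred$pbr),
         rss = fit$deviance,
         converged = converged,
         flagged = flagged,
         message = fit$message,
         subject_id = record$subject_id,
         run_time = record$run_time),
    class = "hcvr_fit")
}

#' @export
print.hcvr_fit <- function(x, ...) {
  print(x$estimates)
  cat(sprintf("  VE55 %.2f L/min, apneic threshold %s mmHg, RSS %.3g%s\n",
              x$ve55,
              ifelse(is.na(x$apneic_threshold), "NA",
                     sprintf("%.2f", x$apneic_threshold)),
              x$rss, if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hcvr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("baseline_ve", "resting_petco2", "vrt", "slope_s", "ve55",
             "apneic_threshold"),
    estimate = c(x$estimates$baseline_ve, x$estimates$resting_petco2,
                 x$estimates$vrt, x$estimates$slope_s, x$ve55,
                 x$apneic_threshold))
}

#' @exportS3Method generics::glance
glance.hcvr_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$fitted), converged = x$converged,
                 flagged = x$flagged)
}

#' @exportS3Method ggplot2::autoplot
autoplot.hcvr_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$brain_pco2)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ve_obs), color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ve_fit), color = "firebrick") +
    ggplot2::labs(x = "effect-site (brain) PCO2, mmHg",
                  y = "ventilation, L/min",
                  title = "HCVR: ventilation vs effect-site PCO2")
}

#' Ventilation extrapolated to a PCO2 of 55 mmHg
#'
#' `VE55 = baseline_ve + slope_s * hinge(55 - vrt, delta)`, the linear
#' extrapolation of the HCVR to an effect-site PCO2 of 55 mmHg (the
#' hinge equals the linear limb whenever 55 exceeds the threshold by
#' much more than `delta`).
#'
#' @param hcvr An [hcvr_parameters()] object.
#' @param delta Hinge smoothness, mmHg.
#' @return VE55, L/min.
#' @export
#' @examples
#' compute_ve55(hcvr_parameters(8.3, 41, 44, 2.5))  # ~35.8
compute_ve55 <- function(hcvr, delta = 0.1) {
  stopifnot(inherits(hcvr, "hcvr_parameters"))
  hcvr$baseline_ve + hcvr$slope_s * hinge(55 - hcvr$vrt, delta)
}

#' Apneic threshold from the extrapolated linear limb
#'
#' The classical single-line description of the HCVR,
#' `VE = S * (PETCO2 - B)`, puts the apneic threshold `B` at the
#' zero-ventilation intercept of the extrapolated linear limb:
#' `B = 55 - VE55 / S`.
#'
#' @param hcvr An [hcvr_parameters()] object.
#' @param delta Hinge smoothness, mmHg.
#' @return B in mmHg, or `NA` when the slope is zero.
#' @export
#' @examples
#' compute_apneic_threshold(hcvr_parameters(8.3, 41, 44, 2.5))  # ~40.68
compute_apneic_threshold <- function(hcvr, delta = 0.1) {
  stopifnot(inherits(hcvr, "hcvr_parameters"))
  if (hcvr$slope_s <= 0) return(NA_real_)
  55 - compute_ve55(hcvr, delta) / hcvr$slope_s
}
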