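#' Coefficient of variation from a log-scale variance
#'
#' For a log-normally distributed parameter with variance `omega2` on
#' the log scale, the coefficient of variation is
#' `100 * sqrt(exp(omega2) - 1)` percent.
#'
#' @param omega2 Between-subject variance of the log parameter
#'   (vectorized, >= 0).
#' @return %CV (percent), same length as `omega2`.
#' @export
#' @examples
#' round(compute_cv(c(0.066, 0.134, 0.105, 0.017)))
compute_cv <- function(omega2) {
  if (any(!is.finite(omega2)) || any(omega2 < 0)) {
    stop("`omega2` must be non-negative", call. = FALSE)
  }
  100 * sqrt(exp(omega2) - 1)
}

#' Invert a %CV back to the log-scale variance
#'
#' @param cv_percent %CV, percent.
#' @return omega2 such that `compute_cv(omega2) == cv_percent`.
#' @export
cv_to_omega2 <- function(cv_percent) {
  if (any(cv_percent < 0)) stop("`cv_percent` must be non-negative",
                                call. = FALSE)
  log(1 + (cv_percent / 100)^2)
}

#' Potency ratios of the resting class relative to S and VE55
#'
#' The ratio of the resting-class C50 to the C50 of the slope and of
#' VE55 quantifies how much more potently the opioid hits the
#' CO2-stimulated limb of the response than the resting variables.
#'
#' @param c50 Named numeric vector or one-row data frame with entries
#'   `resting`, `slope`, and `ve55` (C50 values, mg/L).
#' @return A tibble with columns `comparison`, `ratio`, `rounded`
#'   (ratio rounded to two significant digits, as conventionally
#'   reported).
#' @export
#' @examples
#' potency_ratios(c(resting = 0.81, slope = 0.23, ve55 = 0.08))
potency_ratios <- function(c50) {
  if (is.data.frame(c50)) c50 <- unlist(c50[1, , drop = TRUE])
  need <- c("resting", "slope", "ve55")
  if (!all(need %in% names(c50)) || any(!is.finite(c50[need]))) {
    stop("`c50` must supply finite entries named ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ratios <- c(c50[["resting"]] / c50[["slope"]],
              c50[["resting"]] / c50[["ve55"]])
  tibble::tibble(
    comparison = c("resting / slope", "resting / ve55"),
    ratio = ratios,
    rounded = signif(ratios, 2))
}

#' Bootstrap standard error of the median
#'
#' Nonparametric bootstrap over subjects; reproducible under a fixed
#' seed and exactly zero for degenerate all-equal input.
#'
#' @param estimates Per-subject values.
#' @param B Bootstrap replicates (>= 200).
#' @param seed RNG seed.
#' @return Standard error of the median (scalar).
#' @export
bootstrap_se <- function(estimates, B = 1000, seed = 1L) {
  estimates <- sort(estimates[is.finite(estimates)]) # order-invariant
  n <- length(estimates)
  if (n < 6) stop("need at least 6 subjects", call. = FALSE)
  if (B < 200) stop("`B` must be at least 200", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  meds <- vapply(seq_len(B), function(b) {
    median(estimates[sample.int(n, n, replace = TRUE)])
  }, 0)
  sd(meds)
}

#' Population summary of per-subject parameter estimates
#'
#' Stage-2 aggregation: per parameter the population point estimate is
#' the median of the per-subject values, the standard error comes from
#' a nonparametric bootstrap of the median, the between-subject
#' variance `omega2` is the variance of the log values, and `%CV`
#' follows from [compute_cv()]. Within-subject `sigma` (residual SD in
#' parameter units) can be attached from repeated measurements.
#'
#' @param estimates Data frame with columns `subject_id`, `parameter`,
#'   `value` (one row per subject and parameter).
#' @param B,seed Bootstrap replicates and seed for the SE of the median.
#' @param sigma Optional named vector of within-subject residual SDs to
#'   attach (one per parameter).
#' @return A tibble of class `population_summary` with columns
#'   `parameter`, `estimate`, `se`, `omega2`, `cv_percent`, `sigma`,
#'   `n_subjects`.
#' @export
population_summary <- function(estimates, B = 1000, seed = 1L,
                               sigma = NULL) {
  estimates <- tibble::as_tibble(estimates)
  need <- c("subject_id", "parameter", "value")
  if (!all(need %in% names(estimates))) {
    stop("`estimates` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- estimates |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      estimate = median(.data$value),
      se = bootstrap_se(.data$value, B = B, seed = seed),
      omega2 = var(log(pmax(.data$value, 1e-12))),
      n_subjects = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(cv_percent = compute_cv(.data$omega2))
  if (!is.null(sigma)) {
    out$sigma <- unname(sigma[out$parameter])
  } else {
    out$sigma <- NA_real_
  }
  out <- out[, c("parameter", "estimate", "se", "omega2", "cv_percent",
                 "sigma", "n_subjects")]
  class(out) <- c("population_summary", class(out))
  out
}

#' Dose-effect comparison between study arms
#'
#' For each biomarker, computes the peak drug effect in each arm as the
#' largest fractional deviation from the pre-drug baseline (nadir for
#' depressed biomarkers, zenith for elevated ones) of the
#' population-fitted effect time course, and reports the
#' percentage-point change between the low- and high-dose arms,
#' together with the implied sensitivity ordering.
#'
#' @param fits_low,fits_high Named lists (by biomarker) of one-row data
#'   frames or lists with elements `c50`, `h_half`, `direction`, and a
#'   representative concentration function `cp_fn` for the arm (e.g.
#'   the median subject's).
#' @param times Evaluation grid, h.
#' @return A tibble: `biomarker`, `peak_effect_low`, `peak_effect_high`
#'   (fractional), `percent_change` (percentage points, high - low),
#'   sorted by decreasing dose effect.
#' @export
dose_effect_table <- function(fits_low, fits_high,
                              times = seq(0, 8, by = 0.05)) {
  if (length(fits_low) == 0 || length(fits_high) == 0) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  common <- intersect(names(fits_low), names(fits_high))
  skipped <- setdiff(union(names(fits_low), names(fits_high)), common)
  if (length(skipped) > 0) {
    warning("biomarker(s) missing in one arm, omitted: ",
            paste(skipped, collapse = ", "))
  }
  peak_effect <- function(f) {
    ce <- ce_values(f$cp_fn, f$h_half, times)
    g <- emax_shape(ce, f$c50, 1, f$direction)
    max(abs(g - 1)) # fractional deviation from baseline
  }
  rows <- lapply(common, function(b) {
    lo <- peak_effect(fits_low[[b]])
    hi <- peak_effect(fits_high[[b]])
    tibble::tibble(biomarker = b, peak_effect_low = lo,
                   peak_effect_high = hi,
                   percent_change = 100 * (hi - lo))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(abs(.data$percent_change)))
  out
}
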