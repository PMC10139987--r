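#' Effect-compartment EMAX parameters for one biomarker
#'
#' Links the plasma concentration time course to a biomarker through a
#' first-order effect compartment (`ke0 = log(2) / h_half`) followed by
#' a sigmoid EMAX response. Biomarkers depressed by the opioid use the
#' inhibitory form `e0 * c50^gamma / (c50^gamma + ce^gamma)`; biomarkers
#' that rise (resting PCO2, recruitment threshold) use the reciprocal
#' elevated form `e0 * (c50^gamma + ce^gamma) / c50^gamma`.
#'
#' @param e0 Pre-drug baseline, biomarker units.
#' @param c50 Effect-site concentration at 50% effect, mg/L.
#' @param h_half Blood-to-effect-site equilibration half-life, h.
#' @param gamma Shape factor; fixed to 1 by default.
#' @param direction `"depressed"` or `"elevated"`.
#' @return A list of class `pd_parameters`.
#' @export
pd_parameters <- function(e0, c50, h_half, gamma = 1,
                          direction = c("depressed", "elevated")) {
  direction <- match.arg(direction)
  if (c50 <= 0) stop("`c50` must be positive", call. = FALSE)
  if (h_half <= 0) stop("`h_half` must be positive", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  structure(list(e0 = e0, c50 = c50, h_half = h_half, gamma = gamma,
                 direction = direction),
            class = "pd_parameters")
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat(sprintf(
    "EMAX parameters (%s): E0 %.3g, C50 %.3g mg/L, h1/2 %.2g h, gamma %.2g\n",
    x$direction, x$e0, x$c50, x$h_half, x$gamma))
  invisible(x)
}

#' Effect-site concentration by first-order equilibration
#'
#' Integrates `dCe/dt = ke0 * (Cp - Ce)` with `Ce(0) = 0` and
#' `ke0 = log(2) / h_half`. The plasma curve is evaluated on a fine
#' grid and the filter is applied exactly under piecewise-linear Cp, so
#' the result lags and smooths the plasma curve and collapses onto it
#' as `h_half -> 0`.
#'
#' @param cp_fn Function of time (h) returning plasma concentration.
#' @param h_half Equilibration half-life, h.
#' @param times Output times, h (non-negative).
#' @param dt Internal grid spacing, h.
#' @return A tibble with columns `time_h` and `ce_mg_l`.
#' @export
#' @examples
#' ce <- effect_site_concentration(function(t) rep(1, length(t)), 0.9, 0.9)
#' ce$ce_mg_l  # 0.5: definition of the half-life
effect_site_concentration <- function(cp_fn, h_half, times, dt = 0.005) {
  if (h_half <= 0) stop("`h_half` must be positive", call. = FALSE)
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  ce <- ce_values(cp_fn, h_half, times, dt)
  tibble::tibble(time_h = times, ce_mg_l = ce)
}

# bare numeric version; exact exponential update for piecewise-linear Cp
ce_values <- function(cp_fn, h_half, times, dt = 0.005) {
  ke0 <- log(2) / h_half
  tmax <- max(times, dt)
  grid <- seq(0, tmax, by = dt)
  if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
  cp <- cp_fn(grid)
  nd <- diff(grid)
  a <- exp(-ke0 * nd)
  w1 <- 1 - a
  w2 <- 1 - w1 / (ke0 * nd)
  c0 <- cp[-length(cp)]
  c1 <- cp[-1]
  b <- c0 * w1 + (c1 - c0) * w2
  if (length(unique(round(nd, 12))) == 1) {
    ce_tail <- stats::filter(b, a[1], method = "recursive")
  } else {
    ce_tail <- numeric(length(b))
    acc <- 0
    for (i in seq_along(b)) {
      acc <- acc * a[i] + b[i]
      ce_tail[i] <- acc
    }
  }
  ce_grid <- c(0, as.numeric(ce_tail))
  stats::approx(grid, ce_grid, xout = times, rule = 2)$y
}

#' Sigmoid EMAX biomarker value at an effect-site concentration
#'
#' @param pd A [pd_parameters()] object.
#' @param ce Effect-site concentration, mg/L (vectorized, >= 0).
#' @return Biomarker value in its own units. At `ce = 0` the baseline
#'   `e0`; at `ce = c50` half the baseline (depressed) or twice the
#'   baseline's deviation scale (elevated form doubles the value).
#' @export
#' @examples
#' pd <- pd_parameters(8.3, 0.81, 1.3)
#' emax_effect(pd, c(0, 0.81))  # 8.3, 4.15
emax_effect <- function(pd, ce) {
  stopifnot(inherits(pd, "pd_parameters"))
  if (any(ce < 0)) stop("`ce` must be non-negative", call. = FALSE)
  g <- pd$gamma
  if (pd$direction == "depressed") {
    pd$e0 * pd$c50^g / (pd$c50^g + ce^g)
  } else {
    pd$e0 * (pd$c50^g + ce^g) / pd$c50^g
  }
}

# shape factor g(ce) with e0 divided out
emax_shape <- function(ce, c50, gamma, direction) {
  if (direction == "depressed") {
    c50^gamma / (c50^gamma + ce^gamma)
  } else {
    (c50^gamma + ce^gamma) / c50^gamma
  }
}

# effect-site values from a cached plasma grid (the grid and plasma
# values do not depend on the parameters being optimized)
ce_cached <- function(blk, h_half) {
  ke0 <- log(2) / h_half
  dt <- blk$grid[2] - blk$grid[1]
  a <- exp(-ke0 * dt)
  w1 <- 1 - a
  w2 <- 1 - w1 / (ke0 * dt)
  cp <- blk$cp_grid
  b <- cp[-length(cp)] * w1 + diff(cp) * w2
  ce_grid <- c(0, as.numeric(stats::filter(b, a, method = "recursive")))
  stats::approx(blk$grid, ce_grid, xout = blk$times, rule = 2)$y
}

# core weighted SSR with per-subject baselines profiled out in closed
# form. `blocks` is a list with elements: times, values, weight,
# direction, cp_fn and a cached plasma grid (one block = one subject x
# biomarker series).
pd_objective <- function(c50, h_half, blocks, gamma = 1) {
  rss <- 0
  for (blk in blocks) {
    ce <- ce_cached(blk, h_half)
    g <- emax_shape(ce, c50, gamma, blk$direction)
    denom <- sum(g * g)
    e0 <- if (denom > 0) sum(g * blk$values) / denom else 0
    e0 <- max(e0, 1e-8)
    rss <- rss + blk$weight * sum((blk$values - e0 * g)^2)
  }
  rss
}

pd_profile_e0 <- function(c50, h_half, blocks, gamma = 1) {
  vapply(blocks, function(blk) {
    ce <- ce_cached(blk, h_half)
    g <- emax_shape(ce, c50, gamma, blk$direction)
    denom <- sum(g * g)
    max(if (denom > 0) sum(g * blk$values) / denom else 0, 1e-8)
  }, 0)
}

# grid start + nlminb polish over (log c50, log h_half)
pd_optimize <- function(blocks, gamma = 1,
                        c50_grid = 10^seq(-2.2, 0.9, length.out = 14),
                        hh_grid = c(0.2, 0.35, 0.6, 0.9, 1.3, 2, 3),
                        c50_max = 50) {
  best <- NULL
  for (cc in c50_grid) {
    for (hh in hh_grid) {
      v <- pd_objective(cc, hh, blocks, gamma)
      if (is.null(best) || v < best$value) {
        best <- list(c50 = cc, h_half = hh, value = v)
      }
    }
  }
  obj <- function(th) pd_objective(exp(th[1]), exp(th[2]), blocks, gamma)
  opt <- stats::nlminb(log(c(best$c50, best$h_half)), obj,
                       lower = log(c(1e-4, 0.02)),
                       upper = log(c(c50_max, 24)),
                       control = list(rel.tol = 1e-12, eval.max = 500,
                                      iter.max = 300))
  c50 <- exp(opt$par[1])
  h_half <- exp(opt$par[2])
  # no usable drug signal: the potency ran to a bound, or the EMAX
  # term explains essentially none of the variance beyond a constant
  # per-subject model
  rss_null <- sum(vapply(blocks, function(blk) {
    blk$weight * sum((blk$values - mean(blk$values))^2)
  }, 0))
  boundary <- c50 >= c50_max * 0.99 || c50 <= 1.01e-4 ||
    opt$objective >= rss_null * 0.98
  list(c50 = c50, h_half = h_half, rss = opt$objective,
       converged = opt$convergence == 0, boundary = boundary)
}

series_to_blocks <- function(series, cp_fns, direction, weight = 1) {
  series <- tibble::as_tibble(series)
  need <- c("subject_id", "time_h", "value")
  if (!all(need %in% names(series))) {
    stop("`series` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(series, series$subject_id), function(dat) {
    dat <- dat[order(dat$time_h), , drop = FALSE]
    if (anyDuplicated(dat$time_h)) {
      stop("duplicate time points within a subject's series", call. = FALSE)
    }
    if (!any(dat$time_h == 0)) {
      stop("each subject's series must include the t = 0 pre-drug point",
           call. = FALSE)
    }
    id <- as.character(dat$subject_id[1])
    if (!id %in% names(cp_fns)) {
      stop("no concentration function for subject ", id, call. = FALSE)
    }
    grid <- seq(0, max(dat$time_h, 0.005), by = 0.005)
    list(times = dat$time_h, values = dat$value, weight = weight,
         direction = direction, cp_fn = cp_fns[[id]], subject_id = id,
         grid = grid, cp_grid = cp_fns[[id]](grid))
  })
}

#' Fit the effect-compartment EMAX model to a biomarker series
#'
#' Least squares over all subjects' series with a shared potency `c50`
#' and hysteresis half-life `h_half` and per-subject baselines `e0`
#' (profiled out in closed form at every objective evaluation). Several
#' biomarkers can be constrained to share `c50`/`h_half` (the
#' resting-class constraint) by passing a list of series.
#'
#' @param series A data frame with columns `subject_id`, `time_h`,
#'   `value` for one biomarker, or a named list of such data frames for
#'   a shared-dynamics fit.
#' @param cp_fns Named list (by subject id) of plasma-concentration
#'   functions of time, e.g. from [pk_conc_fns()].
#' @param direction `"depressed"` or `"elevated"`, recycled across the
#'   list when `series` is a list.
#' @param weights Optional per-series inverse-variance weights for the
#'   shared fit (defaults to 1/sigma^2 with sigma = 1 per series).
#' @param gamma Shape factor, fixed (default 1).
#' @return A list of class `pd_fit`: `c50`, `h_half`, `gamma`, `e0`
#'   (tibble per subject and series), `rss` (weighted), `n_obs`,
#'   `n_params`, `converged`, `boundary` (flag: potency ran to a bound,
#'   e.g. no drug signal in the series).
#' @export
fit_pd_biomarker <- function(series, cp_fns, direction, weights = NULL,
                             gamma = 1) {
  if (is.data.frame(series)) {
    series <- list(biomarker = series)
    direction <- rep(direction, 1)
  }
  n_series <- length(series)
  direction <- rep(direction, length.out = n_series)
  if (is.null(weights)) weights <- rep(1, n_series)
  if (length(weights) != n_series) {
    stop("`weights` must match the number of series", call. = FALSE)
  }
  blocks <- list()
  labels <- names(series) %||% paste0("series", seq_len(n_series))
  for (i in seq_len(n_series)) {
    bl <- series_to_blocks(series[[i]], cp_fns, direction[i], weights[i])
    for (b in seq_along(bl)) bl[[b]]$label <- labels[i]
    blocks <- c(blocks, bl)
  }
  n_subj <- length(unique(vapply(blocks, `[[`, "", "subject_id")))
  if (n_subj < 6) stop("need at least 6 subjects", call. = FALSE)
  n_pts <- vapply(blocks, function(b) length(b$times), 0L)
  if (any(n_pts < 5)) {
    stop("each subject needs at least 5 time points", call. = FALSE)
  }
  opt <- pd_optimize(blocks, gamma)
  e0 <- pd_profile_e0(opt$c50, opt$h_half, blocks, gamma)
  structure(
    list(c50 = opt$c50, h_half = opt$h_half, gamma = gamma,
         e0 = tibble::tibble(
           subject_id = vapply(blocks, `[[`, "", "subject_id"),
           series = vapply(blocks, `[[`, "", "label"),
           e0 = e0),
         direction = setNames(direction, labels),
         rss = opt$rss,
         n_obs = sum(n_pts),
         n_params = 2 + length(blocks),
         converged = opt$converged,
         boundary = opt$boundary),
    class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, ...) {
  cat(sprintf(
    "Effect-compartment EMAX fit: C50 %.4g mg/L, h1/2 %.3g h (%d subjects x %d series)%s\n",
    x$c50, x$h_half, length(unique(x$e0$subject_id)),
    length(unique(x$e0$series)),
    if (x$boundary) "  [boundary: no usable drug signal]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pd_fit <- function(x, ...) {
  tibble::tibble(term = c("c50", "h_half"),
                 estimate = c(x$c50, x$h_half))
}

#' @exportS3Method generics::glance
glance.pd_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_obs = x$n_obs, n_params = x$n_params,
                 converged = x$converged, boundary = x$boundary)
}

#' Likelihood-ratio comparison of shared vs separate dynamics
#'
#' Tests whether a set of biomarkers shares one (C50, h1/2) pair
#' against the alternative that each dynamics group has its own, using
#' the Gaussian residual likelihood: the statistic is
#' `N * log(RSS_shared / RSS_separate)` referred to a chi-squared
#' distribution with the difference in parameter count as degrees of
#' freedom. The models must be nested fits of identical data.
#'
#' @param model_shared A `pd_fit` for the constrained (shared) model.
#' @param model_separate A `pd_fit` or list of `pd_fit`s whose series
#'   partition the shared model's data.
#' @param alpha Significance threshold (default 0.01).
#' @return A one-row tibble: `statistic`, `df`, `p_value`,
#'   `significant`.
#' @export
compare_dynamics <- function(model_shared, model_separate, alpha = 0.01) {
  stopifnot(inherits(model_shared, "pd_fit"))
  if (inherits(model_separate, "pd_fit")) {
    model_separate <- list(model_separate)
  }
  if (!all(vapply(model_separate, inherits, TRUE, "pd_fit"))) {
    stop("`model_separate` must be pd_fit objects", call. = FALSE)
  }
  n_sep <- sum(vapply(model_separate, `[[`, 0, "n_obs"))
  if (n_sep != model_shared$n_obs) {
    stop("models are not nested: observation counts differ", call. = FALSE)
  }
  rss_sep <- sum(vapply(model_separate, `[[`, 0, "rss"))
  p_sep <- sum(vapply(model_separate, `[[`, 0, "n_params"))
  df <- p_sep - model_shared$n_params
  if (df < 0) stop("`model_shared` has more parameters than the separate fits",
                   call. = FALSE)
  n <- model_shared$n_obs
  stat <- max(n * log(model_shared$rss / rss_sep), 0)
  p <- pchisq(stat, df = max(df, 1), lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 significant = p < alpha)
}

#' Per-subject plasma concentration functions
#'
#' Convenience builder: one concentration-vs-time closure per subject
#' from a subject table and PK parameters (population structural
#' parameters with per-subject clearance when available).
#'
#' @param subjects Data frame with columns `subject_id`, `dose_mg`,
#'   `weight_kg`, and optionally `cl` (subject-level clearance per
#'   70 kg).
#' @param params A [pk_parameters()] object for the structural
#'   parameters.
#' @return Named list of functions of time (h).
#' @export
pk_conc_fns <- function(subjects, params) {
  subjects <- tibble::as_tibble(subjects)
  fns <- lapply(seq_len(nrow(subjects)), function(i) {
    p <- params
    if ("cl" %in% names(subjects) && is.finite(subjects$cl[i])) {
      p$cl <- subjects$cl[i]
    }
    pk_conc_fn(p, subjects$dose_mg[i], subjects$weight_kg[i])
  })
  setNames(fns, as.character(subjects$subject_id))
}
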