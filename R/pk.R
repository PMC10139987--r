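#' Two-compartment pharmacokinetic parameters
#'
#' Apparent oral parameters of the two-compartment model with zero-order
#' absorption (tablet-to-blood input of fixed duration). Bioavailability
#' is fixed at 1, so volumes and clearances are apparent (V/F, CL/F).
#' Volumes and clearances are expressed for a 70-kg individual and scale
#' linearly with weight / 70.
#'
#' @param v1 Central volume, L per 70 kg.
#' @param v2 Peripheral volume, L per 70 kg.
#' @param cl Elimination clearance, L/h for 70 kg.
#' @param cl2 Intercompartmental clearance, L/h for 70 kg.
#' @param tabs Zero-order absorption duration, h.
#' @param sigma2_prop Proportional residual variance.
#' @param omega2_cl Between-subject variance of log CL.
#' @return A list of class `pk_parameters`.
#' @export
#' @examples
#' pk_parameters()
pk_parameters <- function(v1 = 90, v2 = 557, cl = 197, cl2 = 726,
                          tabs = 1.2, sigma2_prop = 0.015,
                          omega2_cl = 0.06) {
  pos <- c(v1 = v1, cl = cl, tabs = tabs)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("`v1`, `cl` and `tabs` must be strictly positive", call. = FALSE)
  }
  if (v2 < 0 || cl2 < 0 || sigma2_prop < 0 || omega2_cl < 0) {
    stop("`v2`, `cl2`, `sigma2_prop` and `omega2_cl` must be non-negative",
         call. = FALSE)
  }
  structure(list(v1 = v1, v2 = v2, cl = cl, cl2 = cl2, tabs = tabs,
                 sigma2_prop = sigma2_prop, omega2_cl = omega2_cl),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Two-compartment PK parameters (apparent oral, per 70 kg)\n")
  cat(sprintf("  V1 %.3g L  V2 %.3g L  CL %.3g L/h  CL2 %.3g L/h  Tabs %.3g h\n",
              x$v1, x$v2, x$cl, x$cl2, x$tabs))
  cat(sprintf("  prop. residual var %.4g  omega2(CL) %.4g\n",
              x$sigma2_prop, x$omega2_cl))
  invisible(x)
}

# macro constants of the bi-exponential solution, weight-scaled
pk_macro <- function(params, weight_kg) {
  f <- weight_kg / 70
  v1 <- params$v1 * f
  cl <- params$cl * f
  cl2 <- params$cl2 * f
  v2 <- params$v2 * f
  k10 <- cl / v1
  k12 <- cl2 / v1
  k21 <- if (v2 > 0) cl2 / v2 else 0
  s <- k10 + k12 + k21
  disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  if (alpha - beta < 1e-12 * alpha) beta <- alpha * (1 - 1e-9) # avoid 0/0
  a_co <- (alpha - k21) / (alpha - beta)
  b_co <- 1 - a_co
  list(v1 = v1, alpha = alpha, beta = beta, a = a_co, b = b_co)
}

# (1 - exp(-lam * t)) / lam with the lam -> 0 limit; vectorized in t
phi_fun <- function(lam, t) {
  if (lam > 1e-12) -expm1(-lam * t) / lam else t * (1 - lam * t / 2)
}

#' Simulate the noise-free plasma concentration profile
#'
#' Analytic solution of the two-compartment model with a zero-order
#' input of duration `tabs` starting at the dose time. Concentration is
#' zero before ingestion and continuous everywhere. Units: dose mg,
#' volumes L, so concentration is mg/L; the reference potency values in
#' [study_truth()] are expressed on this same scale.
#'
#' @param params A [pk_parameters()] object.
#' @param dose_mg Oral dose, mg.
#' @param weight_kg Body weight, kg.
#' @param times Sampling times, h (sorted, non-negative).
#' @param dose_time Ingestion time, h.
#' @return A tibble with columns `time_h` and `conc_mg_l`.
#' @export
#' @examples
#' simulate_concentration(pk_parameters(), 200, 70, seq(0, 8, 0.5))
simulate_concentration <- function(params, dose_mg, weight_kg, times,
                                   dose_time = 0) {
  stopifnot(inherits(params, "pk_parameters"))
  if (dose_mg <= 0) stop("`dose_mg` must be positive", call. = FALSE)
  if (weight_kg <= 0) stop("`weight_kg` must be positive", call. = FALSE)
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be sorted", call. = FALSE)
  tibble::tibble(
    time_h = times,
    conc_mg_l = pk_conc(params, dose_mg, weight_kg, times, dose_time)
  )
}

# bare numeric version used in inner loops
pk_conc <- function(params, dose_mg, weight_kg, times, dose_time = 0) {
  m <- pk_macro(params, weight_kg)
  r0 <- dose_mg / params$tabs
  tt <- times - dose_time
  conc <- numeric(length(tt))
  during <- tt > 0 & tt <= params$tabs
  after <- tt > params$tabs
  if (any(during)) {
    td <- tt[during]
    conc[during] <- (r0 / m$v1) *
      (m$a * phi_fun(m$alpha, td) + m$b * phi_fun(m$beta, td))
  }
  if (any(after)) {
    ta <- tt[after] - params$tabs
    pa <- phi_fun(m$alpha, params$tabs)
    pb <- phi_fun(m$beta, params$tabs)
    conc[after] <- (r0 / m$v1) *
      (m$a * pa * exp(-m$alpha * ta) + m$b * pb * exp(-m$beta * ta))
  }
  conc
}

# fast closure for repeated evaluation (PD layer)
pk_conc_fn <- function(params, dose_mg, weight_kg, dose_time = 0) {
  force(params); force(dose_mg); force(weight_kg); force(dose_time)
  function(t) pk_conc(params, dose_mg, weight_kg, t, dose_time)
}

#' Fit the PK model to one subject's samples
#'
#' Least squares on the log-concentration scale (the standard transform
#' for a proportional-error model) using Levenberg-Marquardt on
#' log-transformed parameters. The absorption duration is profiled on a
#' grid first (it acts as a breakpoint and traps descent methods), then
#' all free parameters are polished jointly. Samples at or before
#' the dose time, and zero concentrations, are excluded (the model
#' predicts zero before absorption starts).
#'
#' @param samples Data frame with columns `time_h` and `conc_mg_l`.
#' @param dose_mg,weight_kg Dose (mg) and body weight (kg).
#' @param init A [pk_parameters()] object of starting values.
#' @param estimate Character vector naming the free parameters among
#'   `c("v1", "v2", "cl", "cl2", "tabs")`; the rest stay at `init`.
#' @param dose_time Ingestion time, h.
#' @return A list of class `pk_fit` with elements `params`
#'   (a [pk_parameters()] object), `objective`, `converged`, `message`,
#'   and `n_obs`.
#' @export
fit_pk_individual <- function(samples, dose_mg, weight_kg, init,
                              estimate = c("v1", "v2", "cl", "cl2", "tabs"),
                              dose_time = 0) {
  stopifnot(inherits(init, "pk_parameters"))
  samples <- tibble::as_tibble(samples)
  if (!all(c("time_h", "conc_mg_l") %in% names(samples))) {
    stop("`samples` needs columns `time_h` and `conc_mg_l`", call. = FALSE)
  }
  if (nrow(samples) < 5) {
    stop("need at least 5 plasma samples to fit the PK model", call. = FALSE)
  }
  if (!any(samples$time_h > dose_time & samples$time_h <= dose_time + init$tabs)) {
    stop("need at least one sample in the absorption phase", call. = FALSE)
  }
  obs <- samples[samples$time_h > dose_time & samples$conc_mg_l > 0, ,
                 drop = FALSE]
  estimate <- match.arg(estimate, c("v1", "v2", "cl", "cl2", "tabs"),
                        several.ok = TRUE)
  cur <- init
  # two-compartment least squares is multimodal and the absorption
  # duration behaves like a breakpoint: profile tabs on a grid with the
  # smooth parameters fitted by Levenberg-Marquardt, then polish all
  # free parameters jointly from the grid winner
  lm_ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-13,
                                       ptol = 1e-13)
  smooth_pars <- setdiff(estimate, "tabs")
  run_lm <- function(start_named, free) {
    theta0 <- log(start_named[free])
    other <- start_named[setdiff(names(start_named), free)]
    fn <- function(theta) {
      v <- c(exp(theta), other)
      resid_fn_named(v)
    }
    tryCatch(minpack.lm::nls.lm(par = theta0, fn = fn, control = lm_ctl),
             error = function(e) NULL)
  }
  resid_fn_named <- function(v) {
    pars <- cur
    pars[names(v)] <- as.list(unname(v))
    pred <- pk_conc(pars, dose_mg, weight_kg, obs$time_h, dose_time)
    log(obs$conc_mg_l) - log(pmax(pred, 1e-12))
  }
  start0 <- unlist(cur[c("v1", "v2", "cl", "cl2", "tabs")])
  best <- NULL
  tabs_grid <- if ("tabs" %in% estimate) {
    sort(unique(c(seq(0.4, 2.6, by = 0.1), init$tabs)))
  } else init$tabs
  for (tb in tabs_grid) {
    st <- start0
    st["tabs"] <- tb
    cand <- if (length(smooth_pars) > 0) run_lm(st, smooth_pars) else NULL
    if (!is.null(cand) &&
        (is.null(best) || cand$deviance < best$fit$deviance)) {
      st[smooth_pars] <- exp(cand$par)
      best <- list(fit = cand, start = st)
    }
  }
  if (is.null(best)) stop("PK fit failed from every start", call. = FALSE)
  fit <- run_lm(best$start, estimate)
  if (is.null(fit) || fit$deviance > best$fit$deviance) fit <- best$fit
  est <- cur
  est[names(fit$par)] <- as.list(exp(fit$par))
  converged <- fit$info %in% 1:4
  structure(
    list(params = do.call(pk_parameters,
                          est[c("v1", "v2", "cl", "cl2", "tabs",
                                "sigma2_prop", "omega2_cl")]),
         objective = fit$deviance,
         converged = converged,
         message = fit$message,
         n_obs = nrow(obs)),
    class = "pk_fit")
}

# noncompartmental clearance: dose / (trapezoid AUC + log-linear tail),
# normalised to 70 kg; used to start the population fit
nca_cl <- function(times, conc, dose_mg, weight_kg) {
  keep <- conc > 0 | times == 0
  t <- times[keep]; c <- conc[keep]
  auc <- sum(diff(t) * (head(c, -1) + tail(c, -1)) / 2)
  n <- length(c)
  lz <- NA_real_
  if (n >= 3 && all(c[(n - 2):n] > 0)) {
    fitz <- stats::lm.fit(cbind(1, t[(n - 2):n]), log(c[(n - 2):n]))
    lz <- -unname(fitz$coefficients[2])
  }
  tail_auc <- if (is.finite(lz) && lz > 0.05) c[n] / lz else 0
  cl <- dose_mg / (auc + tail_auc)
  cl * 70 / weight_kg
}

#' Two-stage population PK fit
#'
#' Stage 1 estimates one elimination clearance per subject with the
#' structural parameters (V1, V2, CL2, Tabs) shared across subjects, as
#' a joint Levenberg-Marquardt least-squares fit on the
#' log-concentration scale. Per-subject noncompartmental clearances
#' (trapezoid AUC with a log-linear tail) provide the starting values,
#' and a small multi-start over the central volume protects against
#' the one-compartment collapse mode of two-compartment fits. Stage 2 summarizes:
#' the population value of each parameter is the stage-1 estimate (CL:
#' median of the per-subject 70-kg-scaled values), the between-subject
#' variance is the variance of log individual CL, and standard errors
#' come from a nonparametric bootstrap over subjects.
#'
#' @param pk_data Data frame with columns `subject_id`, `dose_mg`,
#'   `weight_kg`, `time_h`, `conc_mg_l`.
#' @param init Starting [pk_parameters()]; defaults are generic.
#' @param n_boot Bootstrap replicates for the stage-2 standard errors.
#' @param seed Seed for the bootstrap resampling.
#' @return A list of class `pk_pop_fit`: `params` (population
#'   [pk_parameters()] including `omega2_cl`), `subjects` (tibble of
#'   per-subject CL estimates), `se` (bootstrap SEs of CL and omega2),
#'   `n_failed`, `converged`.
#' @export
fit_pk_population <- function(pk_data,
                              init = pk_parameters(v1 = 100, v2 = 400,
                                                   cl = 150, cl2 = 500,
                                                   tabs = 1, sigma2_prop = 0.015,
                                                   omega2_cl = 0),
                              n_boot = 500, seed = 1L) {
  pk_data <- tibble::as_tibble(pk_data)
  need <- c("subject_id", "dose_mg", "weight_kg", "time_h", "conc_mg_l")
  if (!all(need %in% names(pk_data))) {
    stop("`pk_data` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  subjects <- split(pk_data, pk_data$subject_id)
  if (length(subjects) < 6) {
    stop("need at least 6 subjects with PK samples", call. = FALSE)
  }

  ids <- names(subjects)
  n_sub <- length(ids)
  obs_list <- lapply(subjects, function(dat) {
    dat[dat$time_h > 0 & dat$conc_mg_l > 0, , drop = FALSE]
  })

  # noncompartmental clearance estimates anchor the starting point so
  # the joint fit starts on the right AUC scale
  cl_nca <- vapply(subjects, function(dat) {
    tryCatch(nca_cl(dat$time_h, dat$conc_mg_l, dat$dose_mg[1],
                    dat$weight_kg[1]), error = function(e) init$cl)
  }, 0)
  cl_nca[!is.finite(cl_nca) | cl_nca <= 0] <- init$cl
  tmax_med <- median(vapply(obs_list, function(o) {
    o$time_h[which.max(o$conc_mg_l)]
  }, 0))

  # stage 1: joint least squares on the log-concentration scale with
  # structural parameters shared and one clearance per subject; a small
  # multi-start over the weakly identified central volume guards
  # against the one-compartment collapse mode
  resid_joint <- function(theta) {
    pars <- init
    pars[c("v1", "v2", "cl2", "tabs")] <- as.list(exp(theta[1:4]))
    cls <- exp(theta[4 + seq_len(n_sub)])
    unlist(lapply(seq_len(n_sub), function(i) {
      obs <- obs_list[[i]]
      pars$cl <- cls[i]
      pred <- pmax(pk_conc(pars, obs$dose_mg[1], obs$weight_kg[1],
                           obs$time_h), 1e-12)
      log(obs$conc_mg_l) - log(pred)
    }))
  }
  # the absorption duration acts as a breakpoint, so profile it on a
  # grid with the smooth parameters refitted each time, then free it
  # in a final joint polish
  resid_fixed_tabs <- function(theta, tabs) {
    resid_joint(c(theta[1], theta[2], theta[3], log(tabs),
                  theta[3 + seq_len(n_sub)]))
  }
  lm_ctl <- minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                       ptol = 1e-12)
  best <- NULL
  for (tb in sort(unique(c(seq(0.6, 2.2, by = 0.2),
                           min(max(tmax_med, 0.5), 2))))) {
    theta0 <- c(log(c(init$v1, init$v2, init$cl2)), log(cl_nca))
    cand <- tryCatch(minpack.lm::nls.lm(
      par = theta0, fn = resid_fixed_tabs, tabs = tb, control = lm_ctl),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(best) || cand$deviance < best$fit$deviance)) {
      best <- list(fit = cand, tabs = tb)
    }
  }
  if (is.null(best)) stop("population PK fit failed from every start",
                          call. = FALSE)
  theta0 <- c(best$fit$par[1:3], log(best$tabs),
              best$fit$par[3 + seq_len(n_sub)])
  fit <- tryCatch(minpack.lm::nls.lm(
    par = theta0, fn = resid_joint, control = lm_ctl),
    error = function(e) NULL)
  if (is.null(fit) || fit$deviance > best$fit$deviance) {
    fit <- best$fit
    fit$par <- theta0
  }
  struct <- init
  struct[c("v1", "v2", "cl2", "tabs")] <- as.list(exp(fit$par[1:4]))
  cl_i <- setNames(exp(fit$par[4 + seq_len(n_sub)]), ids)

  # a subject whose clearance ran away from the NCA anchor by more than
  # an order of magnitude is treated as a failed fit
  bad <- abs(log(cl_i / cl_nca)) > log(10)
  if (any(bad)) {
    warning(sum(bad), " subject(s) excluded after PK fit failure")
    cl_i[bad] <- NA_real_
  }
  if (mean(bad) > 0.25) {
    stop("more than 25% of subject-level PK fits failed", call. = FALSE)
  }
  cl_ok <- cl_i[!is.na(cl_i)]
  pop_cl <- median(cl_ok)
  omega2 <- var(log(cl_ok))

  boot <- replicate_boot(log(cl_ok), n_boot, seed)
  pop <- pk_parameters(v1 = struct$v1, v2 = struct$v2, cl = pop_cl,
                       cl2 = struct$cl2, tabs = struct$tabs,
                       sigma2_prop = init$sigma2_prop, omega2_cl = omega2)
  structure(
    list(params = pop,
         subjects = tibble::tibble(subject_id = names(cl_i),
                                   cl = unname(cl_i),
                                   failed = unname(is.na(cl_i))),
         se = c(cl = boot$se_median_exp, omega2_cl = boot$se_var),
         n_failed = sum(is.na(cl_i)),
         converged = TRUE),
    class = "pk_pop_fit")
}

# bootstrap of median(exp(x)) and var(x) over subjects
replicate_boot <- function(logvals, n_boot, seed) {
  n <- length(logvals)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  meds <- numeric(n_boot)
  vars <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    meds[b] <- median(exp(logvals[idx]))
    vars[b] <- var(logvals[idx])
  }
  list(se_median_exp = sd(meds), se_var = sd(vars))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' @exportS3Method generics::tidy
tidy.pk_pop_fit <- function(x, ...) {
  tibble::tibble(
    term = c("v1", "v2", "cl", "cl2", "tabs", "omega2_cl"),
    estimate = c(x$params$v1, x$params$v2, x$params$cl, x$params$cl2,
                 x$params$tabs, x$params$omega2_cl),
    std.error = c(NA, NA, unname(x$se["cl"]), NA, NA,
                  unname(x$se["omega2_cl"]))
  )
}

#' @exportS3Method generics::glance
glance.pk_pop_fit <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$subjects), n_failed = x$n_failed,
                 converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.pk_fit <- function(x, ...) {
  tibble::tibble(
    term = c("v1", "v2", "cl", "cl2", "tabs"),
    estimate = c(x$params$v1, x$params$v2, x$params$cl, x$params$cl2,
                 x$params$tabs))
}

#' @exportS3Method generics::glance
glance.pk_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_obs = x$n_obs)
}
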