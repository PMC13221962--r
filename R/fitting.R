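#' Normalized mean squared error
#'
#' `nmse(X, Y) = sum((X - Y)^2) / sum(X^2)` between observed values `X` and
#' model predictions `Y`.  It is zero iff `X == Y` and invariant under a
#' common rescaling of both arguments, which makes fit quality comparable
#' across organoids of very different sizes.
#'
#' @param X Observed values (cell counts), not all zero.
#' @param Y Predicted values, same length as `X`.
#'
#' @return A dimensionless nonnegative scalar.
#' @examples
#' nmse(c(10, 20), c(11, 20))  # 1/500
#' @export
nmse <- function(X, Y) {
  stopifnot(is.numeric(X), is.numeric(Y))
  if (length(X) != length(Y) || length(X) < 1L)
    stop("`X` and `Y` must be equal-length, non-empty", call. = FALSE)
  ss <- sum(X^2)
  if (ss == 0) stop("NMSE undefined for all-zero `X`", call. = FALSE)
  sum((X - Y)^2) / ss
}

#' Gaussian-likelihood information criteria
#'
#' For a least-squares fit with `n_points` observations, `n_free` fitted
#' parameters and residual sum of squares `SSE`, computes
#' `AIC = m * log(SSE/m) + 2k` and `BIC = m * log(SSE/m) + k * log(m)`.
#' A perfect fit (`SSE = 0`) yields `-Inf` sentinels with `degenerate =
#' TRUE`.
#'
#' @param x Either a `pdto_fit` object or a numeric SSE.
#' @param n_points,n_free Number of data points and free parameters
#'   (ignored when `x` is a fit object).
#'
#' @return A list with components `aic`, `bic` and `degenerate`.
#' @examples
#' information_criteria(2.0, n_points = 5, n_free = 3)
#' @export
information_criteria <- function(x, n_points = NULL, n_free = NULL) {
  if (inherits(x, "pdto_fit")) {
    sse <- x$sse; n_points <- x$n_points; n_free <- x$n_free
  } else {
    sse <- x
    stopifnot(is.numeric(n_points), is.numeric(n_free))
  }
  stopifnot(is.numeric(sse), length(sse) == 1L, sse >= 0, n_points >= 1)
  if (sse == 0)
    return(list(aic = -Inf, bic = -Inf, degenerate = TRUE))
  base <- n_points * log(sse / n_points)
  list(aic = base + 2 * n_free,
       bic = base + n_free * log(n_points),
       degenerate = FALSE)
}

# ---- multi-start bounded least squares -----------------------------------

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Latin-hypercube start points over the box [lower, upper]; columns listed
# in `sort_idx` are sorted within each row (used to keep T1 < T2 starts).
.lhs_starts <- function(n_starts, lower, upper, seed, sort_idx = NULL) {
  k <- length(lower)
  u <- .with_seed(seed, lhs::randomLHS(n_starts, k))
  starts <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  if (!is.null(sort_idx))
    starts[, sort_idx] <- t(apply(starts[, sort_idx, drop = FALSE], 1, sort))
  starts
}

# Run bounded Levenberg-Marquardt least squares from each start; keep the
# best SSE, breaking near-ties (< 1e-10 relative) by the smaller parameter
# norm.
.multistart_fit <- function(resid_fn, lower, upper, n_starts, seed,
                            sort_idx = NULL, par_names, bound_check = TRUE,
                            extra_starts = NULL) {
  starts <- .lhs_starts(n_starts, lower, upper, seed, sort_idx)
  if (!is.null(extra_starts)) {
    starts <- rbind(extra_starts, starts)
    n_starts <- nrow(starts)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                     ptol = 1e-12, gtol = 0)
  best <- NULL
  start_sse <- rep(NA_real_, n_starts)
  for (i in seq_len(n_starts)) {
    st <- starts[i, ]
    start_sse[i] <- sum(resid_fn(st)^2)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    cand <- list(par = stats::setNames(fit$par, par_names),
                 sse = fit$deviance, info = fit$info)
    if (is.null(best) || cand$sse < best$sse * (1 - 1e-10)) {
      best <- cand
    } else if (abs(cand$sse - best$sse) <= 1e-10 * max(best$sse, 1e-300) &&
               sqrt(sum(cand$par^2)) < sqrt(sum(best$par^2))) {
      best <- cand
    }
  }
  if (is.null(best))
    stop("all optimizer starts failed", call. = FALSE)
  best$converged <- best$info %in% 1:3
  # A parameter that converges onto the upper search bound has no interior
  # optimum: the data do not identify it (typical for K when a trajectory is
  # far from saturation).  Lower bounds at (or near) zero are natural
  # boundaries where the truth may legitimately live and are not flagged.
  best$at_bound <- if (bound_check) {
    names(best$par)[best$par >= upper - 1e-6 * (upper - lower)]
  } else character()
  best$n_starts <- n_starts
  best$start_sse <- start_sse
  best
}

.new_fit <- function(model, scheme, free, fixed, derived = NULL,
                     obs, pred, days, D0, opt) {
  sse <- sum((obs - pred)^2)
  # AIC/BIC are only meaningful with at least one residual degree of freedom
  if (length(obs) >= length(free) + 1L) {
    ic <- information_criteria(sse, length(obs), length(free))
  } else {
    ic <- list(aic = NA_real_, bic = NA_real_, degenerate = FALSE)
  }
  structure(list(model = model, scheme = scheme,
                 free_params = free, fixed_params = fixed,
                 derived_params = derived,
                 days = days, observed_cells = obs, fitted_cells = pred,
                 residuals = obs - pred,
                 sse = sse, nmse = sse / sum(obs^2),
                 n_points = length(obs), n_free = length(free),
                 aic = ic$aic, bic = ic$bic, ic_degenerate = ic$degenerate,
                 converged = opt$converged, optim_info = opt$info,
                 at_bound = opt$at_bound,
                 n_starts = opt$n_starts, start_sse = opt$start_sse,
                 D0 = D0),
            class = "pdto_fit")
}

#' @export
print.pdto_fit <- function(x, ...) {
  cat(sprintf("pdto_fit [%s scheme, model: %s] on %d points%s\n",
              x$scheme, x$model, x$n_points,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  cat("  free:  ", paste(sprintf("%s = %.4g", names(x$free_params),
                                 x$free_params), collapse = ", "), "\n")
  if (length(x$fixed_params))
    cat("  fixed: ", paste(sprintf("%s = %.4g", names(x$fixed_params),
                                   x$fixed_params), collapse = ", "), "\n")
  cat(sprintf("  SSE = %.4g cells^2, NMSE = %.3g, AIC = %.4g, BIC = %.4g\n",
              x$sse, x$nmse, x$aic, x$bic))
  invisible(x)
}

#' @export
coef.pdto_fit <- function(object, ...) {
  c(object$free_params, object$derived_params)
}

# Penalized prediction for the optimizer: integration failures turn into a
# large finite residual rather than an abort.
.safe_resid <- function(obs, predict) {
  m <- length(obs)
  function(par) {
    pred <- tryCatch(predict(par), error = function(e) NULL)
    if (is.null(pred) || anyNA(pred) || any(!is.finite(pred)))
      return(rep(1e9, m))
    obs - pred
  }
}

.traj_cells <- function(traj, D0, min_points) {
  stopifnot(inherits(traj, "organoid_trajectory"))
  if (length(traj$days) < min_points)
    stop(sprintf("trajectory needs >= %d time points", min_points),
         call. = FALSE)
  if (traj$days[1] != 0)
    stop("trajectory must include a day-0 measurement (fixes N0)",
         call. = FALSE)
  diameter_to_cells(traj$diameters, D0)
}

#' Fit the untreated logistic model to a control-arm organoid
#'
#' Calibrates `(lam, K)` of the logistic model by bounded multi-start least
#' squares on cell counts.  The initial population `N0` is fixed to the
#' day-0 measurement (not fitted).  Internally the carrying capacity is
#' parameterized through the carrying diameter `D_K = D0 * K^(1/3)`, which
#' conditions the search well; `K` is reported as a derived parameter.
#'
#' @param traj An [organoid_trajectory()] with >= 3 time points incl. day 0.
#' @param D0 Reference cell diameter (um).
#' @param n_starts Number of Latin-hypercube multi-starts.
#' @param seed RNG seed for the start design (the caller's RNG stream is
#'   left untouched).
#' @param lam_bounds,dk_bounds Box bounds for the growth rate (day^-1) and
#'   the carrying diameter (um).
#'
#' @return A `pdto_fit` with free parameters `lam`, `DK` and derived `K`.
#' @export
fit_control <- function(traj, D0 = 22.5, n_starts = 10, seed = 20260303,
                        lam_bounds = c(0, 3), dk_bounds = c(30, 1200)) {
  obs <- .traj_cells(traj, D0, 3L)
  N0 <- obs[1]
  days <- traj$days
  predict <- function(par) {
    K <- (par[2] / D0)^3
    .solve_ode(c(N = N0), days, "pdto_d_logistic", "pdto_init_logistic",
               c(par[1], K))[, 1]
  }
  # the logistic approaches K from below, so the carrying diameter cannot
  # lie below the largest observed diameter; bounding it there also removes
  # the degenerate K = N0 ridge on which flat data fit with any lam
  dk_lo <- max(dk_bounds[1], 1.001 * max(traj$diameters))
  opt <- .multistart_fit(.safe_resid(obs, predict),
                         lower = c(lam_bounds[1], dk_lo),
                         upper = c(lam_bounds[2], dk_bounds[2]),
                         n_starts, seed, par_names = c("lam", "DK"))
  K <- (opt$par[["DK"]] / D0)^3
  .new_fit("logistic", "control", opt$par, fixed = c(N0 = N0),
           derived = c(K = K), obs, predict(opt$par), days, D0, opt)
}

#' Fit the chemotherapy kill pulse to a chemo-arm organoid
#'
#' Calibrates `(a, b, Tc)` of the chemo model with the growth parameters
#' `(lam, K)` held fixed at the line-level control averages, following the
#' group-wise protocol.  Bounds: `a` in \[0, 5\] /day, `b` in (0, 2\] /day^2,
#' `Tc` in \[0, 14\] days.
#'
#' @inheritParams fit_control
#' @param traj An [organoid_trajectory()] with >= 4 time points incl. day 0.
#' @param growth A [growth_params()] object with the fixed `(lam, K)`.
#'
#' @return A `pdto_fit` with free parameters `a`, `b`, `Tc`.
#' @export
fit_chemo <- function(traj, growth, D0 = 22.5, n_starts = 10,
                      seed = 20260303) {
  stopifnot(inherits(growth, "growth_params"))
  obs <- .traj_cells(traj, D0, 4L)
  N0 <- obs[1]
  days <- traj$days
  predict <- function(par) {
    .solve_ode(c(N = N0), days, "pdto_d_chemo", "pdto_init_chemo",
               c(growth$lam, growth$K, par))[, 1]
  }
  opt <- .multistart_fit(.safe_resid(obs, predict),
                         lower = c(0, 1e-6, 0), upper = c(5, 2, 14),
                         n_starts, seed, par_names = c("a", "b", "Tc"))
  .new_fit("chemo", "chemo", opt$par,
           fixed = c(lam = growth$lam, K = growth$K, N0 = N0),
           obs = obs, pred = predict(opt$par), days = days, D0 = D0,
           opt = opt)
}

# Relabel the two radiation waves so T1 < T2 after an unconstrained fit.
.order_waves <- function(par) {
  if (par[["T1"]] > par[["T2"]]) {
    par[c("u1", "u2", "T1", "T2")] <- par[c("u2", "u1", "T2", "T1")]
  }
  par
}

.fit_wave_scheme <- function(model, scheme, derivs, initfunc, fixed_tail,
                             fixed_record, traj, fp, K, D0, n_starts, seed,
                             min_points = 6L) {
  obs <- .traj_cells(traj, D0, min_points)
  days <- traj$days
  s0 <- lq_split(fp, obs[1])
  y0 <- c(A = s0$A, I = s0$I)
  predict <- function(par) {
    out <- .solve_ode(y0, days, derivs, initfunc,
                      c(par[1], K, fixed_tail, par[2], par[3], par[4], par[5],
                        fp$mu))
    out[, 1] + out[, 2]
  }
  # deterministic anchors besides the random starts: the model defines an
  # early (first-week) and a secondary (second-week) wave, so one start
  # sits at the canonical timing and one at the box center
  anchors <- rbind(c(0.5, 0.5, 1.5, 4, 8),
                   c(1.5, 5, 5, 4.7, 9.3))
  opt <- .multistart_fit(.safe_resid(obs, predict),
                         lower = c(0, 0, 0, 0, 0),
                         upper = c(3, 10, 10, 14, 14),
                         n_starts, seed, sort_idx = 4:5,
                         par_names = c("lam", "u1", "u2", "T1", "T2"),
                         extra_starts = anchors)
  opt$par <- .order_waves(opt$par)
  if (max(days) < opt$par[["T2"]])
    warning(sprintf(
      "secondary wave peak T2 = %.2f lies beyond the last measurement day %g; T2 is weakly identified",
      opt$par[["T2"]], max(days)), call. = FALSE)
  .new_fit(model, scheme, opt$par, fixed = fixed_record,
           obs = obs, pred = predict(opt$par), days = days, D0 = D0,
           opt = opt)
}

#' Fit the radiotherapy model to an irradiated organoid
#'
#' Calibrates `(lam, u1, u2, T1, T2)` of the two-compartment radiotherapy
#' model with the carrying capacity `K`, removal rate `mu` and the
#' linear-quadratic constants held fixed.  The initial state is the LQ
#' split of the day-0 measurement at the arm's dose.  Wave labels are
#' reordered after fitting so that `T1 < T2`; a warning is raised when the
#' fitted `T2` lies beyond the last measurement day.  Bounds: `lam` in
#' \[0, 3\] /day, `u1`, `u2` in \[0, 10\] /day, `T1`, `T2` in \[0, 14\] days.
#'
#' @inheritParams fit_control
#' @param traj An [organoid_trajectory()] with >= 6 time points incl. day 0
#'   (measurement through day 9 is recommended for `T2` identifiability).
#' @param fp A [radio_fixed_params()] object carrying `mu`, `alpha`, `beta`
#'   and the dose.
#' @param K Fixed carrying capacity (cells), from the line's control fits.
#'
#' @return A `pdto_fit` with free parameters `lam`, `u1`, `u2`, `T1`, `T2`.
#' @export
fit_radio <- function(traj, fp, K, D0 = 22.5, n_starts = 25,
                      seed = 20260303) {
  stopifnot(inherits(fp, "radio_fixed_params"), is.numeric(K), K > 1)
  .fit_wave_scheme("radio", "rt", "pdto_d_radio", "pdto_init_radio",
                   fixed_tail = NULL,
                   fixed_record = c(K = K, mu = fp$mu, alpha = fp$alpha,
                                    beta = fp$beta, dose = fp$dose),
                   traj, fp, K, D0, n_starts, seed)
}

#' Fit the chemoradiation chemo component with the radiation component fixed
#'
#' First decomposition study of the combined model: the radiation kill
#' parameters are fixed at the matching radiotherapy-arm estimates (same
#' line, same dose) and `(a, b, Tc)` of the chemo pulse are fitted to the
#' chemoradiotherapy data, with `(lam, K)` fixed from the control fits.
#'
#' @inheritParams fit_chemo
#' @param radio A [radio_kill_params()] object with the fixed radiation
#'   pulse.
#' @param fp A [radio_fixed_params()] object (dose of the CRT arm).
#'
#' @return A `pdto_fit` with free parameters `a`, `b`, `Tc`.
#' @export
fit_crt_fixed_radio <- function(traj, growth, radio, fp, D0 = 22.5,
                                n_starts = 10, seed = 20260303) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(radio, "radio_kill_params"),
            inherits(fp, "radio_fixed_params"))
  obs <- .traj_cells(traj, D0, 4L)
  days <- traj$days
  s0 <- lq_split(fp, obs[1])
  y0 <- c(A = s0$A, I = s0$I)
  predict <- function(par) {
    out <- .solve_ode(y0, days, "pdto_d_crt", "pdto_init_crt",
                      c(growth$lam, growth$K, par,
                        radio$u1, radio$u2, radio$T1, radio$T2, fp$mu))
    out[, 1] + out[, 2]
  }
  opt <- .multistart_fit(.safe_resid(obs, predict),
                         lower = c(0, 1e-6, 0), upper = c(5, 2, 14),
                         n_starts, seed, par_names = c("a", "b", "Tc"))
  .new_fit("crt", "crt_fixed_R", opt$par,
           fixed = c(lam = growth$lam, K = growth$K,
                     u1 = radio$u1, u2 = radio$u2,
                     T1 = radio$T1, T2 = radio$T2,
                     mu = fp$mu, dose = fp$dose),
           obs = obs, pred = predict(opt$par), days = days, D0 = D0,
           opt = opt)
}

#' Fit the chemoradiation radiation component with the chemo component fixed
#'
#' Second decomposition study: the chemo pulse is fixed at the
#' chemotherapy-arm estimates of the same line and `(lam, u1, u2, T1, T2)`
#' of the radiation component are fitted to the chemoradiotherapy data.
#' The result is reported primarily through its NMSE, for contrast with
#' [fit_crt_fixed_radio()] — a higher NMSE under this scheme indicates that
#' the chemo component, not the radiation component, changes between
#' monotherapy and combination therapy.
#'
#' @inheritParams fit_radio
#' @param chemo A [chemo_kill_params()] object with the fixed chemo pulse.
#'
#' @return A `pdto_fit` with free parameters `lam`, `u1`, `u2`, `T1`, `T2`.
#' @export
fit_crt_fixed_chemo <- function(traj, chemo, fp, K, D0 = 22.5,
                                n_starts = 25, seed = 20260303) {
  stopifnot(inherits(chemo, "chemo_kill_params"),
            inherits(fp, "radio_fixed_params"), is.numeric(K), K > 1)
  .fit_wave_scheme("crt", "crt_fixed_C", "pdto_d_crt", "pdto_init_crt",
                   fixed_tail = c(chemo$a, chemo$b, chemo$Tc),
                   fixed_record = c(a = chemo$a, b = chemo$b, Tc = chemo$Tc,
                                    K = K, mu = fp$mu, dose = fp$dose),
                   traj, fp, K, D0, n_starts, seed, min_points = 5L)
}

# ---- population summaries ------------------------------------------------

#' Summarize fitted parameters across the organoids of one group
#'
#' Computes, for each fitted (and derived) parameter, the across-organoid
#' mean, 95% confidence-interval half-width
#' `t(0.975, n-1) * sd / sqrt(n)`, and median, over the converged fits.
#'
#' A parameter that an individual fit drove onto its upper search bound is
#' not identified by that trajectory (typical for the carrying capacity
#' when a noisy trajectory is far from saturation); by default such values
#' are excluded from that parameter's summary, while the fit's other,
#' identified parameters are retained.
#'
#' @param fits A list of `pdto_fit` objects (>= 2 converged).
#' @param params Optional character vector of parameter names to summarize
#'   (default: all parameters shared by every fit).
#' @param drop_at_bound Exclude per-parameter values flagged at the upper
#'   search bound (default `TRUE`).
#'
#' @return A data frame with columns `parameter`, `n`, `mean`, `sd`,
#'   `ci95_half_width`, `median`.  `n` can differ between parameters when
#'   bound-flagged values are dropped.
#' @export
population_summary <- function(fits, params = NULL, drop_at_bound = TRUE) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "pdto_fit")))
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) < 2L)
    stop("population summary needs >= 2 converged fits", call. = FALSE)
  cfs <- lapply(fits, coef)
  common <- Reduce(intersect, lapply(cfs, names))
  if (is.null(params)) params <- common
  if (!all(params %in% common))
    stop("parameter(s) not present in every fit: ",
         paste(setdiff(params, common), collapse = ", "), call. = FALSE)
  rows <- lapply(params, function(p) {
    ok <- if (drop_at_bound) {
      # DK is the fitted surrogate of K: a bound flag on DK disqualifies K
      vapply(fits, function(f)
        !any(f$at_bound == p | (p == "K" & f$at_bound == "DK")), TRUE)
    } else rep(TRUE, length(fits))
    x <- vapply(cfs[ok], `[[`, 0, p)
    n <- length(x)
    if (n < 2L)
      stop(sprintf("parameter %s has < 2 identified estimates", p),
           call. = FALSE)
    data.frame(parameter = p, n = n, mean = mean(x), sd = stats::sd(x),
               ci95_half_width = stats::qt(0.975, n - 1) * stats::sd(x) /
                 sqrt(n),
               median = stats::median(x))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Upper bound on the size achievable within a sample
#'
#' Estimates the largest value achievable by any organoid of a sample as
#' the upper limit of a wide (default 99.9%) confidence interval of the
#' mean: `mean + t(1 - (1 - level)/2, n - 1) * se`.  Either raw values or
#' summary statistics (mean, 95% CI half-width, n) may be supplied.
#'
#' @param values Raw per-organoid values (e.g. fitted carrying diameters).
#' @param mean,ci95_half_width,n Alternatively, the sample mean, its 95%
#'   CI half-width and the sample size.
#' @param level Confidence level of the bound (default 0.999).
#'
#' @return The upper confidence bound (same units as the input).
#' @examples
#' # from summary statistics: mean 302.8 um, 95% CI +/- 155.2 um, n = 33
#' achievable_size_bound(mean = 302.8, ci95_half_width = 155.2, n = 33)
#' @export
achievable_size_bound <- function(values = NULL, mean = NULL,
                                  ci95_half_width = NULL, n = NULL,
                                  level = 0.999) {
  if (!is.null(values)) {
    n <- length(values)
    if (n < 2L) stop("need >= 2 values", call. = FALSE)
    mean <- base::mean(values)
    se <- stats::sd(values) / sqrt(n)
  } else {
    stopifnot(is.numeric(mean), is.numeric(ci95_half_width), is.numeric(n),
              n >= 2)
    se <- ci95_half_width / stats::qt(0.975, n - 1)
  }
  mean + stats::qt(1 - (1 - level) / 2, n - 1) * se
}

#' Compare fitted parameters across patient lines
#'
#' For each parameter, tests for differences across lines in the mean
#' (one-way ANOVA) and in the median/distribution (Kruskal-Wallis), across
#' the converged per-organoid fits of each line.
#'
#' @param fits_by_line A named list (one element per line) of lists of
#'   `pdto_fit` objects; >= 2 lines with >= 3 converged fits each.
#' @param params Optional parameter names (default: shared by all fits).
#'
#' @return A data frame with columns `parameter`, `p_mean` (ANOVA) and
#'   `p_median` (Kruskal-Wallis).
#' @export
compare_lines <- function(fits_by_line, params = NULL) {
  stopifnot(is.list(fits_by_line), length(fits_by_line) >= 2L,
            !is.null(names(fits_by_line)))
  fits_by_line <- lapply(fits_by_line, function(fits)
    Filter(function(f) isTRUE(f$converged), fits))
  sizes <- lengths(fits_by_line)
  if (any(sizes < 3L))
    stop("each line needs >= 3 converged fits", call. = FALSE)
  cfs <- lapply(fits_by_line, function(fits) lapply(fits, coef))
  common <- Reduce(intersect, lapply(unlist(cfs, recursive = FALSE), names))
  if (is.null(params)) params <- common
  if (!all(params %in% common))
    stop("parameter(s) not present in every fit: ",
         paste(setdiff(params, common), collapse = ", "), call. = FALSE)
  line <- factor(rep(names(fits_by_line), times = sizes))
  out <- lapply(params, function(p) {
    value <- unlist(lapply(cfs, function(l) vapply(l, `[[`, 0, p)))
    p_mean <- stats::anova(stats::aov(value ~ line))[["Pr(>F)"]][1]
    p_median <- stats::kruskal.test(value, line)$p.value
    data.frame(parameter = p, p_mean = p_mean, p_median = p_median)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
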