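#' Chemotherapy killing rate C(t)
#'
#' Evaluates the Gaussian chemo kill pulse
#' `C(t) = a * exp(-b * (t - Tc)^2)`.
#'
#' @param p A [chemo_kill_params()] object.
#' @param t Time(s) in days (any finite numeric vector).
#'
#' @return Killing rate(s) in day^-1; nonnegative, maximal at `t = Tc`.
#' @examples
#' p <- chemo_kill_params(0.515, 0.077, 3.5)
#' chemo_kill_rate(p, c(0, 3.5, 7))
#' @export
chemo_kill_rate <- function(p, t) {
  stopifnot(inherits(p, "chemo_kill_params"), is.numeric(t), all(is.finite(t)))
  p$a * exp(-p$b * (t - p$Tc)^2)
}

#' Radiotherapy killing rate R(t)
#'
#' Evaluates the two-wave radiation kill pulse
#' `R(t) = u1 * exp(-(t - T1)^2) + u2 * exp(-(t - T2)^2)`, with both
#' Gaussian widths fixed at 1 day^2 (the construction is dimensionless in
#' time; the widths are never fitted).
#'
#' @param p A [radio_kill_params()] object.
#' @param t Time(s) in days.
#'
#' @return Killing rate(s) in day^-1.
#' @examples
#' p <- radio_kill_params(0.486, 1.518, 4.2, 8.1)
#' radio_kill_rate(p, 0:9)
#' @export
radio_kill_rate <- function(p, t) {
  stopifnot(inherits(p, "radio_kill_params"), is.numeric(t), all(is.finite(t)))
  p$u1 * exp(-(t - p$T1)^2) + p$u2 * exp(-(t - p$T2)^2)
}

#' Linear-quadratic split of an irradiated population
#'
#' Splits an initial population of `N0` cells into active (surviving) and
#' inactive (lethally damaged) compartments immediately after a dose `d`,
#' using the linear-quadratic survival fraction:
#' `A0 = N0 * exp(-alpha*d - beta*d^2)`, `I0 = N0 - A0`.
#' The split conserves cell number exactly.
#'
#' @param fp A [radio_fixed_params()] object (supplies `alpha`, `beta`, `dose`).
#' @param N0 Initial cell count, >= 0.
#'
#' @return A list with components `A` and `I` (class `cell_state`).
#' @examples
#' lq_split(radio_fixed_params(dose = 4), 1000)
#' @export
lq_split <- function(fp, N0) {
  stopifnot(inherits(fp, "radio_fixed_params"),
            is.numeric(N0), length(N0) == 1L, is.finite(N0))
  if (N0 < 0) stop("`N0` must be >= 0", call. = FALSE)
  A <- N0 * exp(-fp$alpha * fp$dose - fp$beta * fp$dose^2)
  structure(list(A = A, I = N0 - A), class = "cell_state")
}

# ---- internal ODE driver -------------------------------------------------

# Validates the requested time grid for the solver front ends.
.check_times <- function(N0, times) {
  if (!is.numeric(N0) || length(N0) != 1L || !is.finite(N0) || N0 <= 0)
    stop("initial population `N0` must be a single positive number",
         call. = FALSE)
  if (!is.numeric(times) || length(times) < 1L || anyNA(times) ||
      any(!is.finite(times)))
    stop("`times` must be finite numeric days", call. = FALSE)
  if (times[1] < 0) stop("`times` must start at day >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  invisible(times)
}

# Solve one of the compiled models from t = 0, returning the state matrix at
# `times`.  Tiny negative excursions (integration round-off) are clipped at
# zero; anything below -1e-8 cells is treated as an integration failure.
.solve_ode <- function(y0, times, derivs, initfunc, parms,
                       rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  tt <- times
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  if (length(tt) == 1L) {
    out <- matrix(y0, nrow = 1L)
  } else {
    sol <- deSolve::ode(y = y0, times = tt, func = derivs, parms = parms,
                        dllname = "pdtogrowth", initfunc = initfunc,
                        method = method, rtol = rtol, atol = atol)
    out <- unname(as.matrix(sol)[, -1, drop = FALSE])
    if (prepend) out <- out[-1, , drop = FALSE]
  }
  if (any(out < -1e-8))
    stop("integration produced negative cell counts beyond round-off; ",
         "check parameter values", call. = FALSE)
  out[out < 0] <- 0
  out
}

#' Solve the untreated logistic growth model
#'
#' Integrates `dN/dt = lam * N * (1 - N/K)` from `N(0) = N0` and returns the
#' population at the requested days.  The numeric solution agrees with the
#' closed-form logistic to better than 1e-6 relative at the default
#' tolerances.
#'
#' @param g A [growth_params()] object.
#' @param N0 Initial cell count (> 0).
#' @param times Strictly increasing days, starting at >= 0.
#' @param rtol,atol Relative/absolute integration tolerances (cell counts).
#' @param method deSolve integration method (default `"lsoda"`; `"ode45"`
#'   gives an explicit Runge-Kutta pair with dense output).
#'
#' @return Numeric vector of cell counts `N(times)`.
#' @examples
#' g <- growth_params(0.464, diameter_to_cells(302.8))
#' solve_logistic(g, 88, c(0, 2, 4, 6, 7))
#' @export
solve_logistic <- function(g, N0, times, rtol = 1e-8, atol = 1e-10,
                           method = "lsoda") {
  stopifnot(inherits(g, "growth_params"))
  .check_times(N0, times)
  .solve_ode(c(N = N0), times, "pdto_d_logistic", "pdto_init_logistic",
             c(g$lam, g$K), rtol, atol, method)[, 1]
}

#' Solve the chemotherapy growth model
#'
#' Integrates `dN/dt = (lam - C(t)) * N * (1 - N/K)`, i.e. logistic growth
#' with the chemo kill pulse subtracted from the growth rate
#' (Norton-Simon-type kill proportional to the unperturbed growth term).
#' With `a = 0` this reduces exactly to [solve_logistic()].
#'
#' @inheritParams solve_logistic
#' @param cp A [chemo_kill_params()] object.
#'
#' @return Numeric vector of cell counts `N(times)`.
#' @examples
#' g <- growth_params(0.657, diameter_to_cells(406.5))
#' cp <- chemo_kill_params(0.907, 0.160, 4.2)
#' solve_chemo(g, cp, 88, c(0, 2, 4, 6, 7))
#' @export
solve_chemo <- function(g, cp, N0, times, rtol = 1e-8, atol = 1e-10,
                        method = "lsoda") {
  stopifnot(inherits(g, "growth_params"), inherits(cp, "chemo_kill_params"))
  .check_times(N0, times)
  .solve_ode(c(N = N0), times, "pdto_d_chemo", "pdto_init_chemo",
             c(g$lam, g$K, cp$a, cp$b, cp$Tc), rtol, atol, method)[, 1]
}

#' Solve the two-compartment radiotherapy model
#'
#' Integrates the active/inactive system
#' \deqn{dA/dt = (lam - R(t)) A (1 - (A+I)/K), \quad
#'       dI/dt = R(t) A (1 - (A+I)/K) - mu I}
#' from the linear-quadratic initial split of `N0` cells at the given dose.
#' With `u1 = u2 = 0` and `dose = 0` the active compartment reproduces
#' [solve_logistic()] and `I(t)` is identically zero.
#'
#' @inheritParams solve_logistic
#' @param rp A [radio_kill_params()] object.
#' @param fp A [radio_fixed_params()] object (`mu`, `alpha`, `beta`, `dose`).
#'
#' @return A data frame with columns `day`, `A`, `I` and `N = A + I`.
#' @examples
#' g <- growth_params(0.416, diameter_to_cells(360.8))
#' rp <- radio_kill_params(0.373, 2.695, 4.7, 8.5)
#' solve_radio(g, rp, radio_fixed_params(dose = 4), 88, c(0, 2, 4, 6, 7, 8, 9))
#' @export
solve_radio <- function(g, rp, fp, N0, times, rtol = 1e-8, atol = 1e-10,
                        method = "lsoda") {
  stopifnot(inherits(g, "growth_params"), inherits(rp, "radio_kill_params"),
            inherits(fp, "radio_fixed_params"))
  .check_times(N0, times)
  s0 <- lq_split(fp, N0)
  out <- .solve_ode(c(A = s0$A, I = s0$I), times,
                    "pdto_d_radio", "pdto_init_radio",
                    c(g$lam, g$K, rp$u1, rp$u2, rp$T1, rp$T2, fp$mu),
                    rtol, atol, method)
  data.frame(day = times, A = out[, 1], I = out[, 2], N = out[, 1] + out[, 2])
}

#' Solve the chemoradiotherapy model
#'
#' Integrates the combined model in which both kill pulses act on active
#' cells,
#' \deqn{dA/dt = (lam - R(t) - C(t)) A (1 - (A+I)/K), \quad
#'       dI/dt = R(t) A (1 - (A+I)/K) - mu I,}
#' with the chemo-induced kill contributing nothing to the inactive
#' compartment.  With `a = 0` this equals [solve_radio()]; with
#' `u1 = u2 = 0` and `dose = 0` it equals [solve_chemo()].
#'
#' @inheritParams solve_radio
#' @param cp A [chemo_kill_params()] object.
#'
#' @return A data frame with columns `day`, `A`, `I` and `N = A + I`.
#' @export
solve_crt <- function(g, cp, rp, fp, N0, times, rtol = 1e-8, atol = 1e-10,
                      method = "lsoda") {
  stopifnot(inherits(g, "growth_params"), inherits(cp, "chemo_kill_params"),
            inherits(rp, "radio_kill_params"),
            inherits(fp, "radio_fixed_params"))
  .check_times(N0, times)
  s0 <- lq_split(fp, N0)
  out <- .solve_ode(c(A = s0$A, I = s0$I), times,
                    "pdto_d_crt", "pdto_init_crt",
                    c(g$lam, g$K, cp$a, cp$b, cp$Tc,
                      rp$u1, rp$u2, rp$T1, rp$T2, fp$mu),
                    rtol, atol, method)
  data.frame(day = times, A = out[, 1], I = out[, 2], N = out[, 1] + out[, 2])
}
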