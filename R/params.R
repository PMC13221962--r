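#' Logistic growth parameters of one organoid
#'
#' @param lam Intrinsic (relative) growth rate in day^-1; must be >= 0.
#' @param K Carrying capacity in cells; must be > 1.
#'
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(lam = 0.464, K = diameter_to_cells(302.8, 22.5))
#' @export
growth_params <- function(lam, K) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam),
            is.numeric(K), length(K) == 1L, is.finite(K))
  if (lam < 0) stop("growth rate `lam` must be >= 0", call. = FALSE)
  if (K <= 1) stop("carrying capacity `K` must be > 1 cell", call. = FALSE)
  structure(list(lam = lam, K = K), class = "growth_params")
}

#' Chemotherapy killing-pulse parameters
#'
#' The chemo-induced killing rate is a single Gaussian pulse
#' `C(t) = a * exp(-b * (t - Tc)^2)`: `a` is the drug sensitivity (peak kill
#' strength), `b` the inverse width of the killing window, and `Tc` the time
#' of the peak killing effect.
#'
#' @param a Peak kill strength (day^-1), >= 0.
#' @param b Inverse squared width of the kill window (day^-2), > 0.
#' @param Tc Day of peak killing effect, >= 0.
#'
#' @return An object of class `chemo_kill_params`.
#' @examples
#' chemo_kill_params(a = 0.515, b = 0.077, Tc = 3.5)
#' @export
chemo_kill_params <- function(a, b, Tc) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(Tc), length(Tc) == 1L, is.finite(Tc))
  if (a < 0) stop("peak kill strength `a` must be >= 0", call. = FALSE)
  if (b <= 0) stop("window parameter `b` must be > 0", call. = FALSE)
  if (Tc < 0) stop("peak time `Tc` must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, Tc = Tc), class = "chemo_kill_params")
}

#' Radiotherapy killing-pulse parameters
#'
#' Radiation-induced killing is modeled as two Gaussian waves with unit
#' (1 day^2) widths: `R(t) = u1 * exp(-(t - T1)^2) + u2 * exp(-(t - T2)^2)`.
#' The widths are part of the model definition and are never fitted.  The
#' ordering convention `T1 < T2` (early wave first) is enforced so wave
#' labels cannot switch.
#'
#' @param u1,u2 Peak strengths (day^-1) of the early and secondary waves,
#'   both >= 0.
#' @param T1,T2 Peak days of the two waves; `0 <= T1 < T2`.
#'
#' @return An object of class `radio_kill_params`.
#' @examples
#' radio_kill_params(u1 = 0.486, u2 = 1.518, T1 = 4.2, T2 = 8.1)
#' @export
radio_kill_params <- function(u1, u2, T1, T2) {
  stopifnot(is.numeric(u1), length(u1) == 1L, is.finite(u1),
            is.numeric(u2), length(u2) == 1L, is.finite(u2),
            is.numeric(T1), length(T1) == 1L, is.finite(T1),
            is.numeric(T2), length(T2) == 1L, is.finite(T2))
  if (u1 < 0 || u2 < 0) stop("wave strengths `u1`, `u2` must be >= 0", call. = FALSE)
  if (T1 < 0) stop("`T1` must be >= 0", call. = FALSE)
  if (T1 >= T2) stop("wave ordering requires T1 < T2", call. = FALSE)
  structure(list(u1 = u1, u2 = u2, T1 = T1, T2 = T2),
            class = "radio_kill_params")
}

#' Fixed radiotherapy constants
#'
#' Constants held fixed during radiotherapy/chemoradiation fits: the
#' inactive-cell removal rate `mu`, the linear-quadratic radiosensitivities
#' `alpha` and `beta`, and the delivered dose.  Defaults follow the values
#' used throughout the calibration protocol (`mu` = 0.3/day,
#' `alpha` = 0.015/Gy, `beta` = `alpha`/9.5 per Gy^2).
#'
#' @param dose Radiation dose in Gy, >= 0.
#' @param mu Removal rate of inactive cells (day^-1), >= 0.
#' @param alpha Linear radiosensitivity (Gy^-1), >= 0.
#' @param beta Quadratic radiosensitivity (Gy^-2), >= 0.
#'
#' @return An object of class `radio_fixed_params`.
#' @examples
#' radio_fixed_params(dose = 4)
#' @export
radio_fixed_params <- function(dose, mu = 0.3, alpha = 0.015,
                               beta = alpha / 9.5) {
  stopifnot(is.numeric(dose), length(dose) == 1L, is.finite(dose),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (dose < 0) stop("`dose` must be >= 0 Gy", call. = FALSE)
  if (mu < 0) stop("`mu` must be >= 0", call. = FALSE)
  if (alpha < 0 || beta < 0) stop("`alpha` and `beta` must be >= 0", call. = FALSE)
  structure(list(mu = mu, alpha = alpha, beta = beta, dose = dose),
            class = "radio_fixed_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("growth_params: lam = %.4g /day, K = %.6g cells\n", x$lam, x$K))
  invisible(x)
}

#' @export
print.chemo_kill_params <- function(x, ...) {
  cat(sprintf("chemo_kill_params: a = %.4g /day, b = %.4g /day^2, Tc = %.4g day\n",
              x$a, x$b, x$Tc))
  invisible(x)
}

#' @export
print.radio_kill_params <- function(x, ...) {
  cat(sprintf(
    "radio_kill_params: u1 = %.4g, u2 = %.4g /day; T1 = %.4g, T2 = %.4g day\n",
    x$u1, x$u2, x$T1, x$T2))
  invisible(x)
}

#' @export
print.radio_fixed_params <- function(x, ...) {
  cat(sprintf(
    "radio_fixed_params: dose = %.4g Gy, mu = %.4g /day, alpha = %.4g /Gy, beta = %.5g /Gy^2\n",
    x$dose, x$mu, x$alpha, x$beta))
  invisible(x)
}
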