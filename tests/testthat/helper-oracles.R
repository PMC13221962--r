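# Independent oracles used across the suite.  These deliberately avoid the
# package's compiled solver path: closed forms where they exist, and a plain
# R right-hand side integrated at much tighter tolerance for the
# two-compartment models.

erf <- function(x) 2 * pnorm(sqrt(2) * x) - 1

# Closed-form logistic solution
closed_logistic <- function(lam, K, N0, t) {
  K * N0 * exp(lam * t) / (K + N0 * (exp(lam * t) - 1))
}

# Closed-form solution of the chemo model: logistic with time-varying rate
# lam - C(t); the Gaussian pulse integrates to an erf expression.
closed_chemo <- function(lam, K, N0, a, b, Tc, t) {
  intC <- a * sqrt(pi / b) / 2 * (erf(sqrt(b) * (t - Tc)) + erf(sqrt(b) * Tc))
  rho <- lam * t - intC
  K / (1 + (K / N0 - 1) * exp(-rho))
}

# Reference integration of the two-compartment models with an R-coded RHS
# at rtol 1e-11 (refinement oracle, independent of the compiled code).
ref_solve_two_comp <- function(lam, K, u1, u2, T1, T2, mu, a, b, Tc,
                               A0, I0, times) {
  rhs <- function(t, y, p) {
    R <- u1 * exp(-(t - T1)^2) + u2 * exp(-(t - T2)^2)
    C <- if (is.na(a)) 0 else a * exp(-b * (t - Tc)^2)
    g <- 1 - (y[1] + y[2]) / K
    list(c((lam - R - C) * y[1] * g,
           R * y[1] * g - mu * y[2]))
  }
  tt <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::lsoda(c(A0, I0), tt, rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-13)
  out <- unname(as.matrix(out)[, -1, drop = FALSE])
  if (times[1] > 0) out <- out[-1, , drop = FALSE]
  out
}

# Printed group-level estimates as named vectors
ref_means <- function(line, arm, dose = 0) {
  df <- reference_estimates()
  df <- df[df$line_id == line & df$arm == arm & df$dose_gy == dose, ]
  setNames(df$estimate, df$parameter)
}

# Noise-free trajectory at given true parameters (through the generator)
make_traj <- function(params, arm, dose = 0, days, noise = 0, id = "t1",
                      line = "L") {
  simulate_trajectory(params, arm, dose, days, noise_sd_log = noise,
                      organoid_id = id, line_id = line)
}

days_std <- c(0, 2, 4, 6, 7)
days_rt <- c(0, 2, 4, 6, 7, 8, 9)

# Admissible random parameter draws for property tests
draw_growth <- function() {
  list(lam = runif(1, 0.2, 1), DK = runif(1, 180, 500))
}
draw_chemo <- function() {
  list(a = runif(1, 0.2, 1.2), b = runif(1, 0.04, 0.4),
       Tc = runif(1, 2, 6))
}
# kept inside the regime the measurement design identifies: the secondary
# wave peak stays within ~the last radiotherapy measurement day
draw_radio <- function() {
  T1 <- runif(1, 3.5, 4.8)
  list(u1 = runif(1, 0.3, 2), u2 = runif(1, 1, 4), T1 = T1,
       T2 = T1 + runif(1, 3, 4))
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)
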