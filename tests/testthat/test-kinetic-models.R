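test_that("chemo kill pulse has the Gaussian shape with peak a at Tc", {
  p <- chemo_kill_params(a = 0.515, b = 0.077, Tc = 3.5)
  expect_equal(chemo_kill_rate(p, 3.5), 0.515)
  # analytic half-maximum at Tc +/- sqrt(ln 2 / b)
  hm <- sqrt(log(2) / p$b)
  expect_equal(chemo_kill_rate(p, 3.5 + hm), 0.515 / 2, tolerance = 1e-12)
  expect_equal(chemo_kill_rate(p, 3.5 - hm), 0.515 / 2, tolerance = 1e-12)
  # direct scalar evaluation at t = 0 for the slow-responder parameter set
  p2 <- chemo_kill_params(a = 0.392, b = 0.072, Tc = 5.2)
  expect_equal(chemo_kill_rate(p2, 0), 0.392 * exp(-0.072 * 5.2^2),
               tolerance = 1e-12)
  expect_true(all(chemo_kill_rate(p, seq(-2, 20, 0.25)) >= 0))
})

test_that("radiation kill pulse superposes two unit-width waves", {
  expect_equal(radio_kill_rate(radio_kill_params(0, 0, 4, 8), c(0, 4, 9)),
               c(0, 0, 0))
  expect_equal(radio_kill_rate(radio_kill_params(1, 0, 4, 9), 4), 1,
               tolerance = 1e-12)
  p <- radio_kill_params(0.486, 1.518, 4.2, 8.1)
  expect_equal(radio_kill_rate(p, 4.2),
               0.486 + 1.518 * exp(-(4.2 - 8.1)^2), tolerance = 1e-12)
  expect_error(radio_kill_params(1, 1, 8, 4), "T1 < T2")
})

test_that("LQ split conserves cells exactly and decreases in dose", {
  expect_equal(lq_split(radio_fixed_params(dose = 0), 500),
               structure(list(A = 500, I = 0), class = "cell_state"))
  # alpha = 0.015/Gy, beta = alpha/9.5: direct scalar evaluation at 4 Gy
  s <- lq_split(radio_fixed_params(dose = 4), 1000)
  expect_equal(s$A, 1000 * exp(-(0.015 * 4 + 0.015 / 9.5 * 16)),
               tolerance = 1e-12)
  set.seed(41)
  prevA <- Inf
  for (d in c(0, 1, 2, 4, 8, 12)) {
    s <- lq_split(radio_fixed_params(dose = d), 1234.5)
    expect_identical(s$A + s$I, 1234.5)   # exact conservation
    expect_lt(s$A, prevA + 1e-12)
    prevA <- s$A
  }
})

test_that("numeric logistic solutions match the closed form", {
  set.seed(7)
  for (i in 1:100) {
    lam <- runif(1, 0.05, 1.2)
    K <- runif(1, 200, 50000)
    N0 <- runif(1, 10, K * 0.9)
    tms <- sort(runif(6, 0, 14))
    tms <- c(0, tms[tms > 0])
    num <- solve_logistic(growth_params(lam, K), N0, tms)
    expect_lt(max(rel_err(num, closed_logistic(lam, K, N0, tms))), 1e-6)
  }
  # explicit Runge-Kutta path agrees too
  g <- growth_params(0.464, 2437)
  expect_lt(max(rel_err(solve_logistic(g, 88, days_std, method = "ode45"),
                        closed_logistic(0.464, 2437, 88, days_std))), 1e-6)
  # equilibrium and zero-growth degeneracies
  expect_equal(solve_logistic(growth_params(0.5, 1000), 1000, days_std),
               rep(1000, 5), tolerance = 1e-8)
  expect_equal(solve_logistic(growth_params(0, 1000), 88, days_std),
               rep(88, 5), tolerance = 1e-10)
})

test_that("treated models collapse to their nested submodels", {
  set.seed(11)
  for (i in 1:20) {
    g <- draw_growth()
    gp <- growth_params(g$lam, diameter_to_cells(g$DK))
    cp <- do.call(chemo_kill_params, draw_chemo())
    rp <- do.call(radio_kill_params, draw_radio())
    cp0 <- chemo_kill_params(0, cp$b, cp$Tc)
    rp0 <- radio_kill_params(0, 0, rp$T1, rp$T2)
    fp0 <- radio_fixed_params(dose = 0)
    fp <- radio_fixed_params(dose = sample(c(4, 8), 1))
    N0 <- runif(1, 50, 200)
    log_ <- solve_logistic(gp, N0, days_rt)
    # chemo with a = 0 equals logistic
    expect_lt(max(rel_err(solve_chemo(gp, cp0, N0, days_rt), log_)), 1e-8)
    # radio with no waves, no dose equals logistic with empty I
    r0 <- solve_radio(gp, rp0, fp0, N0, days_rt)
    expect_lt(max(rel_err(r0$A, log_)), 1e-8)
    expect_true(all(r0$I == 0))
    # crt with a = 0 equals radio
    r1 <- solve_radio(gp, rp, fp, N0, days_rt)
    c1 <- solve_crt(gp, cp0, rp, fp, N0, days_rt)
    expect_lt(max(rel_err(c1$N, r1$N)), 1e-8)
    # crt with no radiation equals chemo
    c2 <- solve_crt(gp, cp, rp0, fp0, N0, days_rt)
    expect_lt(max(rel_err(c2$A, solve_chemo(gp, cp, N0, days_rt))), 1e-8)
  }
})

test_that("compiled solutions match closed-form and refinement oracles", {
  # chemo model vs its closed form at the fast-responder printed set
  gp <- growth_params(0.657, diameter_to_cells(406.5))
  cp <- chemo_kill_params(0.907, 0.160, 4.2)
  num <- solve_chemo(gp, cp, 88, days_std)
  expect_lt(max(rel_err(num, closed_chemo(0.657, gp$K, 88, 0.907, 0.160,
                                          4.2, days_std))), 1e-6)
  # radiotherapy model vs tight-tolerance R-side integration
  gp2 <- growth_params(0.416, diameter_to_cells(360.8))
  rp <- radio_kill_params(0.373, 2.695, 4.7, 8.5)
  fp <- radio_fixed_params(4)
  s0 <- lq_split(fp, 88)
  num2 <- solve_radio(gp2, rp, fp, 88, days_rt)
  ref2 <- ref_solve_two_comp(0.416, gp2$K, 0.373, 2.695, 4.7, 8.5, 0.3,
                             NA, NA, NA, s0$A, s0$I, days_rt)
  expect_lt(max(rel_err(num2$A, ref2[, 1])), 1e-6)
  expect_lt(max(rel_err(num2$I, ref2[, 2])), 1e-6)
  # combined model vs the same oracle
  gp3 <- growth_params(0.464, diameter_to_cells(302.8))
  cp3 <- chemo_kill_params(0.537, 0.061, 3.6)
  rp3 <- radio_kill_params(1.000, 2.151, 3.8, 7.9)
  fp3 <- radio_fixed_params(8)
  s03 <- lq_split(fp3, 88)
  num3 <- solve_crt(gp3, cp3, rp3, fp3, 88, days_std)
  ref3 <- ref_solve_two_comp(0.464, gp3$K, 1.000, 2.151, 3.8, 7.9, 0.3,
                             0.537, 0.061, 3.6, s03$A, s03$I, days_std)
  expect_lt(max(rel_err(num3$A, ref3[, 1])), 1e-6)
  expect_lt(max(rel_err(num3$I, ref3[, 2])), 1e-6)
})

test_that("states stay nonnegative and below carrying capacity", {
  set.seed(23)
  for (i in 1:20) {
    g <- draw_growth()
    gp <- growth_params(g$lam, diameter_to_cells(g$DK))
    rp <- do.call(radio_kill_params, draw_radio())
    cp <- do.call(chemo_kill_params, draw_chemo())
    fp <- radio_fixed_params(dose = runif(1, 0, 10))
    N0 <- runif(1, 30, min(gp$K * 0.9, 2000))
    out <- solve_crt(gp, cp, rp, fp, N0, seq(0, 14, 0.5))
    expect_true(all(out$A >= -1e-9) && all(out$I >= -1e-9))
    expect_true(all(out$N <= gp$K * (1 + 1e-9)))
  }
})

test_that("kill-rate maxima sit at the nominal peak times", {
  grid <- seq(0, 14, 0.01)
  set.seed(31)
  for (i in 1:10) {
    cp <- do.call(chemo_kill_params, draw_chemo())
    expect_equal(grid[which.max(chemo_kill_rate(cp, grid))], cp$Tc,
                 tolerance = 0.011)
    rp <- do.call(radio_kill_params, draw_radio())   # T2 - T1 >= 3
    r <- radio_kill_rate(rp, grid)
    pk <- grid[which(r[2:1400] > r[1:1399] & r[2:1400] > r[3:1401]) + 1L]
    expect_length(pk, 2L)
    expect_lt(abs(pk[1] - rp$T1), 0.05)
    expect_lt(abs(pk[2] - rp$T2), 0.05)
  }
})

test_that("solvers reject invalid inputs", {
  g <- growth_params(0.5, 1000)
  expect_error(solve_logistic(g, -5, days_std), "positive")
  expect_error(solve_logistic(g, 0, days_std), "positive")
  expect_error(solve_logistic(g, 88, c(0, 4, 2)), "increasing")
  expect_error(solve_logistic(g, 88, c(-1, 2)), ">= 0")
  expect_error(growth_params(-0.1, 100), "lam")
  expect_error(growth_params(0.5, 0.5), "carrying capacity")
  expect_error(chemo_kill_params(0.5, 0, 3), "> 0")
})
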