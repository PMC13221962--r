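test_that("NMSE is the normalized residual sum of squares", {
  expect_identical(nmse(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(nmse(10, 11), 0.01)
  X <- c(50, 80, 120); Y <- c(52, 75, 131)
  expect_equal(nmse(7.3 * X, 7.3 * Y), nmse(X, Y))     # scale invariance
  expect_gt(nmse(X, Y), 0)
  expect_error(nmse(c(0, 0), c(1, 1)), "all-zero")
  expect_error(nmse(1:3, 1:2), "equal-length")
})

test_that("information criteria follow the Gaussian least-squares forms", {
  ic <- information_criteria(2.0, n_points = 5, n_free = 3)
  expect_equal(ic$aic, 5 * log(2 / 5) + 2 * 3)
  expect_equal(ic$bic, 5 * log(2 / 5) + 3 * log(5))
  expect_false(ic$degenerate)
  # perfect fit sentinel
  ic0 <- information_criteria(0, n_points = 5, n_free = 2)
  expect_identical(ic0$aic, -Inf)
  expect_true(ic0$degenerate)
  # penalty monotonicity: same SSE, more parameters, larger criteria
  ic2 <- information_criteria(2.0, n_points = 5, n_free = 4)
  expect_gt(ic2$aic, ic$aic)
  expect_gt(ic2$bic, ic$bic)
})

test_that("control fits recover logistic parameters from clean data", {
  # printed parameter set
  tr <- make_traj(list(D_init = 100, lam = 0.464, DK = 302.8), "control",
                  days = days_std)
  f <- fit_control(tr)
  expect_true(f$converged)
  expect_lt(rel_err(coef(f)[["lam"]], 0.464), 0.01)
  expect_lt(rel_err(coef(f)[["DK"]], 302.8), 0.01)
  expect_equal(coef(f)[["K"]], (coef(f)[["DK"]] / 22.5)^3)
  expect_lt(f$nmse, 1e-10)
  # flat series: growth rate pinned at ~0
  flat <- organoid_trajectory("f", "L", "control", 0, days_std, rep(95, 5))
  expect_lte(coef(fit_control(flat))[["lam"]], 1e-3)
  # random admissible draws
  set.seed(13)
  for (i in 1:8) {
    g <- draw_growth()
    tr <- make_traj(c(list(D_init = runif(1, 70, 130)), g), "control",
                    days = days_std)
    f <- fit_control(tr)
    expect_lt(rel_err(coef(f)[["lam"]], g$lam), 0.01)
    expect_lt(rel_err(coef(f)[["DK"]], g$DK), 0.01)
  }
})

test_that("chemo fits recover the kill pulse with growth fixed", {
  g <- ref_means("8510", "control")
  gp <- growth_params(g[["lam"]], diameter_to_cells(g[["DK"]]))
  cp <- ref_means("8510", "chemo")
  tr <- make_traj(c(list(D_init = 100, lam = g[["lam"]], DK = g[["DK"]]),
                    as.list(cp)), "chemo", days = days_std)
  f <- fit_chemo(tr, gp)
  expect_lt(max(rel_err(coef(f)[c("a", "b", "Tc")], cp)), 0.01)
  # no drug effect in the data: fitted strength collapses to zero
  tr0 <- make_traj(list(D_init = 100, lam = g[["lam"]], DK = g[["DK"]],
                        a = 0.0001, b = 0.1, Tc = 3), "chemo",
                   days = days_std)
  expect_lte(coef(fit_chemo(tr0, gp))[["a"]], 1e-3)
  set.seed(17)
  for (i in 1:6) {
    cpr <- draw_chemo()
    tr <- make_traj(c(list(D_init = 100, lam = g[["lam"]], DK = g[["DK"]]),
                      cpr), "chemo", days = days_std)
    f <- fit_chemo(tr, gp)
    expect_lt(max(rel_err(coef(f)[c("a", "b", "Tc")], unlist(cpr))), 0.01)
  }
})

test_that("radiotherapy fits recover both waves and the growth rate", {
  K <- diameter_to_cells(360.8)
  tr <- make_traj(list(D_init = 100, lam = 0.416, DK = 360.8, u1 = 0.373,
                       u2 = 2.695, T1 = 4.7, T2 = 8.5), "rt", dose = 4,
                  days = days_rt)
  f <- fit_radio(tr, radio_fixed_params(4), K = K)
  truth <- c(lam = 0.416, u1 = 0.373, u2 = 2.695, T1 = 4.7, T2 = 8.5)
  expect_lt(max(rel_err(coef(f)[names(truth)], truth)), 0.02)
  expect_lt(coef(f)[["T1"]], coef(f)[["T2"]])
  # unirradiated data: wave strengths collapse, growth matches control
  tr0 <- make_traj(list(D_init = 100, lam = 0.431, DK = 360.8), "control",
                   days = days_rt)
  f0 <- fit_radio(tr0, radio_fixed_params(0), K = K)
  expect_lte(coef(f0)[["u1"]], 1e-3)
  expect_lte(coef(f0)[["u2"]], 1e-3)
  expect_lt(rel_err(coef(f0)[["lam"]], 0.431), 0.01)
  set.seed(19)
  for (i in 1:4) {
    rpr <- draw_radio()
    lam <- runif(1, 0.3, 0.9)
    tr <- make_traj(c(list(D_init = 100, lam = lam, DK = 360.8), rpr),
                    "rt", dose = 8, days = days_rt)
    f <- fit_radio(tr, radio_fixed_params(8), K = K)
    truth <- c(lam = lam, unlist(rpr))
    expect_lt(max(rel_err(coef(f)[names(truth)], truth)), 0.02)
  }
})

test_that("fixed-R chemoradiation fits recover the chemo component", {
  g <- ref_means("7800", "control")
  gp <- growth_params(g[["lam"]], diameter_to_cells(g[["DK"]]))
  rv <- ref_means("7800", "rt", 8)
  rp <- radio_kill_params(rv[["u1"]], rv[["u2"]], rv[["T1"]], rv[["T2"]])
  cv <- ref_means("7800", "crt", 8)
  tr <- make_traj(c(list(D_init = 100, lam = g[["lam"]], DK = g[["DK"]]),
                    as.list(cv), as.list(rv[c("u1", "u2", "T1", "T2")])),
                  "crt", dose = 8, days = days_std)
  f <- fit_crt_fixed_radio(tr, gp, rp, radio_fixed_params(8))
  expect_lt(max(rel_err(coef(f)[c("a", "b", "Tc")], cv)), 0.01)
  set.seed(29)
  for (i in 1:4) {
    cpr <- draw_chemo()
    tr <- make_traj(c(list(D_init = 100, lam = g[["lam"]], DK = g[["DK"]]),
                      cpr, as.list(rv[c("u1", "u2", "T1", "T2")])),
                    "crt", dose = 8, days = days_std)
    f <- fit_crt_fixed_radio(tr, gp, rp, radio_fixed_params(8))
    expect_lt(max(rel_err(coef(f)[c("a", "b", "Tc")], unlist(cpr))), 0.01)
  }
})

test_that("fixed-C chemoradiation fits recover radiation when self-consistent", {
  g <- ref_means("7800", "control")
  cv <- ref_means("7800", "chemo")
  cp <- chemo_kill_params(cv[["a"]], cv[["b"]], cv[["Tc"]])
  rv <- ref_means("7800", "rt", 8)
  K <- diameter_to_cells(g[["DK"]])
  # daily grid through day 9: 5 free parameters need more than 4
  # informative points, and the secondary wave must lie inside the data
  tr <- make_traj(c(list(D_init = 100, lam = g[["lam"]], DK = g[["DK"]]),
                    as.list(cv), as.list(rv[c("u1", "u2", "T1", "T2")])),
                  "crt", dose = 8, days = 0:9)
  f <- suppressWarnings(fit_crt_fixed_chemo(tr, cp, radio_fixed_params(8),
                                            K = K))
  truth <- c(lam = unname(g[["lam"]]), rv[c("u1", "u2", "T1", "T2")])
  expect_lt(max(rel_err(coef(f)[names(truth)], truth)), 0.02)
  # degenerate flat data must return a flagged result, not crash
  flat <- organoid_trajectory("f", "L", "crt", 8, days_std, rep(100, 5))
  ff <- suppressWarnings(fit_crt_fixed_chemo(flat, cp,
                                             radio_fixed_params(8), K = K))
  expect_s3_class(ff, "pdto_fit")
  expect_true(is.logical(ff$converged))
  expect_true(all(is.finite(coef(ff))))
})

test_that("the multi-start optimizer never ends above its best start", {
  set.seed(37)
  for (i in 1:5) {
    g <- draw_growth()
    tr <- make_traj(c(list(D_init = 100), g), "control", days = days_std,
                    noise = 0.05)
    f <- fit_control(tr)
    expect_lte(f$sse, min(f$start_sse) + 1e-12)
  }
})

test_that("population summaries match direct computation", {
  set.seed(43)
  ds <- generate_study(default_study_spec()["7800.control"], seed = 9)
  fits <- lapply(ds$trajectories[1:12], fit_control)
  s <- population_summary(fits, c("lam", "DK"))
  lam <- vapply(fits, function(f) coef(f)[["lam"]], 0)
  keep <- vapply(fits, function(f) !("DK" %in% f$at_bound), TRUE)
  dk <- vapply(fits[keep], function(f) coef(f)[["DK"]], 0)
  expect_equal(s$mean[s$parameter == "lam"], mean(lam))
  expect_equal(s$median[s$parameter == "lam"], median(lam))
  expect_equal(s$ci95_half_width[s$parameter == "lam"],
               qt(0.975, length(lam) - 1) * sd(lam) / sqrt(length(lam)))
  expect_equal(s$mean[s$parameter == "DK"], mean(dk))
  expect_equal(s$n[s$parameter == "DK"], length(dk))
  # identical fits give a zero-width interval
  two <- list(fits[[1]], fits[[1]])
  s2 <- population_summary(two, "lam")
  expect_equal(s2$ci95_half_width, 0)
  expect_error(population_summary(fits[1]), ">= 2")
})

test_that("achievable-size bounds reproduce the published maxima", {
  # 99.9% upper confidence bounds of the mean carrying diameter
  expect_equal(achievable_size_bound(mean = 302.8, ci95_half_width = 155.2,
                                     n = 33), 578.8, tolerance = 1e-3)
  expect_equal(achievable_size_bound(mean = 406.5, ci95_half_width = 164.2,
                                     n = 30), 700.3, tolerance = 1e-3)
  expect_equal(achievable_size_bound(mean = 360.8, ci95_half_width = 187.3,
                                     n = 30), 695.8, tolerance = 2e-3)
  # raw-values interface agrees with the summary-statistics interface
  set.seed(47)
  x <- rnorm(25, 300, 80)
  hw <- qt(0.975, 24) * sd(x) / 5
  expect_equal(achievable_size_bound(x),
               achievable_size_bound(mean = mean(x), ci95_half_width = hw,
                                     n = 25))
})

test_that("line comparisons detect separation and respect null cases", {
  mk_fit <- function(lam, dk) {
    tr <- make_traj(list(D_init = 100, lam = lam, DK = dk), "control",
                    days = days_std)
    fit_control(tr)
  }
  # same spread of values in each group: no line effect
  vals <- c(0.4, 0.5, 0.6)
  same <- lapply(1:3, function(i) lapply(vals, mk_fit, dk = 300))
  names(same) <- c("A", "B", "C")
  res <- compare_lines(same, "lam")
  expect_gte(res$p_mean, 0.99)
  expect_gte(res$p_median, 0.9)
  # groups separated by many standard deviations
  set.seed(53)
  far <- list(A = lapply(rnorm(8, 0.3, 0.01), mk_fit, dk = 300),
              B = lapply(rnorm(8, 0.6, 0.01), mk_fit, dk = 300),
              C = lapply(rnorm(8, 0.9, 0.01), mk_fit, dk = 300))
  res2 <- compare_lines(far, "lam")
  expect_lt(res2$p_mean, 1e-6)
  expect_lt(res2$p_median, 1e-4)
  expect_error(compare_lines(same[1], "lam"), ">= 2")
})

test_that("growth rates separate the three lines in a synthetic study", {
  spec <- default_study_spec()
  specs <- spec[c("7800.control", "8510.control", "11777.control")]
  specs <- lapply(specs, function(sp) { sp$n_organoids <- 10L; sp })
  ds <- generate_study(specs, seed = 61)
  fits_by_line <- split(lapply(ds$trajectories, fit_control),
                        vapply(ds$trajectories, `[[`, "", "line_id"))
  res <- compare_lines(fits_by_line, "lam")
  expect_lt(res$p_mean, 0.01)
  expect_lt(res$p_median, 0.01)
})
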