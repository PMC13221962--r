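#' Published per-group parameter estimates for the three PDTO lines
#'
#' The population-level calibration results for pancreatic PDTO lines
#' #7800, #8510 and #11777 across the six study arms (control, FOLFIRINOX
#' chemotherapy, radiotherapy at 4 and 8 Gy, chemoradiotherapy at 4 and
#' 8 Gy): per-parameter mean estimate, 95% confidence-interval half-width
#' of the mean, and the number of organoids in the group.  Chemoradiation
#' rows carry the chemo-pulse estimates obtained with the radiation
#' component fixed at the matching radiotherapy-arm values.  These
#' estimates seed the synthetic-study generator defaults and serve as
#' generating truths in simulate-and-refit validation.
#'
#' @return A data frame with columns `line_id`, `arm` (`control`, `chemo`,
#'   `rt`, `crt`), `dose_gy`, `parameter`, `estimate`, `ci95_half_width`,
#'   `n_organoids`.  Units: `lam`, `a`, `u1`, `u2` in day^-1; `b` in
#'   day^-2; `Tc`, `T1`, `T2` in days; `DK` in um.
#' @examples
#' subset(reference_estimates(), line_id == "7800" & arm == "control")
#' @export
reference_estimates <- function() {
  # dotted formals so `a = ` / `b = ` in ... cannot partially match them
  row <- function(.line, .arm, .dose, .n, ...) {
    v <- c(...)
    p <- names(v)[seq(1, length(v), by = 2)]
    data.frame(line_id = .line, arm = .arm, dose_gy = .dose, parameter = p,
               estimate = unname(v[seq(1, length(v), by = 2)]),
               ci95_half_width = unname(v[seq(2, length(v), by = 2)]),
               n_organoids = .n, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    row("7800",  "control", 0, 33, lam = 0.464, 0.033, DK = 302.8, 155.2),
    row("8510",  "control", 0, 30, lam = 0.657, 0.053, DK = 406.5, 164.2),
    row("11777", "control", 0, 30, lam = 0.431, 0.047, DK = 360.8, 187.3),
    row("7800",  "chemo", 0, 20, a = 0.515, 0.037, b = 0.077, 0.019,
        Tc = 3.5, 0.3),
    row("8510",  "chemo", 0, 30, a = 0.907, 0.123, b = 0.160, 0.082,
        Tc = 4.2, 0.3),
    row("11777", "chemo", 0, 30, a = 0.392, 0.026, b = 0.072, 0.028,
        Tc = 5.2, 0.9),
    row("7800",  "rt", 4, 30, lam = 0.400, 0.034, u1 = 0.486, 0.090,
        u2 = 1.518, 0.693, T1 = 4.2, 0.4, T2 = 8.1, 0.4),
    row("8510",  "rt", 4, 30, lam = 0.805, 0.082, u1 = 1.699, 0.204,
        u2 = 3.726, 0.545, T1 = 4.2, 0.4, T2 = 8.1, 0.6),
    row("11777", "rt", 4, 30, lam = 0.416, 0.027, u1 = 0.373, 0.090,
        u2 = 2.695, 0.738, T1 = 4.7, 0.5, T2 = 8.5, 0.4),
    row("7800",  "rt", 8, 30, lam = 0.490, 0.041, u1 = 1.000, 0.110,
        u2 = 2.151, 0.627, T1 = 3.8, 0.3, T2 = 7.9, 0.4),
    row("8510",  "rt", 8, 30, lam = 0.769, 0.069, u1 = 1.729, 0.265,
        u2 = 3.155, 0.585, T1 = 4.3, 0.3, T2 = 8.4, 0.4),
    row("11777", "rt", 8, 30, lam = 0.465, 0.046, u1 = 0.788, 0.135,
        u2 = 2.841, 0.714, T1 = 4.5, 0.3, T2 = 8.5, 0.4),
    row("7800",  "crt", 4, 21, a = 0.477, 0.045, b = 0.038, 0.019,
        Tc = 5.5, 0.7),
    row("8510",  "crt", 4, 30, a = 0.944, 0.117, b = 0.173, 0.056,
        Tc = 4.0, 0.3),
    row("11777", "crt", 4, 30, a = 0.376, 0.032, b = 0.098, 0.049,
        Tc = 4.5, 0.8),
    row("7800",  "crt", 8, 26, a = 0.537, 0.032, b = 0.061, 0.020,
        Tc = 3.6, 0.6),
    row("8510",  "crt", 8, 30, a = 1.011, 0.181, b = 0.237, 0.180,
        Tc = 4.3, 0.5),
    row("11777", "crt", 8, 30, a = 0.398, 0.035, b = 0.093, 0.048,
        Tc = 5.6, 0.6)))
}

# Named vectors (estimate, ci95 half-width) and n for one reference group.
.ref_group <- function(line, arm, dose = 0) {
  df <- reference_estimates()
  df <- df[df$line_id == line & df$arm == arm & df$dose_gy == dose, ]
  if (nrow(df) == 0L)
    stop(sprintf("no reference group %s/%s/%g Gy", line, arm, dose),
         call. = FALSE)
  list(means = stats::setNames(df$estimate, df$parameter),
       hw = stats::setNames(df$ci95_half_width, df$parameter),
       n = df$n_organoids[1])
}

# Between-organoid spread used by the generator defaults: the published 95%
# CI half-width itself.  The CI-implied across-organoid sd
# (hw * sqrt(n) / t) is inflated by per-organoid estimation error and would
# place a large fraction of organoids above the published maximum achievable
# sizes; the half-width keeps that ceiling near the 96th percentile of the
# sampled population for every line.
.spread_sd <- function(hw, n) hw

#' Specification of one synthetic line/arm population
#'
#' Describes how to draw one group of synthetic organoids: parameter means
#' and between-organoid standard deviations, the number of organoids, the
#' measurement day grid, the initial-diameter distribution and the
#' multiplicative measurement-noise level.
#'
#' @param line_id,arm,dose Group identity (`arm` in `control`, `chemo`,
#'   `rt`, `crt`; `dose` in Gy).
#' @param n_organoids Number of organoids (>= 1).
#' @param days Measurement day grid, starting at day 0.
#' @param means Named numeric vector of parameter means.  Required names by
#'   arm: `lam`, `DK` always; plus `a`, `b`, `Tc` for `chemo`/`crt`; plus
#'   `u1`, `u2`, `T1`, `T2` for `rt`/`crt`.
#' @param sds Named numeric vector of between-organoid standard deviations
#'   (>= 0), same names as `means`.
#' @param init_diameter_mean,init_diameter_sd Initial organoid diameter
#'   distribution in um (truncated at 40 um).
#' @param noise_sd_log Standard deviation of the lognormal multiplicative
#'   diameter measurement noise (0 = noise-free).
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(line_id, arm, dose = 0, n_organoids, days,
                            means, sds,
                            init_diameter_mean = 100,
                            init_diameter_sd = 15,
                            noise_sd_log = 0.05) {
  arm <- match.arg(arm, .arms)
  need <- switch(arm,
                 control = c("lam", "DK"),
                 chemo = c("lam", "DK", "a", "b", "Tc"),
                 rt = c("lam", "DK", "u1", "u2", "T1", "T2"),
                 crt = c("lam", "DK", "a", "b", "Tc",
                         "u1", "u2", "T1", "T2"))
  if (!all(need %in% names(means)) || !all(need %in% names(sds)))
    stop("`means` and `sds` must provide: ", paste(need, collapse = ", "),
         call. = FALSE)
  stopifnot(n_organoids >= 1, length(days) >= 1, days[1] == 0,
            !is.unsorted(days, strictly = TRUE),
            all(sds[need] >= 0), init_diameter_mean > 0,
            init_diameter_sd >= 0, noise_sd_log >= 0)
  if (arm %in% c("rt", "crt") && dose <= 0)
    stop("irradiated arms require dose > 0", call. = FALSE)
  structure(list(line_id = as.character(line_id), arm = arm, dose = dose,
                 n_organoids = as.integer(n_organoids),
                 days = as.numeric(days),
                 means = means[need], sds = sds[need],
                 init_diameter_mean = init_diameter_mean,
                 init_diameter_sd = init_diameter_sd,
                 noise_sd_log = noise_sd_log),
            class = "population_spec")
}

#' Default synthetic study specification
#'
#' Builds the full 3-line x 6-arm study design emulated by the generator:
#' group sizes of 20-40 organoids (the #7800 arms use the published counts
#' 33/20/30/30/21/26; other groups use 30), day grids 0,2,4,6,7 for
#' control/chemo/chemoradiation and 0,2,4,6,7,8,9 for radiotherapy (or
#' daily grids when `daily = TRUE`), parameter means from
#' [reference_estimates()], and between-organoid standard deviations set to
#' the published 95% CI half-widths (taken as the scale of biological
#' heterogeneity; this keeps the published maximum achievable sizes near the
#' 96th percentile of each sampled population).  Growth parameters of treated
#' arms inherit the line's control-group distribution; radiotherapy arms
#' use their own fitted growth-rate distribution.
#'
#' @param noise_sd_log Measurement noise level (default 0.05, i.e. ~5%
#'   multiplicative diameter noise).
#' @param daily Use daily measurement grids (days 0-7 / 0-9) instead of the
#'   standard sparse grids.
#'
#' @return A named list of [population_spec()] objects (18 groups).
#' @export
default_study_spec <- function(noise_sd_log = 0.05, daily = FALSE) {
  days_std <- if (daily) 0:7 else c(0, 2, 4, 6, 7)
  days_rt <- if (daily) 0:9 else c(0, 2, 4, 6, 7, 8, 9)
  specs <- list()
  for (line in c("7800", "8510", "11777")) {
    ctrl <- .ref_group(line, "control")
    g_means <- ctrl$means
    g_sds <- .spread_sd(ctrl$hw, ctrl$n)
    add <- function(arm, dose, days, extra, key) {
      means <- c(g_means, extra$means)
      sds <- c(g_sds, .spread_sd(extra$hw, extra$n))
      if ("lam" %in% names(extra$means)) {  # rt arms carry their own lam
        means <- c(extra$means, g_means[setdiff(names(g_means),
                                                names(extra$means))])
        sds <- c(.spread_sd(extra$hw, extra$n),
                 g_sds[setdiff(names(g_sds), names(extra$hw))])
      }
      n <- extra$n
      specs[[key]] <<- population_spec(line, arm, dose, n, days,
                                       means, sds,
                                       noise_sd_log = noise_sd_log)
    }
    specs[[paste0(line, ".control")]] <-
      population_spec(line, "control", 0, ctrl$n, days_std, g_means, g_sds,
                      noise_sd_log = noise_sd_log)
    add("chemo", 0, days_std, .ref_group(line, "chemo"),
        paste0(line, ".chemo"))
    add("rt", 4, days_rt, .ref_group(line, "rt", 4), paste0(line, ".rt4"))
    add("rt", 8, days_rt, .ref_group(line, "rt", 8), paste0(line, ".rt8"))
    for (d in c(4, 8)) {
      crt <- .ref_group(line, "crt", d)
      rtg <- .ref_group(line, "rt", d)
      radio_only <- setdiff(names(rtg$means), "lam")
      means <- c(g_means, crt$means, rtg$means[radio_only])
      sds <- c(g_sds, .spread_sd(crt$hw, crt$n),
               .spread_sd(rtg$hw[radio_only], rtg$n))
      specs[[paste0(line, ".crt", d)]] <-
        population_spec(line, "crt", d, crt$n, days_std, means, sds,
                        noise_sd_log = noise_sd_log)
    }
  }
  specs
}

# One truncated-normal draw by rejection; errors after `max_tries` misses.
.rtrunc <- function(mean, sd, lower, what, max_tries = 1000L) {
  if (sd == 0) {
    if (mean < lower)
      stop(sprintf("infeasible spec: fixed %s = %g below bound %g",
                   what, mean, lower), call. = FALSE)
    return(mean)
  }
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
  stop(sprintf("infeasible spec: could not draw %s >= %g from N(%g, %g) in %d tries",
               what, lower, mean, sd, max_tries), call. = FALSE)
}

#' Draw per-organoid true parameters from a population specification
#'
#' Samples each parameter independently from a normal distribution
#' truncated at its admissible bound (`lam`, `a`, `b`, `u1`, `u2` >= 1e-4;
#' peak times >= 0; initial diameter >= 40 um; carrying diameter above the
#' organoid's initial diameter, i.e. `K > N0`), with `T1 < T2` enforced by
#' redrawing the pair.  Draws come from the current RNG stream, so results
#' are reproducible under `set.seed()` (and [generate_study()] seeds them).
#'
#' @param spec A [population_spec()].
#' @param n Number of organoids (default `spec$n_organoids`).
#'
#' @return A data frame of true parameters, one row per organoid, with
#'   columns `D_init`, `lam`, `DK`, `K` and the arm's kill parameters.
#' @export
sample_organoid_params <- function(spec, n = spec$n_organoids) {
  stopifnot(inherits(spec, "population_spec"))
  mu <- spec$means; sd <- spec$sds
  draw <- function(i) {
    D_init <- .rtrunc(spec$init_diameter_mean, spec$init_diameter_sd, 40,
                      "D_init")
    out <- list(D_init = D_init,
                lam = .rtrunc(mu[["lam"]], sd[["lam"]], 1e-4, "lam"),
                DK = .rtrunc(mu[["DK"]], sd[["DK"]],
                             D_init * (1 + 1e-6), "DK"))
    if (spec$arm %in% c("chemo", "crt")) {
      out$a <- .rtrunc(mu[["a"]], sd[["a"]], 1e-4, "a")
      out$b <- .rtrunc(mu[["b"]], sd[["b"]], 1e-4, "b")
      out$Tc <- .rtrunc(mu[["Tc"]], sd[["Tc"]], 0, "Tc")
    }
    if (spec$arm %in% c("rt", "crt")) {
      out$u1 <- .rtrunc(mu[["u1"]], sd[["u1"]], 1e-4, "u1")
      out$u2 <- .rtrunc(mu[["u2"]], sd[["u2"]], 1e-4, "u2")
      for (tries in seq_len(1000L)) {
        T1 <- .rtrunc(mu[["T1"]], sd[["T1"]], 0, "T1")
        T2 <- .rtrunc(mu[["T2"]], sd[["T2"]], 0, "T2")
        if (T1 < T2) break
        if (tries == 1000L)
          stop("infeasible spec: could not draw T1 < T2", call. = FALSE)
      }
      out$T1 <- T1; out$T2 <- T2
    }
    as.data.frame(out)
  }
  rows <- lapply(seq_len(n), draw)
  out <- do.call(rbind, rows)
  out$K <- diameter_to_cells(out$DK, 22.5)  # K in reference cell units
  out
}

#' Simulate one organoid trajectory from true parameters
#'
#' Solves the arm's growth model from the organoid's initial diameter,
#' converts total cell number (active + inactive for irradiated arms) back
#' to diameter, and applies multiplicative lognormal measurement noise
#' `exp(eps)`, `eps ~ N(0, noise_sd_log^2)`, independently per time point.
#' With `noise_sd_log = 0` the measured diameters equal the model output.
#'
#' @param params Named list/one-row data frame of true parameters:
#'   `D_init`, `lam`, `DK` (or `K`), plus `a`, `b`, `Tc` and/or `u1`, `u2`,
#'   `T1`, `T2` as the arm requires.
#' @param arm Treatment arm (`control`, `chemo`, `rt`, `crt`).
#' @param dose Radiation dose in Gy (irradiated arms).
#' @param days Measurement day grid starting at 0.
#' @param noise_sd_log Lognormal noise sd (0 = exact model output).
#' @param D0 Reference cell diameter (um).
#' @param mu,alpha,beta Fixed radiotherapy constants.
#' @param organoid_id,line_id Identifiers for the returned trajectory.
#'
#' @return An [organoid_trajectory()].
#' @export
simulate_trajectory <- function(params, arm, dose = 0, days,
                                noise_sd_log = 0, D0 = 22.5,
                                mu = 0.3, alpha = 0.015, beta = alpha / 9.5,
                                organoid_id = "org1", line_id = "line") {
  arm <- match.arg(arm, .arms)
  p <- as.list(params)
  K <- if (!is.null(p$DK) && is.finite(p$DK)) diameter_to_cells(p$DK, D0)
       else p$K
  g <- growth_params(p$lam, K)
  N0 <- diameter_to_cells(p$D_init, D0)
  N <- switch(arm,
    control = solve_logistic(g, N0, days),
    chemo = solve_chemo(g, chemo_kill_params(p$a, p$b, p$Tc), N0, days),
    rt = solve_radio(g, radio_kill_params(p$u1, p$u2, p$T1, p$T2),
                     radio_fixed_params(dose, mu, alpha, beta), N0, days)$N,
    crt = solve_crt(g, chemo_kill_params(p$a, p$b, p$Tc),
                    radio_kill_params(p$u1, p$u2, p$T1, p$T2),
                    radio_fixed_params(dose, mu, alpha, beta), N0, days)$N)
  D_model <- cells_to_diameter(pmax(N, .Machine$double.eps), D0)
  D_obs <- if (noise_sd_log > 0) {
    D_model * exp(stats::rnorm(length(days), 0, noise_sd_log))
  } else D_model
  organoid_trajectory(organoid_id, line_id, arm, dose, days, D_obs)
}

#' Generate a full synthetic study
#'
#' Draws per-organoid true parameters and simulates measured trajectories
#' for every group of a study specification.  Fully deterministic given the
#' master seed; the caller's RNG stream is left untouched.  The sampled
#' true parameters are attached as attribute `"truth"` (a data frame with
#' one row per organoid) so that simulate-and-refit studies can score
#' recovery against the realized truths.
#'
#' @param specs A named list of [population_spec()] objects
#'   (default [default_study_spec()]).
#' @param seed Master RNG seed.
#' @param D0 Reference cell diameter (um).
#' @param mu,alpha,beta Fixed radiotherapy constants used by the forward
#'   model.
#'
#' @return A [study_dataset()] with attributes `truth` and `seed`.
#' @examples
#' spec <- default_study_spec(noise_sd_log = 0)
#' ds <- generate_study(spec["7800.control"], seed = 1)
#' @export
generate_study <- function(specs = default_study_spec(), seed = 20260303,
                           D0 = 22.5, mu = 0.3, alpha = 0.015,
                           beta = alpha / 9.5) {
  stopifnot(is.list(specs),
            all(vapply(specs, inherits, TRUE, "population_spec")))
  .with_seed(seed, {
    trajs <- list()
    truth <- list()
    for (spec in specs) {
      pars <- sample_organoid_params(spec)
      tag <- paste0(spec$line_id, "_", spec$arm,
                    if (spec$dose > 0) spec$dose else "")
      ids <- sprintf("%s_%02d", tag, seq_len(nrow(pars)))
      for (i in seq_len(nrow(pars))) {
        trajs[[length(trajs) + 1L]] <-
          simulate_trajectory(pars[i, ], spec$arm, spec$dose, spec$days,
                              spec$noise_sd_log, D0, mu, alpha, beta,
                              organoid_id = ids[i], line_id = spec$line_id)
      }
      truth[[length(truth) + 1L]] <-
        cbind(data.frame(organoid_id = ids, line_id = spec$line_id,
                         arm = spec$arm, dose_gy = spec$dose,
                         stringsAsFactors = FALSE),
              pars)
    }
    cols <- c("organoid_id", "line_id", "arm", "dose_gy", "D_init", "lam",
              "DK", "K", "a", "b", "Tc", "u1", "u2", "T1", "T2")
    truth <- do.call(rbind, lapply(truth, function(d) {
      for (col in setdiff(cols, names(d))) d[[col]] <- NA_real_
      d[cols]
    }))
    ds <- study_dataset(trajs, D0 = D0)
    attr(ds, "truth") <- truth
    attr(ds, "seed") <- seed
    ds
  })
}
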