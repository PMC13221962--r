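#' Treatment-response metric
#'
#' The treatment response (TR) at an assessment day is the natural
#' logarithm of the ratio between the size the organoid would have reached
#' untreated (predicted by the logistic control model) and its observed
#' post-treatment size, both in cell numbers:
#' `TR = log(untreated_pred / treated)`.  TR is dimensionless, zero for no
#' effect, and larger for more effective therapy; it captures cytostatic as
#' well as cytotoxic effects.
#'
#' @param treated Observed post-treatment cell count(s), > 0.
#' @param untreated_pred Model-predicted untreated cell count(s), > 0.
#'
#' @return TR value(s).
#' @examples
#' treatment_response(100, 100)        # 0: no effect
#' treatment_response(100 / exp(1), 100)  # 1
#' @export
treatment_response <- function(treated, untreated_pred) {
  stopifnot(is.numeric(treated), is.numeric(untreated_pred))
  if (any(!is.finite(treated)) || any(treated <= 0) ||
      any(!is.finite(untreated_pred)) || any(untreated_pred <= 0))
    stop("cell counts must be positive and finite", call. = FALSE)
  log(untreated_pred / treated)
}

#' Per-group treatment-response table
#'
#' Computes per-organoid TR values for every treated trajectory at the
#' requested assessment days and summarizes them per line/arm/dose/day as
#' mean with a 95% CI half-width across organoids.  The untreated
#' counterfactual for each organoid is the logistic model at the line's
#' control growth parameters, started from the organoid's own day-0
#' measurement.
#'
#' @param dataset A [study_dataset()].
#' @param control_growth A named list mapping `line_id` to
#'   [growth_params()] (typically line-level control-fit averages).
#' @param days_by_arm Assessment days per arm; defaults to day 7 for chemo
#'   and chemoradiation and days 7 and 9 for radiotherapy.
#'
#' @return A data frame with columns `line_id`, `arm`, `dose_gy`, `day`,
#'   `n`, `tr_mean`, `tr_ci95`.
#' @export
treatment_response_table <- function(dataset, control_growth,
                                     days_by_arm = list(chemo = 7,
                                                        rt = c(7, 9),
                                                        crt = 7)) {
  stopifnot(inherits(dataset, "study_dataset"), is.list(control_growth))
  rows <- list()
  for (tr in dataset$trajectories) {
    if (tr$arm == "control" || is.null(days_by_arm[[tr$arm]])) next
    g <- control_growth[[tr$line_id]]
    if (is.null(g))
      stop(sprintf("no control growth parameters for line %s", tr$line_id),
           call. = FALSE)
    N0 <- diameter_to_cells(tr$diameters[1], dataset$D0)
    for (d in intersect(days_by_arm[[tr$arm]], tr$days)) {
      obs <- diameter_to_cells(tr$diameters[tr$days == d], dataset$D0)
      pred <- solve_logistic(g, N0, c(0, d))[2]
      rows[[length(rows) + 1L]] <-
        data.frame(line_id = tr$line_id, arm = tr$arm, dose_gy = tr$dose,
                   day = d, tr = treatment_response(obs, pred),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no treated trajectories at the requested days",
                          call. = FALSE)
  df <- do.call(rbind, rows)
  agg <- split(df, interaction(df$line_id, df$arm, df$dose_gy, df$day,
                               drop = TRUE))
  out <- lapply(agg, function(d) {
    n <- nrow(d)
    ci <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(d$tr) / sqrt(n)
          else NA_real_
    data.frame(line_id = d$line_id[1], arm = d$arm[1],
               dose_gy = d$dose_gy[1], day = d$day[1], n = n,
               tr_mean = mean(d$tr), tr_ci95 = ci,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$line_id, out$arm, out$dose_gy, out$day), ]
}

# Indices of strict interior local maxima of a numeric series.
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

#' Tabulate killing-rate curves over time
#'
#' Evaluates the chemo pulse `C(t)`, the radiation pulse `R(t)` and their
#' sum on a time grid, for plotting or export.  Local maxima of each curve
#' (location and height) are attached as attribute `"peaks"`.
#'
#' @param chemo A [chemo_kill_params()] object, or `NULL`.
#' @param radio A [radio_kill_params()] object, or `NULL`.
#' @param times Evaluation grid in days.
#'
#' @return A data frame with columns `day`, `chemo_rate`, `radio_rate`,
#'   `total_rate`, with attribute `"peaks"`.
#' @examples
#' kc <- killing_curves(radio = radio_kill_params(0.486, 1.518, 4.2, 8.1))
#' attr(kc, "peaks")
#' @export
killing_curves <- function(chemo = NULL, radio = NULL,
                           times = seq(0, 14, by = 0.01)) {
  if (is.null(chemo) && is.null(radio))
    stop("supply at least one of `chemo`, `radio`", call. = FALSE)
  C <- if (!is.null(chemo)) chemo_kill_rate(chemo, times) else rep(0, length(times))
  R <- if (!is.null(radio)) radio_kill_rate(radio, times) else rep(0, length(times))
  out <- data.frame(day = times, chemo_rate = C, radio_rate = R,
                    total_rate = C + R)
  peaks <- lapply(c("chemo_rate", "radio_rate", "total_rate"), function(col) {
    idx <- .local_maxima(out[[col]])
    if (!length(idx)) return(NULL)
    data.frame(curve = col, day = times[idx], rate = out[[col]][idx],
               stringsAsFactors = FALSE)
  })
  attr(out, "peaks") <- do.call(rbind, c(peaks, list(make.row.names = FALSE)))
  out
}

#' Forecast an organoid growth curve under a regimen
#'
#' Simulates the deterministic model trajectory, in diameter units, for a
#' calibrated parameter set under a chosen regimen, initiated from a given
#' starting diameter (default 100 um).  The regimen is inferred from the
#' supplied components: growth only = control; + `chemo` = chemotherapy;
#' + `radio`/`fp` = radiotherapy; all = chemoradiation.
#'
#' @param growth A [growth_params()] object.
#' @param chemo Optional [chemo_kill_params()].
#' @param radio Optional [radio_kill_params()] (requires `fp`).
#' @param fp Optional [radio_fixed_params()] with the dose.
#' @param start_diameter Initial diameter in um (default 100).
#' @param horizon Forecast horizon in days (default 12).
#' @param step Output time step in days.
#' @param D0 Reference cell diameter (um).
#'
#' @return A data frame with columns `day` and `diameter_um`.
#' @export
forecast_growth <- function(growth, chemo = NULL, radio = NULL, fp = NULL,
                            start_diameter = 100, horizon = 12, step = 0.1,
                            D0 = 22.5) {
  stopifnot(inherits(growth, "growth_params"), start_diameter > 0,
            horizon > 0)
  if (!is.null(radio) && is.null(fp))
    stop("radiation forecasts need `fp` (dose and fixed constants)",
         call. = FALSE)
  N0 <- diameter_to_cells(start_diameter, D0)
  times <- seq(0, horizon, by = step)
  N <- if (!is.null(chemo) && !is.null(radio)) {
    solve_crt(growth, chemo, radio, fp, N0, times)$N
  } else if (!is.null(radio)) {
    solve_radio(growth, radio, fp, N0, times)$N
  } else if (!is.null(chemo)) {
    solve_chemo(growth, chemo, N0, times)
  } else {
    solve_logistic(growth, N0, times)
  }
  data.frame(day = times,
             diameter_um = cells_to_diameter(pmax(N, .Machine$double.eps),
                                             D0))
}

# ---- full study orchestration --------------------------------------------

.group_key <- function(line, arm, dose) {
  paste0(line, ".", arm, if (dose > 0) dose else "")
}

.summary_means <- function(fits, params) {
  s <- tryCatch(population_summary(fits, params), error = function(e) NULL)
  if (is.null(s)) {
    # too few identified estimates for some parameter (small groups):
    # fall back to summarizing all converged fits
    warning("falling back to unfiltered parameter means for a small group",
            call. = FALSE)
    s <- population_summary(fits, params, drop_at_bound = FALSE)
  }
  stats::setNames(s$mean, s$parameter)
}

#' Run the full calibration pipeline on a study dataset
#'
#' Executes the group-wise calibration protocol in dependency order:
#' control fits give line-level average growth parameters; these feed the
#' chemotherapy fits and the chemoradiation fits; radiotherapy fits (per
#' dose) supply the fixed radiation component of the chemoradiation
#' fixed-R scheme, and chemotherapy fits supply the fixed chemo component
#' of the contrasting fixed-C scheme.  Writes per-organoid parameter and
#' goodness-of-fit tables, group summaries, an across-line comparison, a
#' treatment-response table, killing curves, 12-day forecast curves from a
#' 100-um start, and a JSON manifest with the seed and file hashes.
#'
#' @param dataset A [study_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list (see [default_study_config()]).
#' @param quiet Suppress progress messages.
#'
#' @return Invisibly, a list with the result tables and the manifest.
#' @export
run_study <- function(dataset, out_dir, config = default_study_config(),
                      quiet = FALSE) {
  stopifnot(inherits(dataset, "study_dataset"))
  config <- utils::modifyList(default_study_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  D0 <- config$D0
  seed <- config$seed
  ns <- config$n_starts

  trajs <- dataset$trajectories
  keys <- vapply(trajs, function(tr) .group_key(tr$line_id, tr$arm, tr$dose),
                 "")
  by_group <- split(trajs, keys)
  meta <- lapply(by_group, function(g)
    list(line = g[[1]]$line_id, arm = g[[1]]$arm, dose = g[[1]]$dose))
  lines <- unique(vapply(meta, `[[`, "", "line"))

  fits <- list()        # key -> list of pdto_fit (scheme crt uses suffix)
  growth_by_line <- list()
  k_by_line <- list()

  # stage 1: control
  for (line in lines) {
    key <- .group_key(line, "control", 0)
    if (is.null(by_group[[key]])) {
      treated <- any(vapply(meta, function(m)
        m$line == line && m$arm != "control", TRUE))
      if (treated)
        stop(sprintf("line %s has treated arms but no control arm; control fits are a prerequisite",
                     line), call. = FALSE)
      next
    }
    say("fitting control arm, line %s (%d organoids)", line,
        length(by_group[[key]]))
    fits[[key]] <- lapply(by_group[[key]], fit_control, D0 = D0,
                          n_starts = ns, seed = seed)
    m <- .summary_means(fits[[key]], c("lam", "DK"))
    k_by_line[[line]] <- diameter_to_cells(m[["DK"]], D0)
    growth_by_line[[line]] <- growth_params(m[["lam"]], k_by_line[[line]])
  }

  # stage 2: chemotherapy
  for (key in names(by_group)) {
    m <- meta[[key]]
    if (m$arm != "chemo") next
    say("fitting chemotherapy arm, line %s (%d organoids)", m$line,
        length(by_group[[key]]))
    fits[[key]] <- lapply(by_group[[key]], fit_chemo,
                          growth = growth_by_line[[m$line]], D0 = D0,
                          n_starts = ns, seed = seed)
  }

  # stage 3: radiotherapy
  for (key in names(by_group)) {
    m <- meta[[key]]
    if (m$arm != "rt") next
    say("fitting radiotherapy arm, line %s at %g Gy (%d organoids)",
        m$line, m$dose, length(by_group[[key]]))
    fp <- radio_fixed_params(m$dose, config$mu, config$alpha, config$beta)
    fits[[key]] <- lapply(by_group[[key]], function(tr)
      suppressWarnings(fit_radio(tr, fp, K = k_by_line[[m$line]], D0 = D0,
                                 n_starts = ns, seed = seed)))
  }

  # stage 4: chemoradiation, both decomposition schemes
  for (key in names(by_group)) {
    m <- meta[[key]]
    if (m$arm != "crt") next
    rt_key <- .group_key(m$line, "rt", m$dose)
    if (is.null(fits[[rt_key]]))
      stop(sprintf("chemoradiation arm %s needs radiotherapy fits for line %s at %g Gy (same line and dose)",
                   key, m$line, m$dose), call. = FALSE)
    ch_key <- .group_key(m$line, "chemo", 0)
    if (is.null(fits[[ch_key]]))
      stop(sprintf("chemoradiation arm %s needs chemotherapy fits for line %s",
                   key, m$line), call. = FALSE)
    say("fitting chemoradiation arm, line %s at %g Gy (%d organoids)",
        m$line, m$dose, length(by_group[[key]]))
    fp <- radio_fixed_params(m$dose, config$mu, config$alpha, config$beta)
    rm_ <- .summary_means(fits[[rt_key]], c("u1", "u2", "T1", "T2"))
    radio <- radio_kill_params(rm_[["u1"]], rm_[["u2"]], rm_[["T1"]],
                               rm_[["T2"]])
    cm <- .summary_means(fits[[ch_key]], c("a", "b", "Tc"))
    chemo <- chemo_kill_params(cm[["a"]], cm[["b"]], cm[["Tc"]])
    fits[[paste0(key, ".fixed_R")]] <-
      lapply(by_group[[key]], fit_crt_fixed_radio,
             growth = growth_by_line[[m$line]], radio = radio, fp = fp,
             D0 = D0, n_starts = ns, seed = seed)
    fits[[paste0(key, ".fixed_C")]] <-
      lapply(by_group[[key]], function(tr)
        suppressWarnings(fit_crt_fixed_chemo(tr, chemo = chemo, fp = fp,
                                             K = k_by_line[[m$line]],
                                             D0 = D0, n_starts = ns,
                                             seed = seed)))
  }

  # ---- tables ----
  org_rows <- list(); gof_rows <- list(); sum_rows <- list()
  for (key in names(fits)) {
    flist <- fits[[key]]
    scheme <- flist[[1]]$scheme
    m <- meta[[sub("\\.fixed_[RC]$", "", key)]]
    for (i in seq_along(flist)) {
      f <- flist[[i]]
      id <- by_group[[sub("\\.fixed_[RC]$", "", key)]][[i]]$organoid_id
      cf <- coef(f)
      org_rows[[length(org_rows) + 1L]] <-
        data.frame(line_id = m$line, arm = m$arm, dose_gy = m$dose,
                   scheme = scheme, organoid_id = id,
                   parameter = names(cf), value = unname(cf),
                   stringsAsFactors = FALSE)
      gof_rows[[length(gof_rows) + 1L]] <-
        data.frame(line_id = m$line, arm = m$arm, dose_gy = m$dose,
                   scheme = scheme, organoid_id = id,
                   n_points = f$n_points, sse = f$sse, nmse = f$nmse,
                   aic = f$aic, bic = f$bic, converged = f$converged,
                   stringsAsFactors = FALSE)
    }
    s <- tryCatch(population_summary(flist), error = function(e)
      population_summary(flist, drop_at_bound = FALSE))
    sum_rows[[length(sum_rows) + 1L]] <-
      cbind(data.frame(line_id = m$line, arm = m$arm, dose_gy = m$dose,
                       scheme = scheme, stringsAsFactors = FALSE), s)
  }
  params_tbl <- do.call(rbind, c(org_rows, list(make.row.names = FALSE)))
  gof_tbl <- do.call(rbind, c(gof_rows, list(make.row.names = FALSE)))
  summary_tbl <- do.call(rbind, c(sum_rows, list(make.row.names = FALSE)))

  ctrl_keys <- names(fits)[vapply(names(fits), function(k)
    !is.null(meta[[k]]) && meta[[k]]$arm == "control", TRUE)]
  lines_tbl <- if (length(ctrl_keys) >= 2L &&
                   all(lengths(fits[ctrl_keys]) >= 3L)) {
    byl <- stats::setNames(fits[ctrl_keys],
                           vapply(ctrl_keys, function(k) meta[[k]]$line, ""))
    compare_lines(byl, params = c("lam", "DK"))
  } else NULL

  tr_tbl <- treatment_response_table(dataset, growth_by_line)

  # killing curves and forecasts from the group-level mean parameters
  grid <- seq(0, 14, by = 0.05)
  kc_rows <- list(); fc_rows <- list()
  for (key in names(by_group)) {
    m <- meta[[key]]
    g <- growth_by_line[[m$line]]
    chemo <- radio <- fp <- NULL
    if (m$arm == "chemo") {
      cm <- .summary_means(fits[[key]], c("a", "b", "Tc"))
      chemo <- chemo_kill_params(cm[["a"]], cm[["b"]], cm[["Tc"]])
    } else if (m$arm == "rt") {
      rm_ <- .summary_means(fits[[key]], c("lam", "u1", "u2", "T1", "T2"))
      radio <- radio_kill_params(rm_[["u1"]], rm_[["u2"]], rm_[["T1"]],
                                 rm_[["T2"]])
      fp <- radio_fixed_params(m$dose, config$mu, config$alpha, config$beta)
      g <- growth_params(rm_[["lam"]], k_by_line[[m$line]])
    } else if (m$arm == "crt") {
      cm <- .summary_means(fits[[paste0(key, ".fixed_R")]],
                           c("a", "b", "Tc"))
      chemo <- chemo_kill_params(cm[["a"]], cm[["b"]], cm[["Tc"]])
      rm_ <- .summary_means(fits[[.group_key(m$line, "rt", m$dose)]],
                            c("u1", "u2", "T1", "T2"))
      radio <- radio_kill_params(rm_[["u1"]], rm_[["u2"]], rm_[["T1"]],
                                 rm_[["T2"]])
      fp <- radio_fixed_params(m$dose, config$mu, config$alpha, config$beta)
    }
    if (!is.null(chemo) || !is.null(radio)) {
      kc <- killing_curves(chemo, radio, grid)
      kc_rows[[length(kc_rows) + 1L]] <-
        cbind(data.frame(line_id = m$line, arm = m$arm, dose_gy = m$dose,
                         stringsAsFactors = FALSE), kc)
    }
    fc <- forecast_growth(g, chemo, radio, fp, D0 = D0)
    fc_rows[[length(fc_rows) + 1L]] <-
      cbind(data.frame(line_id = m$line, arm = m$arm, dose_gy = m$dose,
                       stringsAsFactors = FALSE), fc)
  }
  curves_tbl <- do.call(rbind, c(kc_rows, list(make.row.names = FALSE)))
  forecast_tbl <- do.call(rbind, c(fc_rows, list(make.row.names = FALSE)))

  write_tbl <- function(tbl, file) {
    if (is.null(tbl)) return(NULL)
    path <- file.path(out_dir, file)
    num <- vapply(tbl, is.numeric, TRUE)
    tbl[num] <- lapply(tbl[num], function(x) formatC(x, digits = 10,
                                                     format = "g"))
    utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
    path
  }
  files <- c(write_tbl(params_tbl, "organoid_params.csv"),
             write_tbl(gof_tbl, "goodness_of_fit.csv"),
             write_tbl(summary_tbl, "summary_params.csv"),
             write_tbl(lines_tbl, "line_comparison.csv"),
             write_tbl(tr_tbl, "treatment_response.csv"),
             write_tbl(curves_tbl, "killing_curves.csv"),
             write_tbl(forecast_tbl, "forecasts.csv"))

  manifest <- list(
    package = "pdtogrowth",
    version = as.character(utils::packageVersion("pdtogrowth")),
    seed = seed, n_starts = ns,
    fixed = list(D0 = D0, mu = config$mu, alpha = config$alpha,
                 beta = config$beta),
    n_trajectories = length(trajs),
    groups = names(by_group),
    hashes = as.list(tools::md5sum(files)))
  names(manifest$hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report bundle written to %s", out_dir)

  invisible(list(fits = fits, params = params_tbl, gof = gof_tbl,
                 summary = summary_tbl, line_comparison = lines_tbl,
                 treatment_response = tr_tbl, killing_curves = curves_tbl,
                 forecasts = forecast_tbl, manifest = manifest))
}
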