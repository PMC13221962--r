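#' Convert organoid diameter to cell number
#'
#' Assuming spherical organoids built from cells of average diameter `D0`
#' (22.5 um for pancreatic tumor cells), the cell number of an organoid of
#' diameter `D` is approximated by `(D / D0)^3`.
#'
#' @param D Organoid diameter(s) in um, > 0.
#' @param D0 Average single-cell diameter in um, > 0.
#'
#' @return Estimated cell count(s); strictly increasing in `D`.
#' @examples
#' diameter_to_cells(100)        # ~88 cells
#' diameter_to_cells(45, 22.5)   # doubling the diameter octuples the count
#' @export
diameter_to_cells <- function(D, D0 = 22.5) {
  stopifnot(is.numeric(D), is.numeric(D0), length(D0) == 1L)
  if (any(!is.finite(D)) || any(D <= 0)) stop("`D` must be positive", call. = FALSE)
  if (!is.finite(D0) || D0 <= 0) stop("`D0` must be positive", call. = FALSE)
  (D / D0)^3
}

#' Convert cell number to organoid diameter
#'
#' Exact inverse of [diameter_to_cells()]: `D = D0 * N^(1/3)`.  At the
#' carrying capacity `K` this gives the maximum diameter
#' `D_K = D0 * K^(1/3)`.
#'
#' @param N Cell count(s), > 0.
#' @param D0 Average single-cell diameter in um, > 0.
#'
#' @return Diameter(s) in um.
#' @examples
#' cells_to_diameter(diameter_to_cells(302.8))  # 302.8
#' @export
cells_to_diameter <- function(N, D0 = 22.5) {
  stopifnot(is.numeric(N), is.numeric(D0), length(D0) == 1L)
  if (any(!is.finite(N)) || any(N <= 0)) stop("`N` must be positive", call. = FALSE)
  if (!is.finite(D0) || D0 <= 0) stop("`D0` must be positive", call. = FALSE)
  D0 * N^(1 / 3)
}

.arms <- c("control", "chemo", "rt", "crt")

#' One organoid's measured trajectory
#'
#' @param organoid_id,line_id Identifier strings (line e.g. `"7800"`).
#' @param arm Treatment arm: one of `"control"`, `"chemo"`, `"rt"`, `"crt"`.
#' @param dose Radiation dose in Gy (0 for non-irradiated arms; > 0 required
#'   for `"rt"` and `"crt"`).
#' @param days Strictly increasing measurement days.
#' @param diameters Positive measured diameters in um, one per day.
#'
#' @return An object of class `organoid_trajectory`.
#' @export
organoid_trajectory <- function(organoid_id, line_id, arm, dose, days,
                                diameters) {
  arm <- match.arg(arm, .arms)
  stopifnot(is.character(as.character(organoid_id)), length(organoid_id) == 1L,
            length(line_id) == 1L,
            is.numeric(dose), length(dose) == 1L, is.finite(dose),
            is.numeric(days), is.numeric(diameters))
  if (length(days) != length(diameters))
    stop("`days` and `diameters` must have equal length", call. = FALSE)
  if (length(days) < 1L) stop("trajectory must have >= 1 point", call. = FALSE)
  if (anyNA(days) || anyNA(diameters))
    stop("missing values in trajectory", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE))
    stop("`days` must be strictly increasing", call. = FALSE)
  if (any(diameters <= 0)) stop("`diameters` must be > 0", call. = FALSE)
  if (arm %in% c("rt", "crt") && dose <= 0)
    stop("irradiated arms require `dose` > 0 Gy", call. = FALSE)
  if (dose < 0) stop("`dose` must be >= 0", call. = FALSE)
  structure(list(organoid_id = as.character(organoid_id),
                 line_id = as.character(line_id),
                 arm = arm, dose = dose,
                 days = as.numeric(days),
                 diameters = as.numeric(diameters)),
            class = "organoid_trajectory")
}

#' A study dataset of organoid trajectories
#'
#' @param trajectories A list of [organoid_trajectory()] objects.
#' @param D0 Reference single-cell diameter in um.
#'
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(trajectories, D0 = 22.5) {
  stopifnot(is.list(trajectories),
            all(vapply(trajectories, inherits, TRUE, "organoid_trajectory")),
            is.numeric(D0), length(D0) == 1L, D0 > 0)
  structure(list(trajectories = trajectories, D0 = D0),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  df <- as.data.frame(x)
  groups <- unique(df[, c("line_id", "arm", "dose_gy")])
  cat(sprintf("study_dataset: %d trajectories, %d line/arm/dose groups, D0 = %g um\n",
              length(x$trajectories), nrow(groups), x$D0))
  invisible(x)
}

#' Flatten a study dataset to the long CSV layout
#'
#' @param x A `study_dataset`.
#' @param row.names,optional,... Passed for S3 compatibility (unused).
#' @return A data frame with columns `organoid_id`, `line_id`, `arm`,
#'   `dose_gy`, `day`, `diameter_um`.
#' @export
as.data.frame.study_dataset <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  rows <- lapply(x$trajectories, function(tr) {
    data.frame(organoid_id = tr$organoid_id, line_id = tr$line_id,
               arm = tr$arm, dose_gy = tr$dose,
               day = tr$days, diameter_um = tr$diameters,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(organoid_id = character(), line_id = character(),
                      arm = character(), dose_gy = numeric(),
                      day = numeric(), diameter_um = numeric())
  out
}

.study_cols <- c("organoid_id", "line_id", "arm", "dose_gy", "day",
                 "diameter_um")

#' Read a study dataset from CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `organoid_id,line_id,arm,dose_gy,day,diameter_um`.  Rows are grouped into
#' per-organoid trajectories sorted by day; duplicate (organoid, day) pairs,
#' missing columns and non-numeric fields are reported as errors naming the
#' offending row.
#'
#' @param path File path.
#' @param D0 Reference single-cell diameter in um.
#'
#' @return A [study_dataset()].
#' @export
read_study_csv <- function(path, D0 = 22.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(.study_cols, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(study_dataset(list(), D0 = D0))
  for (col in c("dose_gy", "day", "diameter_um")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric `%s` in data row %d", col, bad[1]),
           call. = FALSE)
    df[[col]] <- val
  }
  key <- paste(df$organoid_id, df$day, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (organoid_id, day) pair in data row %d (%s, day %g)",
                 dup[1], df$organoid_id[dup[1]], df$day[dup[1]]), call. = FALSE)
  trajs <- lapply(split(df, factor(df$organoid_id, unique(df$organoid_id))),
                  function(d) {
    d <- d[order(d$day), , drop = FALSE]
    if (length(unique(d$line_id)) != 1L || length(unique(d$arm)) != 1L ||
        length(unique(d$dose_gy)) != 1L)
      stop(sprintf("inconsistent metadata for organoid %s", d$organoid_id[1]),
           call. = FALSE)
    organoid_trajectory(d$organoid_id[1], d$line_id[1], d$arm[1],
                        d$dose_gy[1], d$day, d$diameter_um)
  })
  study_dataset(unname(trajs), D0 = D0)
}

#' Write a study dataset to CSV
#'
#' Writes the long-format layout read back by [read_study_csv()]; numeric
#' values keep 10 significant digits so that write/read round trips are the
#' identity well past the 6 significant digits of the interchange contract.
#'
#' @param dataset A [study_dataset()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_study_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  df <- as.data.frame(dataset)
  for (col in c("dose_gy", "day", "diameter_um"))
    df[[col]] <- formatC(df[[col]], digits = 10, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study configuration file
#'
#' Reads a YAML file carrying the fixed observation and calibration
#' constants.  Any missing entry falls back to the default configuration
#' ([default_study_config()]).
#'
#' @param path Path to a YAML file.
#' @return A named list (see [default_study_config()] for fields).
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_study_config(), cfg)
}

#' Default study configuration
#'
#' Fixed constants of the calibration protocol: reference cell diameter
#' `D0` = 22.5 um, inactive-cell removal rate `mu` = 0.3/day,
#' linear-quadratic `alpha` = 0.015/Gy and `beta` = `alpha`/9.5/Gy^2, the
#' per-arm measurement day grids (days 0,2,4,6,7, extended to day 9 for
#' radiotherapy), the multi-start random seed and the number of starts.
#'
#' @return A named list of configuration values.
#' @export
default_study_config <- function() {
  list(D0 = 22.5, mu = 0.3, alpha = 0.015, beta = 0.015 / 9.5,
       days_standard = c(0, 2, 4, 6, 7),
       days_rt = c(0, 2, 4, 6, 7, 8, 9),
       seed = 20260303, n_starts = 10)
}
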