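LIMB_PAIRS <- list(
  c("right_hand", "left_hand"), c("right_hand", "right_foot"),
  c("right_hand", "left_foot"), c("left_hand", "right_foot"),
  c("left_hand", "left_foot"), c("right_foot", "left_foot"))

pair_name <- function(p) paste(p, collapse = "__")

#' Compute the full kinematic feature battery
#'
#' Assembles, from the four preprocessed limb trajectories of one recording:
#' mean velocity and mean acceleration per limb (head lengths per frame,
#' with per-second variants); the zero-lag cross-correlation of the smoothed
#' speed series for all six limb pairs; the area from the moving average per
#' limb and axis plus the upper-limb and lower-limb totals; and the
#' mean-crossing periodicity summary (total intersections, mean and SD of
#' crossing distances, periodicity) per limb, pooled over axes, with
#' per-axis values retained. Every feature that cannot be computed is `NA`
#' (an explicit undefined marker), never a silent zero.
#'
#' @param trajs named list of four [limb_trajectory] objects (preprocessed:
#'   head-length units, body frame, gaps filled). Trajectories may have a
#'   third (z) column; velocity uses all coordinates, per-axis features are
#'   emitted for every column.
#' @param fps frame rate (Hz); defaults to the first trajectory's.
#' @param ama_window moving-average window (samples).
#' @param ama_literal see [area_from_moving_average].
#' @param periodicity_window mean-crossing window (samples).
#' @param cc_filtered use Butterworth-smoothed speeds for cross-correlation
#'   (default) or raw speeds.
#' @return Object of class `kinematic_features`.
#' @export
compute_kinematic_features <- function(trajs, fps = NULL, ama_window = 30,
                                       ama_literal = FALSE,
                                       periodicity_window = 500,
                                       cc_filtered = TRUE) {
  stopifnot(is.list(trajs))
  if (!all(LIMBS %in% names(trajs)))
    stop("trajs must be named by the four limbs", call. = FALSE)
  if (is.null(fps)) fps <- trajs[[1]]$fps

  vel <- lapply(trajs[LIMBS], velocity, fps = fps)
  vel_cc <- if (cc_filtered) vel else lapply(trajs[LIMBS], velocity, fps = fps, filter = FALSE)
  acc <- lapply(vel, function(v) acceleration(v$speed))

  cc <- lapply(LIMB_PAIRS, function(p)
    cross_correlation(vel_cc[[p[1]]]$speed, vel_cc[[p[2]]]$speed))
  names(cc) <- vapply(LIMB_PAIRS, pair_name, "")

  ama <- lapply(trajs[LIMBS], function(tr) {
    per_axis <- vapply(seq_len(ncol(tr$points)), function(j)
      area_from_moving_average(tr$points[, j], k = ama_window,
                               literal = ama_literal), 0)
    names(per_axis) <- colnames(tr$points)
    per_axis
  })
  sum_or_na <- function(vals) if (anyNA(vals)) NA_real_ else sum(vals)
  ama_upper <- sum_or_na(c(ama$right_hand[c("x", "y")], ama$left_hand[c("x", "y")]))
  ama_lower <- sum_or_na(c(ama$right_foot[c("x", "y")], ama$left_foot[c("x", "y")]))

  per <- lapply(trajs[LIMBS], function(tr)
    periodicity(tr$points, window = periodicity_window))

  structure(
    list(
      fps = fps,
      mean_velocity = vapply(vel, `[[`, 0, "mean"),
      mean_velocity_per_s = vapply(vel, `[[`, 0, "mean_per_s"),
      mean_acceleration = vapply(acc, `[[`, 0, "mean"),
      cross_correlation = unlist(cc),
      ama = ama, ama_upper = ama_upper, ama_lower = ama_lower,
      periodicity = per),
    class = "kinematic_features")
}

#' @export
print.kinematic_features <- function(x, ...) {
  cat("kinematic_features\n")
  cat("  mean velocity (hl/frame):",
      paste(sprintf("%s=%.4g", names(x$mean_velocity), x$mean_velocity),
            collapse = " "), "\n")
  cat("  mean acceleration      :",
      paste(sprintf("%s=%.4g", names(x$mean_acceleration), x$mean_acceleration),
            collapse = " "), "\n")
  cat("  cross-correlation      :",
      paste(sprintf("%.3f", x$cross_correlation), collapse = " "), "\n")
  cat("  A_ma upper/lower       :",
      sprintf("%.4g / %.4g", x$ama_upper, x$ama_lower), "\n")
  p <- vapply(x$periodicity, `[[`, 0, "p")
  cat("  periodicity            :",
      paste(sprintf("%s=%.4g", names(p), p), collapse = " "), "\n")
  invisible(x)
}

#' Flatten a feature battery to a tidy table
#'
#' One row per feature x limb/pair/axis, columns `feature`, `limb`, `axis`,
#' `value`. Undefined features appear with `NA` values.
#'
#' @param x a `kinematic_features` or `motion_features` object.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.kinematic_features <- function(x, ...) {
  rows <- list()
  add <- function(feature, limb, axis, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, limb = limb, axis = axis, value = unname(value),
      stringsAsFactors = FALSE)
  for (lb in LIMBS) {
    add("mean_velocity", lb, NA, x$mean_velocity[[lb]])
    add("mean_velocity_per_s", lb, NA, x$mean_velocity_per_s[[lb]])
    add("mean_acceleration", lb, NA, x$mean_acceleration[[lb]])
    for (ax in names(x$ama[[lb]])) add("ama", lb, ax, x$ama[[lb]][[ax]])
    pr <- x$periodicity[[lb]]
    add("t_in", lb, NA, pr$t_in)
    add("d_bar", lb, NA, pr$d_bar)
    add("sigma_d", lb, NA, pr$sigma_d)
    add("periodicity", lb, NA, pr$p)
    for (ax in names(pr$per_axis)) {
      add("t_in", lb, ax, pr$per_axis[[ax]]$t_in)
      add("d_bar", lb, ax, pr$per_axis[[ax]]$d_bar)
      add("periodicity", lb, ax, pr$per_axis[[ax]]$p)
    }
  }
  for (nm in names(x$cross_correlation))
    add("cross_correlation", nm, NA, x$cross_correlation[[nm]])
  add("ama_total", "upper", NA, x$ama_upper)
  add("ama_total", "lower", NA, x$ama_lower)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature set to disk
#'
#' JSON (nested, `NA` written as `null` with an explicit `"undefined"`
#' marker semantics) or tidy CSV (one row per feature x limb/pair/axis,
#' empty cells for undefined values).
#'
#' @param fs a `kinematic_features` or `motion_features` object (or a named
#'   list combining both).
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_features <- function(fs, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    strip <- function(z) {
      if (inherits(z, "kinematic_features") || inherits(z, "motion_features"))
        z <- unclass(z)
      if (is.list(z) && !is.data.frame(z)) return(lapply(z, strip))
      if (is.atomic(z) && !is.null(names(z))) return(as.list(z))
      z
    }
    jsonlite::write_json(strip(fs), path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    df <- if (is.data.frame(fs)) fs else as.data.frame(fs)
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
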