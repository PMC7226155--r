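#' Limb trajectories
#'
#' A `limb_trajectory` holds the per-frame coordinates of one tracked end
#' effector: an `N x 2` (or `N x 3` for depth-augmented data) matrix of
#' points, a logical mask of missing frames (skipped or failed), and the
#' frame indices at which the point was (re)set externally. Frame indices are
#' 0-based; frame 0 is always a reset (the initial selection) for tracker
#' output. Points at missing frames are `NA` and never used.
#'
#' @param points `N x 2` or `N x 3` numeric matrix (columns x, y[, z]).
#' @param missing logical vector of length `N`; defaults to rows with any NA.
#' @param limb one of `"right_hand"`, `"left_hand"`, `"right_foot"`,
#'   `"left_foot"` (or `NA` for anonymous series).
#' @param resets integer vector of 0-based frame indices set externally.
#' @param units `"px"` or `"hl"` (head lengths).
#' @param fps optional frame rate (Hz) carried for convenience.
#' @return An object of class `limb_trajectory`.
#' @export
limb_trajectory <- function(points, missing = NULL, limb = NA_character_,
                            resets = integer(0), units = "px", fps = NULL) {
  points <- as.matrix(points)
  if (!ncol(points) %in% c(2L, 3L))
    stop("'points' must have 2 or 3 columns", call. = FALSE)
  n <- nrow(points)
  if (is.null(missing)) missing <- apply(points, 1, anyNA)
  missing <- as.logical(missing)
  if (length(missing) != n)
    stop("'missing' length must match number of rows", call. = FALSE)
  points[missing, ] <- NA_real_
  colnames(points) <- c("x", "y", "z")[seq_len(ncol(points))]
  structure(
    list(points = points, missing = missing, limb = limb,
         resets = as.integer(resets), units = units, fps = fps,
         n = n),
    class = "limb_trajectory")
}

#' @export
print.limb_trajectory <- function(x, ...) {
  cat(sprintf("limb_trajectory [%s]: %d frames (%d missing, %d reset), units=%s\n",
              x$limb, x$n, sum(x$missing), length(x$resets), x$units))
  invisible(x)
}

LIMBS <- c("right_hand", "left_hand", "right_foot", "left_foot")

#' Write a set of limb trajectories to CSV
#'
#' One file per recording, long format: columns `frame` (0-based), `limb`,
#' `x`, `y`[, `z`], `missing` (0/1), `reset` (0/1); missing rows carry empty
#' coordinates. Pixel or head-length units, as stored.
#'
#' @param trajs named list of [limb_trajectory] objects.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectories <- function(trajs, path) {
  stopifnot(is.list(trajs), length(trajs) >= 1)
  rows <- lapply(trajs, function(tr) {
    n <- tr$n
    d <- data.frame(frame = seq_len(n) - 1L,
                    limb = rep(tr$limb, n),
                    x = tr$points[, 1], y = tr$points[, 2])
    if (ncol(tr$points) == 3) d$z <- tr$points[, 3]
    d$missing <- as.integer(tr$missing)
    d$reset <- as.integer((seq_len(n) - 1L) %in% tr$resets)
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read limb trajectories from CSV
#'
#' Inverse of [write_trajectories].
#'
#' @param path CSV path.
#' @param units unit label to attach (`"px"` or `"hl"`).
#' @param fps optional frame rate (Hz).
#' @return Named list of [limb_trajectory] objects.
#' @export
read_trajectories <- function(path, units = "px", fps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "limb", "x", "y", "missing")
  if (!all(need %in% names(d)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(d, d$limb), function(dd) {
    dd <- dd[order(dd$frame), ]
    cols <- c("x", "y", if ("z" %in% names(dd) && !all(is.na(dd$z))) "z")
    pts <- as.matrix(dd[, cols, drop = FALSE])
    resets <- if ("reset" %in% names(dd)) dd$frame[dd$reset == 1] else integer(0)
    limb_trajectory(pts, missing = dd$missing == 1, limb = dd$limb[1],
                    resets = resets, units = units, fps = fps)
  })
  # keep canonical limb order when present
  known <- intersect(LIMBS, names(out))
  out[c(known, setdiff(names(out), known))]
}

# valid (non-missing) index helper
valid_idx <- function(tr) which(!tr$missing)
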