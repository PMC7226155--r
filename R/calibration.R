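#' Per-video calibration
#'
#' The operator supplies two line segments on a frame where they are clearly
#' visible: the head line, from forehead to chin, whose pixel length is the
#' anthropometric unit used to normalize all trajectories; and the body
#' symmetry line, from the midpoint of the clavicle line to the midpoint of
#' the inferior margin of the pelvis, which fixes the body orientation in the
#' image.
#'
#' @param head_line 2 x 2 matrix (rows = endpoints, columns = x, y; pixels),
#'   forehead first, chin second.
#' @param symmetry_line 2 x 2 matrix, clavicle midpoint first, pelvis second.
#' @param frame_size optional `c(width, height)`; endpoints are validated
#'   against it when given.
#' @return Object of class `calibration` with fields `head_line`,
#'   `symmetry_line`, `head_length` (pixels) and `body_angle` (radians,
#'   signed angle of the symmetry line relative to the image +y axis).
#' @export
calibration <- function(head_line, symmetry_line, frame_size = NULL) {
  head_line <- as_endpoints(head_line, "head_line")
  symmetry_line <- as_endpoints(symmetry_line, "symmetry_line")
  hl <- sqrt(sum((head_line[2, ] - head_line[1, ])^2))
  if (hl <= 0)
    stop("calibration error: coincident head-line endpoints", call. = FALSE)
  u <- symmetry_line[2, ] - symmetry_line[1, ]
  if (sqrt(sum(u^2)) <= 0)
    stop("calibration error: degenerate symmetry line", call. = FALSE)
  if (!is.null(frame_size)) {
    pts <- rbind(head_line, symmetry_line)
    if (any(pts[, 1] < 0 | pts[, 1] > frame_size[1] - 1 |
            pts[, 2] < 0 | pts[, 2] > frame_size[2] - 1))
      stop("calibration error: endpoints outside frame bounds", call. = FALSE)
  }
  structure(
    list(head_line = head_line, symmetry_line = symmetry_line,
         head_length = hl,
         body_angle = atan2(u[1], u[2])),
    class = "calibration")
}

as_endpoints <- function(m, what) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 2)) || !is.numeric(m) || anyNA(m))
    stop("'", what, "' must be a numeric 2x2 matrix of endpoints", call. = FALSE)
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: head length %.3f px, body angle %.2f deg from +y\n",
              x$head_length, x$body_angle * 180 / pi))
  invisible(x)
}

#' Head length of a calibration
#'
#' Euclidean distance between the head-line endpoints, in pixels: the unit
#' all trajectories are expressed in after normalization.
#'
#' @param cal a [calibration].
#' @return Length in pixels.
#' @export
head_length <- function(cal) {
  stopifnot(inherits(cal, "calibration"))
  cal$head_length
}

#' Normalize a trajectory by head length
#'
#' Divides every coordinate by the calibration's head length, converting the
#' trajectory from pixels into head-length units; the missing mask is
#' preserved. Linear: `normalize(a * traj) == a * normalize(traj)`.
#'
#' @param traj a [limb_trajectory] in pixels.
#' @param cal a [calibration].
#' @return A [limb_trajectory] with `units = "hl"`.
#' @export
normalize_trajectory <- function(traj, cal) {
  stopifnot(inherits(traj, "limb_trajectory"), inherits(cal, "calibration"))
  out <- traj
  out$points <- traj$points / cal$head_length
  out$units <- "hl"
  out
}

#' Rotate a trajectory into the standard body frame
#'
#' Rigidly rotates coordinates about the symmetry-line midpoint so the
#' symmetry line maps onto the image +y axis with the head end (clavicle
#' midpoint) toward smaller y. Positive rotation angles are counter-clockwise
#' in the (x right, y down) image frame. Inter-point distances are preserved;
#' per-axis feature components afterwards mean medio-lateral (x) and
#' cranio-caudal (y) consistently across videos.
#'
#' Only the first two coordinate columns are rotated; a z column, when
#' present, is carried through unchanged.
#'
#' @param traj a [limb_trajectory].
#' @param cal a [calibration]. When the trajectory is in head-length units,
#'   the rotation center is scaled accordingly.
#' @return A [limb_trajectory] in the body frame.
#' @export
reorient_trajectory <- function(traj, cal) {
  stopifnot(inherits(traj, "limb_trajectory"), inherits(cal, "calibration"))
  u <- cal$symmetry_line[2, ] - cal$symmetry_line[1, ]
  # rotation taking u to (0, 1): angle = pi/2 - atan2(uy, ux)
  a <- pi / 2 - atan2(u[2], u[1])
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ctr <- colMeans(cal$symmetry_line)
  if (identical(traj$units, "hl")) ctr <- ctr / cal$head_length
  out <- traj
  xy <- traj$points[, 1:2, drop = FALSE]
  rot <- sweep(xy, 2, ctr) %*% t(R)
  rot <- sweep(rot, 2, ctr, FUN = "+")
  out$points[, 1:2] <- rot
  out$points[traj$missing, ] <- NA_real_
  out
}

#' Read / write calibration JSON
#'
#' The on-disk form is
#' `{"head_line": [[x,y],[x,y]], "symmetry_line": [[x,y],[x,y]]}` in pixel
#' units, 0-based coordinates.
#'
#' @param path JSON file path.
#' @return [read_calibration] returns a [calibration].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path)
  if (is.null(j$head_line) || is.null(j$symmetry_line))
    stop("calibration JSON must contain head_line and symmetry_line",
         call. = FALSE)
  to_mat <- function(v) if (is.matrix(v)) v else do.call(rbind, v)
  calibration(to_mat(j$head_line), to_mat(j$symmetry_line))
}

#' @rdname read_calibration
#' @param cal a [calibration].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration"))
  jsonlite::write_json(
    list(head_line = cal$head_line, symmetry_line = cal$symmetry_line),
    path, digits = NA)
  invisible(path)
}
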