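#' Binary motion image from two consecutive frames
#'
#' Frame-differencing motion segmentation: the absolute grayscale difference
#' of the two frames is median-filtered over `median_size` x `median_size`
#' neighborhoods (salt-and-pepper removal), binarized at `> threshold`, then
#' cleaned by a `kernel_size` x `kernel_size` equally weighted averaging
#' kernel whose output is re-binarized by majority vote: a pixel survives iff
#' its neighborhood mean is at least `majority` (default 5/9, which deletes
#' isolated pixels and preserves block interiors). Both filters use
#' symmetric-reflection borders.
#'
#' @param frame_t,frame_prev frames (grayscale matrices or color arrays,
#'   0-255); color input is converted with [to_grayscale].
#' @param threshold binarization threshold on the 0-255 difference scale, or
#'   `"otsu"` for automatic selection from the difference histogram (a
#'   convenience mode beyond the fixed-threshold protocol).
#' @param median_size median-filter window (px).
#' @param kernel_size averaging-kernel window (px).
#' @param majority minimum neighborhood mean for a pixel to survive
#'   re-binarization.
#' @return `H x W` integer matrix with values in `{0, 1}`.
#' @export
motion_image <- function(frame_t, frame_prev, threshold = 15,
                         median_size = 5, kernel_size = 3, majority = 5 / 9) {
  g1 <- to_grayscale(frame_t)
  g0 <- to_grayscale(frame_prev)
  if (!all(dim(g1) == dim(g0)))
    stop("frames of mismatched size", call. = FALSE)
  d <- abs(g1 - g0)
  d <- median_filter_cpp(d, as.integer(median_size))
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(d)
  b <- (d > threshold) * 1
  a <- mean_filter_cpp(b, as.integer(kernel_size))
  out <- (a >= majority - 1e-12) * 1L
  storage.mode(out) <- "integer"
  out
}

# Otsu's threshold on an integer-binned histogram of the difference image
otsu_threshold <- function(d) {
  v <- as.integer(round(d))
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  which.max(sb) - 1L
}

#' Motion-image sequence for a whole video
#'
#' @param seq a [video_sequence] with at least 2 frames.
#' @param ... passed to [motion_image].
#' @return List of `N - 1` motion images; element `t` is the difference of
#'   frames `t` and `t - 1` (0-based source index `t = 1 .. N-1`).
#' @export
motion_images <- function(seq, ...) {
  stopifnot(inherits(seq, "video_sequence"))
  if (seq$n_frames < 2) stop("need at least 2 frames", call. = FALSE)
  gf <- gray_frames(seq)
  lapply(2:seq$n_frames, function(t) motion_image(gf[[t]], gf[[t - 1]], ...))
}

#' Quantity of motion
#'
#' Fraction of image pixels marked as moving: count of ones divided by the
#' total pixel count.
#'
#' @param mi a binary motion image.
#' @return Q in `[0, 1]`.
#' @export
quantity_of_motion <- function(mi) {
  sum(mi) / length(mi)
}

#' Centroid of motion
#'
#' Central point of the movement in one motion image: the centroid of the
#' single cluster a one-cluster k-means run on the movement pixels converges
#' to, which is exactly the arithmetic mean of the movement-pixel
#' coordinates. Undefined (NA) when no pixel moved.
#'
#' @param mi a binary motion image.
#' @return `c(x, y)` in 0-based pixel coordinates, or `c(NA, NA)`.
#' @export
centroid_of_motion <- function(mi) {
  idx <- which(mi == 1L)
  if (length(idx) == 0) return(c(x = NA_real_, y = NA_real_))
  h <- nrow(mi)
  rows <- (idx - 1L) %% h          # 0-based row = y
  cols <- (idx - 1L) %/% h         # 0-based col = x
  c(x = mean(cols), y = mean(rows))
}

#' Summary features of a motion-image sequence
#'
#' Quantity-of-motion statistics (`q_mean`, `q_sd`, `q_max`) over all motion
#' images; centroid statistics (`c_xmean`, `c_ymean`, `c_xsd`, `c_ysd`) over
#' the frames where the centroid is defined; and centroid kinematics: speed
#' as the Euclidean displacement of the centroid between consecutive defined
#' frames and acceleration as its one-lag difference, with means and SDs
#' (`v_mean`, `v_sd`, `a_mean`, `a_sd`). Gaps in the centroid series break
#' the chain (no interpolation). SDs use the `n - 1` denominator. All
#' centroid quantities are in pixels (per frame for the kinematics);
#' quantities that cannot be computed are `NA`.
#'
#' @param mis list of motion images (from [motion_images]).
#' @param fps frame rate (Hz), carried into the output for unit conversion.
#' @return Object of class `motion_features`.
#' @export
motion_feature_summary <- function(mis, fps = NULL) {
  stopifnot(is.list(mis), length(mis) >= 1)
  q <- vapply(mis, quantity_of_motion, 0)
  cent <- t(vapply(mis, centroid_of_motion, c(x = 0, y = 0)))
  ok <- !is.na(cent[, 1])
  n <- length(mis)
  v <- rep(NA_real_, n)
  if (n >= 2) {
    both <- which(ok[-1] & ok[-n]) + 1L
    d <- cent[both, , drop = FALSE] - cent[both - 1L, , drop = FALSE]
    v[both] <- sqrt(rowSums(d^2))
  }
  a <- rep(NA_real_, n)
  if (n >= 2) {
    both <- which(!is.na(v[-1]) & !is.na(v[-n])) + 1L
    a[both] <- v[both] - v[both - 1L]
  }
  stat <- function(x, f) if (any(!is.na(x))) f(x[!is.na(x)]) else NA_real_
  structure(
    list(fps = fps,
         q = q, q_mean = mean(q), q_sd = stats::sd(q), q_max = max(q),
         centroid = cent,
         c_xmean = stat(cent[, 1], mean), c_ymean = stat(cent[, 2], mean),
         c_xsd = stat(cent[, 1], stats::sd), c_ysd = stat(cent[, 2], stats::sd),
         v = v, v_mean = stat(v, mean), v_sd = stat(v, stats::sd),
         a = a, a_mean = stat(a, mean), a_sd = stat(a, stats::sd)),
    class = "motion_features")
}

#' @export
print.motion_features <- function(x, ...) {
  cat(sprintf("motion_features: %d motion image(s)\n", length(x$q)))
  cat(sprintf("  Q    mean=%.5g sd=%.5g max=%.5g\n", x$q_mean, x$q_sd, x$q_max))
  cat(sprintf("  C    x=%.4g+/-%.4g  y=%.4g+/-%.4g px\n",
              x$c_xmean, x$c_xsd, x$c_ymean, x$c_ysd))
  cat(sprintf("  V    %.4g+/-%.4g px/frame; A %.4g+/-%.4g\n",
              x$v_mean, x$v_sd, x$a_mean, x$a_sd))
  invisible(x)
}

#' @export
as.data.frame.motion_features <- function(x, ...) {
  nm <- c("q_mean", "q_sd", "q_max", "c_xmean", "c_ymean", "c_xsd", "c_ysd",
          "v_mean", "v_sd", "a_mean", "a_sd")
  data.frame(feature = nm, limb = NA, axis = NA,
             value = vapply(nm, function(k) x[[k]], 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dump motion images as a PNG sequence
#'
#' Writes each binary motion image as a 0/255 PNG for visual inspection.
#'
#' @param mis list of motion images.
#' @param path output directory.
#' @return Invisibly, the files written.
#' @export
write_motion_images <- function(mis, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(path, sprintf("motion_%06d.png", seq_along(mis)))
  for (i in seq_along(mis)) png::writePNG(mis[[i]] * 1.0, files[i])
  invisible(files)
}
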