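#' Reset providers
#'
#' Tracking is semi-automatic: when the tracker cannot locate a point, a
#' reset provider is consulted in place of the interactive operator. A
#' provider is a function `(frame, limb)` (0-based frame index) returning one
#' of `list(action = "set", point = c(x, y))` — a new point, recorded as a
#' reset; `list(action = "skip")` — the limb is not visible, the frame is
#' marked missing; or `list(action = "abstain")` — the frame is marked
#' missing and tracking re-anchors at the next provided point.
#'
#' @name reset_provider
NULL

#' @describeIn reset_provider always abstains (fully automatic tracking).
#' @export
reset_provider_none <- function() {
  function(frame, limb) list(action = "abstain")
}

#' @describeIn reset_provider replays a recorded operator session: a data
#'   frame (or CSV path) with columns `frame`, `limb`, `action` (`set`|`skip`),
#'   `x`, `y`. Abstains for unlisted frames.
#' @param script data frame or CSV path of scripted events.
#' @export
reset_provider_script <- function(script) {
  if (is.character(script)) script <- utils::read.csv(script, stringsAsFactors = FALSE)
  need <- c("frame", "limb", "action")
  if (!all(need %in% names(script)))
    stop("reset script needs columns frame, limb, action[, x, y]", call. = FALSE)
  function(frame, limb) {
    row <- script[script$frame == frame & script$limb == limb, , drop = FALSE]
    if (nrow(row) == 0) return(list(action = "abstain"))
    if (row$action[1] == "set")
      return(list(action = "set", point = c(row$x[1], row$y[1])))
    list(action = "skip")
  }
}

#' @describeIn reset_provider backed by synthetic ground truth: supplies the
#'   true point when the limb is visible at the frame, otherwise skips.
#' @param gt ground truth from [render_scene].
#' @export
reset_provider_ground_truth <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  function(frame, limb) {
    if (!limb %in% names(gt$trajectories)) return(list(action = "abstain"))
    if (!gt$visible[[limb]][frame + 1]) return(list(action = "skip"))
    list(action = "set", point = gt$trajectories[[limb]][frame + 1, ])
  }
}

# ---- pyramidal translation Lucas-Kanade ------------------------------------

# bilinear sampling of img (H x W, 0-based pixel-center coords) on the grid
# (x + ox) x (y + oy); returns matrix length(oy) x length(ox), or NULL if the
# patch leaves the image.
sample_patch <- function(img, x, y, ox, oy) {
  h <- nrow(img); w <- ncol(img)
  xs <- x + ox; ys <- y + oy
  if (min(xs) < 0 || max(xs) > w - 1 || min(ys) < 0 || max(ys) > h - 1)
    return(NULL)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  x0 <- pmin(x0, w - 2); y0 <- pmin(y0, h - 2)  # keep x0+1 in range when xs == w-1
  fx <- xs - x0; fy <- ys - y0
  # index matrices (1-based rows = y, cols = x)
  i0 <- outer(y0 + 1, (x0) * h, "+")      # img[(y0+1) + x0*h] column-major
  a <- img[i0]; b <- img[i0 + h]          # (y0, x0), (y0, x0+1)
  c2 <- img[i0 + 1]; d <- img[i0 + 1 + h] # (y0+1, x0), (y0+1, x0+1)
  FX <- matrix(fx, length(oy), length(ox), byrow = TRUE)
  FY <- matrix(fy, length(oy), length(ox))
  a * (1 - FX) * (1 - FY) + b * FX * (1 - FY) + c2 * (1 - FX) * FY + d * FX * FY
}

# one-level iterative LK: find d minimizing sum (I2(p+d+o) - I1(p+o))^2.
lk_refine <- function(img1, img2, p, d0, half, max_iter = 30, tol = 0.01) {
  off <- -half:half
  tmpl <- sample_patch(img1, p[1], p[2], off, off)
  if (is.null(tmpl)) return(NULL)
  d <- d0
  for (it in seq_len(max_iter)) {
    q <- p + d
    cur <- sample_patch(img2, q[1], q[2], off, off)
    gxp <- sample_patch(img2, q[1] + 0.5, q[2], off, off)
    gxm <- sample_patch(img2, q[1] - 0.5, q[2], off, off)
    gyp <- sample_patch(img2, q[1], q[2] + 0.5, off, off)
    gym <- sample_patch(img2, q[1], q[2] - 0.5, off, off)
    if (is.null(cur) || is.null(gxp) || is.null(gxm) || is.null(gyp) || is.null(gym))
      return(NULL)
    gx <- gxp - gxm
    gy <- gyp - gym
    err <- cur - tmpl
    G <- matrix(c(sum(gx * gx), sum(gx * gy), sum(gx * gy), sum(gy * gy)), 2, 2)
    if (abs(det(G)) < 1e-8) return(NULL)
    delta <- -solve(G, c(sum(gx * err), sum(gy * err)))
    d <- d + delta
    if (max(abs(delta)) < tol) break
  }
  d
}

downsample2 <- function(img) {
  h2 <- nrow(img) %/% 2; w2 <- ncol(img) %/% 2
  i <- seq_len(h2) * 2; j <- seq_len(w2) * 2
  (img[i - 1, j - 1] + img[i - 1, j] + img[i, j - 1] + img[i, j]) / 4
}

# pyramidal LK: track point p from img1 to img2; returns c(x, y) or NULL.
lk_track <- function(pyr1, pyr2, p, half, max_iter = 30, tol = 0.01) {
  levels <- length(pyr1)
  d <- c(0, 0)
  for (L in levels:1) {
    s <- 2^(L - 1)
    if (min(dim(pyr1[[L]])) < 2 * half + 3) next
    dl <- lk_refine(pyr1[[L]], pyr2[[L]], p / s, d / s, half,
                    max_iter = max_iter, tol = tol)
    if (is.null(dl)) {
      if (L == 1) return(NULL)
      next
    }
    d <- dl * s
  }
  p + d
}

# full KLT step with quality gates: forward track from pyr1 to pyr2, then
# window, appearance-residual, and forward-backward checks.
klt_match <- function(pyr1, pyr2, p, half, win_half, quality_threshold,
                      max_residual) {
  q <- lk_track(pyr1, pyr2, p, half)
  if (is.null(q)) return(NULL)
  if (any(abs(q - p) > win_half)) return(NULL)
  off <- -half:half
  tmpl <- sample_patch(pyr1[[1]], p[1], p[2], off, off)
  cur <- sample_patch(pyr2[[1]], q[1], q[2], off, off)
  if (is.null(tmpl) || is.null(cur)) return(NULL)
  if (mean(abs(cur - tmpl)) > max_residual) return(NULL)
  pb <- lk_track(pyr2, pyr1, q, half)
  if (is.null(pb) || sqrt(sum((pb - p)^2)) > quality_threshold) return(NULL)
  q
}

build_pyramid <- function(img, levels) {
  out <- vector("list", levels)
  out[[1]] <- img
  if (levels > 1) for (L in 2:levels) out[[L]] <- downsample2(out[[L - 1]])
  out
}

# ---- public tracking API ----------------------------------------------------

#' Track one end effector through a video
#'
#' Frame-by-frame Kanade-Lucas-Tomasi tracking of a single reference point on
#' grayscale frames. For each frame the tracker proposes a match for the
#' point of the previous frame (pyramidal translation-only Lucas-Kanade with
#' a template patch of `patch_frac` of the head length, odd-rounded). The
#' match is accepted iff its forward-backward error is at most
#' `quality_threshold` pixels AND it lies inside the axis-aligned square
#' search window of side `window_frac` of the head length centered on the
#' previous point. On rejection (or when the previous frame is missing) the
#' reset provider is consulted: a new point is recorded as a reset, a skip
#' marks the frame missing, an abstention marks it missing and tracking
#' re-anchors at the next provided point.
#'
#' @param seq a [video_sequence].
#' @param limb limb label for the output trajectory.
#' @param init_point `c(x, y)` initial selection (pixels, frame 0).
#' @param cal a [calibration] (supplies the head length that scales the
#'   search window and the template patch).
#' @param resets a reset provider (see [reset_provider]); defaults to fully
#'   automatic tracking.
#' After a skip the last valid point is retained as the anchor, so tracking
#' resumes automatically (and without a reset) if the limb reappears inside
#' the search window around where it disappeared.
#'
#' @param quality_threshold maximum forward-backward error (px) for a match
#'   to be accepted.
#' @param window_frac search-window side as a fraction of head length.
#' @param patch_frac template-patch side as a fraction of head length.
#' @param pyramid_levels number of pyramid levels.
#' @param max_residual maximum mean absolute intensity difference (0-255
#'   scale) between template and matched patch; rejects matches where the
#'   tracked appearance has vanished (e.g. the limb became hidden).
#' @return A [limb_trajectory] in pixels, with `missing` mask and `resets`
#'   (frame 0 is always a reset: the initial selection).
#' @export
track_limb <- function(seq, limb, init_point, cal,
                       resets = reset_provider_none(),
                       quality_threshold = 1.0,
                       window_frac = 0.25, patch_frac = 0.1,
                       pyramid_levels = 2, max_residual = 25) {
  stopifnot(inherits(seq, "video_sequence"), inherits(cal, "calibration"))
  if (seq$n_frames < 2) stop("video with < 2 frames", call. = FALSE)
  if (init_point[1] < 0 || init_point[1] > seq$width - 1 ||
      init_point[2] < 0 || init_point[2] > seq$height - 1)
    stop("init_point outside frame", call. = FALSE)

  hl <- cal$head_length
  win_half <- (window_frac * hl) / 2
  # floor keeps the template big enough to hold appearance structure when the
  # calibration is small; real recordings have head lengths of hundreds of px
  patch <- max(9L, round(patch_frac * hl))
  if (patch %% 2 == 0) patch <- patch + 1L
  half <- patch %/% 2

  gf <- gray_frames(seq)
  pyrs <- lapply(gf, build_pyramid, levels = pyramid_levels)

  n <- seq$n_frames
  pts <- matrix(NA_real_, n, 2)
  miss <- rep(TRUE, n)
  rst <- 0L
  pts[1, ] <- init_point
  miss[1] <- FALSE
  anchor_pt <- as.numeric(init_point)  # last valid point (template source)
  anchor_fr <- 1L

  for (t in 2:n) {
    accepted <- FALSE
    if (!is.null(anchor_pt)) {
      q <- klt_match(pyrs[[anchor_fr]], pyrs[[t]], anchor_pt, half, win_half,
                     quality_threshold, max_residual)
      if (!is.null(q)) {
        pts[t, ] <- q
        miss[t] <- FALSE
        anchor_pt <- q
        anchor_fr <- t
        accepted <- TRUE
      }
    }
    if (!accepted) {
      r <- resets(t - 1L, limb)   # 0-based frame index
      if (identical(r$action, "set")) {
        pts[t, ] <- as.numeric(r$point)
        miss[t] <- FALSE
        rst <- c(rst, t - 1L)
        anchor_pt <- as.numeric(r$point)
        anchor_fr <- t
      } else if (identical(r$action, "skip")) {
        # limb not visible: keep the anchor, try again next frame
      } else {
        anchor_pt <- NULL  # abstain: re-anchor only at the next reset
      }
    }
  }
  limb_trajectory(pts, missing = miss, limb = limb, resets = rst,
                  units = "px", fps = seq$fps)
}

#' Track all four end effectors
#'
#' Independent per-limb tracking with fixed output ordering: right hand,
#' left hand, right foot, left foot.
#'
#' @param seq a [video_sequence].
#' @param init_points named list (or 4 x 2 matrix in canonical order) of
#'   initial points.
#' @param cal a [calibration].
#' @param resets a reset provider shared across limbs.
#' @param ... further arguments passed to [track_limb].
#' @return Named list of four [limb_trajectory] objects.
#' @export
track_all <- function(seq, init_points, cal, resets = reset_provider_none(), ...) {
  if (is.matrix(init_points)) {
    stopifnot(nrow(init_points) == 4)
    init_points <- stats::setNames(lapply(seq_len(4), function(i) init_points[i, ]), LIMBS)
  }
  if (!all(LIMBS %in% names(init_points)))
    stop("init_points must cover all four limbs", call. = FALSE)
  out <- lapply(LIMBS, function(lb)
    track_limb(seq, lb, init_points[[lb]], cal, resets = resets, ...))
  stats::setNames(out, LIMBS)
}

#' Tracking failure rate
#'
#' Percentage of frames at which the point had to be re-set externally,
#' excluding the initial selection at frame 0. Skipped frames (limb not
#' visible) are not failures.
#'
#' @param traj a [limb_trajectory].
#' @return Failure rate in percent.
#' @export
failure_rate <- function(traj) {
  stopifnot(inherits(traj, "limb_trajectory"))
  100 * sum(traj$resets != 0L) / traj$n
}
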