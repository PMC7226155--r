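#' Synthetic supine-infant scenes with ground truth
#'
#' The generator emulates the geometry of a nursery recording — a camera
#' about half a metre above a supine infant on a textured blanket — at desk
#' scale: a low-contrast textured background, a head region of known pixel
#' length, and four limb blobs moving along known trajectories, optionally
#' occluded for given frame intervals, with Gaussian and salt-and-pepper
#' pixel noise. Everything is deterministic under the scene seed, with one
#' RNG stream per component (background, noise, jitter, jerky paths) so
#' toggling noise does not change trajectories.
#'
#' Defaults describe the reference benchmark condition used throughout the
#' package: a 160 x 120 px frame at 12.5 Hz for 60 s (750 frames), head
#' length 24 px, four sinusoidal limbs with periods of 3.2--6.4 s and
#' amplitudes up to 12 px, noise off.
#'
#' @param width,height frame size in pixels.
#' @param fps frame rate (Hz).
#' @param duration recording length (s).
#' @param head_line,symmetry_line calibration endpoints (2 x 2 matrices, px).
#' @param limbs named list (right_hand, left_hand, right_foot, left_foot) of
#'   blob specs: `list(radius, intensity, model = trajectory model spec)`.
#' @param occlusions named list of per-limb lists of `c(start, end)` 0-based
#'   frame intervals, end exclusive, during which the limb is not drawn.
#' @param noise list `(sigma, salt_pepper)`: Gaussian intensity SD and
#'   salt-and-pepper pixel probability.
#' @param background list `(mean, contrast, smooth)` for the textured
#'   blanket: mean gray level, texture SD, smoothing radius (px).
#' @param seed master integer seed; fully determines the rendered output.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(width = 160, height = 120, fps = 12.5, duration = 60,
                       head_line = rbind(c(80, 14), c(80, 38)),
                       symmetry_line = rbind(c(80, 44), c(80, 104)),
                       limbs = default_limbs(),
                       occlusions = list(),
                       noise = list(sigma = 0, salt_pepper = 0),
                       background = list(mean = 80, contrast = 10, smooth = 2),
                       seed = 1L) {
  spec <- structure(
    list(width = width, height = height, fps = fps, duration = duration,
         head_line = as_endpoints(head_line, "head_line"),
         symmetry_line = as_endpoints(symmetry_line, "symmetry_line"),
         limbs = limbs, occlusions = occlusions, noise = noise,
         background = background, seed = as.integer(seed)),
    class = "scene_spec")
  spec$n_frames <- as.integer(round(duration * fps))
  if (spec$n_frames < 2) stop("scene must have at least 2 frames", call. = FALSE)
  bad <- !names(limbs) %in% LIMBS
  if (length(limbs) != 4 || any(bad) || anyDuplicated(names(limbs)))
    stop("'limbs' must name exactly right_hand, left_hand, right_foot, left_foot",
         call. = FALSE)
  for (nm in names(occlusions)) {
    iv <- occlusions[[nm]]
    for (i in iv) {
      if (length(i) != 2 || i[1] < 0 || i[2] > spec$n_frames || i[1] >= i[2])
        stop("occlusion intervals must be [start,end) within [0, n_frames)",
             call. = FALSE)
    }
  }
  spec
}

default_limbs <- function() {
  sin_limb <- function(cx, cy, ax, ay, tx, ty, ph) {
    list(radius = 4, intensity = 230,
         model = list(kind = "sinusoid", center = c(cx, cy),
                      amplitude = c(ax, ay), period = c(tx, ty),
                      phase = c(ph, ph + pi / 3)))
  }
  list(
    right_hand = sin_limb(40, 55, 12, 8, 4.0, 3.2, 0),
    left_hand  = sin_limb(120, 55, 10, 9, 3.6, 4.8, 1.1),
    right_foot = sin_limb(45, 100, 11, 7, 5.6, 4.0, 2.0),
    left_foot  = sin_limb(115, 100, 9, 10, 4.8, 6.4, 0.7))
}

# Independent RNG stream per scene component, derived from the master seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic trajectory models
#'
#' Generates an `N x 2` pixel path for one limb blob. Kinds:
#' \describe{
#'   \item{constant}{fixed at `params$center`.}
#'   \item{linear}{`params$start` plus `params$velocity` (px/frame) each frame.}
#'   \item{sinusoid}{per-axis `center + amplitude * sin(2*pi*t/period + phase)`
#'     with `t` in seconds and `period` in seconds.}
#'   \item{sum_of_sinusoids}{`center` plus the sum of `params$components`,
#'     each a sinusoid spec `(amplitude, period, phase)` per axis.}
#'   \item{jerky}{seeded piecewise-linear motion between random waypoints
#'     drawn every `params$interval` seconds inside `center +/- range`.}
#' }
#'
#' @param kind model name (see above).
#' @param params named list of parameters for the kind.
#' @param n_frames number of frames.
#' @param fps frame rate (Hz).
#' @return `N x 2` matrix of pixel coordinates.
#' @export
trajectory_model <- function(kind, params, n_frames, fps) {
  t_s <- (seq_len(n_frames) - 1) / fps
  two <- function(v) if (length(v) == 1) rep(v, 2) else v
  switch(kind,
    constant = {
      matrix(rep(two(params$center), each = n_frames), n_frames, 2)
    },
    linear = {
      st <- two(params$start); v <- two(params$velocity)
      cbind(st[1] + v[1] * (seq_len(n_frames) - 1),
            st[2] + v[2] * (seq_len(n_frames) - 1))
    },
    sinusoid = {
      ctr <- two(params$center); A <- two(params$amplitude)
      Tt <- two(params$period); ph <- two(if (is.null(params$phase)) 0 else params$phase)
      cbind(ctr[1] + A[1] * sin(2 * pi * t_s / Tt[1] + ph[1]),
            ctr[2] + A[2] * sin(2 * pi * t_s / Tt[2] + ph[2]))
    },
    sum_of_sinusoids = {
      ctr <- two(params$center)
      acc <- matrix(0, n_frames, 2)
      for (cmp in params$components) {
        A <- two(cmp$amplitude); Tt <- two(cmp$period)
        ph <- two(if (is.null(cmp$phase)) 0 else cmp$phase)
        acc <- acc + cbind(A[1] * sin(2 * pi * t_s / Tt[1] + ph[1]),
                           A[2] * sin(2 * pi * t_s / Tt[2] + ph[2]))
      }
      sweep(acc, 2, ctr, FUN = "+")
    },
    jerky = {
      ctr <- two(params$center); rg <- two(params$range)
      interval <- if (is.null(params$interval)) 0.8 else params$interval
      seed <- if (is.null(params$seed)) 0L else params$seed
      step <- max(1L, as.integer(round(interval * fps)))
      n_way <- ceiling(n_frames / step) + 1L
      way <- with_seed(derive_seed(seed, "jerky"), {
        cbind(stats::runif(n_way, ctr[1] - rg[1], ctr[1] + rg[1]),
              stats::runif(n_way, ctr[2] - rg[2], ctr[2] + rg[2]))
      })
      idx <- (seq_len(n_frames) - 1) / step
      lo <- floor(idx) + 1L
      fr <- idx - (lo - 1L)
      way[lo, , drop = FALSE] * (1 - fr) + way[lo + 1L, , drop = FALSE] * fr
    },
    stop("unknown trajectory model kind: ", kind, call. = FALSE))
}

#' Render a synthetic scene
#'
#' Composites anti-aliased limb blobs over a static textured background at
#' the true trajectory centers, skips occluded limbs, then applies pixel
#' noise. The same spec and seed give bit-identical output.
#'
#' @param spec a [scene_spec].
#' @return List with `video` (a [video_sequence], grayscale) and `gt`, the
#'   ground truth: per-limb true center paths (`N x 2`, px), per-limb
#'   visibility masks, and the scene [calibration].
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$n_frames
  w <- spec$width; h <- spec$height

  paths <- lapply(spec$limbs, function(lb)
    trajectory_model(lb$model$kind, lb$model, n, spec$fps))
  for (nm in names(paths)) {
    r <- spec$limbs[[nm]]$radius
    p <- paths[[nm]]
    if (any(p[, 1] < r | p[, 1] > w - 1 - r | p[, 2] < r | p[, 2] > h - 1 - r))
      stop("config error: limb '", nm, "' leaves the frame", call. = FALSE)
  }
  visible <- lapply(names(spec$limbs), function(nm) {
    v <- rep(TRUE, n)
    for (iv in spec$occlusions[[nm]]) v[(iv[1] + 1):iv[2]] <- FALSE
    v
  })
  names(visible) <- names(spec$limbs)

  bg <- with_seed(derive_seed(spec$seed, "background"), {
    tex <- matrix(stats::rnorm(h * w), h, w)
    sm <- 2L * as.integer(spec$background$smooth) + 1L
    tex <- mean_filter_cpp(tex, sm)
    spec$background$mean + spec$background$contrast * tex / stats::sd(tex)
  })

  # pixel-center coordinate grids (0-based)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)

  frames <- vector("list", n)
  for (f in seq_len(n)) {
    img <- bg
    for (nm in names(spec$limbs)) {
      if (!visible[[nm]][f]) next
      lb <- spec$limbs[[nm]]
      c0 <- paths[[nm]][f, ]
      # anti-aliased disc: coverage ramps linearly across the rim
      rr <- sqrt((xs - c0[1])^2 + (ys - c0[2])^2)
      alpha <- pmin(1, pmax(0, lb$radius + 0.5 - rr))
      img <- img * (1 - alpha) + lb$intensity * alpha
    }
    frames[[f]] <- img
  }

  if (spec$noise$sigma > 0 || spec$noise$salt_pepper > 0) {
    frames <- with_seed(derive_seed(spec$seed, "noise"), {
      lapply(frames, function(img) {
        if (spec$noise$sigma > 0)
          img <- img + stats::rnorm(length(img), 0, spec$noise$sigma)
        if (spec$noise$salt_pepper > 0) {
          hit <- stats::runif(length(img)) < spec$noise$salt_pepper
          val <- ifelse(stats::runif(length(img)) < 0.5, 0, 255)
          img[hit] <- val[hit]
        }
        img
      })
    })
  }
  frames <- lapply(frames, function(img) {
    img <- round(img)
    img[img < 0] <- 0; img[img > 255] <- 255
    img
  })

  gt <- structure(
    list(trajectories = paths, visible = visible,
         calibration = calibration(spec$head_line, spec$symmetry_line,
                                   frame_size = c(w, h)),
         fps = spec$fps),
    class = "ground_truth")
  list(video = video_sequence(frames, spec$fps), gt = gt)
}

#' Ground truth as limb trajectories
#'
#' @param gt ground truth from [render_scene].
#' @return Named list of [limb_trajectory] (pixels; occluded frames missing).
#' @export
gt_trajectories <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  out <- lapply(names(gt$trajectories), function(nm) {
    limb_trajectory(gt$trajectories[[nm]], missing = !gt$visible[[nm]],
                    limb = nm, resets = 0L, units = "px", fps = gt$fps)
  })
  names(out) <- names(gt$trajectories)
  out
}

#' Simulate a pair of independent raters
#'
#' Produces two independently jittered copies of the ground-truth
#' trajectories, emulating two operators tracking the same recording; used
#' to exercise the inter-rater correlation and agreement statistics.
#'
#' @param gt ground truth from [render_scene].
#' @param jitter_sigma per-coordinate Gaussian jitter SD (px), `>= 0`.
#' @param seed integer seed (two independent sub-streams are derived).
#' @return List of two named lists of [limb_trajectory] (pixels).
#' @export
make_rater_pair <- function(gt, jitter_sigma, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), jitter_sigma >= 0)
  jig <- function(sub) {
    with_seed(derive_seed(seed, sub), {
      out <- lapply(names(gt$trajectories), function(nm) {
        p <- gt$trajectories[[nm]]
        p <- p + matrix(stats::rnorm(length(p), 0, jitter_sigma), nrow(p), ncol(p))
        limb_trajectory(p, missing = !gt$visible[[nm]], limb = nm,
                        resets = 0L, units = "px", fps = gt$fps)
      })
      names(out) <- names(gt$trajectories)
      out
    })
  }
  list(rater_a = jig("rater_a"), rater_b = jig("rater_b"))
}
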