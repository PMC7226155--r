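#' Inter-operator trajectory correlation
#'
#' Zero-lag Pearson correlation per axis between the same limb tracked by
#' two operators, computed over the frames valid in both runs (pairwise
#' deletion). A trend comparison: invariant to a constant positional offset
#' between the two runs, which is why it is computed on raw pixel-space
#' trajectories. Constant series give `NA`.
#'
#' @param traj_a,traj_b two [limb_trajectory] objects of equal length (one
#'   limb), or two named lists of trajectories (whole recordings).
#' @return For single trajectories, a named vector of per-axis correlations;
#'   for lists, a data frame with columns `limb`, `axis`, `r`.
#' @export
trajectory_correlation <- function(traj_a, traj_b) {
  if (!inherits(traj_a, "limb_trajectory") && is.list(traj_a)) {
    limbs <- intersect(names(traj_a), names(traj_b))
    rows <- lapply(limbs, function(lb) {
      r <- trajectory_correlation(traj_a[[lb]], traj_b[[lb]])
      data.frame(limb = lb, axis = names(r), r = unname(r),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(traj_a, "limb_trajectory"), inherits(traj_b, "limb_trajectory"))
  if (traj_a$n != traj_b$n) stop("trajectories of unequal length", call. = FALSE)
  ok <- !traj_a$missing & !traj_b$missing
  if (sum(ok) < 2)
    stop("fewer than 2 frames valid in both trajectories", call. = FALSE)
  axes <- intersect(colnames(traj_a$points), colnames(traj_b$points))
  vapply(axes, function(ax)
    pearson_or_na(traj_a$points[ok, ax], traj_b$points[ok, ax]), 0)
}

pearson_or_na <- function(a, b) {
  ca <- a - mean(a); cb <- b - mean(b)
  va <- sum(ca^2); vb <- sum(cb^2)
  if (va == 0 || vb == 0) return(NA_real_)
  sum(ca * cb) / sqrt(va * vb)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement: the
#' Shrout-Fleiss ICC(2,1), from the two-way ANOVA mean squares of an
#' `n x k` ratings matrix (n targets, k raters):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`
#' with `MSR` the between-target, `MSC` the between-rater, and `MSE` the
#' residual mean square. Point estimate only (no confidence interval).
#' Invariant to adding a common constant to all cells and to multiplying all
#' cells by a positive constant; equal to 1 iff the raters agree exactly on
#' all targets while target variance is present.
#'
#' @param m numeric `n x k` matrix, `n >= 2`, `k >= 2`, no missing cells.
#' @return The ICC estimate, or `NA` when the total variance is zero.
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ratings matrix must be at least 2 x 2", call. = FALSE)
  if (anyNA(m)) stop("ratings matrix must have no missing cells", call. = FALSE)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0) return(NA_real_)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' z-axis contribution of per-axis features
#'
#' For depth-augmented (3D) recordings, quantifies how much of a per-axis
#' feature lives on the depth axis: `100 * f_z / (f_x + f_y + f_z)` percent,
#' per feature per limb. Applies to the features computed on single axes
#' (area from moving average, crossing count, mean crossing distance,
#' periodicity). `NA` when the sum is zero or any component is undefined.
#'
#' @param features3d either a `kinematic_features` object computed from
#'   `N x 3` trajectories, or a data frame with columns `feature`, `limb`,
#'   `x`, `y`, `z`.
#' @return Data frame with columns `feature`, `limb`, `z_contribution`.
#' @export
z_contribution <- function(features3d) {
  if (inherits(features3d, "kinematic_features")) {
    x <- features3d
    rows <- list()
    for (lb in LIMBS) {
      per <- x$periodicity[[lb]]$per_axis
      stopifnot(!is.null(per))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = c("ama", "t_in", "d_bar", "periodicity"),
        limb = lb,
        x = c(x$ama[[lb]][["x"]], per$x$t_in, per$x$d_bar, per$x$p),
        y = c(x$ama[[lb]][["y"]], per$y$t_in, per$y$d_bar, per$y$p),
        z = c(x$ama[[lb]][["z"]], per$z$t_in, per$z$d_bar, per$z$p),
        stringsAsFactors = FALSE)
    }
    features3d <- do.call(rbind, rows)
  }
  stopifnot(all(c("feature", "limb", "x", "y", "z") %in% names(features3d)))
  tot <- features3d$x + features3d$y + features3d$z
  zc <- ifelse(is.na(tot) | tot == 0, NA_real_, 100 * features3d$z / tot)
  out <- data.frame(feature = features3d$feature, limb = features3d$limb,
                    z_contribution = zc, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-feature inter-operator agreement
#'
#' Given the kinematic feature batteries extracted by two operators from the
#' same set of videos, computes one ICC(2,1) per scalar feature across the
#' videos (targets = videos, raters = operators).
#'
#' @param features_a,features_b lists of `kinematic_features`, one per video,
#'   same order and length.
#' @return Data frame with columns `feature`, `icc`; features undefined in
#'   any video for either operator get `NA`.
#' @export
compare_operators <- function(features_a, features_b) {
  stopifnot(length(features_a) == length(features_b), length(features_a) >= 2)
  fa <- lapply(features_a, feature_vector)
  fb <- lapply(features_b, feature_vector)
  nms <- names(fa[[1]])
  rows <- lapply(nms, function(nm) {
    a <- vapply(fa, `[[`, 0, nm)
    b <- vapply(fb, `[[`, 0, nm)
    icc <- if (anyNA(a) || anyNA(b)) NA_real_ else icc_2_1(cbind(a, b))
    data.frame(feature = nm, icc = icc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# scalar summary of a battery, named feature__limb/pair style
feature_vector <- function(x) {
  stopifnot(inherits(x, "kinematic_features"))
  out <- c(
    stats::setNames(x$mean_velocity, paste0("mean_velocity__", names(x$mean_velocity))),
    stats::setNames(x$mean_acceleration,
                    paste0("mean_acceleration__", names(x$mean_acceleration))),
    stats::setNames(x$cross_correlation,
                    paste0("cc__", names(x$cross_correlation))),
    stats::setNames(vapply(x$ama, function(v) {
      if (anyNA(v[c("x", "y")])) NA_real_ else sum(v[c("x", "y")])
    }, 0), paste0("ama__", names(x$ama))),
    stats::setNames(vapply(x$periodicity, `[[`, 0, "d_bar"),
                    paste0("d_bar__", names(x$periodicity))),
    stats::setNames(vapply(x$periodicity, function(p) as.numeric(p$t_in), 0),
                    paste0("t_in__", names(x$periodicity))),
    stats::setNames(vapply(x$periodicity, `[[`, 0, "p"),
                    paste0("periodicity__", names(x$periodicity))))
  out
}
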