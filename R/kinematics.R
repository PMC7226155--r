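#' Gap interpolation
#'
#' Fills interior runs of missing samples of length at most `max_gap` by
#' linear interpolation between the flanking valid points, per coordinate.
#' Longer runs, and runs touching either end of the recording, are left
#' missing (never extrapolated). Originally valid samples are never changed.
#' At the nominal 12.5 Hz rate the default of 5 samples caps interpolation at
#' 400 ms of missing data.
#'
#' @param traj a [limb_trajectory].
#' @param max_gap longest missing run (in samples) that is filled.
#' @return A [limb_trajectory] with the gaps filled and the mask updated.
#' @export
interpolate_gaps <- function(traj, max_gap = 5) {
  stopifnot(inherits(traj, "limb_trajectory"))
  miss <- traj$missing
  n <- traj$n
  if (!any(miss) || all(miss)) return(traj)
  pts <- traj$points
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]
    if (s == 1L || e == n) next            # boundary run: never extrapolate
    if (r$lengths[i] > max_gap) next
    w <- (seq(s, e) - (s - 1)) / (e + 1 - (s - 1))
    for (j in seq_len(ncol(pts)))
      pts[s:e, j] <- pts[s - 1, j] + w * (pts[e + 1, j] - pts[s - 1, j])
    miss[s:e] <- FALSE
  }
  out <- traj
  out$points <- pts
  out$missing <- miss
  out
}

#' Standard trajectory preprocessing
#'
#' Convenience composition of the preprocessing chain applied before feature
#' extraction: normalize by head length, rotate into the standard body
#' frame, and fill short gaps.
#'
#' @param traj a [limb_trajectory] in pixels.
#' @param cal a [calibration].
#' @param max_gap passed to [interpolate_gaps].
#' @return A [limb_trajectory] in head-length units, body frame.
#' @export
preprocess_trajectory <- function(traj, cal, max_gap = 5) {
  interpolate_gaps(
    reorient_trajectory(normalize_trajectory(traj, cal), cal),
    max_gap = max_gap)
}

# ---- zero-phase Butterworth -------------------------------------------------

# direct-form II transposed filtering with explicit initial state
df2t_filter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  z <- if (is.null(zi)) rep(0, nf - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (nf > 2) {
      for (k in 1:(nf - 2)) z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * y[i]
    }
    z[nf - 1] <- b[nf] * x[i] - a[nf] * y[i]
  }
  y
}

# steady-state initial filter state for a unit step (lfilter_zi scheme):
# solving (I - A) zi = column such that a constant input passes transient-free
filter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  n <- nf - 1
  if (n == 0) return(numeric(0))
  # companion form of the DF2T state update: z' = A z + B x with
  # A[k,1] = -a[k+1], A[k,k+1] = 1; B[k] = b[k+1] - a[k+1] b[1]
  A <- matrix(0, n, n)
  A[, 1] <- -a[2:nf]
  if (n > 1) A[cbind(1:(n - 1), 2:n)] <- 1
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(n) - A, B)
}

#' Zero-phase low-pass filtering
#'
#' Forward-backward application of an IIR filter with odd-reflection padding
#' and steady-state initial conditions at both ends, so that a constant
#' series is returned exactly unchanged (unit DC gain with no edge
#' transient).
#'
#' @param b,a filter numerator/denominator coefficients.
#' @param x numeric series (no NAs).
#' @return Filtered series, same length.
#' @export
filtfilt_ss <- function(b, a, x) {
  n <- length(x)
  padlen <- min(3 * (max(length(a), length(b)) - 1) * 2, n - 1)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- filter_zi(b, a)
  y <- df2t_filter(b, a, ext, zi * ext[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

butter_lowpass <- function(order = 3, cutoff = 0.95) {
  flt <- signal::butter(order, cutoff)
  list(b = flt$b, a = flt$a)
}

#' Limb velocity
#'
#' Per-frame speed as the Euclidean distance of the reference point between
#' two subsequent frames, defined only where both frames are valid, then
#' smoothed by a zero-phase third-order low-pass Butterworth filter with
#' cutoff at 95% of the Nyquist frequency, applied per contiguous valid
#' segment. Segments shorter than three times the filter order are left
#' unfiltered (and flagged). Units are head lengths per frame when the input
#' is normalized; per-second values are `fps` times larger.
#'
#' @param traj a [limb_trajectory] (normally preprocessed, head-length units).
#' @param fps frame rate (Hz); defaults to the trajectory's.
#' @param filter apply the Butterworth smoothing (default) or return raw
#'   speeds.
#' @param order,cutoff Butterworth design parameters (cutoff as a fraction
#'   of Nyquist).
#' @return List with `speed` (length `N`, `NA` where undefined; element `t`
#'   is the speed from frame `t-1` to `t`, 1-based), `mean` (over defined
#'   samples, per frame), `mean_per_s`, and `unfiltered_segments` (count of
#'   segments too short to filter).
#' @export
velocity <- function(traj, fps = NULL, filter = TRUE, order = 3, cutoff = 0.95) {
  stopifnot(inherits(traj, "limb_trajectory"))
  if (is.null(fps)) fps <- traj$fps
  p <- traj$points
  n <- traj$n
  v <- rep(NA_real_, n)
  ok <- !traj$missing
  both <- which(ok[-1] & ok[-n]) + 1L     # frames t with t and t-1 valid
  if (length(both) == 0)
    return(list(speed = v, mean = NA_real_, mean_per_s = NA_real_,
                unfiltered_segments = 0L, defined = FALSE))
  d <- p[both, , drop = FALSE] - p[both - 1L, , drop = FALSE]
  v[both] <- sqrt(rowSums(d^2))
  unfilt <- 0L
  if (filter) {
    flt <- butter_lowpass(order, cutoff)
    segs <- contiguous_runs(!is.na(v))
    for (sg in segs) {
      if (length(sg) >= 3 * order) {
        v[sg] <- filtfilt_ss(flt$b, flt$a, v[sg])
      } else {
        unfilt <- unfilt + 1L
      }
    }
  }
  m <- mean(v, na.rm = TRUE)
  list(speed = v, mean = m, mean_per_s = if (!is.null(fps)) m * fps else NA_real_,
       unfiltered_segments = unfilt, defined = TRUE)
}

contiguous_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$lengths))
    if (r$values[i]) out[[length(out) + 1L]] <- starts[i]:ends[i]
  out
}

#' Limb acceleration
#'
#' One-lag difference of the (smoothed) speed series on contiguous defined
#' segments: `a_t = v_t - v_{t-1}`.
#'
#' @param speed numeric speed series (`NA` where undefined), as returned in
#'   `velocity()$speed`.
#' @return List with `accel` (same length, `NA` where undefined) and `mean`.
#' @export
acceleration <- function(speed) {
  n <- length(speed)
  a <- rep(NA_real_, n)
  if (n >= 2) {
    both <- which(!is.na(speed[-1]) & !is.na(speed[-n])) + 1L
    a[both] <- speed[both] - speed[both - 1L]
  }
  m <- if (any(!is.na(a))) mean(a, na.rm = TRUE) else NA_real_
  list(accel = a, mean = m, defined = any(!is.na(a)))
}

#' Zero-lag cross-correlation of two limb-speed series
#'
#' Synchrony index for a limb pair: the covariance of the two speed series
#' over their common defined frames, normalized by the product of their
#' standard deviations. Undefined (NA) when the overlap is shorter than 2
#' samples or either series is constant on the overlap.
#'
#' @param v1,v2 numeric speed series (`NA` where undefined), equal length.
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
cross_correlation <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 2) return(NA_real_)
  a <- v1[ok]; b <- v2[ok]
  ca <- a - mean(a); cb <- b - mean(b)
  va <- sum(ca^2); vb <- sum(cb^2)
  if (va == 0 || vb == 0) return(NA_real_)
  sum(ca * cb) / sqrt(va * vb)
}

#' Area from moving average
#'
#' Movement-smoothness index for one trajectory component: the centered
#' moving average over a window of `k` samples around each frame is
#' subtracted from the series, and the absolute deviations are summed over
#' the frames where the window has full support. With the default even `k`
#' the centered window holds `k + 1` samples; the mean is taken over all of
#' them (so a constant series scores exactly 0). Setting `literal = TRUE`
#' instead divides the `k + 1`-sample sum by `k`.
#'
#' Samples whose window overlaps a missing value contribute nothing.
#'
#' @param x numeric component series (`NA` allowed), length `l > k`.
#' @param k moving-average window size in samples (default 30; about 2 s at
#'   the nominal rate).
#' @param literal divide the window sum by `k` instead of by the number of
#'   samples in the window.
#' @return The summed absolute deviation (same units as `x`), or `NA` when
#'   `l <= k` or no frame has full window support.
#' @export
area_from_moving_average <- function(x, k = 30, literal = FALSE) {
  l <- length(x)
  if (l <= k) return(NA_real_)
  h <- k %/% 2
  idx <- (h + 1):(l - h)                      # full-support frames (1-based)
  if (k %% 2 == 1) idx <- (h + 1):(l - h - 1) # odd k: asymmetric tail guard
  dev <- rep(NA_real_, length(idx))
  denom <- if (literal) k else (2 * h + 1)
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    win <- x[(i - h):(i + h)]
    if (anyNA(win)) next
    dev[ii] <- abs(x[i] - sum(win) / denom)
  }
  if (all(is.na(dev))) return(NA_real_)
  sum(dev, na.rm = TRUE)
}

#' Mean-crossing periodicity
#'
#' Splits each trajectory component into non-overlapping windows of
#' `window` samples (40 s at the nominal 12.5 Hz; a trailing partial window
#' is discarded), computes the window mean, and detects the crossings of the
#' series with that mean. A crossing lies between consecutive samples with
#' strictly opposite signs about the mean; samples exactly on the mean adopt
#' the sign of the nearest preceding off-mean sample (leading ties adopt the
#' first following sign). Distances in samples between consecutive crossings
#' are pooled — across both (or all three) axes when a matrix is given — and
#' summarized as `d_bar` (mean), `sigma_d` (SD, denominator `n`), the total
#' crossing count `t_in`, and the periodicity `p = 1 / (d_bar + sigma_d)`.
#'
#' @param x numeric vector (one component) or `N x m` matrix of components.
#' @param window window length in samples.
#' @return List with `t_in`, `d_bar`, `sigma_d`, `p`, `distances`, and
#'   `per_axis` (the same summary per component when `x` is a matrix).
#'   `p` is `NA` when fewer than 2 crossings exist.
#' @export
periodicity <- function(x, window = 500) {
  if (is.matrix(x)) {
    per_axis <- lapply(seq_len(ncol(x)), function(j) periodicity(x[, j], window))
    names(per_axis) <- colnames(x)
    dist <- unlist(lapply(per_axis, `[[`, "distances"), use.names = FALSE)
    out <- summarize_crossings(dist, sum(vapply(per_axis, `[[`, 0L, "t_in")))
    out$per_axis <- per_axis
    return(out)
  }
  l <- length(x)
  n_win <- l %/% window
  dist <- numeric(0)
  n_cross <- 0L
  if (n_win >= 1) {
    for (wi in seq_len(n_win)) {
      seg <- x[((wi - 1) * window + 1):(wi * window)]
      ci <- crossing_info(seg)
      dist <- c(dist, ci$distances)
      n_cross <- n_cross + ci$count
    }
  }
  out <- summarize_crossings(dist, n_cross)
  out$per_axis <- NULL
  out
}

# crossings of a segment about its mean: count plus distances between
# consecutive crossings, chain broken at missing samples
crossing_info <- function(seg) {
  ok <- !is.na(seg)
  if (sum(ok) < 2) return(list(count = 0L, distances = numeric(0)))
  m <- mean(seg[ok])
  s <- sign(seg - m)
  # ties adopt the preceding off-mean sign; leading ties the following one
  nz <- which(s != 0 & !is.na(s))
  if (length(nz) == 0) return(list(count = 0L, distances = numeric(0)))
  filled <- s
  last <- NA_real_
  for (i in seq_along(s)) {
    if (is.na(s[i])) { last <- NA_real_; next }  # break at missing samples
    if (s[i] == 0) {
      filled[i] <- if (is.na(last)) 0 else last
    } else last <- s[i]
  }
  # leading run of zeros (with valid data): adopt first nonzero sign
  first_nz <- nz[1]
  lead <- seq_len(first_nz - 1)
  lead <- lead[!is.na(s[lead]) & filled[lead] == 0]
  filled[lead] <- s[first_nz]
  cross <- integer(0)
  for (i in seq_len(length(seg) - 1)) {
    a <- filled[i]; b <- filled[i + 1]
    if (is.na(a) || is.na(b) || a == 0 || b == 0) next
    if (a * b < 0) cross <- c(cross, i)
  }
  if (length(cross) < 2)
    return(list(count = length(cross), distances = numeric(0)))
  # distances only between crossings not separated by a missing run
  d <- numeric(0)
  for (i in seq_len(length(cross) - 1)) {
    span <- cross[i]:(cross[i + 1] + 1)
    if (anyNA(seg[span])) next
    d <- c(d, cross[i + 1] - cross[i])
  }
  list(count = length(cross), distances = d)
}

summarize_crossings <- function(dist, t_in) {
  if (length(dist) < 1)
    return(list(t_in = as.integer(t_in), d_bar = NA_real_, sigma_d = NA_real_,
                p = NA_real_, distances = dist))
  d_bar <- mean(dist)
  sigma_d <- sqrt(mean((dist - d_bar)^2))
  list(t_in = as.integer(t_in), d_bar = d_bar, sigma_d = sigma_d,
       p = 1 / (d_bar + sigma_d), distances = dist)
}
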