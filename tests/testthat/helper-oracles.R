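# Independent brute-force oracles used across the suite. These are written
# naively (explicit loops over the defining sums) and stay independent of the
# implementation code paths they check.

# zero-lag normalized covariance of two series
oracle_cc <- function(v1, v2) {
  ok <- !is.na(v1) & !is.na(v2)
  a <- v1[ok]; b <- v2[ok]
  n <- length(a)
  cov_ab <- sum((a - mean(a)) * (b - mean(b))) / n
  var_a <- sum((a - mean(a))^2) / n
  var_b <- sum((b - mean(b))^2) / n
  cov_ab / sqrt(var_a * var_b)
}

# centered moving average + summed absolute deviation, explicit loops
oracle_ama <- function(x, k = 30, literal = FALSE) {
  l <- length(x)
  if (l <= k) return(NA_real_)
  h <- k %/% 2
  lo <- h + 1
  hi <- if (k %% 2 == 0) l - h else l - h - 1
  total <- 0
  any_ok <- FALSE
  for (i in lo:hi) {
    win <- x[(i - h):(i + h)]
    if (any(is.na(win))) next
    mbar <- sum(win) / (if (literal) k else length(win))
    total <- total + abs(x[i] - mbar)
    any_ok <- TRUE
  }
  if (!any_ok) return(NA_real_)
  total
}

# mean-crossing distances of one windowed segment (no missing samples)
oracle_crossings <- function(x, window = 500) {
  n_win <- length(x) %/% window
  dists <- numeric(0)
  count <- 0
  for (w in seq_len(n_win)) {
    seg <- x[((w - 1) * window + 1):(w * window)]
    m <- mean(seg)
    s <- sign(seg - m)
    # resolve exact ties to the preceding off-mean sign (leading: following)
    for (i in seq_along(s)) if (s[i] == 0) {
      j <- i - 1
      while (j >= 1 && s[j] == 0) j <- j - 1
      if (j >= 1) s[i] <- s[j] else {
        j <- i + 1
        while (j <= length(s) && s[j] == 0) j <- j + 1
        if (j <= length(s)) s[i] <- s[j]
      }
    }
    cross <- which(s[-length(s)] * s[-1] < 0)
    count <- count + length(cross)
    if (length(cross) >= 2) dists <- c(dists, diff(cross))
  }
  list(count = count, distances = dists)
}

oracle_periodicity <- function(x, window = 500) {
  ci <- oracle_crossings(x, window)
  if (length(ci$distances) < 1)
    return(list(t_in = ci$count, d_bar = NA, sigma_d = NA, p = NA))
  d_bar <- mean(ci$distances)
  sigma_d <- sqrt(mean((ci$distances - d_bar)^2))
  list(t_in = ci$count, d_bar = d_bar, sigma_d = sigma_d,
       p = 1 / (d_bar + sigma_d))
}

# naive reference motion-image pipeline (explicit loops, reflect borders)
oracle_reflect <- function(i, n) {
  if (i < 1) i <- 1 - i          # 1-based symmetric reflection
  if (i > n) i <- 2 * n + 1 - i
  min(max(i, 1), n)
}

oracle_median_filter <- function(img, size) {
  h <- nrow(img); w <- ncol(img); r <- size %/% 2
  out <- img
  for (i in 1:h) for (j in 1:w) {
    vals <- numeric(0)
    for (di in -r:r) for (dj in -r:r) {
      vals <- c(vals, img[oracle_reflect(i + di, h), oracle_reflect(j + dj, w)])
    }
    out[i, j] <- sort(vals)[(length(vals) + 1) %/% 2]
  }
  out
}

oracle_mean_filter <- function(img, size) {
  h <- nrow(img); w <- ncol(img); r <- size %/% 2
  out <- img
  for (i in 1:h) for (j in 1:w) {
    s <- 0
    for (di in -r:r) for (dj in -r:r) {
      s <- s + img[oracle_reflect(i + di, h), oracle_reflect(j + dj, w)]
    }
    out[i, j] <- s / size^2
  }
  out
}

oracle_motion_image <- function(f1, f0, threshold = 15, median_size = 5,
                                kernel_size = 3, majority = 5 / 9) {
  d <- abs(f1 - f0)
  d <- oracle_median_filter(d, median_size)
  b <- (d > threshold) * 1
  a <- oracle_mean_filter(b, kernel_size)
  (a >= majority - 1e-12) * 1
}

# two-way ANOVA mean squares via stats::aov (independent route)
oracle_icc_2_1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   target = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ target + rater, data = df))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# small helper fixtures ------------------------------------------------------

# quick scene for tracking tests: slower/smaller default unless overridden
test_scene <- function(duration = 12, seed = 7, ...) {
  render_scene(scene_spec(duration = duration, seed = seed, ...))
}

# single moving blob video rendered through the public generator
single_blob_scene <- function(model, n_frames = 20, fps = 12.5, radius = 4,
                              width = 80, height = 60, seed = 5,
                              noise = list(sigma = 0, salt_pepper = 0),
                              occl = list()) {
  limb <- list(radius = radius, intensity = 230, model = model)
  still <- function(cx, cy) list(radius = 2, intensity = 200,
                                 model = list(kind = "constant", center = c(cx, cy)))
  spec <- scene_spec(width = width, height = height, fps = fps,
                     duration = n_frames / fps,
                     head_line = rbind(c(8, 6), c(8, 30)),
                     symmetry_line = rbind(c(8, 32), c(8, 52)),
                     limbs = list(right_hand = limb,
                                  left_hand = still(70, 10),
                                  right_foot = still(70, 30),
                                  left_foot = still(70, 50)),
                     occlusions = occl,
                     noise = noise, seed = seed)
  render_scene(spec)
}

rmse_vs_gt <- function(traj, gt_path) {
  ok <- !traj$missing
  sqrt(mean(rowSums((traj$points[ok, , drop = FALSE] -
                     gt_path[ok, , drop = FALSE])^2)))
}
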