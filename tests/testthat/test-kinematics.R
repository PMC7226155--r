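make_traj <- function(x, y = x, missing = NULL, fps = 12.5) {
  limb_trajectory(cbind(x, y), missing = missing, units = "hl", fps = fps)
}

test_that("gap interpolation fills short interior runs linearly and only those", {
  x <- c(0, NA, 2, 5, 6)
  tr <- interpolate_gaps(make_traj(x))
  expect_equal(unname(tr$points[2, 1]), 1)  # linear midpoint
  expect_false(any(tr$missing))

  # run of exactly 5 filled; run of 6 untouched
  x5 <- c(0, rep(NA, 5), 6, 1, rep(NA, 6), 8, 2)
  tr5 <- interpolate_gaps(make_traj(x5), max_gap = 5)
  expect_equal(unname(tr5$points[1:7, 1]), 0:6)
  expect_true(all(tr5$missing[9:14]))

  # boundary runs never extrapolated
  xb <- c(NA, NA, 3, 4, NA)
  trb <- interpolate_gaps(make_traj(xb))
  expect_true(all(trb$missing[c(1, 2, 5)]))

  # originally valid samples never change
  set.seed(4)
  xr <- rnorm(60)
  miss <- rep(FALSE, 60); miss[sample(2:59, 12)] <- TRUE
  trr <- interpolate_gaps(make_traj(xr, missing = miss))
  expect_equal(trr$points[!miss, 1], cbind(xr, xr)[!miss, 1])
})

test_that("the longest filled gap spans 400 ms at 12.5 Hz", {
  max_gap <- 5; fps <- 12.5
  expect_equal(max_gap / fps * 1000, 400)
  # and a 5-sample gap is indeed the longest that gets filled
  x <- c(0, rep(NA, 5), 6)
  expect_false(any(interpolate_gaps(make_traj(x), 5)$missing))
  x <- c(0, rep(NA, 6), 7)
  expect_true(any(interpolate_gaps(make_traj(x), 5)$missing))
})

test_that("velocity is the inter-frame Euclidean step, Butterworth passes DC", {
  # constant trajectory -> zero speeds
  v0 <- velocity(make_traj(rep(2, 30)), fps = 12.5)
  expect_equal(unname(v0$speed[-1]), rep(0, 29))
  expect_equal(v0$mean, 0)

  # uniform motion d per frame -> mean exactly d (unit DC gain, no transient)
  d <- 0.35
  tr <- make_traj(cumsum(rep(d, 40)), rep(0, 40))
  v <- velocity(tr, fps = 12.5)
  expect_equal(v$mean, d, tolerance = 1e-12)
  expect_equal(v$mean_per_s, d * 12.5, tolerance = 1e-12)

  # sinusoidal path: filtering at 95% Nyquist barely attenuates the mean
  t <- seq_len(400)
  trs <- make_traj(3 * sin(2 * pi * t / 40), 2 * cos(2 * pi * t / 40))
  vf <- velocity(trs, fps = 12.5)
  vraw <- velocity(trs, fps = 12.5, filter = FALSE)
  expect_lt(abs(vf$mean - vraw$mean) / vraw$mean, 0.02)

  # speeds undefined across missing frames
  xm <- c(1, 2, NA, 4, 5)
  vm <- velocity(make_traj(xm))
  expect_true(all(is.na(vm$speed[c(1, 3, 4)])))
  expect_false(anyNA(vm$speed[c(2, 5)]))
})

test_that("acceleration is the one-lag speed difference", {
  a0 <- acceleration(rep(0.2, 20))
  expect_equal(unname(a0$accel[-1]), rep(0, 19))
  expect_equal(a0$mean, 0)

  alin <- acceleration(0.01 * seq_len(20))
  expect_equal(unname(alin$accel[-1]), rep(0.01, 19))

  set.seed(8)
  v <- rnorm(50)
  aa <- acceleration(v)
  expect_equal(unname(aa$accel[-1]), diff(v))  # brute-force diff oracle
  expect_true(is.na(aa$accel[1]))
})

test_that("cross-correlation reproduces hand-computed and degenerate cases", {
  v <- c(1, 2, 3, 4)
  expect_equal(cross_correlation(v, v), 1)
  expect_equal(cross_correlation(v, -v), -1)
  expect_equal(cross_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(cross_correlation(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(cross_correlation(c(1, NA, NA, NA), c(1, NA, NA, 2))))
  expect_equal(cross_correlation(c(1, NA, NA, 2), c(1, NA, NA, 2)), 1)
  # symmetry and bounds on random series
  set.seed(15)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(cross_correlation(a, b), cross_correlation(b, a))
    expect_lte(abs(cross_correlation(a, b)), 1)
  }
})

test_that("area from moving average matches the brute-force oracle", {
  expect_equal(area_from_moving_average(rep(3, 100)), 0)
  ramp <- seq(0, 1, length.out = 100)
  expect_lt(area_from_moving_average(ramp), 1e-9)
  expect_true(is.na(area_from_moving_average(seq_len(30), k = 30)))

  t <- seq_len(200)
  sine <- sin(2 * pi * t / 10)
  expect_equal(area_from_moving_average(sine, k = 30), oracle_ama(sine, 30),
               tolerance = 1e-12)
  expect_equal(area_from_moving_average(sine, k = 30, literal = TRUE),
               oracle_ama(sine, 30, literal = TRUE), tolerance = 1e-12)
  # literal variant scores a constant series as nonzero -- the reason the
  # true centered mean is the default
  expect_gt(area_from_moving_average(rep(3, 100), literal = TRUE), 0)
})

test_that("periodicity of a sampled sinusoid has the analytic crossing structure", {
  t <- 0:999
  # period 50 samples, zero-mean windows; phase offset keeps the zeros off
  # the sample grid so the crossing spacing is exact
  x <- 10 * sin(2 * pi * t / 50 + pi / 7)
  p <- periodicity(x, window = 500)
  expect_equal(p$d_bar, 25)
  expect_equal(p$sigma_d, 0)
  expect_equal(p$p, 0.04)
  expect_gt(p$t_in, 0)

  # constant series: no crossings, P undefined (flagged, not zero)
  pc <- periodicity(rep(1, 600), window = 500)
  expect_equal(pc$t_in, 0L)
  expect_true(is.na(pc$p))

  # the 500-sample window spans 40 s at 12.5 Hz
  expect_equal(500 / 12.5, 40)
})

test_that("periodicity pools axes and matches the oracle on random walks", {
  set.seed(23)
  for (rep_i in 1:5) {
    x <- cumsum(rnorm(1100)); y <- cumsum(rnorm(1100))
    px <- periodicity(x); py <- periodicity(y)
    ox <- oracle_periodicity(x); oy <- oracle_periodicity(y)
    expect_equal(px$d_bar, ox$d_bar, tolerance = 1e-12)
    expect_equal(px$sigma_d, ox$sigma_d, tolerance = 1e-12)
    expect_equal(px$t_in, ox$t_in)
    expect_equal(py$p, oy$p, tolerance = 1e-12)
    # pooled limb summary merges the two axes' distances
    pm <- periodicity(cbind(x = x, y = y))
    pooled <- c(ox$d_bar * 0 + oracle_crossings(x)$distances,
                oracle_crossings(y)$distances)
    expect_equal(pm$d_bar, mean(pooled), tolerance = 1e-12)
    expect_equal(pm$t_in, ox$t_in + oy$t_in)
    expect_equal(pm$per_axis$x$p, px$p)
  }
})

test_that("periodicity decreases when crossing spread grows at fixed mean", {
  mk <- function(dists) {
    # build a +/- square series whose crossings are spaced as given
    s <- unlist(lapply(seq_along(dists), function(i)
      rep(c(1, -1)[(i %% 2) + 1], dists[i])))
    c(s, rep(c(1, -1)[(length(dists) %% 2) + 1], 500 - length(s)))[1:500] * 1.0
  }
  tight <- periodicity(mk(rep(25, 19)), window = 500)
  spread <- periodicity(mk(rep(c(15, 35), 9)), window = 500)
  expect_equal(tight$d_bar, spread$d_bar, tolerance = 0.1)
  expect_gt(tight$p, spread$p)
})

test_that("Eq-style features match brute force on random 1000-sample series", {
  set.seed(99)
  for (i in 1:12) {
    v1 <- rnorm(1000); v2 <- rnorm(1000)
    expect_equal(cross_correlation(v1, v2), oracle_cc(v1, v2), tolerance = 1e-9)
    x <- cumsum(rnorm(1000))
    expect_equal(area_from_moving_average(x), oracle_ama(x), tolerance = 1e-9)
    po <- oracle_periodicity(x)
    pi_ <- periodicity(x)
    expect_equal(pi_$p, po$p, tolerance = 1e-9)
    a <- acceleration(v1)
    expect_equal(unname(a$accel[-1]), diff(v1), tolerance = 1e-9)
  }
})

test_that("full battery: constants give zeros, undefined features are flagged", {
  trs <- stats::setNames(lapply(1:4, function(i)
    make_traj(rep(i, 600), rep(2 * i, 600))), LIMBS <- c("right_hand", "left_hand", "right_foot", "left_foot"))
  fs <- compute_kinematic_features(trs, fps = 12.5)
  expect_equal(unname(fs$mean_velocity), rep(0, 4))
  expect_equal(unname(fs$mean_acceleration), rep(0, 4))
  expect_equal(unname(fs$ama_upper), 0)
  expect_true(all(is.na(fs$cross_correlation)))       # constant speeds
  expect_true(all(is.na(vapply(fs$periodicity, `[[`, 0, "p"))))
  df <- as.data.frame(fs)
  expect_true(all(c("feature", "limb", "axis", "value") %in% names(df)))
  expect_true(any(is.na(df$value)))                    # undefined, not zero
})

test_that("battery CC matrix matches direct evaluation on analytic speeds", {
  t <- seq_len(600)
  mk <- function(ph) make_traj(5 + sin(2 * pi * t / 40 + ph), rep(0, 600))
  trs <- list(right_hand = mk(0), left_hand = mk(pi / 3),
              right_foot = mk(pi), left_foot = mk(3 * pi / 2))
  fs <- compute_kinematic_features(trs, fps = 12.5)
  sp <- lapply(trs, function(tr) velocity(tr, 12.5)$speed)
  expect_equal(unname(fs$cross_correlation["right_hand__left_hand"]),
               oracle_cc(sp$right_hand, sp$left_hand), tolerance = 1e-9)
  expect_equal(unname(fs$cross_correlation["right_foot__left_foot"]),
               oracle_cc(sp$right_foot, sp$left_foot), tolerance = 1e-9)
})

test_that("halving the scale halves velocity and A_ma, leaves CC and P unchanged", {
  set.seed(31)
  t <- seq_len(700)
  mk <- function(sc) {
    pts <- lapply(1:4, function(i)
      cbind(10 + 2 * sin(2 * pi * t / (30 + 5 * i)) + 0.1 * cumsum(rnorm(700, sd = 0.1)),
            10 + 1.5 * cos(2 * pi * t / (25 + 4 * i))))
    stats::setNames(lapply(pts, function(p)
      limb_trajectory(p * sc, units = "hl", fps = 12.5)),
      c("right_hand", "left_hand", "right_foot", "left_foot"))
  }
  set.seed(31); trs1 <- mk(1)
  set.seed(31); trs2 <- mk(0.5)   # equivalent to doubling the head length
  f1 <- compute_kinematic_features(trs1, fps = 12.5)
  f2 <- compute_kinematic_features(trs2, fps = 12.5)
  expect_equal(f2$mean_velocity, f1$mean_velocity / 2, tolerance = 1e-9)
  expect_equal(f2$ama_upper, f1$ama_upper / 2, tolerance = 1e-9)
  expect_equal(f2$cross_correlation, f1$cross_correlation, tolerance = 1e-9)
  expect_equal(vapply(f2$periodicity, `[[`, 0, "p"),
               vapply(f1$periodicity, `[[`, 0, "p"), tolerance = 1e-12)
  expect_equal(vapply(f2$periodicity, function(p) as.numeric(p$t_in), 0),
               vapply(f1$periodicity, function(p) as.numeric(p$t_in), 0))
})
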