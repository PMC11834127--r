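test_that("low-pass filter preserves DC exactly and is linear", {
  x <- rep(3, 2000)
  y <- lowpass_filter(x, 1000, 15)
  expect_lt(max(abs(y - 3)), 1e-9)
  # mean of a long constant segment preserved to 1e-9 relative error
  expect_lt(abs(mean(y) - 3) / 3, 1e-9)

  set.seed(4)
  a <- rnorm(1500); b <- rnorm(1500)
  lhs <- lowpass_filter(a + b, 1000, 15)
  rhs <- lowpass_filter(a, 1000, 15) + lowpass_filter(b, 1000, 15)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("filter attenuation at 50 Hz matches the analytic Butterworth response", {
  rate <- 1000; fc <- 15; f <- 50
  t <- seq(0, 3, by = 1 / rate)
  y <- lowpass_filter(sin(2 * pi * f * t), rate, fc)
  mid <- y[1000:2000]
  measured <- max(abs(mid))
  # forward-backward pass of a 2nd-order Butterworth: |H|^2 = 1/(1+(f/fc)^4)
  analytic <- 1 / (1 + (f / fc)^4)
  expect_lt(abs(measured - analytic) / analytic, 0.05)
})

test_that("filter rejects invalid cutoffs and too-short series", {
  expect_error(lowpass_filter(rnorm(100), 60, 30), "Nyquist")
  expect_error(lowpass_filter(rnorm(100), 60, 40), "Nyquist")
  expect_error(lowpass_filter(rnorm(3), 1000, 15), "short")
})

test_that("central difference is exact on polynomials of degree <= 2", {
  rate <- 1000
  t <- seq(0, 1, by = 1 / rate)
  v <- central_difference(8 * t, rate)
  expect_equal(v[2:(length(v) - 1)], rep(8, length(v) - 2), tolerance = 1e-9)
  expect_equal(central_difference(rep(2.5, 100), rate), rep(0, 100))
  expect_error(central_difference(c(1, 2), rate), "3 samples")
})

test_that("central difference error on a sinusoid obeys the Taylor bound", {
  rate <- 1000; f <- 2
  t <- seq(0, 1, by = 1 / rate)
  x <- sin(2 * pi * f * t)
  d <- central_difference(x, rate)
  true_d <- 2 * pi * f * cos(2 * pi * f * t)
  interior <- 2:(length(t) - 1)
  bound <- (2 * pi * f)^3 / (6 * rate^2)
  expect_lt(max(abs(d[interior] - true_d[interior])), bound * 1.0001)
})

test_that("saccade detector returns nothing below threshold", {
  n <- 1000
  out <- detect_saccades(rep(8, n), rep(0, n), 1000)
  expect_equal(nrow(out), 0)
})

test_that("detector finds one injected saccade and agrees with the scan oracle", {
  tr <- pursuit_trace()
  x <- inject_saccade(tr$x, 0.5, 10, 0.05, timebase = tr$time)
  v <- central_difference(x, tr$rate)
  a <- central_difference(v, tr$rate)
  det <- detect_saccades(abs(v), a, tr$rate, time = tr$time)
  expect_equal(nrow(det), 1)
  expect_true(det$t_start <= 0.525 && det$t_end >= 0.525)
  expect_gte(det$peak_velocity, 30)
  expect_gte(det$peak_acceleration, 1000)

  # sample-level agreement with the per-sample threshold scan (padding off)
  det0 <- detect_saccades(abs(v), a, tr$rate, time = tr$time, pad = 0)
  lab_det <- rep(FALSE, length(v))
  for (k in seq_len(nrow(det0)))
    lab_det[det0$i_start[k]:det0$i_end[k]] <- TRUE
  lab_orc <- saccade_label_oracle(abs(v), a)
  expect_gte(mean(lab_det == lab_orc), 0.99)
})

test_that("two saccades 300 ms apart give two disjoint intervals", {
  tr <- pursuit_trace()
  x <- inject_saccade(tr$x, 0.5, 8, 0.04, timebase = tr$time)
  x <- inject_saccade(x, 0.8, -6, 0.04, timebase = tr$time)
  v <- central_difference(x, tr$rate)
  a <- central_difference(v, tr$rate)
  det <- detect_saccades(abs(v), a, tr$rate, time = tr$time)
  expect_equal(nrow(det), 2)
  expect_lt(det$t_end[1], det$t_start[2])
})

test_that("detector rejects mismatched input lengths", {
  expect_error(detect_saccades(rnorm(10), rnorm(9), 1000), "length")
})

test_that("interpolation bridges gaps linearly and leaves a line invariant", {
  rate <- 1000
  x <- seq(0, 2, length.out = 2001)  # a line
  iv <- tibble::tibble(i_start = 500L, i_end = 700L)
  expect_equal(remove_and_interpolate(x, iv), x)

  # 0 -> 2 deg over a 100 ms gap: interior velocity exactly 20 deg/s
  y <- c(rep(0, 1000), rnorm(99, 5, 3), rep(2, 1000))
  iv <- tibble::tibble(i_start = 1000L, i_end = 1100L)
  y2 <- remove_and_interpolate(y, iv)
  v <- central_difference(y2, rate)
  expect_equal(v[1002:1098], rep(20, 97), tolerance = 1e-9)

  # no-op and idempotence
  expect_identical(remove_and_interpolate(y, iv[0, ]), y)
  expect_identical(remove_and_interpolate(y2, iv), y2)
  expect_error(remove_and_interpolate(y, tibble::tibble(i_start = 0L, i_end = 50L)),
               "outside")
})

test_that("blink detection returns padded, merged runs", {
  rate <- 1000
  m <- rep(FALSE, 2000)
  expect_equal(nrow(detect_blinks(m, rate)), 0)

  m[800:949] <- TRUE  # 150 ms run
  b <- detect_blinks(m, rate, pad = 0.05)
  expect_equal(nrow(b), 1)
  expect_lte(b$i_start, 800); expect_gte(b$i_end, 949)

  m2 <- rep(FALSE, 2000)
  m2[200:260] <- TRUE
  m2[1500:1560] <- TRUE  # far apart: two intervals
  expect_equal(nrow(detect_blinks(m2, rate, pad = 0.05)), 2)
  m3 <- rep(FALSE, 2000)
  m3[200:260] <- TRUE
  m3[300:360] <- TRUE    # within 2*pad: merged
  expect_equal(nrow(detect_blinks(m3, rate, pad = 0.05)), 1)
})

test_that("eye preprocessing recovers a clean pursuit trace and desaccades", {
  cfg <- quiet_config(n_participants = 1, trials_per_cell = 1, seed = 5)
  co <- simulate_cohort(cfg)
  id <- names(co$traces)[1]
  pe <- preprocess_eye(co$traces[[id]]$eye, rate = 1000)
  onset <- co$metadata$onset_time[1]
  v <- compute_asem_velocity(pe$kin, onset)
  expect_equal(v, co$ground_truth$asem_true[1], tolerance = 1e-3)

  # plant a small fixational saccade before onset; after desaccading, the
  # interior of the bridged gap carries the interpolation slope, which for
  # a catch-up-sized saccade stays below the 30 deg/s criterion (the gap
  # edges keep brief filter transients and are not part of the guarantee)
  eye <- co$traces[[id]]$eye
  eye$x <- inject_saccade(eye$x, 0.25, 1.5, 0.04, timebase = eye$time)
  pe2 <- preprocess_eye(eye, rate = 1000)
  expect_equal(nrow(pe2$saccades), 1)
  inside <- pe2$kin$time > pe2$saccades$t_start[1] + 0.02 &
    pe2$kin$time < pe2$saccades$t_end[1] - 0.02
  expect_lt(max(abs(pe2$kin$vx[inside])), 30)

  eye$missing <- rep(TRUE, nrow(eye))
  expect_error(preprocess_eye(eye, rate = 1000), "missing")
})

test_that("cursor preprocessing recovers stationary, linear and bell profiles", {
  rate <- 60
  t <- seq(0, 2, by = 1 / rate)
  still <- tibble::tibble(time = t, x = rep(0, length(t)), y = rep(-15, length(t)))
  k <- preprocess_cursor(still, rate = rate)
  expect_lt(max(abs(k$vx)), 1e-9)
  expect_lt(max(abs(k$vy)), 1e-9)

  lin <- tibble::tibble(time = t, x = 5 * t, y = rep(0, length(t)))
  k2 <- preprocess_cursor(lin, rate = rate)
  interior <- 30:90
  expect_equal(k2$vx[interior], rep(5, length(interior)), tolerance = 0.01)

  # minimum-jerk reach: peak speed = 1.875 * distance / duration
  dist <- 15; dur <- 0.45; t0 <- 0.9
  tau <- pmin(pmax((t - t0) / dur, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  reach <- tibble::tibble(time = t, x = rep(0, length(t)), y = -15 + dist * s)
  k3 <- preprocess_cursor(reach, rate = rate)
  expect_equal(max(abs(k3$vy)), 1.875 * dist / dur, tolerance = 0.02 * 1.875 * dist / dur)
})
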