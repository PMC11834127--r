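# Trace preprocessing: zero-phase Butterworth filtering, central-difference
# differentiation, saccade detection/removal and blink detection.

#' Zero-phase second-order Butterworth low-pass filter
#'
#' Applies a second-order Butterworth low-pass design forward and backward
#' (zero phase, so event timing is not shifted; the effective magnitude
#' response is the square of the single-pass design). The series is
#' extended by odd reflection at both ends before filtering so that edge
#' transients decay inside the padding, which keeps the DC gain exactly 1
#' on constant segments.
#'
#' @param x numeric samples.
#' @param rate sampling rate, Hz.
#' @param cutoff passband edge, Hz; must be below the Nyquist rate.
#' @return filtered samples, same length as `x`.
#' @export
lowpass_filter <- function(x, rate, cutoff) {
  if (cutoff >= rate / 2)
    stop("cutoff must be below the Nyquist frequency (rate/2)", call. = FALSE)
  if (cutoff <= 0 || rate <= 0)
    stop("rate and cutoff must be positive", call. = FALSE)
  n <- length(x)
  npad <- min(n - 1L, max(as.integer(ceiling(6 * rate / cutoff)), 50L))
  if (npad < 3L)
    stop("series too short to filter at this rate/cutoff", call. = FALSE)
  if (anyNA(x)) stop("series contains NA; interpolate gaps first", call. = FALSE)
  # odd reflection about the end points
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(left, x, right)
  bf <- butter_cached(cutoff / (rate / 2))
  yp <- signal::filtfilt(bf, xp)
  yp[(npad + 1):(npad + n)]
}

# second-order Butterworth designs are reused constantly; cache by
# normalized cutoff
.butter_cache <- new.env(parent = emptyenv())
butter_cached <- function(w) {
  key <- sprintf("%.12g", w)
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(2, w, type = "low")
    .butter_cache[[key]] <- bf
  }
  bf
}

fast_tbl <- function(...) tibble::new_tibble(list(...))

#' Central-difference differentiation
#'
#' Interior samples use the central difference
#' `(x[i+1] - x[i-1]) * rate / 2`; the two boundary samples use one-sided
#' first differences. Exact for polynomials of degree <= 2 on the interior.
#'
#' @param x numeric samples.
#' @param rate sampling rate, Hz.
#' @return the derivative, same length as `x`.
#' @export
central_difference <- function(x, rate) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}

#' Detect saccades from velocity and acceleration
#'
#' A saccade interval seeds wherever velocity exceeds `vel_threshold`
#' jointly with |acceleration| exceeding `acc_threshold`, then grows to the
#' surrounding contiguous run of samples with velocity above
#' `vel_threshold` (the interval extends to where velocity falls back below
#' criterion). Each interval is padded by `pad` seconds on both sides and
#' overlapping intervals are merged.
#'
#' @param velocity speed samples, deg/s (use the magnitude or the
#'   horizontal component; must be the same length as `acceleration`).
#' @param acceleration acceleration samples, deg/s^2 (sign retained; the
#'   absolute value is compared to the threshold).
#' @param rate sampling rate, Hz.
#' @param time optional time base, s; defaults to `(i - 1)/rate`.
#' @param vel_threshold,acc_threshold detection criteria.
#' @param pad padding, s.
#' @return tibble with columns `t_start`, `t_end`, `peak_velocity`,
#'   `peak_acceleration`, `i_start`, `i_end` (indices of the padded
#'   interval); zero rows when the criterion never holds.
#' @export
detect_saccades <- function(velocity, acceleration, rate, time = NULL,
                            vel_threshold = 30, acc_threshold = 1000,
                            pad = 0.010) {
  n <- length(velocity)
  if (length(acceleration) != n)
    stop("velocity and acceleration must have equal length", call. = FALSE)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  fast <- velocity > vel_threshold
  seed <- fast & abs(acceleration) > acc_threshold
  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          peak_velocity = numeric(),
                          peak_acceleration = numeric(),
                          i_start = integer(), i_end = integer())
  if (!any(seed)) return(empty)

  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & vapply(seq_along(r$values), function(k)
    r$values[k] && any(seed[starts[k]:ends[k]]), logical(1))
  iv <- cbind(starts[keep], ends[keep])
  if (nrow(iv) == 0) return(empty)

  npad <- as.integer(round(pad * rate))
  iv[, 1] <- pmax(1L, iv[, 1] - npad)
  iv[, 2] <- pmin(n, iv[, 2] + npad)
  # merge overlapping/adjacent intervals
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[k, 1] <= last[2] + 1L) {
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[k, 2]))
      } else merged[[length(merged) + 1L]] <- iv[k, ]
    }
  }
  iv <- do.call(rbind, merged)
  tibble::tibble(
    t_start = time[iv[, 1]], t_end = time[iv[, 2]],
    peak_velocity = vapply(seq_len(nrow(iv)), function(k)
      max(velocity[iv[k, 1]:iv[k, 2]]), numeric(1)),
    peak_acceleration = vapply(seq_len(nrow(iv)), function(k)
      max(abs(acceleration[iv[k, 1]:iv[k, 2]])), numeric(1)),
    i_start = as.integer(iv[, 1]), i_end = as.integer(iv[, 2]))
}

#' Excise intervals and bridge them by linear interpolation
#'
#' Samples strictly inside each interval are replaced by the straight line
#' joining the two boundary samples; all other samples are returned
#' unchanged. Applying the operation twice with the same intervals is a
#' no-op.
#'
#' @param x numeric position samples.
#' @param intervals tibble/data.frame with `i_start`, `i_end` sample
#'   indices (as returned by [detect_saccades()]), or with `t_start`,
#'   `t_end` when `time` is given.
#' @param time optional time base used to translate `t_start`/`t_end`.
#' @return the edited samples.
#' @export
remove_and_interpolate <- function(x, intervals, time = NULL) {
  if (is.null(intervals) || nrow(intervals) == 0) return(x)
  n <- length(x)
  if (!all(c("i_start", "i_end") %in% names(intervals))) {
    if (is.null(time))
      stop("need i_start/i_end indices or a time base", call. = FALSE)
    intervals$i_start <- vapply(intervals$t_start, function(t)
      which.min(abs(time - t)), integer(1))
    intervals$i_end <- vapply(intervals$t_end, function(t)
      which.min(abs(time - t)), integer(1))
  }
  for (k in seq_len(nrow(intervals))) {
    i0 <- intervals$i_start[k]; i1 <- intervals$i_end[k]
    if (i0 < 1 || i1 > n || i0 > i1)
      stop("interval outside the trace", call. = FALSE)
    if (i1 - i0 > 1) {
      inner <- (i0 + 1):(i1 - 1)
      x[inner] <- x[i0] + (x[i1] - x[i0]) * (inner - i0) / (i1 - i0)
    }
  }
  x
}

#' Detect blinks from a missing-sample mask
#'
#' Maximal runs of missing samples, padded by `pad` seconds to cover
#' pupil-loss transients; runs whose padded extents touch are merged.
#'
#' @param missing logical mask, TRUE where the sample is missing.
#' @param rate sampling rate, Hz.
#' @param time optional time base, s.
#' @param pad padding, s.
#' @return tibble with `t_start`, `t_end`, `i_start`, `i_end`.
#' @export
detect_blinks <- function(missing, rate, time = NULL, pad = 0.050) {
  n <- length(missing)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  out <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                        i_start = integer(), i_end = integer())
  if (!any(missing)) return(out)
  r <- rle(as.logical(missing))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  npad <- as.integer(round(pad * rate))
  iv[, 1] <- pmax(1L, iv[, 1] - npad)
  iv[, 2] <- pmin(n, iv[, 2] + npad)
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[k, 1] <= last[2] + 1L) {
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[k, 2]))
      } else merged[[length(merged) + 1L]] <- iv[k, ]
    }
  }
  iv <- do.call(rbind, merged)
  tibble::tibble(t_start = time[iv[, 1]], t_end = time[iv[, 2]],
                 i_start = as.integer(iv[, 1]), i_end = as.integer(iv[, 2]))
}

# linear interpolation across masked samples (rule 2 handles masked ends)
fill_missing <- function(x, missing) {
  if (!any(missing)) return(x)
  if (all(missing)) stop("trace is entirely missing", call. = FALSE)
  idx <- seq_along(x)
  stats::approx(idx[!missing], x[!missing], xout = idx, rule = 2)$y
}

#' Preprocess an eye trace
#'
#' The full signal chain: masked (blink) samples are bridged linearly;
#' position is low-pass filtered at `eye_pos_cutoff`; velocity and
#' acceleration are computed by central differences and filtered at
#' `eye_vel_cutoff`; saccades are detected on the (horizontal, by default)
#' velocity/acceleration; position is desaccaded by linear interpolation
#' and velocity/acceleration recomputed from the desaccaded position.
#'
#' @param eye tibble/data.frame with columns `time`, `x`, `y` and
#'   optionally `missing` (logical).
#' @param rate sampling rate, Hz.
#' @param config an [analysis_config()].
#' @return list with `kin` (tibble: time, x, y, vx, vy, ax, ay —
#'   desaccaded), `saccades`, `blinks`, and `raw_vel` (tibble vx, vy before
#'   desaccading).
#' @export
preprocess_eye <- function(eye, rate = NULL, config = analysis_config()) {
  if (is.null(rate)) rate <- 1 / stats::median(diff(eye$time))
  missing <- if ("missing" %in% names(eye)) as.logical(eye$missing) else
    rep(FALSE, nrow(eye))
  missing <- missing | !is.finite(eye$x) | !is.finite(eye$y)
  if (all(missing)) stop("eye trace is entirely missing", call. = FALSE)
  blinks <- detect_blinks(missing, rate, time = eye$time,
                          pad = config$blink_pad)

  px <- lowpass_filter(fill_missing(eye$x, missing), rate, config$eye_pos_cutoff)
  py <- lowpass_filter(fill_missing(eye$y, missing), rate, config$eye_pos_cutoff)
  vx <- lowpass_filter(central_difference(px, rate), rate, config$eye_vel_cutoff)
  vy <- lowpass_filter(central_difference(py, rate), rate, config$eye_vel_cutoff)
  ax <- lowpass_filter(central_difference(vx, rate), rate, config$eye_vel_cutoff)
  ay <- lowpass_filter(central_difference(vy, rate), rate, config$eye_vel_cutoff)

  if (config$saccade_axis == "x") {
    det_v <- abs(vx); det_a <- ax
  } else {
    det_v <- sqrt(vx^2 + vy^2)
    det_a <- sqrt(ax^2 + ay^2)
  }
  saccades <- detect_saccades(det_v, det_a, rate, time = eye$time,
                              vel_threshold = config$saccade_vel_threshold,
                              acc_threshold = config$saccade_acc_threshold,
                              pad = config$saccade_pad)

  dx <- remove_and_interpolate(px, saccades)
  dy <- remove_and_interpolate(py, saccades)
  vdx <- lowpass_filter(central_difference(dx, rate), rate, config$eye_vel_cutoff)
  vdy <- lowpass_filter(central_difference(dy, rate), rate, config$eye_vel_cutoff)
  adx <- lowpass_filter(central_difference(vdx, rate), rate, config$eye_vel_cutoff)
  ady <- lowpass_filter(central_difference(vdy, rate), rate, config$eye_vel_cutoff)

  list(kin = fast_tbl(time = eye$time, x = dx, y = dy,
                      vx = vdx, vy = vdy, ax = adx, ay = ady),
       saccades = saccades, blinks = blinks,
       raw_vel = fast_tbl(vx = vx, vy = vy))
}

#' Preprocess a cursor trace
#'
#' Position is low-pass filtered at `cursor_cutoff`; velocity and
#' acceleration follow by central differences. No further velocity filter
#' is applied: at a 60 Hz cursor rate the 30 Hz velocity passband used for
#' the eye would sit at the Nyquist frequency.
#'
#' @param cursor tibble/data.frame with `time`, `x`, `y`.
#' @param rate sampling rate, Hz.
#' @param config an [analysis_config()].
#' @return tibble: time, x, y, vx, vy, ax, ay.
#' @export
preprocess_cursor <- function(cursor, rate = NULL,
                              config = analysis_config()) {
  if (is.null(rate)) rate <- 1 / stats::median(diff(cursor$time))
  px <- lowpass_filter(cursor$x, rate, config$cursor_cutoff)
  py <- lowpass_filter(cursor$y, rate, config$cursor_cutoff)
  vx <- central_difference(px, rate)
  vy <- central_difference(py, rate)
  ax <- central_difference(vx, rate)
  ay <- central_difference(vy, rate)
  fast_tbl(time = cursor$time, x = px, y = py,
           vx = vx, vy = vy, ax = ax, ay = ay)
}
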