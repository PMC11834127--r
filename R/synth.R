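# Synthetic cohort generation: participant parameter draws, trial-level
# ground truth, and full eye/cursor traces with planted saccades, blinks
# and (optionally) exclusion violations.

asem_sigmoid <- function(x, a, mu, sigma, b) {
  a / 2 * (1 + erf((x - mu) / (sigma * sqrt(2)))) + b
}

# minimum-jerk position fraction s(tau), tau in [0, 1]
minjerk_s <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

draw2 <- function(p, n) stats::rnorm(n, p[1], p[2])

simulate_participants <- function(cfg) {
  n <- cfg$n_participants
  sp <- cfg$sigmoid_population
  lp <- cfg$latency_population
  tibble::tibble(
    participant = sprintf("p%02d", seq_len(n)),
    a_control = draw2(sp$a_control, n),
    a_gap     = draw2(sp$a_gap, n),
    mu        = draw2(sp$mu, n),
    sigma     = pmax(draw2(sp$sigma, n), 0.02),
    b         = draw2(sp$b, n),
    lat_c     = draw2(lp$c, n),
    lat_mu    = draw2(lp$mu, n),
    lat_sigma = pmax(draw2(lp$sigma, n), 0.02),
    beta0     = draw2(lp$beta0, n),
    beta1     = draw2(lp$beta1, n))
}

#' Simulate trial-level ground truth without traces
#'
#' Draws per-participant tuning and coupling parameters and per-trial true
#' ASEM velocity, target direction and true interception latency, following
#' the generative model described in [simulation_config()]. This is the
#' fast path used by [simulate_cohort()] before trace synthesis; it is also
#' useful on its own for testing the statistical layer at scale.
#'
#' @param config an [simulation_config()] object.
#' @return a tibble with one row per trial (columns `participant`, `trial`,
#'   `condition`, `coherence`, `direction`, `asem_true` (deg/s, raw
#'   rightward-positive), `latency_true` (s), `violation`) carrying the
#'   per-participant parameter draws as attribute `"participants"`.
#' @export
simulate_trial_table <- function(config) {
  stopifnot(inherits(config, "asem_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  pp <- simulate_participants(config)

  grid <- expand.grid(condition = config$conditions,
                      coherence = config$coherence_levels,
                      rep = seq_len(config$trials_per_cell),
                      participant = pp$participant,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant), , drop = FALSE]
  n <- nrow(grid)
  trials <- tibble::tibble(
    participant = grid$participant,
    trial = stats::ave(seq_len(n), grid$participant, FUN = seq_along),
    condition = grid$condition,
    coherence = grid$coherence)

  idx <- match(trials$participant, pp$participant)
  a <- ifelse(trials$condition == config$conditions[1],
              pp$a_control[idx], pp$a_gap[idx])
  v_mean <- asem_sigmoid(trials$coherence, a, pp$mu[idx], pp$sigma[idx],
                         pp$b[idx])
  trials$asem_true <- v_mean + stats::rnorm(n, 0, config$asem_trial_sd)

  dir <- sign(trials$coherence)
  zero <- dir == 0
  dir[zero] <- sample(c(-1, 1), sum(zero), replace = TRUE)
  trials$direction <- dir

  lp <- config$latency_population
  g <- pp$lat_c[idx] *
    exp(-(trials$coherence - pp$lat_mu[idx])^2 / (2 * pp$lat_sigma[idx]^2))
  lat <- pp$beta0[idx] + g +
    pp$beta1[idx] * (trials$asem_true * trials$direction) +
    stats::rnorm(n, 0, lp$resid_sd)
  trials$latency_true <- pmax(lat, config$latency_floor)

  trials$violation <- "none"
  if (config$violation_rate > 0) {
    hit <- stats::runif(n) < config$violation_rate
    kinds <- c("blink_during_motion", "saccade_in_asem_epoch",
               "pre_onset_movement", "latency_over_500ms")
    trials$violation[hit] <- sample(kinds, sum(hit), replace = TRUE)
    late <- trials$violation == "latency_over_500ms"
    trials$latency_true[late] <- stats::runif(sum(late), 0.55, 0.75)
  }
  attr(trials, "participants") <- pp
  trials
}

# anticipatory + pursuit horizontal velocity profile (deg/s) on times t
# relative to target motion onset
eye_velocity_profile <- function(t, v_true, direction, cfg) {
  v <- numeric(length(t))
  t0 <- -cfg$anticipation_start      # ramp start
  t1 <- -cfg$anticipation_plateau    # ramp end (plateau onset)
  ramp <- t >= t0 & t < t1
  v[ramp] <- v_true * (t[ramp] - t0) / (t1 - t0)
  plateau <- t >= t1 & t < cfg$pursuit_latency
  v[plateau] <- v_true
  pursue <- t >= cfg$pursuit_latency
  vt <- cfg$target_speed * direction
  v[pursue] <- vt + (v_true - vt) *
    exp(-(t[pursue] - cfg$pursuit_latency) / cfg$pursuit_tau)
  v
}

#' Add a smooth saccadic displacement to a position trace
#'
#' Superimposes a minimum-jerk (bell-velocity) displacement of the given
#' amplitude over `[time, time + duration]`; samples outside the interval
#' are shifted by 0 (before) or the full amplitude (after), so the edit is
#' purely additive and disjoint edits superpose.
#'
#' @param x numeric position samples (deg).
#' @param time saccade start, s on `timebase`.
#' @param amplitude displacement, deg (signed).
#' @param duration saccade duration, s (> 0).
#' @param rate sampling rate, Hz (used when `timebase` is NULL).
#' @param timebase optional explicit time base, s.
#' @return the edited position samples.
#' @export
inject_saccade <- function(x, time, amplitude, duration, rate = 1000,
                           timebase = NULL) {
  if (is.null(timebase)) timebase <- (seq_along(x) - 1) / rate
  if (length(timebase) != length(x))
    stop("timebase and x must have equal length", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (time < timebase[1] || time + duration > timebase[length(timebase)])
    stop("saccade interval lies outside the trace", call. = FALSE)
  tau <- (timebase - time) / duration
  x + amplitude * minjerk_s(tau)
}

#' Simulate a full synthetic cohort with traces
#'
#' Generates trial-level ground truth via [simulate_trial_table()] and then
#' synthesises, per trial, a 2-D eye position trace (fixational noise, a
#' linear anticipatory velocity ramp reaching the trial's true ASEM
#' velocity before onset, then first-order pursuit of the 8 deg/s target)
#' and a 2-D cursor trace (stationary, then a minimum-jerk reach starting
#' at the true latency toward the interception point). Incidental saccades
#' and blinks are planted away from the ASEM epoch / target motion;
#' `violation_rate` plants excludable trials instead.
#'
#' @param config an [simulation_config()] object.
#' @return an object of class `asem_cohort`: a list with `metadata`
#'   (tibble: participant, trial, condition, coherence, direction,
#'   onset_time), `traces` (named list per trial of `eye` and `cursor`
#'   tibbles), `ground_truth` (trial table plus planted event tables
#'   `saccades`, `blinks` as attributes of the cohort), `participants`,
#'   `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  trials <- simulate_trial_table(config)  # seeds the RNG
  pp <- attr(trials, "participants")
  n <- nrow(trials)

  t_eye <- seq(0, config$pre_onset + config$post_onset, by = 1 / config$eye_rate)
  t_cur <- seq(0, config$pre_onset + config$post_onset, by = 1 / config$cursor_rate)
  onset <- config$pre_onset
  start_pos <- c(0, -15)

  traces <- vector("list", n)
  sacc_list <- vector("list", n)
  blink_list <- vector("list", n)

  for (i in seq_len(n)) {
    tr <- trials[i, ]
    vio <- tr$violation

    ## --- eye ---
    vx <- eye_velocity_profile(t_eye - onset, tr$asem_true, tr$direction,
                               config)
    if (config$noise_sd_eye > 0) {
      vx <- vx + stats::rnorm(length(t_eye), 0, config$noise_sd_eye)
      vy <- stats::rnorm(length(t_eye), 0, config$noise_sd_eye)
    } else vy <- numeric(length(t_eye))
    ex <- cumsum(vx) / config$eye_rate
    ey <- cumsum(vy) / config$eye_rate

    sacc <- NULL
    n_sac <- stats::rpois(1, config$saccade_rate * max(t_eye))
    if (n_sac > 0) {
      for (k in seq_len(n_sac)) {
        dur <- stats::runif(1, config$saccade_duration[1],
                            config$saccade_duration[2])
        t_s <- NA_real_
        for (try in 1:20) {
          cand <- stats::runif(1, 0.05, max(t_eye) - dur - 0.05)
          # keep incidental saccades clear of the ASEM epoch (+ margin)
          if (cand + dur < onset - 0.09 || cand > onset + 0.09) {
            t_s <- cand; break
          }
        }
        if (is.na(t_s)) next
        amp <- stats::runif(1, config$saccade_amplitude[1],
                            config$saccade_amplitude[2]) *
          sample(c(-1, 1), 1)
        ex <- inject_saccade(ex, t_s, amp, dur, timebase = t_eye)
        sacc <- rbind(sacc, data.frame(t_start = t_s, t_end = t_s + dur,
                                       amplitude = amp))
      }
    }
    if (vio == "saccade_in_asem_epoch") {
      dur <- 0.04
      t_s <- onset - 0.02
      amp <- 2 * sample(c(-1, 1), 1)
      ex <- inject_saccade(ex, t_s, amp, dur, timebase = t_eye)
      sacc <- rbind(sacc, data.frame(t_start = t_s, t_end = t_s + dur,
                                     amplitude = amp))
    }

    missing <- rep(FALSE, length(t_eye))
    blink <- NULL
    if (vio == "blink_during_motion") {
      b0 <- onset + 0.1; b1 <- onset + 0.25
      missing[t_eye >= b0 & t_eye <= b1] <- TRUE
      blink <- data.frame(t_start = b0, t_end = b1)
    } else if (stats::runif(1) < config$blink_prob && onset - 0.55 > 0.05) {
      b0 <- stats::runif(1, 0.05, onset - 0.55)
      b1 <- b0 + 0.15
      missing[t_eye >= b0 & t_eye <= b1] <- TRUE
      blink <- data.frame(t_start = b0, t_end = b1)
    }

    ## --- cursor ---
    lat <- if (vio == "pre_onset_movement") -0.2 else tr$latency_true
    reach_start <- onset + lat
    # the reach shoots through the target's y position (overshoot factor
    # kappa), crossing y = 0 at tau_star of the movement; the endpoint is
    # planned so the crossing happens where the target is at that moment
    t_hit <- lat + tau_star_overshoot * config$movement_time
    x_hit <- tr$direction * config$target_speed * t_hit
    xf <- start_pos[1] + reach_overshoot * (x_hit - start_pos[1])
    yf <- start_pos[2] + reach_overshoot * (0 - start_pos[2])
    tau <- (t_cur - reach_start) / config$movement_time
    s <- minjerk_s(tau)
    cx <- start_pos[1] + (xf - start_pos[1]) * s
    cy <- start_pos[2] + (yf - start_pos[2]) * s
    if (config$noise_sd_cursor > 0) {
      cx <- cx + cumsum(stats::rnorm(length(t_cur), 0,
                                     config$noise_sd_cursor)) / config$cursor_rate
      cy <- cy + cumsum(stats::rnorm(length(t_cur), 0,
                                     config$noise_sd_cursor)) / config$cursor_rate
    }

    id <- trial_id(tr$participant, tr$trial)
    traces[[i]] <- list(
      eye = fast_tbl(time = t_eye, x = ex, y = ey, missing = missing),
      cursor = fast_tbl(time = t_cur, x = cx, y = cy))
    names(traces)[i] <- id
    if (!is.null(sacc)) sacc_list[[i]] <- cbind(participant = tr$participant,
                                                trial = tr$trial, sacc)
    if (!is.null(blink)) blink_list[[i]] <- cbind(participant = tr$participant,
                                                  trial = tr$trial, blink)
  }

  metadata <- tibble::tibble(
    participant = trials$participant, trial = trials$trial,
    condition = trials$condition, coherence = trials$coherence,
    direction = trials$direction, onset_time = onset)

  gt <- trials
  attr(gt, "participants") <- NULL
  cohort <- list(
    metadata = metadata,
    traces = stats::setNames(traces, vapply(seq_len(n), function(i)
      trial_id(trials$participant[i], trials$trial[i]), character(1))),
    ground_truth = gt,
    saccades = do.call(rbind, sacc_list[!vapply(sacc_list, is.null, logical(1))]) %||%
      data.frame(participant = character(), trial = integer(),
                 t_start = numeric(), t_end = numeric(), amplitude = numeric()),
    blinks = do.call(rbind, blink_list[!vapply(blink_list, is.null, logical(1))]) %||%
      data.frame(participant = character(), trial = integer(),
                 t_start = numeric(), t_end = numeric()),
    participants = pp,
    config = config)
  class(cohort) <- "asem_cohort"
  cohort
}

trial_id <- function(participant, trial) sprintf("%s_t%03d", participant, trial)

# 15% overshoot past the target's y position ("shoot through" reaches);
# tau_star is the movement fraction at which the minimum-jerk path covers
# 1/kappa of the planned displacement, i.e. crosses the target's y
reach_overshoot <- 1.15
tau_star_overshoot <- stats::uniroot(
  function(tau) minjerk_s(tau) - 1 / reach_overshoot,
  c(0.01, 0.99), tol = 1e-12)$root

#' @export
print.asem_cohort <- function(x, ...) {
  cat("<asem_cohort>\n")
  cat(sprintf("  %d trials, %d participants, conditions: %s\n",
              nrow(x$metadata), length(unique(x$metadata$participant)),
              paste(unique(x$metadata$condition), collapse = ", ")))
  cat(sprintf("  planted saccades: %d, blinks: %d, violations: %d\n",
              nrow(x$saccades), nrow(x$blinks),
              sum(x$ground_truth$violation != "none")))
  invisible(x)
}
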