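# Per-trial scalar features: ASEM velocity, interception onset/latency,
# hand kinematics, and the exclusion rules.

#' Mean anticipatory eye velocity around target motion onset
#'
#' Arithmetic mean of the (desaccaded) horizontal eye velocity over all
#' samples in the closed window `[onset - window, onset + window]`, at the
#' trace's native rate.
#'
#' @param kin a kinematic tibble with `time` and `vx` (e.g.
#'   `preprocess_eye(...)$kin`).
#' @param target_onset target motion onset, s on the trace's clock.
#' @param window half-width, s (default 50 ms).
#' @return mean horizontal velocity, deg/s (raw sign: rightward positive).
#' @export
compute_asem_velocity <- function(kin, target_onset, window = 0.050) {
  eps <- 1e-9
  sel <- kin$time >= target_onset - window - eps &
    kin$time <= target_onset + window + eps
  if (kin$time[1] > target_onset - window + eps ||
      kin$time[nrow(kin)] < target_onset + window - eps)
    stop("ASEM window exceeds the trace", call. = FALSE)
  mean(kin$vx[sel])
}

#' Interception onset from cursor speed
#'
#' Time of the first sample (searching from the trace start, so pre-onset
#' movement is detectable) at which 2-D cursor speed exceeds the
#' criterion.
#'
#' @param kin cursor kinematic tibble with `time`, `vx`, `vy`.
#' @param threshold speed criterion, deg/s.
#' @return onset time, s; `NA_real_` when the cursor never exceeds the
#'   criterion (no usable interception).
#' @export
detect_interception_onset <- function(kin, threshold = 1.0) {
  speed <- sqrt(kin$vx^2 + kin$vy^2)
  i <- which(speed > threshold)
  if (length(i) == 0) return(NA_real_)
  kin$time[i[1]]
}

#' Re-sign a velocity so that target direction is positive
#'
#' @param asem_velocity raw horizontal velocity, deg/s.
#' @param direction target direction, -1 (left) or +1 (right).
#' @return `asem_velocity * direction`.
#' @export
resign_by_direction <- function(asem_velocity, direction) {
  if (!all(direction %in% c(-1, 1)))
    stop("direction must be -1 or +1", call. = FALSE)
  asem_velocity * direction
}

#' Hand-kinematic features of one trial
#'
#' Computes, from the preprocessed cursor trace: initial accelerations
#' (mean per-axis acceleration over the first `accel_window` after target
#' onset), initial direction (angle from the +y midline, rightward
#' positive, of the vector from the start position to the cursor position
#' at peak 2-D acceleration magnitude after interception onset), endpoint
#' error (absolute horizontal distance between cursor and target at the
#' first sample where the cursor reaches the target's y position),
#' movement time (interception onset to that crossing), and per-axis peak
#' velocities over the movement.
#'
#' @param kin cursor kinematic tibble.
#' @param target_onset target motion onset, s.
#' @param direction target direction, -1/+1.
#' @param target_speed target speed, deg/s.
#' @param interception_onset onset time from
#'   [detect_interception_onset()] (NA allowed; all fields become NA).
#' @param start_pos cursor start position `c(x, y)`, deg.
#' @param target_y target vertical position, deg.
#' @param accel_window initial-acceleration window, s.
#' @return one-row tibble of hand features.
#' @export
compute_hand_features <- function(kin, target_onset, direction,
                                  target_speed = 8,
                                  interception_onset = NULL,
                                  start_pos = c(0, -15), target_y = 0,
                                  accel_window = 0.100) {
  if (is.null(interception_onset))
    interception_onset <- detect_interception_onset(kin)
  na_row <- tibble::tibble(
    interception_onset = NA_real_, initial_accel_x = NA_real_,
    initial_accel_y = NA_real_, initial_direction = NA_real_,
    endpoint_error = NA_real_, movement_time = NA_real_,
    peak_velocity_x = NA_real_, peak_velocity_y = NA_real_)
  if (is.na(interception_onset)) return(na_row)

  eps <- 1e-9
  acc_sel <- kin$time > target_onset + eps &
    kin$time <= target_onset + accel_window + eps
  ia_x <- if (any(acc_sel)) mean(kin$ax[acc_sel]) else NA_real_
  ia_y <- if (any(acc_sel)) mean(kin$ay[acc_sel]) else NA_real_

  mv <- kin$time >= interception_onset - eps
  amag <- sqrt(kin$ax^2 + kin$ay^2)
  i_peak <- which(mv)[which.max(amag[mv])]
  dx <- kin$x[i_peak] - start_pos[1]
  dy <- kin$y[i_peak] - start_pos[2]
  init_dir <- atan2(dx, dy) * 180 / pi  # 0 = straight up, right positive

  pvx <- kin$vx[mv][which.max(abs(kin$vx[mv]))]
  pvy <- kin$vy[mv][which.max(abs(kin$vy[mv]))]

  cross <- which(mv & kin$y >= target_y - eps)
  if (length(cross) == 0) {
    ep <- NA_real_; mt <- NA_real_
  } else {
    i_c <- cross[1]
    t_c <- kin$time[i_c]
    target_x <- direction * target_speed * (t_c - target_onset)
    ep <- abs(kin$x[i_c] - target_x)
    mt <- t_c - interception_onset
  }
  tibble::tibble(
    interception_onset = interception_onset,
    initial_accel_x = ia_x, initial_accel_y = ia_y,
    initial_direction = init_dir,
    endpoint_error = ep, movement_time = mt,
    peak_velocity_x = pvx, peak_velocity_y = pvy)
}

#' Apply the trial exclusion rules
#'
#' A trial is excluded when any of the following holds: a blink interval
#' overlaps the target-motion epoch; a saccade interval overlaps the ASEM
#' epoch (`+/- asem_window` around target onset); the interception onset
#' precedes target motion onset (or no onset exists); or the interception
#' latency exceeds `max_latency`. Each rule is evaluated independently and
#' all violated rules are reported.
#'
#' @param interception_onset s, `NA` when the cursor never moved.
#' @param target_onset s.
#' @param motion_end end of target motion epoch, s.
#' @param saccades,blinks interval tibbles with `t_start`, `t_end`.
#' @param asem_window half-width of the ASEM epoch, s.
#' @param max_latency maximum latency, s.
#' @return list with `retained` (flag) and `reasons` (character vector,
#'   empty when retained).
#' @export
apply_exclusion_rules <- function(interception_onset, target_onset,
                                  motion_end, saccades = NULL,
                                  blinks = NULL, asem_window = 0.050,
                                  max_latency = 0.500) {
  reasons <- character()
  overlaps <- function(iv, lo, hi)
    !is.null(iv) && nrow(iv) > 0 && any(iv$t_start <= hi & iv$t_end >= lo)
  if (overlaps(blinks, target_onset, motion_end))
    reasons <- c(reasons, "blink_during_motion")
  if (overlaps(saccades, target_onset - asem_window,
               target_onset + asem_window))
    reasons <- c(reasons, "saccade_in_asem_epoch")
  if (is.na(interception_onset)) {
    reasons <- c(reasons, "no_onset")
  } else {
    if (interception_onset < target_onset)
      reasons <- c(reasons, "pre_onset_movement")
    else if (interception_onset - target_onset > max_latency)
      reasons <- c(reasons, "latency_over_500ms")
  }
  list(retained = length(reasons) == 0, reasons = reasons)
}

#' Extract per-trial features for a whole cohort
#'
#' Runs [preprocess_eye()] and [preprocess_cursor()] on every trial, then
#' computes ASEM velocity, interception onset/latency, hand features and
#' the exclusion outcome. Ground-truth columns are appended when the
#' cohort carries them.
#'
#' @param cohort an `asem_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config an [analysis_config()].
#' @return tibble with one row per trial: metadata, `asem_velocity` (raw),
#'   `asem_velocity_signed`, `latency`, hand features, `retained`,
#'   `exclusion_reasons` (comma-separated), and ground-truth columns if
#'   available.
#' @export
extract_features <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "asem_cohort"))
  md <- cohort$metadata
  n <- nrow(md)
  rows <- vector("list", n)
  eye_rate <- cohort$config$eye_rate %||% NULL
  cur_rate <- cohort$config$cursor_rate %||% NULL
  post <- cohort$config$post_onset %||% 1.2

  for (i in seq_len(n)) {
    id <- trial_id(md$participant[i], md$trial[i])
    tr <- cohort$traces[[id]]
    if (is.null(tr)) stop("no trace for trial ", id, call. = FALSE)
    onset <- md$onset_time[i]

    eye <- preprocess_eye(tr$eye, rate = eye_rate, config = config)
    cur <- preprocess_cursor(tr$cursor, rate = cur_rate, config = config)

    v_asem <- compute_asem_velocity(eye$kin, onset,
                                    window = config$asem_window)
    io <- detect_interception_onset(cur, threshold = config$onset_threshold)
    hand <- compute_hand_features(
      cur, target_onset = onset, direction = md$direction[i],
      target_speed = cohort$config$target_speed %||% 8,
      interception_onset = io, accel_window = config$initial_accel_window)
    exc <- apply_exclusion_rules(
      io, onset, motion_end = onset + post,
      saccades = eye$saccades, blinks = eye$blinks,
      asem_window = config$asem_window, max_latency = config$max_latency)

    rows[[i]] <- tibble::tibble(
      participant = md$participant[i], trial = md$trial[i],
      condition = md$condition[i], coherence = md$coherence[i],
      direction = md$direction[i],
      asem_velocity = v_asem,
      asem_velocity_signed = resign_by_direction(v_asem, md$direction[i]),
      latency = if (is.na(io)) NA_real_ else io - onset,
      hand,
      retained = exc$retained,
      exclusion_reasons = paste(exc$reasons, collapse = ","))
  }
  feats <- do.call(rbind, rows)
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth[, c("participant", "trial", "asem_true",
                                  "latency_true", "violation")]
    feats <- merge(feats, gt, by = c("participant", "trial"), sort = FALSE)
    feats <- feats[order(feats$participant, feats$trial), ]
  }
  tibble::as_tibble(feats)
}
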