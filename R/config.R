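#' Simulation configuration for a synthetic cohort
#'
#' Builds the configuration object consumed by [simulate_trial_table()] and
#' [simulate_cohort()]. Defaults reproduce the study design the analysis
#' assumes: 10 participants, 2 fixation conditions (control / gap) crossed
#' with 9 signed coherence levels at 20 trials per cell (360 trials per
#' participant), a target moving horizontally at 8 deg/s, eye traces sampled
#' at 1 kHz and cursor traces at 60 Hz.
#'
#' Population parameters are given as `c(mean, sd)` pairs; each participant
#' draws their own value. The ASEM-velocity tuning over signed coherence `x`
#' follows the cumulative Gaussian
#' `v(x) = a/2 * (1 + erf((x - mu)/(sigma*sqrt(2)))) + b`
#' with a condition-dependent height (`a_control`, `a_gap`). Per-trial true
#' latency is
#' `beta0_i + c_i * exp(-(x - mu_lat)^2 / (2*sigma_lat^2)) + beta1_i * v_signed + e`,
#' where `v_signed` is the trial's true ASEM velocity re-signed so target
#' direction is positive and `e` is Gaussian residual noise. By default the
#' direct (coherence-Gaussian) pathway has amplitude 0, so the coherence
#' dependence of latency is wholly mediated by the eye; planting `c > 0`
#' adds an unmediated pathway.
#'
#' @param n_participants number of simulated participants.
#' @param trials_per_cell trials per condition x coherence cell.
#' @param coherence_levels signed coherence levels, symmetric about 0.
#' @param conditions condition labels; the first is treated as "control",
#'   the second as "gap" for the height parameter.
#' @param eye_rate,cursor_rate sampling rates, Hz.
#' @param target_speed target speed, deg/s.
#' @param pre_onset,post_onset trace extent before/after target motion
#'   onset, s.
#' @param sigmoid_population list of `c(mean, sd)` for `a_control`, `a_gap`,
#'   `mu`, `sigma`, `b` of the ASEM tuning curve.
#' @param asem_trial_sd trial-to-trial SD of true ASEM velocity, deg/s.
#' @param latency_population list of `c(mean, sd)` for the latency model:
#'   `c`, `mu`, `sigma` (coherence-Gaussian component), `beta0` (participant
#'   intercept, s), `beta1` (coupling slope, s per deg/s), and scalar
#'   `resid_sd` (s).
#' @param latency_floor minimum simulated latency, s.
#' @param pursuit_latency visually driven pursuit latency after onset, s.
#' @param pursuit_tau time constant of the first-order approach to target
#'   speed, s.
#' @param anticipation_start time before onset at which the anticipatory
#'   ramp starts, s (the gap duration).
#' @param anticipation_plateau time before onset at which the ramp reaches
#'   the trial's true ASEM velocity, s.
#' @param saccade_rate rate of incidental saccades, events/s. Incidental
#'   saccades are kept clear of the ASEM epoch so they do not trigger
#'   exclusion; epoch saccades are planted only via `violation_rate`.
#' @param saccade_amplitude,saccade_duration ranges (`c(lo, hi)`) for
#'   incidental saccade amplitude (deg) and duration (s).
#' @param blink_prob per-trial probability of an incidental blink before
#'   target motion.
#' @param noise_sd_eye,noise_sd_cursor white velocity-noise SD integrated
#'   into the position traces, deg/s.
#' @param movement_time duration of the interceptive reach, s.
#' @param violation_rate fraction of trials planted with an exclusion
#'   violation (blink during motion, saccade in the ASEM epoch, pre-onset
#'   movement, or latency > 500 ms, drawn uniformly).
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   cohort.
#'
#' @return an object of class `asem_sim_config` (a named list).
#' @export
simulation_config <- function(n_participants = 10,
                              trials_per_cell = 20,
                              coherence_levels = c(-0.64, -0.32, -0.16, -0.08,
                                                   0, 0.08, 0.16, 0.32, 0.64),
                              conditions = c("control", "gap"),
                              eye_rate = 1000,
                              cursor_rate = 60,
                              target_speed = 8,
                              pre_onset = 0.8,
                              post_onset = 1.2,
                              sigmoid_population = list(
                                a_control = c(0.85, 0.15),
                                a_gap     = c(1.60, 0.20),
                                mu        = c(0.00, 0.02),
                                sigma     = c(0.20, 0.04),
                                b         = c(-0.45, 0.08)),
                              asem_trial_sd = 0.3,
                              latency_population = list(
                                c      = c(0.00, 0.00),
                                mu     = c(0.00, 0.00),
                                sigma  = c(0.30, 0.00),
                                beta0  = c(0.315, 0.04),
                                beta1  = c(-0.03, 0.01),
                                resid_sd = 0.05),
                              latency_floor = 0.05,
                              pursuit_latency = 0.1,
                              pursuit_tau = 0.12,
                              anticipation_start = 0.3,
                              anticipation_plateau = 0.15,
                              saccade_rate = 0.2,
                              saccade_amplitude = c(1, 4),
                              saccade_duration = c(0.02, 0.05),
                              blink_prob = 0.05,
                              noise_sd_eye = 0.2,
                              noise_sd_cursor = 0.1,
                              movement_time = 0.45,
                              violation_rate = 0,
                              seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    trials_per_cell = as.integer(trials_per_cell),
    coherence_levels = as.numeric(coherence_levels),
    conditions = as.character(conditions),
    eye_rate = eye_rate, cursor_rate = cursor_rate,
    target_speed = target_speed,
    pre_onset = pre_onset, post_onset = post_onset,
    sigmoid_population = sigmoid_population,
    asem_trial_sd = asem_trial_sd,
    latency_population = latency_population,
    latency_floor = latency_floor,
    pursuit_latency = pursuit_latency, pursuit_tau = pursuit_tau,
    anticipation_start = anticipation_start,
    anticipation_plateau = anticipation_plateau,
    saccade_rate = saccade_rate,
    saccade_amplitude = saccade_amplitude,
    saccade_duration = saccade_duration,
    blink_prob = blink_prob,
    noise_sd_eye = noise_sd_eye, noise_sd_cursor = noise_sd_cursor,
    movement_time = movement_time,
    violation_rate = violation_rate,
    seed = as.integer(seed))
  class(cfg) <- "asem_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$eye_rate, cfg$cursor_rate, cfg$target_speed)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rates and the target speed must be positive", call. = FALSE)
  if (cfg$n_participants < 1L || cfg$trials_per_cell < 1L)
    stop("n_participants and trials_per_cell must be >= 1", call. = FALSE)
  if (length(cfg$coherence_levels) == 0)
    stop("coherence_levels must be non-empty", call. = FALSE)
  lv <- sort(cfg$coherence_levels)
  if (max(abs(lv + rev(lv))) > 1e-12)
    stop("coherence_levels must be symmetric about 0", call. = FALSE)
  sds <- c(vapply(cfg$sigmoid_population, `[`, numeric(1), 2),
           vapply(cfg$latency_population[c("c", "mu", "sigma", "beta0", "beta1")],
                  `[`, numeric(1), 2),
           cfg$latency_population$resid_sd,
           cfg$asem_trial_sd, cfg$noise_sd_eye, cfg$noise_sd_cursor)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (cfg$violation_rate < 0 || cfg$violation_rate > 1)
    stop("violation_rate must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Analysis configuration
#'
#' All tunable constants of the analysis chain, with defaults equal to the
#' values the pipeline is designed around: 15 Hz low-pass for eye position,
#' 30 Hz for eye velocity/acceleration, 20 Hz for cursor position; saccade
#' criteria of velocity > 30 deg/s jointly with |acceleration| >
#' 1000 deg/s^2; a +/- 50 ms ASEM window around target motion onset; a
#' 1.0 deg/s cursor-speed criterion for interception onset; a 100 ms window
#' for initial hand acceleration; a 500 ms maximum latency; and a 20%
#' selection fraction for the extreme-quintile contrast.
#'
#' @param eye_pos_cutoff,eye_vel_cutoff,cursor_cutoff Butterworth passband
#'   edges, Hz.
#' @param saccade_vel_threshold deg/s.
#' @param saccade_acc_threshold deg/s^2.
#' @param saccade_pad padding added to each side of a detected saccade
#'   before removal, s. The default (25 ms) spans the tails the 15 Hz
#'   position filter smears beyond the velocity-criterion core, so the
#'   bridged gap carries the interpolation slope rather than saccade
#'   remnants.
#' @param blink_pad padding added to each side of a blink, s.
#' @param asem_window half-width of the ASEM-velocity window, s.
#' @param onset_threshold cursor speed criterion for interception onset,
#'   deg/s.
#' @param initial_accel_window window after target onset for initial hand
#'   acceleration, s.
#' @param max_latency exclusion threshold on interception latency, s.
#' @param quintile_frac selection fraction for the extreme-quintile
#'   contrast.
#' @param min_cell_trials minimum retained trials per cell for the
#'   extreme-quintile contrast.
#' @param saccade_axis `"x"` (horizontal; stimuli move horizontally) or
#'   `"both"` for the detection signals.
#' @return an object of class `asem_analysis_config`.
#' @export
analysis_config <- function(eye_pos_cutoff = 15,
                            eye_vel_cutoff = 30,
                            cursor_cutoff = 20,
                            saccade_vel_threshold = 30,
                            saccade_acc_threshold = 1000,
                            saccade_pad = 0.025,
                            blink_pad = 0.050,
                            asem_window = 0.050,
                            onset_threshold = 1.0,
                            initial_accel_window = 0.100,
                            max_latency = 0.500,
                            quintile_frac = 0.20,
                            min_cell_trials = 5L,
                            saccade_axis = c("x", "both")) {
  cfg <- list(
    eye_pos_cutoff = eye_pos_cutoff,
    eye_vel_cutoff = eye_vel_cutoff,
    cursor_cutoff = cursor_cutoff,
    saccade_vel_threshold = saccade_vel_threshold,
    saccade_acc_threshold = saccade_acc_threshold,
    saccade_pad = saccade_pad,
    blink_pad = blink_pad,
    asem_window = asem_window,
    onset_threshold = onset_threshold,
    initial_accel_window = initial_accel_window,
    max_latency = max_latency,
    quintile_frac = quintile_frac,
    min_cell_trials = as.integer(min_cell_trials),
    saccade_axis = match.arg(saccade_axis))
  class(cfg) <- "asem_analysis_config"
  cfg
}

#' @export
print.asem_sim_config <- function(x, ...) {
  cat("<asem_sim_config>\n")
  cat(sprintf("  %d participants x %d conditions x %d coherences x %d trials = %d trials each\n",
              x$n_participants, length(x$conditions),
              length(x$coherence_levels), x$trials_per_cell,
              length(x$conditions) * length(x$coherence_levels) * x$trials_per_cell))
  cat(sprintf("  eye %g Hz, cursor %g Hz, target %g deg/s, seed %d\n",
              x$eye_rate, x$cursor_rate, x$target_speed, x$seed))
  invisible(x)
}

#' @export
print.asem_analysis_config <- function(x, ...) {
  cat("<asem_analysis_config>\n")
  cat(sprintf("  filters: eye pos %g Hz, eye vel %g Hz, cursor %g Hz\n",
              x$eye_pos_cutoff, x$eye_vel_cutoff, x$cursor_cutoff))
  cat(sprintf("  saccade: v > %g deg/s & |a| > %g deg/s^2 (pad %g ms)\n",
              x$saccade_vel_threshold, x$saccade_acc_threshold,
              1000 * x$saccade_pad))
  cat(sprintf("  ASEM window +/- %g ms, onset > %g deg/s, max latency %g ms\n",
              1000 * x$asem_window, x$onset_threshold, 1000 * x$max_latency))
  invisible(x)
}

# stable short hash of a configuration (provenance stamp on outputs):
# a polynomial rolling hash over the serialized object bytes
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(unclass(cfg), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
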