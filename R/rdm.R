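# Random-dot motion (RDM) stimulus kinematics: three interleaved dot sets,
# each redrawn three frames after it is shown, either displaced coherently
# (a "signal" redraw, probability |coherence|) or at a random aperture
# location.

#' Generate random-dot motion frame kinematics
#'
#' Simulates the dot-field update rule of the coherence-cued stimulus:
#' dots are split into three interleaved sets shown on successive frames;
#' when a dot disappears it is redrawn three frames later, displaced by
#' `speed * 3 / refresh` deg in the coherent direction with probability
#' `|coherence|` (a signal redraw) or at a uniform-random location inside
#' the circular aperture otherwise. A signal redraw that would land outside
#' the aperture re-enters at the diametrically opposite point (wrap),
#' keeping the dot count and signal fraction intact.
#'
#' @param coherence signed fraction in `[-1, 1]`; the sign sets the motion
#'   direction (positive = rightward).
#' @param duration stimulus duration, s.
#' @param refresh display refresh rate, Hz.
#' @param aperture aperture diameter, deg.
#' @param density dot density, dots/deg^2/s (dots drawn per deg^2 per
#'   second, aggregated over frames).
#' @param speed coherent dot speed, deg/s.
#' @param seed integer seed.
#' @return an object of class `rdm_frameset`: list with `frames` (tibble:
#'   frame, dot, x, y, set, signal, wrapped), `displacement` (deg per
#'   redraw), `aperture`, `coherence`, `n_dots_per_frame`.
#' @export
generate_rdm_frames <- function(coherence, duration = 1, refresh = 60,
                                aperture = 15, density = 16.7, speed = 8,
                                seed = 1L) {
  if (!is.finite(coherence) || abs(coherence) > 1)
    stop("|coherence| must be <= 1", call. = FALSE)
  if (refresh <= 0 || duration <= 0)
    stop("refresh and duration must be positive", call. = FALSE)
  n_frames <- floor(duration * refresh)
  if (n_frames < 3)
    stop("duration too short for the 3-frame redraw cycle", call. = FALSE)
  set.seed(seed)

  R <- aperture / 2
  area <- pi * R^2
  n_per_frame <- max(1L, round(density * area / refresh))
  disp <- speed * 3 / refresh
  dir <- if (coherence >= 0) 1 else -1

  rand_in_aperture <- function(n) {
    r <- R * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  }

  # positions of each of the three sets; set s is visible on frames
  # s, s+3, s+6, ... (1-based)
  pos <- lapply(1:3, function(s) rand_in_aperture(n_per_frame))
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    s <- ((f - 1) %% 3) + 1
    if (f <= 3) {
      sig <- rep(FALSE, n_per_frame)
      wrapped <- rep(FALSE, n_per_frame)
    } else {
      # this set was last shown on frame f-3 and is now redrawn
      sig <- stats::runif(n_per_frame) < abs(coherence)
      p <- pos[[s]]
      p[sig, 1] <- p[sig, 1] + dir * disp
      wrapped <- rep(FALSE, n_per_frame)
      outside <- sig & (p[, 1]^2 + p[, 2]^2 > R^2)
      if (any(outside)) {
        # re-enter at the diametrically opposite point
        nr <- sqrt(p[outside, 1]^2 + p[outside, 2]^2)
        p[outside, 1] <- p[outside, 1] * (1 - 2 * R / nr)
        p[outside, 2] <- p[outside, 2] * (1 - 2 * R / nr)
        wrapped[outside] <- TRUE
      }
      p[!sig, ] <- rand_in_aperture(sum(!sig))
      pos[[s]] <- p
    }
    out[[f]] <- tibble::tibble(
      frame = f, dot = seq_len(n_per_frame),
      x = pos[[s]][, 1], y = pos[[s]][, 2],
      set = s, signal = sig, wrapped = wrapped)
  }
  res <- list(frames = do.call(rbind, out),
              displacement = disp, aperture = aperture,
              coherence = coherence, n_dots_per_frame = n_per_frame,
              refresh = refresh)
  class(res) <- "rdm_frameset"
  res
}

#' Empirical coherence of an RDM frame set
#'
#' Fraction of redraws flagged as signal (first showing of each set
#' excluded, since those dots have no predecessor).
#' @param rdm an `rdm_frameset`.
#' @return list with `fraction`, `n_redraws`.
#' @export
rdm_signal_fraction <- function(rdm) {
  stopifnot(inherits(rdm, "rdm_frameset"))
  fr <- rdm$frames[rdm$frames$frame > 3, ]
  list(fraction = mean(fr$signal), n_redraws = nrow(fr))
}

#' @export
print.rdm_frameset <- function(x, ...) {
  cat(sprintf("<rdm_frameset> %d frames, %d dots/frame, coherence %+0.2f, displacement %.3f deg\n",
              max(x$frames$frame), x$n_dots_per_frame, x$coherence,
              x$displacement))
  invisible(x)
}
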