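# Psychometric layer: cumulative-Gaussian fit of ASEM velocity over signed
# coherence, Gaussian fit of latency over coherence, condition contrasts on
# fitted parameters, and pooled z-normalized distributions.

fit_nls_multistart <- function(x, y, model, starts, lower, upper,
                               par_names) {
  best <- NULL; best_ss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        model, data = data.frame(x = x, y = y), start = s,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(resid(fit)^2)
      if (ss < best_ss) { best <- fit; best_ss <- ss }
    }
  }
  best
}

finish_fit <- function(fit, y, par_names, out_names) {
  ss_tot <- sum((y - mean(y))^2)
  if (is.null(fit)) {
    pars <- stats::setNames(rep(NA_real_, length(out_names)), out_names)
    return(tibble::tibble(!!!as.list(pars), r_squared = NA_real_,
                          converged = FALSE))
  }
  cf <- coef(fit)[par_names]
  ss_res <- sum(resid(fit)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  tibble::tibble(!!!stats::setNames(as.list(unname(cf)), out_names),
                 r_squared = r2,
                 converged = TRUE)
}

#' Fit a cumulative Gaussian to per-coherence ASEM velocities
#'
#' Least-squares fit of `y = a/2 * (1 + erf((x - mu)/(sigma*sqrt(2)))) + b`
#' where `x` is signed motion coherence, `a` the curve height, `b` the
#' baseline (lower asymptote). Multi-start Levenberg-Marquardt with starts
#' on a `mu x sigma` grid and bounds `sigma` in `(1e-3, 2]`, `|mu| <= 1`;
#' nine-point fits are initialization-sensitive, so the best of all starts
#' by residual sum of squares is kept. Flat data (zero variance across
#' coherences) are unidentifiable and returned with `converged = FALSE`.
#'
#' @param coherences signed coherence levels.
#' @param means mean ASEM velocity per level, deg/s.
#' @return one-row tibble: `a`, `mu`, `sigma`, `b`, `r_squared`,
#'   `converged`.
#' @export
fit_cumulative_gaussian <- function(coherences, means) {
  if (length(coherences) != length(means))
    stop("coherences and means must have equal length", call. = FALSE)
  ok <- is.finite(coherences) & is.finite(means)
  x <- coherences[ok]; y <- means[ok]
  if (length(x) < 5)
    stop("need at least 5 coherence points", call. = FALSE)
  if (stats::sd(y) < 1e-12) {
    return(tibble::tibble(a = 0, mu = NA_real_, sigma = NA_real_,
                          b = mean(y), r_squared = NA_real_,
                          converged = FALSE))
  }
  rng <- max(y) - min(y)
  starts <- list()
  for (mu0 in c(-0.2, 0, 0.2)) for (s0 in c(0.1, 0.3))
    starts[[length(starts) + 1]] <-
      list(a = rng, mu = mu0, sigma = s0, b = min(y))
  fit <- fit_nls_multistart(
    x, y, y ~ a / 2 * (1 + erf((x - mu) / (sigma * sqrt(2)))) + b,
    starts, lower = c(a = -Inf, mu = -1, sigma = 1e-3, b = -Inf),
    upper = c(a = Inf, mu = 1, sigma = 2, b = Inf),
    par_names = c("a", "mu", "sigma", "b"))
  finish_fit(fit, y, c("a", "mu", "sigma", "b"), c("a", "mu", "sigma", "b"))
}

#' Fit a Gaussian to per-coherence interception latencies
#'
#' Least-squares fit of `y = c * exp(-(x - mu)^2 / (2*sigma^2)) + d`,
#' where `c` is the peak amplitude over the constant offset `d`. Same
#' multi-start scheme and bounds as [fit_cumulative_gaussian()]. Monotone
#' (non-peaked) data return the best attainable fit, typically with a wide
#' `sigma`, rather than an error.
#'
#' @param coherences signed coherence levels.
#' @param means mean latency per level, s.
#' @return one-row tibble: `c`, `mu`, `sigma`, `d`, `r_squared`,
#'   `converged`.
#' @export
fit_latency_gaussian <- function(coherences, means) {
  if (length(coherences) != length(means))
    stop("coherences and means must have equal length", call. = FALSE)
  ok <- is.finite(coherences) & is.finite(means)
  x <- coherences[ok]; y <- means[ok]
  if (length(x) < 5)
    stop("need at least 5 coherence points", call. = FALSE)
  if (stats::sd(y) < 1e-12) {
    return(tibble::tibble(c = 0, mu = NA_real_, sigma = NA_real_,
                          d = mean(y), r_squared = NA_real_,
                          converged = FALSE))
  }
  rng <- max(y) - min(y)
  starts <- list()
  for (mu0 in c(-0.2, 0, 0.2)) for (s0 in c(0.1, 0.3)) {
    starts[[length(starts) + 1]] <-
      list(c = rng, mu = mu0, sigma = s0, d = min(y))
    starts[[length(starts) + 1]] <-
      list(c = -rng, mu = mu0, sigma = s0, d = max(y))
  }
  fit <- fit_nls_multistart(
    x, y, y ~ c * exp(-(x - mu)^2 / (2 * sigma^2)) + d,
    starts, lower = c(c = -Inf, mu = -1, sigma = 1e-3, d = -Inf),
    upper = c(c = Inf, mu = 1, sigma = 2, d = Inf),
    par_names = c("c", "mu", "sigma", "d"))
  finish_fit(fit, y, c("c", "mu", "sigma", "d"), c("c", "mu", "sigma", "d"))
}

#' Fit both psychometric curves per participant and condition
#'
#' Computes condition x coherence cell means of retained trials and fits
#' the cumulative Gaussian (raw ASEM velocity over signed coherence) and
#' the latency Gaussian per participant and condition.
#'
#' @param features a features table from [extract_features()] (or any
#'   table with `participant`, `condition`, `coherence`, `asem_velocity`,
#'   `latency`, `retained`).
#' @return list with tibbles `asem` (participant, condition, a, mu, sigma,
#'   b, r_squared, converged) and `latency` (participant, condition, c,
#'   mu, sigma, d, r_squared, converged).
#' @export
fit_psychometric_curves <- function(features) {
  f <- features[features$retained & is.finite(features$latency), ]
  cells <- stats::aggregate(
    cbind(asem_velocity, latency) ~ participant + condition + coherence,
    data = f, FUN = mean)
  combos <- unique(cells[, c("participant", "condition")])
  asem <- list(); lat <- list()
  for (k in seq_len(nrow(combos))) {
    sel <- cells$participant == combos$participant[k] &
      cells$condition == combos$condition[k]
    cc <- cells[sel, ]
    asem[[k]] <- cbind(combos[k, ],
                       fit_cumulative_gaussian(cc$coherence, cc$asem_velocity))
    lat[[k]] <- cbind(combos[k, ],
                      fit_latency_gaussian(cc$coherence, cc$latency))
  }
  list(asem = tibble::as_tibble(do.call(rbind, asem)),
       latency = tibble::as_tibble(do.call(rbind, lat)))
}

#' Paired per-participant values of a fitted parameter across conditions
#'
#' @param fits a fits tibble (one of the elements of
#'   [fit_psychometric_curves()] output).
#' @param parameter column name, e.g. `"a"` (sigmoid height) or `"d"`
#'   (latency offset).
#' @param conditions the two condition labels, in (reference, contrast)
#'   order.
#' @return tibble: participant, the parameter per condition, `diff`
#'   (second minus first).
#' @export
condition_contrast <- function(fits, parameter,
                               conditions = c("control", "gap")) {
  stopifnot(parameter %in% names(fits))
  ps <- unique(fits$participant)
  v1 <- v2 <- rep(NA_real_, length(ps))
  for (i in seq_along(ps)) {
    r1 <- fits[fits$participant == ps[i] & fits$condition == conditions[1], ]
    r2 <- fits[fits$participant == ps[i] & fits$condition == conditions[2], ]
    if (nrow(r1) != 1 || nrow(r2) != 1)
      stop("participant ", ps[i], " is missing a condition fit",
           call. = FALSE)
    v1[i] <- r1[[parameter]]; v2[i] <- r2[[parameter]]
  }
  out <- tibble::tibble(participant = ps, v1 = v1, v2 = v2,
                        diff = v2 - v1)
  names(out)[2:3] <- conditions
  out
}

#' Pooled z-normalized ASEM-velocity distributions
#'
#' z-normalizes each participant's ASEM velocities across ALL of that
#' participant's trials (not per cell), pools participants, and exposes
#' cumulative frequency curves per condition x coherence group. A bimodal
#' group distribution would indicate that the eye reflects the categorical
#' decision outcome; unimodality indicates graded decision confidence.
#'
#' @param features features table; only retained trials are used.
#' @param value column to normalize (default `"asem_velocity"`).
#' @return object of class `asem_zdist`: tibble `z_scores` (participant,
#'   condition, coherence, z).
#' @export
znormalize_and_pool <- function(features, value = "asem_velocity") {
  f <- features[features$retained, ]
  ps <- unique(f$participant)
  zs <- rep(NA_real_, nrow(f))
  for (p in ps) {
    sel <- f$participant == p
    if (sum(sel) < 2)
      stop("participant ", p, " has fewer than 2 trials", call. = FALSE)
    v <- f[[value]][sel]
    s <- stats::sd(v)
    if (s < 1e-12)
      stop("participant ", p, " has zero variance in ", value,
           call. = FALSE)
    zs[sel] <- (v - mean(v)) / s
  }
  out <- list(z_scores = tibble::tibble(
    participant = f$participant, condition = f$condition,
    coherence = f$coherence, z = zs))
  class(out) <- "asem_zdist"
  out
}

#' Cumulative frequency curve of one condition x coherence group
#'
#' @param zdist an `asem_zdist`.
#' @param condition,coherence group selectors.
#' @return tibble with the sorted pooled z-scores (`z`) and the cumulative
#'   frequency (`cumfreq`), rising from 1/n to 1.
#' @export
cumulative_frequency <- function(zdist, condition, coherence) {
  stopifnot(inherits(zdist, "asem_zdist"))
  z <- zdist$z_scores
  sel <- z$condition == condition & abs(z$coherence - coherence) < 1e-12
  v <- sort(z$z[sel])
  tibble::tibble(z = v, cumfreq = seq_along(v) / length(v))
}

#' Count modes of a kernel density estimate
#'
#' Simple unimodality check used on the pooled z-score groups: number of
#' local maxima of a Gaussian kernel density estimate at the given
#' bandwidth.
#'
#' @param x numeric sample.
#' @param bw bandwidth passed to [stats::density()] (default `"SJ"` falls
#'   back to `"nrd0"` on failure).
#' @return integer mode count.
#' @export
count_density_modes <- function(x, bw = "nrd0") {
  d <- stats::density(x, bw = bw)
  y <- d$y
  # local maxima strictly above both neighbours, ignoring numerical dust
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  floor_ <- 0.05 * max(y)
  sum(y[peaks] > floor_)
}
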