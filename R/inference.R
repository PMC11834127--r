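# Statistical layer: paired tests with effect sizes, two-way
# repeated-measures ANOVA with Holm-corrected post hocs, the
# three-candidate linear mixed-effects comparison by BIC, per-participant
# regressions and the extreme-quintile control contrast.

#' Paired t test with Cohen's d
#'
#' Two-sided paired t test on `x - y` with both common effect-size
#' conventions: `cohens_d` is the paired-differences convention
#' `mean(d)/sd(d)` (d_z); `cohens_d_av` standardizes by the average of the
#' two condition SDs (d_av), which is often what published values of
#' within-subject contrasts correspond to.
#'
#' @param x,y paired per-participant values (equal length, n >= 3).
#' @return list of class `paired_test`: `t`, `df`, `p`, `cohens_d`,
#'   `cohens_d_av`, `mean_diff`, `n`.
#' @export
paired_t_cohens_d <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd < 1e-15) {
    if (all(abs(d) < 1e-15)) {
      out <- list(t = 0, df = n - 1, p = 1, cohens_d = 0,
                  cohens_d_av = 0, mean_diff = 0, n = n)
      class(out) <- "paired_test"
      return(out)
    }
    stop("zero variance of paired differences", call. = FALSE)
  }
  t <- mean(d) / (sdd / sqrt(n))
  out <- list(
    t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
    cohens_d = mean(d) / sdd,
    cohens_d_av = mean(d) / ((stats::sd(x) + stats::sd(y)) / 2),
    mean_diff = mean(d), n = n)
  class(out) <- "paired_test"
  out
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.3g, d_z = %.3f, d_av = %.3f, mean diff = %.4g\n",
              x$df, x$t, x$p, x$cohens_d, x$cohens_d_av, x$mean_diff))
  invisible(x)
}

#' Two-way repeated-measures ANOVA with Holm-corrected post hocs
#'
#' Within-participant two-way ANOVA (condition x coherence) on per-cell
#' participant means of the chosen dependent variable, followed, for
#' significant main effects, by pairwise paired t tests with Holm
#' adjustment. Cells with no retained trials raise an error naming them.
#' Effects with zero sum of squares are reported as F = 0, p = 1.
#'
#' @param features features table (retained trials are used).
#' @param dv dependent-variable column name.
#' @param alpha significance level gating the post hocs.
#' @return list of class `rm_anova`: `table` (effect, df1, df2, F, p),
#'   `posthoc` (list per significant effect of tibbles with Holm-adjusted
#'   p), `cells` (the participant x cell means).
#' @export
rm_anova_holm <- function(features, dv, alpha = 0.05) {
  f <- features[features$retained & is.finite(features[[dv]]), ]
  cells <- stats::aggregate(f[[dv]],
                            by = list(participant = f$participant,
                                      condition = f$condition,
                                      coherence = f$coherence),
                            FUN = mean)
  names(cells)[4] <- "y"
  full <- expand.grid(participant = unique(f$participant),
                      condition = unique(f$condition),
                      coherence = unique(f$coherence),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  chk <- merge(full, cells, all.x = TRUE)
  if (anyNA(chk$y)) {
    bad <- chk[is.na(chk$y), c("participant", "condition", "coherence")]
    stop("empty cells: ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  cells$participant <- factor(cells$participant)
  cells$condition <- factor(cells$condition)
  cells$coherence_f <- factor(cells$coherence)

  fit <- stats::aov(y ~ condition * coherence_f +
                      Error(participant / (condition * coherence_f)),
                    data = cells)
  s <- summary(fit)
  pick <- function(stratum, row) {
    tab <- s[[stratum]][[1]]
    i <- grep(row, trimws(rownames(tab)), fixed = TRUE)[1]
    c(df1 = tab$Df[i], df2 = tab$Df[nrow(tab)],
      ss = tab$`Sum Sq`[i], F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  eff <- rbind(
    condition = pick("Error: participant:condition", "condition"),
    coherence = pick("Error: participant:coherence_f", "coherence_f"),
    interaction = pick("Error: participant:condition:coherence_f",
                       "condition:coherence_f"))
  tab <- tibble::tibble(effect = rownames(eff),
                        df1 = unname(eff[, "df1"]), df2 = unname(eff[, "df2"]),
                        F = unname(eff[, "F"]), p = unname(eff[, "p"]))
  # degenerate inputs: zero effect variance
  zero <- eff[, "ss"] < 1e-12
  tab$F[zero] <- 0; tab$p[zero] <- 1
  tab$F[is.na(tab$F)] <- 0; tab$p[is.na(tab$p)] <- 1

  posthoc <- list()
  wide_t <- function(split_col) {
    m <- stats::aggregate(cells$y,
                          by = list(participant = cells$participant,
                                    lev = cells[[split_col]]),
                          FUN = mean)
    names(m)[3] <- "y"
    m <- m[order(m$lev, m$participant), ]
    pairs <- utils::combn(levels(m$lev), 2, simplify = FALSE)
    res <- lapply(pairs, function(pr) {
      a <- m$y[m$lev == pr[1]]
      b <- m$y[m$lev == pr[2]]
      d <- a - b
      if (stats::sd(d) < 1e-15 && any(abs(d) > 1e-15)) {
        # constant nonzero difference: the statistic degenerates
        tt <- list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0)
      } else tt <- paired_t_cohens_d(a, b)
      tibble::tibble(level_1 = as.character(pr[1]),
                     level_2 = as.character(pr[2]),
                     t = tt$t, df = tt$df, p = tt$p)
    })
    res <- do.call(rbind, res)
    res$p_holm <- stats::p.adjust(res$p, method = "holm")
    res
  }
  if (tab$p[tab$effect == "condition"] < alpha)
    posthoc$condition <- wide_t("condition")
  if (tab$p[tab$effect == "coherence"] < alpha)
    posthoc$coherence <- wide_t("coherence_f")

  out <- list(table = tab, posthoc = posthoc, cells = tibble::as_tibble(cells))
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA\n")
  print(as.data.frame(x$table), row.names = FALSE)
  if (length(x$posthoc))
    cat("Holm-corrected post hocs computed for:",
        paste(names(x$posthoc), collapse = ", "), "\n")
  invisible(x)
}

#' Holm step-down adjustment
#'
#' Thin, named wrapper over `stats::p.adjust(method = "holm")` so the
#' correction used by the post hocs is directly testable.
#' @param p raw p values.
#' @return adjusted p values in the original order.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Fit and compare the three latency ~ ASEM velocity mixed models
#'
#' The three candidates, all with interception latency (s) as the
#' dependent variable and direction-signed ASEM velocity as the fixed
#' effect, are: (1) correlated random intercept + slope per participant,
#' (2) random intercept per participant, (3) fixed effects only (ordinary
#' least squares). All are fitted by maximum likelihood (not REML) so
#' their BICs, `-2 logLik + k log(n_obs)`, are comparable across
#' random-effects structures. The minimum-BIC model is selected; its fixed
#' slope is reported with SE, `t = estimate/SE`, and a two-sided p from a
#' t distribution on `n_obs - 2` residual degrees of freedom.
#'
#' @param trials table of retained trials with columns `latency` (s),
#'   `asem_velocity_signed` (deg/s), `participant`.
#' @return object of class `lme_comparison`: `table` (model, k, logLik,
#'   BIC, singular), `best` (model id), `fixed` (intercept, slope,
#'   slope_se, t, df, p), `r_squared` (list: marginal, conditional),
#'   `participant_effects` (per-participant fitted intercept/slope of the
#'   random-slope model), `n_obs`, `models` (the fitted objects).
#' @export
fit_lme_candidates <- function(trials) {
  d <- data.frame(latency = trials$latency,
                  v = trials$asem_velocity_signed,
                  participant = factor(trials$participant))
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (length(unique(d$participant)) < 2)
    stop("need at least 2 participants", call. = FALSE)
  if (stats::sd(d$v) < 1e-12)
    stop("ASEM velocity is constant; slope unidentifiable", call. = FALSE)

  m1 <- suppressMessages(suppressWarnings(
    lme4::lmer(latency ~ v + (1 + v | participant), data = d, REML = FALSE)))
  m2 <- suppressMessages(suppressWarnings(
    lme4::lmer(latency ~ v + (1 | participant), data = d, REML = FALSE)))
  m3 <- stats::lm(latency ~ v, data = d)

  models <- list(`random_slope_intercept` = m1,
                 `random_intercept` = m2,
                 `fixed_only` = m3)
  ll <- unname(vapply(models, function(m) as.numeric(logLik(m)), numeric(1)))
  ks <- unname(vapply(models, function(m) attr(logLik(m), "df"), numeric(1)))
  bic <- -2 * ll + ks * log(n)
  singular <- c(lme4::isSingular(m1), lme4::isSingular(m2), FALSE)

  best <- names(models)[which.min(bic)]
  bm <- models[[best]]
  if (inherits(bm, "merMod")) {
    fe <- lme4::fixef(bm)
  } else {
    fe <- coef(bm)
  }
  se <- sqrt(diag(as.matrix(stats::vcov(bm))))
  tval <- fe[["v"]] / se[[2]]
  df_resid <- n - 2
  fixed <- list(intercept = unname(fe[[1]]), slope = unname(fe[["v"]]),
                slope_se = unname(se[[2]]), t = unname(tval),
                df = df_resid, p = 2 * stats::pt(-abs(tval), df_resid))

  # marginal / conditional r^2 of the random-slope model (variance of the
  # fixed-effect predictions vs fixed + random, over total)
  fe1 <- lme4::fixef(m1)
  yf <- fe1[[1]] + fe1[["v"]] * d$v
  yc <- stats::fitted(m1)
  vr <- stats::var(d$latency)
  r2 <- list(marginal = stats::var(yf) / vr,
             conditional = stats::var(yc) / vr)

  ce <- coef(m1)$participant
  pe <- tibble::tibble(participant = rownames(ce),
                       intercept = ce[[1]], slope = ce[["v"]])

  out <- list(
    table = tibble::tibble(model = names(models), k = ks,
                           logLik = ll, BIC = bic, singular = singular),
    best = best, fixed = fixed, r_squared = r2,
    participant_effects = pe, n_obs = n, models = models)
  class(out) <- "lme_comparison"
  out
}

#' @export
print.lme_comparison <- function(x, ...) {
  cat("LME comparison (interception latency ~ ASEM velocity), n =",
      x$n_obs, "\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("best: %s; fixed slope %.4f +/- %.4f s/(deg/s), t(%d) = %.2f, p = %.3g\n",
              x$best, x$fixed$slope, x$fixed$slope_se, x$fixed$df,
              x$fixed$t, x$fixed$p))
  invisible(x)
}

#' Per-participant latency ~ ASEM velocity regressions
#'
#' Ordinary least squares per participant of interception latency on
#' direction-signed ASEM velocity.
#'
#' @param trials retained-trial table (`latency`,
#'   `asem_velocity_signed`, `participant`).
#' @param min_trials minimum trials per participant.
#' @return tibble: participant, slope, intercept, r_squared, mean_latency,
#'   n.
#' @export
participant_effects <- function(trials, min_trials = 10) {
  d <- data.frame(latency = trials$latency,
                  v = trials$asem_velocity_signed,
                  participant = as.character(trials$participant))
  d <- d[stats::complete.cases(d), ]
  ps <- unique(d$participant)
  rows <- lapply(ps, function(p) {
    dd <- d[d$participant == p, ]
    if (nrow(dd) < min_trials)
      stop("participant ", p, " has fewer than ", min_trials, " trials",
           call. = FALSE)
    m <- stats::lm(latency ~ v, data = dd)
    r2 <- summary(m)$r.squared
    tibble::tibble(participant = p, slope = coef(m)[["v"]],
                   intercept = coef(m)[["(Intercept)"]],
                   r_squared = r2, mean_latency = mean(dd$latency),
                   n = nrow(dd))
  })
  do.call(rbind, rows)
}

#' Correlate per-participant effects with mean latency
#'
#' Pearson correlation (and two-sided p) across participants between a
#' per-participant regression quantity (slope or explained variance) and
#' mean interception latency.
#'
#' @param effects output of [participant_effects()].
#' @param which `"slope"` or `"r_squared"`.
#' @return list: `r`, `p`, `n`.
#' @export
correlate_effects <- function(effects, which = c("slope", "r_squared")) {
  which <- match.arg(which)
  if (nrow(effects) < 3) stop("need at least 3 participants", call. = FALSE)
  ct <- stats::cor.test(effects[[which]], effects$mean_latency,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(effects))
}

#' Upper vs lower ASEM-velocity quintile contrast on latency
#'
#' Within each participant x coherence cell (one condition only, normally
#' the control condition), trials are ranked by direction-signed ASEM
#' velocity and the top and bottom `frac` selected (`floor(frac * n)`,
#' minimum 1; ties broken by trial order). Cell-stratum latencies are
#' averaged per participant and the upper vs lower strata compared by a
#' paired t test across participants. Cells with fewer than
#' `min_cell_trials` retained trials are skipped (counted in
#' `skipped_cells`).
#'
#' @param trials retained-trial table for one condition.
#' @param frac selection fraction.
#' @param min_cell_trials minimum trials per cell.
#' @return list of class `quintile_contrast`: `test` (a `paired_test` of
#'   upper vs lower), `per_participant` (tibble with upper/lower mean
#'   latencies), `skipped_cells`.
#' @export
extreme_quintile_contrast <- function(trials, frac = 0.20,
                                      min_cell_trials = 5L) {
  d <- data.frame(latency = trials$latency,
                  v = trials$asem_velocity_signed,
                  participant = as.character(trials$participant),
                  coherence = trials$coherence)
  d <- d[stats::complete.cases(d), ]
  ps <- sort(unique(d$participant))
  skipped <- 0L
  rows <- lapply(ps, function(p) {
    up <- lo <- c()
    for (coh in unique(d$coherence[d$participant == p])) {
      dd <- d[d$participant == p & d$coherence == coh, ]
      if (nrow(dd) < min_cell_trials) { skipped <<- skipped + 1L; next }
      k <- max(1L, floor(frac * nrow(dd)))
      o <- order(dd$v)  # stable: ties broken by trial order
      lo <- c(lo, mean(dd$latency[o[seq_len(k)]]))
      up <- c(up, mean(dd$latency[rev(o)[seq_len(k)]]))
    }
    tibble::tibble(participant = p,
                   upper = mean(up), lower = mean(lo),
                   n_cells = length(up))
  })
  pp <- do.call(rbind, rows)
  test <- paired_t_cohens_d(pp$upper, pp$lower)
  out <- list(test = test, per_participant = pp, skipped_cells = skipped)
  class(out) <- "quintile_contrast"
  out
}

#' @export
print.quintile_contrast <- function(x, ...) {
  cat("Upper vs lower ASEM-velocity fraction, latency contrast\n")
  print(x$test)
  if (x$skipped_cells > 0)
    cat(x$skipped_cells, "cells below the trial minimum were skipped\n")
  invisible(x)
}
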