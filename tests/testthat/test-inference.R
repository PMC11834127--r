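# features-like trial table straight from the generative model (no traces)
trial_features <- function(cfg) {
  tt <- simulate_trial_table(cfg)
  tibble::tibble(participant = tt$participant, condition = tt$condition,
                 coherence = tt$coherence, direction = tt$direction,
                 asem_velocity = tt$asem_true,
                 asem_velocity_signed = tt$asem_true * tt$direction,
                 latency = tt$latency_true, retained = TRUE)
}

test_that("paired t and Cohen's d match hand computation", {
  r <- paired_t_cohens_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0); expect_equal(r$p, 1); expect_equal(r$cohens_d, 0)

  # differences (-1, -2, -3): mean -2, sd 1 -> t = -2/(1/sqrt(3)) = -3.4641
  x <- c(0, 0, 0); y <- c(1, 2, 3)
  r2 <- paired_t_cohens_d(x, y)
  expect_equal(r2$t, -2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r2$t, -3.4641, tolerance = 1e-4)
  expect_equal(r2$df, 2)
  expect_equal(r2$cohens_d, -2)
  expect_equal(r2$mean_diff, -2)
  expect_equal(r2$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)

  # antisymmetry
  set.seed(3); a <- rnorm(8); b <- rnorm(8)
  f <- paired_t_cohens_d(a, b); g <- paired_t_cohens_d(b, a)
  expect_equal(f$t, -g$t); expect_equal(f$p, g$p)
  expect_equal(f$cohens_d, -g$cohens_d)

  expect_error(paired_t_cohens_d(c(1, 2, 3), c(0, 1, 2)), "variance")
})

test_that("paired t rejection rate matches a Monte Carlo power oracle", {
  n <- 10; delta <- 1  # shift of 1 SD
  run <- function(seed, fun) {
    set.seed(seed)
    mean(replicate(400, fun()))
  }
  rate_pkg <- run(101, function() {
    x <- rnorm(n, delta); y <- rnorm(n, 0)
    paired_t_cohens_d(x, y)$p < 0.05
  })
  # brute-force oracle evaluates the same design via the textbook statistic
  rate_orc <- run(202, function() {
    d <- rnorm(n, delta) - rnorm(n, 0)
    tt <- mean(d) / (sd(d) / sqrt(n))
    2 * pt(-abs(tt), n - 1) < 0.05
  })
  expect_lt(abs(rate_pkg - rate_orc), 0.06)
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  # never below raw p; monotone in the raw ordering
  set.seed(5)
  p <- runif(10, 0, 0.2)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  # direct stepwise oracle
  o <- order(p)
  step <- pmin(1, cummax((length(p) - seq_along(p) + 1) * p[o]))
  expect_equal(adj[o], step)
})

test_that("rmANOVA returns F = 0, p = 1 for constant data and detects planted effects", {
  grid <- expand.grid(participant = sprintf("p%02d", 1:6),
                      condition = c("control", "gap"),
                      coherence = c(-0.3, 0, 0.3),
                      rep = 1:2, stringsAsFactors = FALSE)
  fconst <- tibble::tibble(grid, retained = TRUE, dv = 0.5)
  r <- rm_anova_holm(fconst, "dv")
  expect_equal(r$table$F, c(0, 0, 0))
  expect_equal(r$table$p, c(1, 1, 1))

  # planted pure condition effect, zero noise
  f2 <- fconst
  f2$dv <- ifelse(f2$condition == "gap", 1, 0) +
    0.001 * as.numeric(factor(f2$participant))
  r2 <- rm_anova_holm(f2, "dv")
  expect_lt(r2$table$p[r2$table$effect == "condition"], 1e-10)
  expect_equal(r2$table$F[r2$table$effect == "coherence"], 0,
               tolerance = 1e-6)
  expect_equal(r2$table$F[r2$table$effect == "interaction"], 0,
               tolerance = 1e-6)
  # condition was significant: Holm post hoc present
  expect_true("condition" %in% names(r2$posthoc))

  # missing cell -> explicit error naming it
  f3 <- fconst[!(fconst$participant == "p01" & fconst$condition == "gap" &
                   fconst$coherence == 0), ]
  expect_error(rm_anova_holm(f3, "dv"), "p01")
})

test_that("noise-free common slope is recovered exactly by the LME layer", {
  set.seed(7)
  d <- expand.grid(participant = sprintf("p%02d", 1:8), i = 1:40)
  d$asem_velocity_signed <- runif(nrow(d), -0.5, 1.5)
  b0 <- rnorm(8, 0.3, 0.05)
  d$latency <- b0[as.integer(factor(d$participant))] -
    0.03 * d$asem_velocity_signed
  cmp <- fit_lme_candidates(d)
  ri <- cmp$models$random_intercept
  expect_equal(unname(lme4::fixef(ri)[["v"]]), -0.03, tolerance = 1e-8)
  # no residual or slope variance left for the fuller model to explain
  vc <- as.data.frame(lme4::VarCorr(cmp$models$random_slope_intercept))
  slope_var <- vc$vcov[which(vc$var1 == "v" & is.na(vc$var2))]
  expect_lt(max(slope_var), 1e-6)
})

test_that("BIC of the fixed-only model equals the closed-form OLS BIC", {
  cfg <- quiet_config(n_participants = 4, trials_per_cell = 4, seed = 83)
  f <- trial_features(cfg)
  cmp <- fit_lme_candidates(f)
  d <- f[is.finite(f$latency), ]
  m <- lm(latency ~ asem_velocity_signed, data = d)
  n <- nrow(d)
  s2 <- sum(resid(m)^2) / n  # ML variance estimate
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  bic_closed <- -2 * ll + 3 * log(n)  # k = intercept, slope, variance
  expect_equal(cmp$table$BIC[cmp$table$model == "fixed_only"], bic_closed,
               tolerance = 1e-8)
  expect_equal(cmp$table$k[cmp$table$model == "fixed_only"], 3)
})

test_that("random-slope model wins BIC when slopes truly vary, and slope is recovered", {
  # slope heterogeneity well above its measurement error, full trial count
  cfg <- simulation_config(n_participants = 10, trials_per_cell = 20,
                           latency_population = list(
                             c = c(0, 0), mu = c(0, 0), sigma = c(0.3, 0),
                             beta0 = c(0.315, 0.04), beta1 = c(-0.03, 0.02),
                             resid_sd = 0.05),
                           seed = 89)
  f <- trial_features(cfg)
  cmp <- fit_lme_candidates(f)
  expect_equal(cmp$best, "random_slope_intercept")
  expect_lt(abs(cmp$fixed$slope - (-0.03)), 2 * cmp$fixed$slope_se)
  # OLS-per-participant oracle: average of individual slopes agrees
  pe <- participant_effects(f)
  expect_lt(abs(mean(pe$slope) - cmp$fixed$slope), 0.01)
  expect_error(fit_lme_candidates(transform(f, asem_velocity_signed = 1)),
               "unidentifiable")
})

test_that("per-participant regressions and correlations match direct formulas", {
  eff <- tibble::tibble(participant = c("a", "b", "c"),
                        slope = c(1, 2, 3), r_squared = c(0.1, 0.2, 0.3),
                        mean_latency = c(2, 4, 6))
  expect_equal(correlate_effects(eff, "slope")$r, 1, tolerance = 1e-12)

  eff2 <- tibble::tibble(participant = letters[1:4],
                         slope = c(1, -1, 1, -1), r_squared = 0.2,
                         mean_latency = c(1, 1, 2, 2))
  expect_equal(correlate_effects(eff2, "slope")$r, 0, tolerance = 1e-12)

  # hand-computable 4-point Pearson: x=(1,2,3,4), y=(2,1,4,3) -> r = 0.6
  eff3 <- tibble::tibble(participant = letters[1:4],
                         slope = c(1, 2, 3, 4), r_squared = 0.2,
                         mean_latency = c(2, 1, 4, 3))
  expect_equal(correlate_effects(eff3, "slope")$r, 0.6, tolerance = 1e-12)
  expect_error(correlate_effects(eff3[1:2, ], "slope"), "3 participants")
})

test_that("extreme 20% selection picks 2 of 10 and orders latency by coupling", {
  # 10 trials per cell -> exactly 2 in each stratum
  set.seed(97)
  make_p <- function(p) tibble::tibble(
    participant = p, coherence = 0.16,
    asem_velocity_signed = rnorm(10),
    latency = runif(10, 0.2, 0.4), retained = TRUE)
  d3 <- rbind(make_p("p01"), make_p("p02"), make_p("p03"))
  d <- d3[d3$participant == "p01", ]
  q <- extreme_quintile_contrast(d3, frac = 0.2, min_cell_trials = 5)
  o <- order(d$asem_velocity_signed)
  expect_equal(q$per_participant$lower[1], mean(d$latency[o[1:2]]))
  expect_equal(q$per_participant$upper[1], mean(d$latency[rev(o)[1:2]]))

  # negative coupling, zero noise: upper stratum strictly faster everywhere
  cfg <- quiet_config(n_participants = 5, trials_per_cell = 8, seed = 101)
  f <- trial_features(cfg)
  q2 <- extreme_quintile_contrast(f[f$condition == "control", ])
  expect_true(all(q2$per_participant$upper < q2$per_participant$lower))
  expect_lt(q2$test$t, 0)
})

test_that("upper-minus-lower contrast is negative in nearly all seeded cohorts", {
  signs <- vapply(1:25, function(s) {
    cfg <- simulation_config(n_participants = 8, trials_per_cell = 10,
                             seed = 1000 + s)
    f <- trial_features(cfg)
    q <- extreme_quintile_contrast(f[f$condition == "control", ])
    q$test$t < 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})
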