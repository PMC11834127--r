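# End-to-end driver: preprocess -> features -> exclusion -> psychometric
# fits -> statistical layer, with a summary report.

#' Run the full analysis pipeline on a cohort
#'
#' Extracts per-trial features (with exclusion), fits both psychometric
#' curves per participant and condition, contrasts the sigmoid height and
#' the latency offset across conditions with paired t tests, fits and
#' compares the three latency ~ ASEM velocity mixed models by BIC,
#' computes per-participant regressions and their correlations with mean
#' latency, and runs the upper/lower-selection control contrast on the
#' reference condition. If fewer than `min_retained` trials survive
#' exclusion the statistical layer is skipped and the retention summary
#' still returned.
#'
#' @param cohort an `asem_cohort` (in memory or from [read_cohort()]).
#' @param config an [analysis_config()].
#' @param control_condition label of the condition used for the
#'   extreme-quintile control analysis.
#' @param min_retained minimum retained trials for the statistical layer.
#' @return object of class `asem_report`: list with `features`,
#'   `retention` (counts per reason), `fits` (asem + latency tibbles),
#'   `height_contrast`, `offset_contrast` (paired tests), `lme`,
#'   `participant_effects`, `cor_slope`, `cor_r2`, `quintile`, `zdist`,
#'   `config_hash`.
#' @export
run_pipeline <- function(cohort, config = analysis_config(),
                         control_condition = "control",
                         min_retained = 20L) {
  features <- extract_features(cohort, config)

  reasons <- unlist(strsplit(features$exclusion_reasons[!features$retained],
                             ","))
  retention <- list(
    n_total = nrow(features),
    n_retained = sum(features$retained),
    rate = mean(features$retained),
    by_reason = if (length(reasons)) table(reasons) else table(character()))

  out <- list(features = features, retention = retention,
              config_hash = config_hash(config))
  class(out) <- "asem_report"
  if (retention$n_retained < min_retained) {
    message("only ", retention$n_retained,
            " trials retained; statistical layer skipped")
    return(out)
  }

  ret <- features[features$retained & is.finite(features$latency), ]
  conds <- unique(ret$condition)

  out$fits <- fit_psychometric_curves(features)
  if (length(conds) == 2) {
    hc <- condition_contrast(out$fits$asem, "a", conditions = conds)
    oc <- condition_contrast(out$fits$latency, "d", conditions = conds)
    # participants whose fit did not converge in one condition drop out of
    # the paired contrast
    contrast_or_null <- function(pairs) {
      ok <- is.finite(pairs[[2]]) & is.finite(pairs[[3]])
      if (sum(ok) >= 3) paired_t_cohens_d(pairs[[2]][ok], pairs[[3]][ok])
      else NULL
    }
    out$height_contrast <- contrast_or_null(hc)
    out$offset_contrast <- contrast_or_null(oc)
    out$height_pairs <- hc
    out$offset_pairs <- oc
  }

  out$zdist <- znormalize_and_pool(features)
  out$lme <- fit_lme_candidates(ret)
  out$participant_effects <- participant_effects(ret)
  out$cor_slope <- correlate_effects(out$participant_effects, "slope")
  out$cor_r2 <- correlate_effects(out$participant_effects, "r_squared")

  ctrl <- ret[ret$condition == control_condition, ]
  if (nrow(ctrl) > 0)
    out$quintile <- extreme_quintile_contrast(
      ctrl, frac = config$quintile_frac,
      min_cell_trials = config$min_cell_trials)
  out
}

#' @export
print.asem_report <- function(x, ...) {
  cat("<asem_report>  config", x$config_hash, "\n")
  cat(sprintf("  trials: %d, retained %d (%.1f%%)\n",
              x$retention$n_total, x$retention$n_retained,
              100 * x$retention$rate))
  if (length(x$retention$by_reason)) {
    br <- x$retention$by_reason
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(br), as.integer(br)), collapse = ", "),
        "\n")
  }
  if (!is.null(x$height_contrast)) {
    cat("  sigmoid height contrast: "); print(x$height_contrast)
    cat("  latency offset contrast: "); print(x$offset_contrast)
  }
  if (!is.null(x$lme)) print(x$lme)
  invisible(x)
}

#' Write the pipeline report to disk
#'
#' Writes `features.csv`, the two psychometric fits tables, the
#' per-participant effects table, and `report.json` with the scalar
#' results (retention, contrasts, LME comparison, correlations). Every
#' file carries the analysis-config hash in `report.json`.
#'
#' @param report an `asem_report`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "asem_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(report$features),
                     file.path(path, "features.csv"))
  js <- list(config_hash = report$config_hash,
             retention = list(
               n_total = report$retention$n_total,
               n_retained = report$retention$n_retained,
               rate = report$retention$rate,
               by_reason = as.list(report$retention$by_reason)))
  if (!is.null(report$fits)) {
    data.table::fwrite(as.data.frame(report$fits$asem),
                       file.path(path, "fits_asem.csv"))
    data.table::fwrite(as.data.frame(report$fits$latency),
                       file.path(path, "fits_latency.csv"))
  }
  if (!is.null(report$participant_effects))
    data.table::fwrite(as.data.frame(report$participant_effects),
                       file.path(path, "participant_effects.csv"))
  strip <- function(tt) tt[c("t", "df", "p", "cohens_d", "cohens_d_av",
                             "mean_diff", "n")]
  if (!is.null(report$height_contrast)) {
    js$height_contrast <- strip(report$height_contrast)
    js$offset_contrast <- strip(report$offset_contrast)
  }
  if (!is.null(report$lme)) {
    js$lme <- list(table = as.data.frame(report$lme$table),
                   best = report$lme$best, fixed = report$lme$fixed,
                   r_squared = report$lme$r_squared,
                   n_obs = report$lme$n_obs)
    js$cor_slope <- report$cor_slope
    js$cor_r2 <- report$cor_r2
  }
  if (!is.null(report$quintile))
    js$quintile <- c(strip(report$quintile$test),
                     list(skipped_cells = report$quintile$skipped_cells))
  jsonlite::write_json(js, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
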