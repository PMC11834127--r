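# Cohort persistence: CSV metadata/ground truth plus per-trial trace CSVs
# and a JSON manifest with schema version and provenance.

COHORT_SCHEMA_VERSION <- "1.0"

#' Write a cohort to disk
#'
#' Layout: `manifest.json` (schema version, seed, config hash),
#' `metadata.csv`, `ground_truth.csv`, `participants.csv`,
#' `saccades.csv`/`blinks.csv` (planted events), and under `traces/` one
#' `eye_<id>.csv` (time, x, y, missing; 1 kHz) and one `cursor_<id>.csv`
#' (time, x, y; 60 Hz) per trial. All positions in deg, times in s,
#' coherence as signed fraction, direction as -1/+1.
#'
#' @param cohort an `asem_cohort`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "asem_cohort"))
  dir.create(file.path(path, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(as.data.frame(x),
                                          file.path(path, f))
  fw(cohort$metadata, "metadata.csv")
  fw(cohort$ground_truth, "ground_truth.csv")
  fw(cohort$participants, "participants.csv")
  fw(cohort$saccades, "saccades.csv")
  fw(cohort$blinks, "blinks.csv")
  for (id in names(cohort$traces)) {
    data.table::fwrite(cohort$traces[[id]]$eye,
                       file.path(path, "traces", paste0("eye_", id, ".csv")))
    data.table::fwrite(cohort$traces[[id]]$cursor,
                       file.path(path, "traces", paste0("cursor_", id, ".csv")))
  }
  manifest <- list(schema_version = COHORT_SCHEMA_VERSION,
                   seed = cohort$config$seed,
                   config_hash = config_hash(cohort$config),
                   n_trials = nrow(cohort$metadata),
                   eye_rate = cohort$config$eye_rate,
                   cursor_rate = cohort$config$cursor_rate,
                   target_speed = cohort$config$target_speed,
                   pre_onset = cohort$config$pre_onset,
                   post_onset = cohort$config$post_onset)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from disk
#'
#' Validates the schema version and that every metadata row has both trace
#' files before reading anything trial-level; distinct errors are raised
#' for a missing manifest, a schema-version mismatch and missing trace
#' files (naming the trial).
#'
#' @param path directory written by [write_cohort()].
#' @return an `asem_cohort`. The returned `config` is a plain list holding
#'   the manifest scalars (rates, speed, window extents), which is all the
#'   analysis side needs.
#' @export
read_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("not a cohort directory (no manifest.json): ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, COHORT_SCHEMA_VERSION))
    stop("unsupported cohort schema version: ", manifest$schema_version,
         call. = FALSE)
  fr <- function(f) tibble::as_tibble(
    data.table::fread(file.path(path, f), data.table = FALSE))
  metadata <- fr("metadata.csv")

  ids <- vapply(seq_len(nrow(metadata)), function(i)
    trial_id(metadata$participant[i], metadata$trial[i]), character(1))
  eye_files <- file.path(path, "traces", paste0("eye_", ids, ".csv"))
  cur_files <- file.path(path, "traces", paste0("cursor_", ids, ".csv"))
  missing <- !file.exists(eye_files) | !file.exists(cur_files)
  if (any(missing))
    stop("missing trace files for trial(s): ",
         paste(ids[missing], collapse = ", "), call. = FALSE)

  traces <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    eye <- fr(file.path("traces", paste0("eye_", ids[i], ".csv")))
    eye$missing <- as.logical(eye$missing)
    traces[[i]] <- list(eye = eye,
                        cursor = fr(file.path("traces",
                                              paste0("cursor_", ids[i], ".csv"))))
  }
  cohort <- list(
    metadata = metadata,
    traces = traces,
    ground_truth = if (file.exists(file.path(path, "ground_truth.csv")))
      fr("ground_truth.csv") else NULL,
    saccades = if (file.exists(file.path(path, "saccades.csv")))
      fr("saccades.csv") else NULL,
    blinks = if (file.exists(file.path(path, "blinks.csv")))
      fr("blinks.csv") else NULL,
    participants = if (file.exists(file.path(path, "participants.csv")))
      fr("participants.csv") else NULL,
    config = list(seed = manifest$seed,
                  eye_rate = manifest$eye_rate,
                  cursor_rate = manifest$cursor_rate,
                  target_speed = manifest$target_speed,
                  pre_onset = manifest$pre_onset,
                  post_onset = manifest$post_onset,
                  config_hash = manifest$config_hash))
  class(cohort) <- "asem_cohort"
  cohort
}
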