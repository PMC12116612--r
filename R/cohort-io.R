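COHORT_SCHEMA_VERSION <- "1.0"

recording_filename <- function(rec) {
  sprintf("%s_w%02d_%s.csv", rec$patient_id, rec$week, rec$exercise)
}

#' Save a cohort to a directory
#'
#' Writes a diffable plain-text layout: `manifest.json` (counts, schema
#' version, per-recording file index), `patients.csv`, `outcomes.csv`, and one
#' delimited signal file per recording under `signals/` whose first column is
#' time in seconds and remaining columns are the 8 channels headed by their
#' muscle codes. Signal values round-trip at full precision.
#'
#' The cohort is validated first; nothing is written for an invalid cohort.
#'
#' @param chrt a valid `semg_cohort`.
#' @param path directory to create/write into.
#' @param complete passed to [validate_cohort()]; set `FALSE` to allow saving
#'   partial cohorts.
#' @return the manifest (invisibly).
#' @export
save_cohort <- function(chrt, path, complete = TRUE) {
  report <- validate_cohort(chrt, complete = complete)
  if (nrow(report)) {
    abort_semg(sprintf(
      "refusing to save an invalid cohort: %d violation(s), first: %s",
      nrow(report), report$message[1L]), "semgcobb_invalid_cohort")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort_semg(sprintf("cannot create cohort directory '%s'", path),
               "semgcobb_io_error")
  }
  sigdir <- file.path(path, "signals")
  dir.create(sigdir, showWarnings = FALSE)

  data.table::fwrite(chrt$statics, file.path(path, "patients.csv"))
  data.table::fwrite(chrt$outcomes, file.path(path, "outcomes.csv"))

  index <- lapply(chrt$recordings, function(rec) {
    fn <- recording_filename(rec)
    tt <- (seq_len(ncol(rec$signals)) - 1) / rec$sample_rate_hz
    # %.17g guarantees bit-exact double round-trip through the text format
    df <- data.table::as.data.table(
      matrix(sprintf("%.17g", t(rec$signals)), ncol = 8L))
    data.table::setnames(df, muscle_channels())
    df <- cbind(data.table::data.table(time_s = sprintf("%.17g", tt)), df)
    data.table::fwrite(df, file.path(sigdir, fn), quote = FALSE)
    list(file = file.path("signals", fn), patient_id = rec$patient_id,
         week = rec$week, exercise = rec$exercise,
         sample_rate_hz = rec$sample_rate_hz, n_samples = ncol(rec$signals))
  })
  manifest <- list(
    schema_version = COHORT_SCHEMA_VERSION,
    n_patients = nrow(chrt$statics),
    n_outcome_rows = nrow(chrt$outcomes),
    n_recordings = length(chrt$recordings),
    channels = muscle_channels(),
    recordings = index
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a cohort from a directory
#'
#' Reads the layout written by [save_cohort()]. Channel order is restored
#' from the per-file column headers, so signal files remain valid under any
#' on-disk column permutation. The loaded cohort is validated; structural
#' violations raise an error.
#'
#' @param path cohort directory.
#' @param complete passed to [validate_cohort()].
#' @return a `semg_cohort`.
#' @export
load_cohort <- function(path, complete = TRUE) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    abort_semg(sprintf("missing manifest: '%s'", mf_path),
               "semgcobb_missing_manifest")
  }
  manifest <- jsonlite::read_json(mf_path)
  statics <- as.data.frame(data.table::fread(file.path(path, "patients.csv")))
  outcomes <- as.data.frame(data.table::fread(file.path(path, "outcomes.csv")))
  outcomes$week <- as.integer(outcomes$week)
  for (v in OUTCOME_VARS) outcomes[[v]] <- as.numeric(outcomes[[v]])

  recs <- vector("list", length(manifest$recordings))
  for (i in seq_along(manifest$recordings)) {
    entry <- manifest$recordings[[i]]
    fp <- file.path(path, entry$file)
    if (!file.exists(fp)) {
      abort_semg(sprintf(
        "manifest declares %d recordings but '%s' is missing",
        length(manifest$recordings), entry$file),
        "semgcobb_missing_recording")
    }
    df <- data.table::fread(fp)
    want <- muscle_channels()
    if (!all(want %in% names(df))) {
      abort_semg(sprintf("'%s' lacks channel column(s): %s", entry$file,
                         paste(setdiff(want, names(df)), collapse = ", ")),
                 "semgcobb_bad_signal_file")
    }
    sig <- t(as.matrix(df[, want, with = FALSE]))  # header-driven remap
    if (!all(is.finite(sig))) {
      abort_semg(sprintf("non-finite signal values in '%s'", entry$file),
                 "semgcobb_bad_signal_file")
    }
    recs[[i]] <- emg_recording(entry$patient_id, entry$week, entry$exercise,
                               sig, entry$sample_rate_hz)
  }
  chrt <- cohort(statics, outcomes, recs)
  report <- validate_cohort(chrt, complete = complete)
  if (nrow(report)) {
    abort_semg(sprintf("loaded cohort is invalid: %d violation(s), first: %s",
                       nrow(report), report$message[1L]),
               "semgcobb_invalid_cohort")
  }
  chrt
}
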