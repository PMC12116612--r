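#' Canonical sEMG channel set
#'
#' The montage records four bilateral trunk-muscle pairs -- erector spinae
#' (L4--L5), multifidus, rectus abdominis and external oblique -- giving eight
#' channels in a fixed canonical order. All signal matrices in the package use
#' this row order, and on-disk signal files carry these codes as column
#' headers.
#'
#' @return `muscle_channels()`: character vector of the 8 channel codes.
#'   `muscle_channel_info()`: data.frame with one row per channel and columns
#'   `code`, `muscle`, `side` (`"L"`/`"R"`) and `region` -- the spinal region
#'   whose convex/concave labelling applies to the pair (`"thoracic"` for
#'   erector spinae and the abdominal pairs, `"lumbar"` for multifidus).
#' @export
#' @examples
#' muscle_channels()
muscle_channels <- function() {
  muscle_channel_info()$code
}

#' @rdname muscle_channels
#' @export
muscle_channel_info <- function() {
  data.frame(
    code = c("erector_spinae_L", "erector_spinae_R",
             "multifidus_L", "multifidus_R",
             "rectus_abdominis_L", "rectus_abdominis_R",
             "external_oblique_L", "external_oblique_R"),
    muscle = rep(c("erector_spinae", "multifidus",
                   "rectus_abdominis", "external_oblique"), each = 2L),
    side = rep(c("L", "R"), 4L),
    region = rep(c("thoracic", "lumbar", "thoracic", "thoracic"), each = 2L),
    stringsAsFactors = FALSE
  )
}

#' Schroth exercise codes
#'
#' The four isometric holds of the exercise programme: quadruped hold, squat
#' on the bar, unilateral kneel, and lateral flexion in sitting. Each hold is
#' recorded once per patient per measurement week.
#'
#' @return character vector of 4 exercise codes.
#' @export
exercise_types <- function() {
  c("quadruped", "bar_squat", "unilateral_kneel", "lateral_flexion_sit")
}

OUTCOME_VARS <- c("cobb_T", "cobb_L", "art_T", "art_L", "srs22", "bst")

#' Construct a single-exercise sEMG recording
#'
#' @param patient_id character identifier.
#' @param week measurement week, one of 0, 8, 16, 24.
#' @param exercise one of [exercise_types()].
#' @param signals numeric matrix, 8 rows (channels in [muscle_channels()]
#'   order) by T columns (samples), in microvolts.
#' @param sample_rate_hz sampling rate in Hz; must exceed 800 Hz so the
#'   20--400 Hz analysis band is admissible (study value: 1000).
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(patient_id, week, exercise, signals,
                          sample_rate_hz = 1000) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  week <- assert_week(week)
  if (!exercise %in% exercise_types()) {
    abort_semg(sprintf("unknown exercise '%s'", exercise),
               "semgcobb_bad_exercise")
  }
  if (!is.matrix(signals) || !is.numeric(signals) || nrow(signals) != 8L ||
      ncol(signals) < 1L) {
    abort_semg("`signals` must be a numeric 8 x T matrix with T >= 1",
               "semgcobb_bad_signals")
  }
  if (!all(is.finite(signals))) {
    abort_semg("`signals` contains non-finite values", "semgcobb_bad_signals")
  }
  if (!is_scalar_number(sample_rate_hz) || sample_rate_hz <= 2 * 400) {
    abort_semg("`sample_rate_hz` must exceed 800 Hz (Nyquist for the 400 Hz band edge)",
               "semgcobb_bad_rate")
  }
  rownames(signals) <- muscle_channels()
  structure(list(patient_id = patient_id, week = week, exercise = exercise,
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 signals = signals),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> patient %s, week %d, %s: 8 x %d @ %g Hz\n",
              x$patient_id, x$week, x$exercise, ncol(x$signals),
              x$sample_rate_hz))
  invisible(x)
}

#' Construct a patient statics record
#'
#' Time-invariant patient descriptors. `curve_direction` is the side of the
#' main (thoracic) curve's convexity; the per-region convex-side map follows
#' the usual S-curve convention (lumbar convexity opposite the thoracic one)
#' unless given explicitly.
#'
#' @param patient_id character identifier.
#' @param age years, in \[10, 18\].
#' @param sex `"female"` or `"male"`.
#' @param bmi body mass index, kg/m^2, positive.
#' @param risser Risser sign, continuous in \[0, 5\].
#' @param curve_direction `"left"` or `"right"`.
#' @param convex_thoracic,convex_lumbar `"L"`/`"R"`; defaults derived from
#'   `curve_direction`.
#' @return one-row data.frame (a row of a cohort statics table).
#' @export
patient_static <- function(patient_id, age, sex, bmi, risser, curve_direction,
                           convex_thoracic = NULL, convex_lumbar = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (!sex %in% c("female", "male"))
    abort_semg("`sex` must be 'female' or 'male'", "semgcobb_bad_static")
  if (!curve_direction %in% c("left", "right"))
    abort_semg("`curve_direction` must be 'left' or 'right'",
               "semgcobb_bad_static")
  convex_thoracic <- convex_thoracic %||%
    (if (curve_direction == "left") "L" else "R")
  convex_lumbar <- convex_lumbar %||%
    (if (convex_thoracic == "L") "R" else "L")
  if (!convex_thoracic %in% c("L", "R") || !convex_lumbar %in% c("L", "R"))
    abort_semg("convex sides must be 'L' or 'R'", "semgcobb_bad_static")
  data.frame(patient_id = patient_id, age = as.numeric(age), sex = sex,
             bmi = as.numeric(bmi), risser = as.numeric(risser),
             curve_direction = curve_direction,
             convex_thoracic = convex_thoracic,
             convex_lumbar = convex_lumbar,
             stringsAsFactors = FALSE)
}

#' Construct an outcome panel for one patient
#'
#' Clinical labels at the four measurement weeks. Cobb angles are measured
#' radiographically at baseline and week 24 only; `cobb_T`/`cobb_L` may be
#' `NA` at weeks 8 and 16 (values there are permitted but off-protocol).
#'
#' @param patient_id character identifier.
#' @param week integer vector of measurement weeks.
#' @param cobb_T,cobb_L Cobb angles in degrees, \[0, 90\].
#' @param art_T,art_L angle of trunk rotation in degrees, nonnegative.
#' @param srs22 SRS-22r total score, \[1, 5\].
#' @param bst Biering-Sorensen hold time in seconds, \[0, 240\].
#' @return data.frame with one row per week.
#' @export
outcome_panel <- function(patient_id, week = MEASUREMENT_WEEKS,
                          cobb_T = NA_real_, cobb_L = NA_real_,
                          art_T = NA_real_, art_L = NA_real_,
                          srs22 = NA_real_, bst = NA_real_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  data.frame(patient_id = patient_id, week = as.integer(week),
             cobb_T = as.numeric(cobb_T), cobb_L = as.numeric(cobb_L),
             art_T = as.numeric(art_T), art_L = as.numeric(art_L),
             srs22 = as.numeric(srs22), bst = as.numeric(bst),
             stringsAsFactors = FALSE)
}

#' Assemble a cohort
#'
#' @param statics data.frame of patient statics (rows as from
#'   [patient_static()]).
#' @param outcomes data.frame of outcome rows (as from [outcome_panel()]).
#' @param recordings list of [emg_recording()] objects.
#' @return object of class `semg_cohort` with elements `statics`, `outcomes`,
#'   `recordings`.
#' @export
cohort <- function(statics, outcomes, recordings = list()) {
  stopifnot(is.data.frame(statics), is.data.frame(outcomes),
            is.list(recordings))
  structure(list(statics = statics, outcomes = outcomes,
                 recordings = recordings),
            class = "semg_cohort")
}

#' @export
print.semg_cohort <- function(x, ...) {
  cat(sprintf("<semg_cohort> %d patients, %d outcome rows, %d recordings\n",
              nrow(x$statics), nrow(x$outcomes), length(x$recordings)))
  invisible(x)
}

violation <- function(rule, message, patient_id = NA_character_,
                      week = NA_integer_, exercise = NA_character_) {
  data.frame(rule = rule, patient_id = patient_id, week = week,
             exercise = exercise, message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  violation(character(0), character(0), character(0), integer(0),
            character(0))[0, ]
}

#' Validate a cohort
#'
#' Checks every structural invariant -- field ranges, week levels, channel
#' layout, referential integrity between statics/outcomes/recordings, and
#' completeness (one recording per exercise per measurement week per patient).
#' This function never raises on malformed content: it always returns a
#' report. An empty report means the cohort is valid.
#'
#' @param chrt a `semg_cohort`.
#' @param complete if `TRUE` (default) missing (patient, week, exercise)
#'   recordings are reported; set `FALSE` for partial cohorts.
#' @return data.frame with columns `rule`, `patient_id`, `week`, `exercise`,
#'   `message`; zero rows iff valid.
#' @export
validate_cohort <- function(chrt, complete = TRUE) {
  out <- list(no_violations())
  add <- function(v) out[[length(out) + 1L]] <<- v

  st <- chrt$statics
  ids <- st$patient_id
  if (anyDuplicated(ids)) {
    add(violation("statics_unique", "duplicated patient_id in statics",
                  ids[duplicated(ids)][1L]))
  }
  for (i in seq_len(nrow(st))) {
    p <- st[i, ]
    if (!is.finite(p$age) || p$age < 10 || p$age > 18)
      add(violation("age_range", sprintf("age %.2f outside [10, 18]", p$age),
                    p$patient_id))
    if (!is.finite(p$bmi) || p$bmi <= 0)
      add(violation("bmi_positive", "bmi must be > 0", p$patient_id))
    if (!is.finite(p$risser) || p$risser < 0 || p$risser > 5)
      add(violation("risser_range", "risser outside [0, 5]", p$patient_id))
    if (!p$sex %in% c("female", "male"))
      add(violation("sex_level", "sex not in {female, male}", p$patient_id))
    if (!p$curve_direction %in% c("left", "right"))
      add(violation("curve_level", "curve_direction not in {left, right}",
                    p$patient_id))
    if (!isTRUE(p$convex_thoracic %in% c("L", "R")) ||
        !isTRUE(p$convex_lumbar %in% c("L", "R")))
      add(violation("convex_side", "convex side undefined for a region",
                    p$patient_id))
  }

  oc <- chrt$outcomes
  if (nrow(oc)) {
    bad_week <- !oc$week %in% MEASUREMENT_WEEKS
    for (i in which(bad_week))
      add(violation("week_level", sprintf("outcome week %s not measured",
                                          oc$week[i]),
                    oc$patient_id[i], oc$week[i]))
    rng <- function(v, lo, hi, rule) {
      x <- oc[[v]]
      bad <- !is.na(x) & (x < lo | x > hi)
      for (i in which(bad))
        add(violation(rule, sprintf("%s = %.3g outside [%g, %g]",
                                    v, x[i], lo, hi),
                      oc$patient_id[i], oc$week[i]))
    }
    rng("cobb_T", 0, 90, "cobb_range"); rng("cobb_L", 0, 90, "cobb_range")
    rng("srs22", 1, 5, "srs22_range"); rng("bst", 0, 240, "bst_range")
    rng("art_T", 0, Inf, "art_range"); rng("art_L", 0, Inf, "art_range")
    for (id in ids) {
      w <- oc$week[oc$patient_id == id]
      if (!setequal(w, MEASUREMENT_WEEKS) || anyDuplicated(w))
        add(violation("outcome_panel", "expected exactly one row per week 0/8/16/24",
                      id))
      for (wk in intersect(c(0L, 24L), w)) {
        r <- oc[oc$patient_id == id & oc$week == wk, ]
        if (nrow(r) == 1L && (is.na(r$cobb_T) || is.na(r$cobb_L)))
          add(violation("cobb_mandatory",
                        sprintf("Cobb angles mandatory at week %d", wk),
                        id, wk))
      }
    }
    orphans <- setdiff(unique(oc$patient_id), ids)
    for (id in orphans)
      add(violation("outcome_orphan", "outcome patient_id absent from statics",
                    id))
  } else if (length(ids)) {
    add(violation("outcome_panel", "no outcomes for any patient"))
  }

  seen <- character(0)
  for (rec in chrt$recordings) {
    ok <- inherits(rec, "emg_recording") && is.matrix(rec$signals)
    if (!ok) {
      add(violation("recording_type", "element is not an emg_recording"))
      next
    }
    if (!rec$patient_id %in% ids)
      add(violation("recording_orphan",
                    "recording patient_id absent from statics",
                    rec$patient_id, rec$week, rec$exercise))
    if (!rec$week %in% MEASUREMENT_WEEKS)
      add(violation("week_level", sprintf("recording week %s not measured",
                                          rec$week),
                    rec$patient_id, NA_integer_, rec$exercise))
    if (!rec$exercise %in% exercise_types())
      add(violation("exercise_level", "unknown exercise code",
                    rec$patient_id, rec$week))
    if (nrow(rec$signals) != 8L || ncol(rec$signals) < 1L)
      add(violation("signal_shape", "signals must be 8 x T, T >= 1",
                    rec$patient_id, rec$week, rec$exercise))
    if (!all(is.finite(rec$signals)))
      add(violation("signal_finite", "non-finite signal values",
                    rec$patient_id, rec$week, rec$exercise))
    if (!is_scalar_number(rec$sample_rate_hz) || rec$sample_rate_hz <= 800)
      add(violation("sample_rate", "sample_rate_hz must exceed 800 Hz",
                    rec$patient_id, rec$week, rec$exercise))
    key <- paste(rec$patient_id, rec$week, rec$exercise, sep = "|")
    if (key %in% seen)
      add(violation("recording_duplicate",
                    "duplicate (patient, week, exercise) recording",
                    rec$patient_id, rec$week, rec$exercise))
    seen <- c(seen, key)
  }
  if (complete && length(ids)) {
    expected <- expand.grid(patient_id = ids, week = MEASUREMENT_WEEKS,
                            exercise = exercise_types(),
                            stringsAsFactors = FALSE)
    keys <- paste(expected$patient_id, expected$week, expected$exercise,
                  sep = "|")
    missing <- which(!keys %in% seen)
    for (i in missing)
      add(violation("recording_missing",
                    sprintf("missing recording for (%s, week %d, %s)",
                            expected$patient_id[i], expected$week[i],
                            expected$exercise[i]),
                    expected$patient_id[i], expected$week[i],
                    expected$exercise[i]))
  }
  do.call(rbind, out)
}
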