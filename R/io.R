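#' Reading, writing and reporting
#'
#' Studies travel as two CSV files: long-format measurements (one row per
#' subject and slot) and a roster. The validation report has one canonical
#' machine-readable form (JSON) from which the human-readable markdown
#' rendering is derived, so the two can never disagree.
#'
#' @name io_reporting
NULL

MEASUREMENT_COLS <- readr::cols(
  subject_id = readr::col_character(),
  slot = readr::col_character(),
  role = readr::col_character(),
  sbp = readr::col_double(),
  dbp = readr::col_double(),
  hr = readr::col_double()
)

ROSTER_COLS <- readr::cols(
  subject_id = readr::col_character(),
  sex = readr::col_character(),
  age = readr::col_double(),
  height_cm = readr::col_double(),
  weight_kg = readr::col_double(),
  bmi = readr::col_double(),
  arm_circumference_mm = readr::col_double(),
  arm = readr::col_character(),
  flags = readr::col_character()
)

#' Read a study from CSV
#'
#' Reads and validates the measurement and roster files. Any sequence
#' violation (unknown slot, missing slot, out-of-range or non-integer
#' reading, role mismatch) is a hard error naming the offending subject,
#' slot and data line.
#'
#' @param measurements_path CSV with columns `subject_id`, `slot`, `role`,
#'   `sbp`, `dbp`, `hr`.
#' @param roster_path Optional roster CSV (`subject_id`, `sex`, `age`,
#'   `height_cm`, `weight_kg`, `bmi`, `arm_circumference_mm`, `arm`,
#'   `flags`).
#' @return List with `measurements` and `roster` (NULL when no roster path
#'   given).
#' @export
read_study <- function(measurements_path, roster_path = NULL) {
  measurements <- readr::read_csv(measurements_path,
                                  col_types = MEASUREMENT_COLS,
                                  progress = FALSE)
  required <- c("subject_id", "slot", "role", "sbp", "dbp", "hr")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    stop(measurements_path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  viol <- validate_sequences(measurements)
  if (nrow(viol) > 0) {
    # +1 for the header: report file line numbers, not row indices
    line_of <- function(sid, slot) {
      hit <- which(measurements$subject_id == sid & measurements$slot == slot)
      if (length(hit) == 0) NA_integer_ else hit[1] + 1L
    }
    msgs <- vapply(seq_len(nrow(viol)), function(i) {
      ln <- line_of(viol$subject_id[i], viol$slot[i])
      sprintf("  line %s: subject %s slot %s: %s",
              ifelse(is.na(ln), "?", ln), viol$subject_id[i], viol$slot[i],
              viol$rule[i])
    }, character(1))
    stop(measurements_path, ": ", nrow(viol), " validation failure(s)\n",
         paste(msgs, collapse = "\n"), call. = FALSE)
  }
  roster <- NULL
  if (!is.null(roster_path)) {
    roster <- readr::read_csv(roster_path, col_types = ROSTER_COLS,
                              progress = FALSE)
    roster$flags[is.na(roster$flags)] <- ""
  }
  list(measurements = measurements, roster = roster)
}

#' Write a study to CSV
#'
#' Writes the dialects [read_study()] reads; a written study round-trips
#' exactly.
#'
#' @param study An `esh_study` (or any list with `measurements` and
#'   optionally `roster`).
#' @param measurements_path,roster_path Output paths (roster skipped when
#'   NULL or absent).
#' @return Invisibly, the measurement path.
#' @export
write_study <- function(study, measurements_path, roster_path = NULL) {
  readr::write_csv(study$measurements, measurements_path, progress = FALSE)
  if (!is.null(roster_path) && !is.null(study$roster)) {
    readr::write_csv(study$roster, roster_path, progress = FALSE)
  }
  invisible(measurements_path)
}

grade_word <- function(pass) if (isTRUE(pass)) "Pass" else "Fail"

#' Build the canonical report object from a validation
#'
#' A plain nested list, schema-stable, mirroring the protocol's reporting
#' tables: per-parameter requirements and achieved counts for Parts 1 and 2,
#' the Part 3 decisions, agreement summaries, cohort screening, and a
#' provenance block echoing every constant that can affect a grade.
#'
#' @param validation An `esh_validation` from [grade_device()].
#' @return Nested list ready for JSON serialization.
#' @export
validation_report <- function(validation) {
  stopifnot(inherits(validation, "esh_validation"))
  cfg <- validation$config
  param_block <- function(p) {
    pp <- validation$parameters[[p]]
    d1 <- pp$part1$detail
    d2 <- pp$part2$detail
    ag <- pp$agreement
    list(
      part1 = list(
        cutoffs = d1$cutoff,
        units = d1$units[1],
        achieved_within = d1$within,
        required_two_of = d1$required_two_of,
        required_all_of = d1$required_all_of,
        grade = grade_word(pp$part1$pass)
      ),
      part2 = list(
        subjects_2of3 = d2$subjects_2of3,
        required_min_2of3 = d2$required_min_2of3,
        subjects_0of3 = d2$subjects_0of3,
        required_max_0of3 = d2$required_max_0of3,
        grade = grade_word(pp$part2$pass)
      ),
      agreement = list(
        n = ag$n,
        mean_signed_difference = ag$mean_signed_difference,
        sd_signed_difference = ag$sd_signed_difference,
        mean_absolute_difference = ag$mean_absolute_difference,
        loa_lower = ag$loa_lower,
        loa_upper = ag$loa_upper
      )
    )
  }
  screening <- NULL
  if (!is.null(validation$screening)) {
    s <- validation$screening
    screening <- list(
      n_included = s$n_included,
      sex_counts = as.list(s$sex_counts),
      excluded = lapply(seq_len(nrow(s$excluded)), function(i) {
        list(subject_id = s$excluded$subject_id[i], reason = s$excluded$reason[i])
      }),
      cohort_pass = s$cohort_pass
    )
  }
  list(
    n_subjects = validation$n_subjects,
    n_comparisons = 3L * validation$n_subjects,
    parameters = lapply(stats::setNames(PARAMETERS, PARAMETERS), param_block),
    bp_part3 = grade_word(validation$bp_part3$pass),
    hr_part3 = grade_word(validation$hr_part3$pass),
    screening = screening,
    provenance = list(
      bp_cutoffs = cfg$bp_thresholds$cutoffs,
      hr_cutoffs = cfg$hr_thresholds$cutoffs,
      part1_two_of = cfg$part1$two_of,
      part1_all_of = cfg$part1$all_of,
      part1_n_comparisons = cfg$part1$n_comparisons,
      part2_min_2of3 = cfg$part2$min_subjects_2of3,
      part2_max_0of3 = cfg$part2$max_subjects_0of3,
      part2_n_subjects = cfg$part2$n_subjects,
      selection_mode = cfg$selection_mode,
      loa_multiplier = cfg$loa_multiplier
    )
  )
}

#' Render a report as markdown
#'
#' Renders the JSON report structure (a `validation_report()` list, or the
#' same re-read from disk with [jsonlite::read_json()]) into markdown tables
#' mirroring the protocol's Part 1 / Part 2 / Part 3 layout. Deterministic:
#' the same report always renders the same text.
#'
#' @param report Report list.
#' @return A single markdown string.
#' @export
render_report_markdown <- function(report) {
  n <- function(x) unlist(x)  # tolerate jsonlite list-of-scalars round trips
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("# Device validation report")
  add("")
  add("Subjects: %d; comparisons per parameter: %d",
      n(report$n_subjects), n(report$n_comparisons))
  add("")
  labels <- c(sbp = "Systolic blood pressure",
              dbp = "Diastolic blood pressure", hr = "Heart rate")
  add("## Part 1 (pooled comparisons)")
  add("")
  add("| Parameter | Band cutoffs | Two of | All of | Achieved | Grade |")
  add("|---|---|---|---|---|---|")
  for (p in names(labels)) {
    b <- report$parameters[[p]]$part1
    add("| %s | %s %s | %s | %s | %s | %s |",
        labels[[p]],
        paste(n(b$cutoffs), collapse = "/"), n(b$units),
        paste(n(b$required_two_of), collapse = "/"),
        paste(n(b$required_all_of), collapse = "/"),
        paste(n(b$achieved_within), collapse = "/"),
        n(b$grade))
  }
  add("")
  add("## Part 2 (per-subject)")
  add("")
  add("| Parameter | 2/3 within first band | Required | 0/3 within first band | Allowed | Grade |")
  add("|---|---|---|---|---|---|")
  for (p in names(labels)) {
    b <- report$parameters[[p]]$part2
    add("| %s | %d | >=%d | %d | <=%d | %s |",
        labels[[p]], n(b$subjects_2of3), n(b$required_min_2of3),
        n(b$subjects_0of3), n(b$required_max_0of3), n(b$grade))
  }
  add("")
  add("## Part 3")
  add("")
  add("- Blood pressure (SBP + DBP): **%s**", n(report$bp_part3))
  add("- Heart rate: **%s**", n(report$hr_part3))
  add("")
  add("## Agreement (test - reference)")
  add("")
  add("| Parameter | n | Bias | SD | Mean abs diff | LoA lower | LoA upper |")
  add("|---|---|---|---|---|---|---|")
  for (p in names(labels)) {
    a <- report$parameters[[p]]$agreement
    add("| %s | %d | %.2f | %.2f | %.2f | %.2f | %.2f |",
        labels[[p]], n(a$n), n(a$mean_signed_difference),
        n(a$sd_signed_difference), n(a$mean_absolute_difference),
        n(a$loa_lower), n(a$loa_upper))
  }
  if (!is.null(report$screening)) {
    s <- report$screening
    add("")
    add("## Cohort screening")
    add("")
    add("Included: %d (male %d / female %d) — %s", n(s$n_included),
        n(s$sex_counts$male), n(s$sex_counts$female),
        if (isTRUE(n(s$cohort_pass))) "Pass" else "Fail")
    for (e in s$excluded) {
      add("- excluded %s: %s", n(e$subject_id), n(e$reason))
    }
  }
  add("")
  add("## Provenance")
  add("")
  pr <- report$provenance
  for (k in names(pr)) add("- %s: %s", k, paste(n(pr[[k]]), collapse = "/"))
  paste(lines, collapse = "\n")
}

#' Write the validation report to disk
#'
#' Serializes the canonical JSON report and, optionally, its markdown
#' rendering. Given the same validation the bytes are identical across runs.
#'
#' @param validation An `esh_validation`.
#' @param json_path Output path for the JSON report.
#' @param md_path Optional output path for the markdown rendering.
#' @return Invisibly, the report list.
#' @export
write_report <- function(validation, json_path, md_path = NULL) {
  report <- validation_report(validation)
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!is.null(md_path)) {
    writeLines(render_report_markdown(report), md_path)
  }
  invisible(report)
}
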