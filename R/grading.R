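#' ESH-IP2 Part 1 / Part 2 / Part 3 grading
#'
#' Part 1 pools all 99 comparisons and counts how many fall within each
#' cumulative band; it passes when at least two of the three bands reach the
#' higher required count and all three reach the lower one. Part 2 grades
#' subjects: enough subjects must have at least two of their three
#' differences within the first band, and few enough may have none. Part 3
#' is the conjunction of the parts supplied to it — SBP and DBP jointly for
#' the BP grade, HR alone for the heart-rate extension.
#'
#' @name grading
NULL

#' Cumulative band counts of paired differences
#'
#' Counts comparisons whose absolute difference is within each cutoff
#' (inclusive `<=`). Counts are cumulative by construction because the
#' cutoffs ascend.
#'
#' @param differences Tibble of paired differences for a single parameter
#'   (see [all_differences()]).
#' @param thresholds A [band_thresholds()] object.
#' @return List of class `band_counts` with `n`, `within` (three counts) and
#'   the thresholds used.
#' @examples
#' d <- tibble::tibble(parameter = "sbp", abs_difference = c(0, 5, 10, 15, 16))
#' band_counts(d, band_thresholds())$within  # 2 3 4
#' @export
band_counts <- function(differences, thresholds = band_thresholds()) {
  stopifnot(inherits(thresholds, "band_thresholds"))
  if (nrow(differences) > 0 && length(unique(differences$parameter)) > 1) {
    stop("band_counts expects differences for a single parameter; got: ",
         paste(unique(differences$parameter), collapse = ", "), call. = FALSE)
  }
  absd <- differences$abs_difference
  within <- vapply(thresholds$cutoffs, function(k) sum(absd <= k), integer(1))
  structure(list(n = length(absd), within = within, thresholds = thresholds),
            class = "band_counts")
}

# Build a band_counts object directly from three cumulative counts, e.g. the
# achieved counts printed in a published validation report.
#' @rdname band_counts
#' @param within Three cumulative within-band counts.
#' @param n Total number of comparisons.
#' @export
band_counts_from_totals <- function(within, n = 99L,
                                    thresholds = band_thresholds()) {
  within <- as.integer(within)
  stopifnot(length(within) == 3L)
  if (is.unsorted(within) || within[3] > n || within[1] < 0) {
    stop("within-band counts must be non-decreasing and between 0 and n", call. = FALSE)
  }
  structure(list(n = as.integer(n), within = within, thresholds = thresholds),
            class = "band_counts")
}

#' Grade Part 1 from band counts
#'
#' Pass requires the higher count (`two_of`) in at least two of the three
#' bands and the lower count (`all_of`) in all three.
#'
#' @param counts A `band_counts` object.
#' @param requirements A [part1_requirements()] object.
#' @return List of class `part_grade`: `pass`, and a `detail` tibble with the
#'   achieved and required counts per band.
#' @examples
#' grade_part1(band_counts_from_totals(c(81, 92, 96)))$pass  # TRUE
#' @export
grade_part1 <- function(counts, requirements = part1_requirements()) {
  stopifnot(inherits(counts, "band_counts"),
            inherits(requirements, "part1_requirements"))
  if (counts$n != requirements$n_comparisons) {
    stop(sprintf("part 1 expects %d comparisons, got %d",
                 requirements$n_comparisons, counts$n), call. = FALSE)
  }
  meets_two <- counts$within >= requirements$two_of
  meets_all <- counts$within >= requirements$all_of
  pass <- sum(meets_two) >= 2L && all(meets_all)
  structure(list(
    part = "part1",
    pass = pass,
    detail = tibble::tibble(
      band = 1:3,
      cutoff = counts$thresholds$cutoffs,
      units = counts$thresholds$units,
      within = counts$within,
      required_two_of = requirements$two_of,
      required_all_of = requirements$all_of,
      meets_two_of = meets_two,
      meets_all_of = meets_all
    )
  ), class = "part_grade")
}

#' Per-subject first-band profiles
#'
#' For each subject, counts how many of the three differences fall within
#' the first band (5 mm Hg for BP, 3 bpm for HR).
#'
#' @param differences Single-parameter paired differences.
#' @param first_cutoff First band cutoff.
#' @return Tibble `subject_id`, `n_within_first_band` (0-3).
#' @export
subject_band_profiles <- function(differences, first_cutoff = 5) {
  differences |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_within_first_band = sum(.data$abs_difference <= first_cutoff),
      .groups = "drop"
    )
}

#' Grade Part 2 from subject profiles
#'
#' Tally A counts subjects with at least 2 of 3 differences within the first
#' band; tally B counts subjects with none. Pass requires
#' A >= `min_subjects_2of3` and B <= `max_subjects_0of3`.
#'
#' @param profiles Tibble from [subject_band_profiles()].
#' @param requirements A [part2_requirements()] object.
#' @return List of class `part_grade` with `pass` and a one-row `detail`
#'   tibble carrying both tallies and their requirements.
#' @export
grade_part2 <- function(profiles, requirements = part2_requirements()) {
  stopifnot(inherits(requirements, "part2_requirements"))
  if (nrow(profiles) != requirements$n_subjects) {
    stop(sprintf("part 2 expects %d subjects, got %d",
                 requirements$n_subjects, nrow(profiles)), call. = FALSE)
  }
  if (any(profiles$n_within_first_band < 0 | profiles$n_within_first_band > 3)) {
    stop("n_within_first_band must be between 0 and 3", call. = FALSE)
  }
  n_2of3 <- sum(profiles$n_within_first_band >= 2L)
  n_0of3 <- sum(profiles$n_within_first_band == 0L)
  pass <- n_2of3 >= requirements$min_subjects_2of3 &&
    n_0of3 <= requirements$max_subjects_0of3
  structure(list(
    part = "part2",
    pass = pass,
    detail = tibble::tibble(
      n_subjects = requirements$n_subjects,
      subjects_2of3 = n_2of3,
      required_min_2of3 = requirements$min_subjects_2of3,
      subjects_0of3 = n_0of3,
      required_max_0of3 = requirements$max_subjects_0of3
    )
  ), class = "part_grade")
}

#' Grade Part 3 as the conjunction of supplied part grades
#'
#' For the BP grade, supply Part 1 and Part 2 for both SBP and DBP; for the
#' HR extension, the HR Part 1 and Part 2 alone.
#'
#' @param ... `part_grade` objects (or lists of them).
#' @return List of class `part_grade` with the overall `pass`.
#' @export
grade_part3 <- function(...) {
  parts <- list(...)
  # allow a single list of grades
  if (length(parts) == 1L && !inherits(parts[[1]], "part_grade")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) > 0, all(vapply(parts, inherits, logical(1), "part_grade")))
  structure(list(part = "part3",
                 pass = all(vapply(parts, function(p) isTRUE(p$pass), logical(1)))),
            class = "part_grade")
}

#' @export
print.part_grade <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$part, if (x$pass) "Pass" else "Fail"))
  if (!is.null(x$detail)) print(x$detail)
  invisible(x)
}

# Scale requirement constants to a non-standard cohort size, keeping the
# required fractions: minima round up, maxima round down.
scale_requirements <- function(part1, part2, n_subjects) {
  n_comp <- 3L * n_subjects
  f <- n_comp / part1$n_comparisons
  p1 <- part1_requirements(n_comparisons = n_comp,
                           two_of = ceiling(part1$two_of * f),
                           all_of = ceiling(part1$all_of * f))
  g <- n_subjects / part2$n_subjects
  p2 <- part2_requirements(n_subjects = n_subjects,
                           min_subjects_2of3 = ceiling(part2$min_subjects_2of3 * g),
                           max_subjects_0of3 = floor(part2$max_subjects_0of3 * g))
  list(part1 = p1, part2 = p2)
}

#' Grade a device from a full study
#'
#' Runs the whole analysis: favorable pairing, band counting, Part 1 and
#' Part 2 per parameter, the joint BP Part 3 (SBP and DBP), the separate HR
#' Part 3, and Bland-Altman agreement summaries. Deterministic: identical
#' input yields identical output.
#'
#' The requirement constants assume the protocol's 33 subjects; with a
#' different cohort size a warning is issued and the requirements are scaled
#' proportionally (minima rounded up, maxima down).
#'
#' @param measurements Long-format measurements (validated internally).
#' @param roster Optional subject roster; when given, cohort screening is
#'   included in the result.
#' @param config A [validation_config()].
#' @return Object of class `esh_validation`: per-parameter `band_counts`,
#'   `part1`, `part2`, `agreement`, plus `bp_part3`, `hr_part3`,
#'   `differences`, optional `screening`, and the `config` used.
#' @examples
#' study <- simulate_study(seed = 42)
#' v <- grade_device(study$measurements, study$roster)
#' v$bp_part3$pass
#' @export
grade_device <- function(measurements, roster = NULL,
                         config = validation_config()) {
  stopifnot(inherits(config, "validation_config"))
  diffs <- all_differences(measurements, selection_mode = config$selection_mode)
  n_subjects <- length(unique(diffs$subject_id))

  part1_req <- config$part1
  part2_req <- config$part2
  if (n_subjects != part2_req$n_subjects) {
    warning(sprintf(paste0("study has %d subjects but the protocol expects %d; ",
                           "requirements scaled proportionally"),
                    n_subjects, part2_req$n_subjects), call. = FALSE)
    scaled <- scale_requirements(part1_req, part2_req, n_subjects)
    part1_req <- scaled$part1
    part2_req <- scaled$part2
  }

  thresholds <- list(sbp = config$bp_thresholds, dbp = config$bp_thresholds,
                     hr = config$hr_thresholds)
  per_param <- lapply(stats::setNames(PARAMETERS, PARAMETERS), function(p) {
    d <- diffs[diffs$parameter == p, , drop = FALSE]
    counts <- band_counts(d, thresholds[[p]])
    profiles <- subject_band_profiles(d, thresholds[[p]]$cutoffs[1])
    list(
      band_counts = counts,
      part1 = grade_part1(counts, part1_req),
      part2 = grade_part2(profiles, part2_req),
      profiles = profiles,
      agreement = difference_summary(d, loa_multiplier = config$loa_multiplier)
    )
  })

  structure(list(
    n_subjects = n_subjects,
    parameters = per_param,
    bp_part3 = grade_part3(per_param$sbp$part1, per_param$sbp$part2,
                           per_param$dbp$part1, per_param$dbp$part2),
    hr_part3 = grade_part3(per_param$hr$part1, per_param$hr$part2),
    differences = diffs,
    screening = if (!is.null(roster)) cohort_screen(roster) else NULL,
    config = config
  ), class = "esh_validation")
}

#' @export
print.esh_validation <- function(x, ...) {
  cat(sprintf("ESH-IP2 validation, %d subjects (%d comparisons per parameter)\n",
              x$n_subjects, 3L * x$n_subjects))
  for (p in names(x$parameters)) {
    pp <- x$parameters[[p]]
    cat(sprintf("  %s: part 1 %s (within = %s), part 2 %s (2of3 = %d, 0of3 = %d)\n",
                toupper(p),
                if (pp$part1$pass) "Pass" else "Fail",
                paste(pp$band_counts$within, collapse = "/"),
                if (pp$part2$pass) "Pass" else "Fail",
                pp$part2$detail$subjects_2of3, pp$part2$detail$subjects_0of3))
  }
  cat(sprintf("  BP part 3: %s; HR part 3: %s\n",
              if (x$bp_part3$pass) "Pass" else "Fail",
              if (x$hr_part3$pass) "Pass" else "Fail"))
  invisible(x)
}
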