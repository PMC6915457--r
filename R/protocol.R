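#' Protocol constants for ESH-IP2 device validation
#'
#' The 2010 revision of the European Society of Hypertension International
#' Protocol (ESH-IP2) grades a device from 99 paired test-vs-reference
#' comparisons (33 subjects, 3 graded test readings each). Differences are
#' classified into cumulative absolute-difference bands and graded in three
#' parts. These constructors hold the protocol's constants; every grading
#' function takes them as arguments so alternative requirement sets can be
#' explored, but the defaults are the published values.
#'
#' @name esh_protocol
NULL

#' Band thresholds for cumulative difference classification
#'
#' Three strictly ascending non-negative cutoffs. A comparison falls "within"
#' band *i* when its absolute difference is less than or equal to `cutoffs[i]`
#' (inclusive: a difference of exactly 5 mm Hg is within 5 mm Hg). The blood
#' pressure defaults are 5/10/15 mm Hg; the heart-rate extension uses
#' 3/5/8 beats per minute.
#'
#' @param cutoffs Numeric vector of exactly three strictly ascending
#'   non-negative values.
#' @param units Unit label, `"mmHg"` or `"bpm"` (informational).
#' @return An object of class `band_thresholds`.
#' @examples
#' band_thresholds()            # BP bands: 5, 10, 15 mm Hg
#' hr_band_thresholds()         # HR bands: 3, 5, 8 bpm
#' @export
band_thresholds <- function(cutoffs = c(5, 10, 15), units = "mmHg") {
  stopifnot(is.numeric(cutoffs), length(cutoffs) == 3L)
  if (any(cutoffs < 0) || any(diff(cutoffs) <= 0)) {
    stop("band cutoffs must be non-negative and strictly ascending", call. = FALSE)
  }
  structure(list(cutoffs = as.numeric(cutoffs), units = units),
            class = "band_thresholds")
}

#' @rdname band_thresholds
#' @export
hr_band_thresholds <- function(cutoffs = c(3, 5, 8)) {
  band_thresholds(cutoffs, units = "bpm")
}

#' Part 1 pass requirements
#'
#' Part 1 grades the pooled 99 comparisons. For each band there are two
#' required counts: a higher one that must be met in at least two of the
#' three bands (`two_of`, defaults 73/87/96) and a lower one that must be
#' met in all three (`all_of`, defaults 65/81/93).
#'
#' @param n_comparisons Total comparisons expected (default 99).
#' @param two_of Counts that at least two of the three bands must reach.
#' @param all_of Counts that all three bands must reach.
#' @return An object of class `part1_requirements`.
#' @export
part1_requirements <- function(n_comparisons = 99L,
                               two_of = c(73L, 87L, 96L),
                               all_of = c(65L, 81L, 93L)) {
  stopifnot(length(two_of) == 3L, length(all_of) == 3L)
  two_of <- as.integer(two_of); all_of <- as.integer(all_of)
  n_comparisons <- as.integer(n_comparisons)
  if (any(all_of > two_of)) {
    stop("'all_of' requirements cannot exceed 'two_of' requirements", call. = FALSE)
  }
  if (any(two_of > n_comparisons)) {
    stop("requirements cannot exceed the number of comparisons", call. = FALSE)
  }
  structure(list(n_comparisons = n_comparisons, two_of = two_of, all_of = all_of),
            class = "part1_requirements")
}

#' Part 2 pass requirements
#'
#' Part 2 grades subjects individually on their three first-band differences
#' (within 5 mm Hg for BP, within 3 bpm for HR): at least
#' `min_subjects_2of3` of the 33 subjects must have two or more of their
#' three differences within the first band, and at most `max_subjects_0of3`
#' may have none within it.
#'
#' @param n_subjects Number of subjects expected (default 33).
#' @param min_subjects_2of3 Minimum subjects with >= 2 of 3 within the first
#'   band (default 24).
#' @param max_subjects_0of3 Maximum subjects with 0 of 3 within the first
#'   band (default 3).
#' @return An object of class `part2_requirements`.
#' @export
part2_requirements <- function(n_subjects = 33L,
                               min_subjects_2of3 = 24L,
                               max_subjects_0of3 = 3L) {
  n_subjects <- as.integer(n_subjects)
  min_subjects_2of3 <- as.integer(min_subjects_2of3)
  max_subjects_0of3 <- as.integer(max_subjects_0of3)
  if (min_subjects_2of3 + max_subjects_0of3 > n_subjects) {
    stop("infeasible part 2 requirements: minimum passing plus maximum failing subjects exceed n", call. = FALSE)
  }
  structure(list(n_subjects = n_subjects,
                 min_subjects_2of3 = min_subjects_2of3,
                 max_subjects_0of3 = max_subjects_0of3),
            class = "part2_requirements")
}

# Slot labels in protocol order. BPA (entry reading, reference device) and
# BPB (device-detection reading, test device) are acquisition readings and
# are never consumed by grading.
SLOT_LABELS <- c("BPA", "BPB", "BP1", "BP2", "BP3", "BP4", "BP5", "BP6", "BP7")

#' Device role of each measurement slot
#'
#' Roles are a pure function of the slot label: the reference device takes
#' BPA, BP1, BP3, BP5, BP7 and the test device BPB, BP2, BP4, BP6. Only
#' BP1..BP7 enter grading.
#'
#' @param slot Character vector of slot labels.
#' @return Character vector of `"reference"` / `"test"`; `NA` for unknown
#'   labels.
#' @export
slot_role <- function(slot) {
  roles <- c(BPA = "reference", BPB = "test",
             BP1 = "reference", BP2 = "test", BP3 = "reference",
             BP4 = "test", BP5 = "reference", BP6 = "test", BP7 = "reference")
  unname(roles[as.character(slot)])
}

#' Run configuration for a validation analysis
#'
#' Bundles every constant that can affect a grade so that the report can echo
#' the full provenance: band thresholds for BP and HR, Part 1/2 requirements,
#' the favorable-selection mode, and the limits-of-agreement multiplier.
#'
#' @param bp_thresholds,hr_thresholds [band_thresholds()] objects.
#' @param part1,part2 Requirement objects.
#' @param selection_mode `"independent"` (each parameter picks its own flank)
#'   or `"joint"` (SBP and DBP share the flank minimizing their summed
#'   absolute difference; HR stays independent).
#' @param loa_multiplier Multiplier for the limits of agreement (default 1.96).
#' @return An object of class `validation_config`.
#' @export
validation_config <- function(bp_thresholds = band_thresholds(),
                              hr_thresholds = hr_band_thresholds(),
                              part1 = part1_requirements(),
                              part2 = part2_requirements(),
                              selection_mode = c("independent", "joint"),
                              loa_multiplier = 1.96) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(inherits(bp_thresholds, "band_thresholds"),
            inherits(hr_thresholds, "band_thresholds"),
            inherits(part1, "part1_requirements"),
            inherits(part2, "part2_requirements"),
            is.numeric(loa_multiplier), loa_multiplier > 0)
  structure(list(bp_thresholds = bp_thresholds,
                 hr_thresholds = hr_thresholds,
                 part1 = part1,
                 part2 = part2,
                 selection_mode = selection_mode,
                 loa_multiplier = loa_multiplier),
            class = "validation_config")
}
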