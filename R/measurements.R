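#' Measurement sequences and cohort screening
#'
#' A study is stored in long format: one row per (subject, slot) with integer
#' SBP / DBP (mm Hg) and HR (bpm) readings, plus a subject roster. Both
#' devices display integer readings, so values are stored as integers and
#' all downstream differences are exact — there is no band-edge floating
#' point ambiguity.
#'
#' @name measurements
NULL

# Physiologic plausibility ranges for a single reading.
READING_RANGES <- list(sbp = c(40L, 300L), dbp = c(20L, 200L), hr = c(20L, 250L))

#' Validate nine-reading measurement sequences
#'
#' Checks every subject's sequence against the schedule invariants: exactly
#' the nine slots BPA, BPB, BP1..BP7, each exactly once; the device role
#' fixed by the slot label; integer readings inside physiologic ranges
#' (SBP 40-300, DBP 20-200 mm Hg, HR 20-250 bpm); and SBP strictly greater
#' than DBP. Violations are returned as data, one row each, rather than
#' raised — a well-formed dataset yields a zero-row tibble.
#'
#' @param measurements Tibble with columns `subject_id`, `slot`, `role`,
#'   `sbp`, `dbp`, `hr`.
#' @return Tibble with columns `subject_id`, `slot`, `rule` (empty when
#'   everything is well formed).
#' @examples
#' study <- simulate_study(seed = 1)
#' nrow(validate_sequences(study$measurements))  # 0
#' @export
validate_sequences <- function(measurements) {
  required_cols <- c("subject_id", "slot", "role", "sbp", "dbp", "hr")
  missing_cols <- setdiff(required_cols, names(measurements))
  if (length(missing_cols) > 0) {
    stop("measurements are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  v <- list()
  add <- function(subject_id, slot, rule) {
    tibble::tibble(subject_id = as.character(subject_id),
                   slot = as.character(slot), rule = rule)
  }

  unknown <- !(measurements$slot %in% SLOT_LABELS)
  if (any(unknown)) {
    v[[length(v) + 1L]] <- add(measurements$subject_id[unknown],
                               measurements$slot[unknown],
                               "unknown slot label")
  }
  m <- measurements[!unknown, , drop = FALSE]

  per_subject <- split(seq_len(nrow(m)), m$subject_id)
  for (sid in names(per_subject)) {
    rows <- m[per_subject[[sid]], , drop = FALSE]
    dup <- unique(rows$slot[duplicated(rows$slot)])
    for (s in dup) v[[length(v) + 1L]] <- add(sid, s, "duplicate slot")
    missing_slots <- setdiff(SLOT_LABELS, rows$slot)
    for (s in missing_slots) v[[length(v) + 1L]] <- add(sid, s, "missing slot")
  }

  bad_role <- m$role != slot_role(m$slot)
  if (any(bad_role)) {
    v[[length(v) + 1L]] <- add(m$subject_id[bad_role], m$slot[bad_role],
                               "role does not match slot label")
  }

  for (param in names(READING_RANGES)) {
    x <- m[[param]]
    rng <- READING_RANGES[[param]]
    non_int <- !is.finite(x) | x != round(x)
    if (any(non_int)) {
      v[[length(v) + 1L]] <- add(m$subject_id[non_int], m$slot[non_int],
                                 paste0(param, " is not an integer reading"))
    }
    oob <- is.finite(x) & x == round(x) & (x < rng[1] | x > rng[2])
    if (any(oob)) {
      v[[length(v) + 1L]] <- add(m$subject_id[oob], m$slot[oob],
                                 sprintf("%s outside %d-%d", param, rng[1], rng[2]))
    }
  }

  inverted <- is.finite(m$sbp) & is.finite(m$dbp) & m$sbp <= m$dbp
  if (any(inverted)) {
    v[[length(v) + 1L]] <- add(m$subject_id[inverted], m$slot[inverted],
                               "sbp must exceed dbp")
  }

  if (length(v) == 0) {
    return(tibble::tibble(subject_id = character(), slot = character(),
                          rule = character()))
  }
  dplyr::arrange(dplyr::bind_rows(v), .data$subject_id, .data$slot, .data$rule)
}

#' Screen a subject roster against the cohort rules
#'
#' Subjects are excluded when younger than 25 years or carrying any
#' contraindication flag (arrhythmia, circulatory problem, pregnancy, or a
#' device failure during measurement). The cohort passes when at least 33
#' subjects remain and each sex contributes at least 10.
#'
#' @param roster Tibble with columns `subject_id`, `sex` (`"male"`/
#'   `"female"`), `age`, and optionally `flags` (semicolon-separated strings).
#' @param min_subjects,min_per_sex Cohort size rules (defaults 33 and 10).
#' @return A list of class `cohort_screening`: `included` (ids), `excluded`
#'   (tibble id + reason), `sex_counts`, `cohort_pass`, and the failed rules
#'   if any.
#' @export
cohort_screen <- function(roster, min_subjects = 33L, min_per_sex = 10L) {
  stopifnot(nrow(roster) > 0)
  flags <- if ("flags" %in% names(roster)) roster$flags else character(nrow(roster))
  flags[is.na(flags)] <- ""
  reasons <- character(nrow(roster))
  too_young <- roster$age < 25
  reasons[too_young] <- "age below 25"
  flagged <- nzchar(trimws(flags))
  reasons[flagged] <- ifelse(nzchar(reasons[flagged]),
                             paste(reasons[flagged], flags[flagged], sep = "; "),
                             flags[flagged])
  excluded <- nzchar(reasons)

  included_ids <- as.character(roster$subject_id[!excluded])
  sex_counts <- table(factor(roster$sex[!excluded], levels = c("male", "female")))
  failed <- character()
  if (length(included_ids) < min_subjects) {
    failed <- c(failed, sprintf("fewer than %d included subjects", min_subjects))
  }
  if (any(sex_counts < min_per_sex)) {
    failed <- c(failed, sprintf("fewer than %d subjects of each sex", min_per_sex))
  }
  structure(list(
    included = included_ids,
    excluded = tibble::tibble(subject_id = as.character(roster$subject_id[excluded]),
                              reason = reasons[excluded]),
    sex_counts = c(male = unname(sex_counts["male"]),
                   female = unname(sex_counts["female"])),
    n_included = length(included_ids),
    cohort_pass = length(failed) == 0,
    failed_rules = failed
  ), class = "cohort_screening")
}

#' @export
print.cohort_screening <- function(x, ...) {
  cat(sprintf("Cohort screening: %d included (%d male / %d female), %d excluded — %s\n",
              x$n_included, x$sex_counts[["male"]], x$sex_counts[["female"]],
              nrow(x$excluded), if (x$cohort_pass) "PASS" else "FAIL"))
  if (nrow(x$excluded) > 0) {
    for (i in seq_len(nrow(x$excluded))) {
      cat(sprintf("  excluded %s: %s\n", x$excluded$subject_id[i], x$excluded$reason[i]))
    }
  }
  if (!x$cohort_pass) cat("  failed:", paste(x$failed_rules, collapse = "; "), "\n")
  invisible(x)
}
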