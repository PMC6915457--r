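#' Flanking-reference pairing with favorable selection
#'
#' Each test reading (BP2, BP4, BP6) is flanked by two reference readings
#' (BP1/BP3, BP3/BP5, BP5/BP7). The protocol compares the test reading with
#' both flanks and keeps the comparison more favorable to the device — the
#' flank with the smaller absolute difference. Ties go to the preceding
#' flank. By default each parameter (SBP, DBP, HR) chooses its own flank;
#' a joint mode forces SBP and DBP onto the flank minimizing their summed
#' absolute difference, for sensitivity analysis.
#'
#' @name pairing
NULL

# Graded comparisons: test slot and its two candidate reference flanks.
COMPARISON_SLOTS <- tibble::tibble(
  comparison_index = 1:3,
  test_slot = c("BP2", "BP4", "BP6"),
  preceding_slot = c("BP1", "BP3", "BP5"),
  following_slot = c("BP3", "BP5", "BP7")
)

PARAMETERS <- c("sbp", "dbp", "hr")

# Reshape validated long measurements into one row per subject x comparison,
# with test / preceding / following values for every parameter.
candidate_table <- function(measurements) {
  viol <- validate_sequences(measurements)
  if (nrow(viol) > 0) {
    stop("measurements fail validation (", nrow(viol), " violation(s), first: ",
         viol$subject_id[1], " ", viol$slot[1], ": ", viol$rule[1], ")",
         call. = FALSE)
  }
  subjects <- unique(as.character(measurements$subject_id))
  n <- length(subjects)
  subj_idx <- match(as.character(measurements$subject_id), subjects)
  slot_idx <- match(measurements$slot, SLOT_LABELS)

  out <- tibble::tibble(
    subject_id = rep(subjects, each = 3L),
    comparison_index = rep(COMPARISON_SLOTS$comparison_index, n),
    test_slot = rep(COMPARISON_SLOTS$test_slot, n),
    preceding_slot = rep(COMPARISON_SLOTS$preceding_slot, n),
    following_slot = rep(COMPARISON_SLOTS$following_slot, n)
  )
  # subject x slot value matrix per parameter, then the three comparisons
  # (rows ordered subject, then comparison index)
  for (param in PARAMETERS) {
    M <- matrix(NA_real_, n, length(SLOT_LABELS))
    M[cbind(subj_idx, slot_idx)] <- as.numeric(measurements[[param]])
    for (role_col in c("test", "preceding", "following")) {
      cols <- match(COMPARISON_SLOTS[[paste0(role_col, "_slot")]], SLOT_LABELS)
      out[[paste0(param, "_", role_col)]] <- as.vector(t(M[, cols, drop = FALSE]))
    }
  }
  out
}

#' Candidate test-vs-reference pairs for one parameter
#'
#' Returns the three candidate comparisons per subject — the test reading
#' with both its flanking reference readings — before favorable selection.
#' The entry readings BPA/BPB never appear.
#'
#' @param measurements Validated long-format measurements.
#' @param parameter One of `"sbp"`, `"dbp"`, `"hr"`.
#' @return Tibble with `subject_id`, `comparison_index`, `test_slot`,
#'   `test_value`, `preceding_value`, `following_value`.
#' @export
candidate_pairs <- function(measurements, parameter = c("sbp", "dbp", "hr")) {
  parameter <- match.arg(tolower(parameter), PARAMETERS)
  ct <- candidate_table(measurements)
  tibble::tibble(
    subject_id = ct$subject_id,
    comparison_index = ct$comparison_index,
    test_slot = ct$test_slot,
    test_value = ct[[paste0(parameter, "_test")]],
    preceding_value = ct[[paste0(parameter, "_preceding")]],
    following_value = ct[[paste0(parameter, "_following")]]
  )
}

# Favorable flank per row given test and two candidate reference values;
# ties break toward the preceding reference.
favorable_flank <- function(d_preceding, d_following) {
  ifelse(abs(d_following) < abs(d_preceding), "following", "preceding")
}

#' Select the favorable flank for candidate pairs
#'
#' For each candidate comparison, keeps the flanking reference with the
#' smaller absolute difference from the test reading (ties toward the
#' preceding flank). Differences are signed test minus reference.
#'
#' @param candidates Output of [candidate_pairs()].
#' @param parameter Parameter label recorded in the output.
#' @return Tibble of paired differences: `subject_id`, `comparison_index`,
#'   `parameter`, `test_value`, `reference_value`, `flank`,
#'   `signed_difference`, `abs_difference`.
#' @export
select_favorable <- function(candidates, parameter) {
  d_prec <- candidates$test_value - candidates$preceding_value
  d_foll <- candidates$test_value - candidates$following_value
  flank <- favorable_flank(d_prec, d_foll)
  signed <- ifelse(flank == "preceding", d_prec, d_foll)
  tibble::tibble(
    subject_id = candidates$subject_id,
    comparison_index = candidates$comparison_index,
    parameter = parameter,
    test_value = candidates$test_value,
    reference_value = ifelse(flank == "preceding",
                             candidates$preceding_value,
                             candidates$following_value),
    flank = flank,
    signed_difference = signed,
    abs_difference = abs(signed)
  )
}

#' All favorable paired differences for a study
#'
#' Composes [candidate_pairs()] and [select_favorable()] over every subject
#' and parameter: 3 comparisons per subject per parameter (99 for the
#' protocol's 33 subjects). Rows are ordered by subject (input order) then
#' comparison index.
#'
#' @param measurements Validated long-format measurements.
#' @param parameters Parameters to pair (default all three).
#' @param selection_mode `"independent"` (default) lets each parameter pick
#'   its own flank; `"joint"` makes SBP and DBP share the flank minimizing
#'   `|dSBP| + |dDBP|` (HR remains independent).
#' @return Tibble of paired differences for all requested parameters.
#' @examples
#' study <- simulate_study(seed = 1)
#' diffs <- all_differences(study$measurements)
#' table(diffs$parameter)  # 99 each
#' @export
all_differences <- function(measurements, parameters = PARAMETERS,
                            selection_mode = c("independent", "joint")) {
  selection_mode <- match.arg(selection_mode)
  parameters <- match.arg(tolower(parameters), PARAMETERS, several.ok = TRUE)
  ct <- candidate_table(measurements)

  one <- function(param, flank) {
    test <- ct[[paste0(param, "_test")]]
    ref <- ifelse(flank == "preceding",
                  ct[[paste0(param, "_preceding")]],
                  ct[[paste0(param, "_following")]])
    signed <- test - ref
    tibble::tibble(subject_id = ct$subject_id,
                   comparison_index = ct$comparison_index,
                   parameter = param, test_value = test, reference_value = ref,
                   flank = flank, signed_difference = signed,
                   abs_difference = abs(signed))
  }

  independent_flank <- function(param) {
    favorable_flank(ct[[paste0(param, "_test")]] - ct[[paste0(param, "_preceding")]],
                    ct[[paste0(param, "_test")]] - ct[[paste0(param, "_following")]])
  }

  flanks <- lapply(stats::setNames(PARAMETERS, PARAMETERS), independent_flank)
  if (selection_mode == "joint") {
    score <- function(flank_col) {
      abs(ct$sbp_test - ct[[paste0("sbp_", flank_col)]]) +
        abs(ct$dbp_test - ct[[paste0("dbp_", flank_col)]])
    }
    joint <- ifelse(score("following") < score("preceding"), "following", "preceding")
    flanks$sbp <- joint
    flanks$dbp <- joint
  }

  dplyr::bind_rows(lapply(parameters, function(p) one(p, flanks[[p]])))
}
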