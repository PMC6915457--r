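# Shared fixture builders. Everything is generated in code; no data files.

# A single well-formed nine-slot sequence with specified per-slot readings.
# `values` is a named list slot -> c(sbp, dbp, hr); unspecified slots get a
# neutral 120/80/70.
make_sequence <- function(subject_id = "S001", values = list()) {
  slots <- c("BPA", "BPB", "BP1", "BP2", "BP3", "BP4", "BP5", "BP6", "BP7")
  default <- c(120L, 80L, 70L)
  m <- t(vapply(slots, function(s) {
    v <- values[[s]]
    if (is.null(v)) default else as.integer(v)
  }, integer(3)))
  tibble::tibble(subject_id = subject_id, slot = slots,
                 role = slot_role(slots),
                 sbp = m[, 1], dbp = m[, 2], hr = m[, 3])
}

# n identical well-formed subjects.
make_study_measurements <- function(n = 33) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_sequence(sprintf("S%03d", i))
  }))
}

# A roster row.
make_profile <- function(subject_id, sex = "male", age = 60, flags = "") {
  tibble::tibble(subject_id = subject_id, sex = sex, age = age,
                 height_cm = 170, weight_kg = 70, bmi = 24.22,
                 arm_circumference_mm = 280, arm = "right", flags = flags)
}

make_roster <- function(n_male = 18, n_female = 15, flags = character(0)) {
  n <- n_male + n_female
  fl <- character(n)
  fl[seq_along(flags)] <- flags
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_profile(sprintf("S%03d", i),
                 sex = if (i <= n_male) "male" else "female",
                 flags = fl[i])
  }))
}

# Subject band profiles realizing given part-2 tallies: `n_2of3` subjects
# with 3/3 within the first band, `n_0of3` with 0/3, remainder with 1/3.
make_profiles_from_tallies <- function(n_2of3, n_0of3, n_subjects = 33) {
  stopifnot(n_2of3 + n_0of3 <= n_subjects)
  counts <- c(rep(3L, n_2of3), rep(0L, n_0of3),
              rep(1L, n_subjects - n_2of3 - n_0of3))
  tibble::tibble(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                 n_within_first_band = counts)
}

# A paired-differences tibble from raw signed differences (single parameter).
make_differences <- function(signed, parameter = "sbp",
                             test_value = 120 + signed,
                             reference_value = 120) {
  n <- length(signed)
  tibble::tibble(
    subject_id = sprintf("S%03d", ceiling(seq_len(n) / 3)),
    comparison_index = rep_len(1:3, n),
    parameter = parameter,
    test_value = test_value,
    reference_value = reference_value,
    flank = "preceding",
    signed_difference = signed,
    abs_difference = abs(signed)
  )
}

# Independent truth-table oracle for part 1: literal transcription of the
# rule, kept separate from the implementation.
oracle_part1 <- function(within, two_of = c(73, 87, 96),
                         all_of = c(65, 81, 93)) {
  sum(within >= two_of) >= 2 && all(within >= all_of)
}

oracle_part2 <- function(n_2of3, n_0of3, min_2of3 = 24, max_0of3 = 3) {
  n_2of3 >= min_2of3 && n_0of3 <= max_0of3
}

# Random cumulative within-band triple at total n.
random_cumulative_triple <- function(n = 99) {
  sort(sample(0:n, 3, replace = TRUE))
}
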