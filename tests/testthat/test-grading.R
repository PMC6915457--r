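test_that("band counts are cumulative with inclusive cutoffs", {
  d <- make_differences(c(0, 5, 10, 15, 16))
  bc <- band_counts(d, band_thresholds())
  expect_identical(bc$within, c(2L, 3L, 4L))
  expect_identical(bc$n, 5L)

  empty <- make_differences(numeric(0))
  bc0 <- band_counts(empty)
  expect_identical(bc0$within, c(0L, 0L, 0L))
  expect_identical(bc0$n, 0L)
})

test_that("band counts match a brute-force recount on noisy draws", {
  set.seed(20)
  draws <- round(stats::rnorm(99, 0, 4.4))
  bc <- band_counts(make_differences(draws))
  recount <- vapply(c(5, 10, 15), function(k) {
    total <- 0L
    for (x in draws) if (abs(x) <= k) total <- total + 1L
    total
  }, integer(1))
  expect_identical(bc$within, recount)
})

test_that("mixed parameters are rejected by band_counts", {
  d <- dplyr::bind_rows(make_differences(1, "sbp"), make_differences(1, "dbp"))
  expect_error(band_counts(d), "single parameter")
})

test_that("part 1 reproduces the published pass/fail decisions", {
  expect_true(grade_part1(band_counts_from_totals(c(81, 92, 96)))$pass)  # SBP
  expect_true(grade_part1(band_counts_from_totals(c(85, 95, 95)))$pass)  # DBP
  expect_true(grade_part1(band_counts_from_totals(c(85, 94, 95)))$pass)  # HR
  # all_of violated in the first band
  expect_false(grade_part1(band_counts_from_totals(c(64, 99, 99)))$pass)
  # third band below its all_of requirement of 93
  expect_false(grade_part1(band_counts_from_totals(c(73, 87, 92)))$pass)
})

test_that("part 1 rejects a comparison-count mismatch, naming 99", {
  bc <- band_counts(make_differences(rep(0, 30)))
  expect_error(grade_part1(bc), "99")
})

test_that("part 2 reproduces the published pass/fail decisions", {
  expect_true(grade_part2(make_profiles_from_tallies(29, 2))$pass)   # SBP
  expect_true(grade_part2(make_profiles_from_tallies(30, 0))$pass)   # DBP
  expect_true(grade_part2(make_profiles_from_tallies(29, 1))$pass)   # HR
  expect_false(grade_part2(make_profiles_from_tallies(23, 0))$pass)  # < 24
  expect_false(grade_part2(make_profiles_from_tallies(24, 4))$pass)  # > 3
  expect_error(grade_part2(make_profiles_from_tallies(20, 0, n_subjects = 30)),
               "33")
})

test_that("part 3 is the conjunction of its parts", {
  pass <- grade_part1(band_counts_from_totals(c(81, 92, 96)))
  fail <- grade_part1(band_counts_from_totals(c(60, 70, 80)))
  p2 <- grade_part2(make_profiles_from_tallies(29, 2))
  expect_true(grade_part3(pass, p2, pass, p2)$pass)
  expect_true(grade_part3(pass, p2)$pass)
  expect_false(grade_part3(pass, p2, fail, p2)$pass)
  expect_false(grade_part3(list(pass, pass, fail))$pass)
})

test_that("part 1 grading agrees with the truth-table oracle on random triples", {
  set.seed(101)
  for (i in 1:2000) {
    w <- random_cumulative_triple(99)
    got <- grade_part1(band_counts_from_totals(w))$pass
    expect_identical(got, oracle_part1(w), info = paste(w, collapse = ","))
  }
})

test_that("increasing a within-band count never flips part 1 pass to fail", {
  set.seed(77)
  for (i in 1:500) {
    w <- random_cumulative_triple(99)
    if (!grade_part1(band_counts_from_totals(w))$pass) next
    j <- sample(1:3, 1)
    w2 <- w
    w2[j] <- min(99L, w2[j] + sample(1:5, 1))
    w2 <- cummax(w2)  # keep cumulativity
    expect_true(grade_part1(band_counts_from_totals(w2))$pass)
  }
})

test_that("improving subject tallies never flips part 2 pass to fail", {
  set.seed(78)
  for (i in 1:500) {
    a <- sample(0:33, 1)
    b <- sample(0:(33 - a), 1)
    if (!oracle_part2(a, b)) next
    expect_true(grade_part2(make_profiles_from_tallies(a, b))$pass)
    a2 <- min(33L, a + 1L)
    b2 <- max(0L, b - 1L)
    if (a2 + b2 <= 33) {
      expect_true(grade_part2(make_profiles_from_tallies(a2, b2))$pass)
    }
  }
})

test_that("heart-rate grading reuses the identical machinery with bpm cutoffs", {
  # the same within-band structure graded under either unit label is identical
  d_hr <- make_differences(c(rep(0, 85), rep(4, 9), rep(7, 1), rep(20, 4)), "hr")
  bc <- band_counts(d_hr, hr_band_thresholds())
  expect_identical(bc$within, c(85L, 94L, 95L))
  g <- grade_part1(bc)
  expect_true(g$pass)
  expect_identical(g$detail$units[1], "bpm")
  # same counts under BP labels grade identically
  d_bp <- make_differences(c(rep(0, 85), rep(8, 9), rep(12, 1), rep(40, 4)), "sbp")
  expect_identical(grade_part1(band_counts(d_bp, band_thresholds()))$pass, g$pass)
})

test_that("grade_device on an identity device passes everything with full counts", {
  study <- simulate_study(physiology = physiology_model(within_sd = 0), seed = 2)
  v <- grade_device(study$measurements, study$roster)
  for (p in c("sbp", "dbp", "hr")) {
    expect_identical(v$parameters[[p]]$band_counts$within, rep(99L, 3))
    expect_true(v$parameters[[p]]$part1$pass)
    expect_true(v$parameters[[p]]$part2$pass)
    expect_true(all(v$parameters[[p]]$profiles$n_within_first_band == 3L))
  }
  expect_true(v$bp_part3$pass)
  expect_true(v$hr_part3$pass)
  expect_true(v$screening$cohort_pass)
})

test_that("a +20 mm Hg systolic bias fails Part 1 for SBP", {
  study <- simulate_study(test_device = device_error_model(bias = c(sbp = 20)),
                          physiology = physiology_model(within_sd = 0),
                          seed = 2)
  v <- grade_device(study$measurements)
  expect_false(v$parameters$sbp$part1$pass)
  expect_identical(v$parameters$sbp$band_counts$within, rep(0L, 3))
  expect_true(v$parameters$dbp$part1$pass)
})

test_that("grading is deterministic for identical input", {
  study <- simulate_study(seed = 13)
  v1 <- grade_device(study$measurements, study$roster)
  v2 <- grade_device(study$measurements, study$roster)
  expect_identical(validation_report(v1), validation_report(v2))
})

test_that("non-protocol cohort sizes warn and scale the requirements", {
  m <- make_study_measurements(11)
  expect_warning(v <- grade_device(m), "33")
  expect_identical(v$parameters$sbp$part1$detail$within, rep(33L, 3))
  expect_true(v$bp_part3$pass)
})
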