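test_that("candidate pairs use the flanking reference slots, never BPA/BPB", {
  m <- make_sequence()
  cp <- candidate_pairs(m, "sbp")
  expect_identical(nrow(cp), 3L)
  expect_identical(cp$test_slot, c("BP2", "BP4", "BP6"))
  # the second comparison tests BP4 against BP3 and BP5
  m2 <- make_sequence(values = list(BP4 = c(130, 80, 70),
                                    BP3 = c(124, 80, 70),
                                    BP5 = c(140, 80, 70)))
  cp2 <- candidate_pairs(m2, "sbp")
  expect_identical(cp2$test_value[2], 130)
  expect_identical(cp2$preceding_value[2], 124)
  expect_identical(cp2$following_value[2], 140)
  # entry readings never appear even with extreme values
  m3 <- make_sequence(values = list(BPA = c(250, 150, 200),
                                    BPB = c(251, 151, 201)))
  d <- all_differences(m3, "sbp")
  expect_true(all(d$signed_difference == 0))
})

test_that("favorable selection keeps the smaller absolute difference, ties to preceding", {
  cand <- tibble::tibble(subject_id = "S001", comparison_index = 1L,
                         test_slot = "BP2",
                         test_value = c(120, 120, 80),
                         preceding_value = c(118, 122, 70),
                         following_value = c(125, 118, 79))
  sel <- select_favorable(cand, "sbp")
  # test 120 vs 118/125 -> preceding, +2
  expect_identical(sel$flank[1], "preceding")
  expect_identical(sel$signed_difference[1], 2)
  # tie |120-122| = |120-118| = 2 -> preceding
  expect_identical(sel$flank[2], "preceding")
  expect_identical(sel$signed_difference[2], -2)
  # test 80 vs 70/79 -> following, +1
  expect_identical(sel$flank[3], "following")
  expect_identical(sel$signed_difference[3], 1)
})

test_that("selected absolute difference never exceeds either candidate (exhaustive grid)", {
  grid <- expand.grid(test = 95:105, prec = 95:105, foll = 95:105)
  cand <- tibble::tibble(subject_id = "S001", comparison_index = 1L,
                         test_slot = "BP2",
                         test_value = grid$test,
                         preceding_value = grid$prec,
                         following_value = grid$foll)
  sel <- select_favorable(cand, "sbp")
  oracle <- pmin(abs(grid$test - grid$prec), abs(grid$test - grid$foll))
  expect_identical(sel$abs_difference, oracle)
  # chosen flank's value matches the recorded reference
  expect_identical(sel$reference_value,
                   ifelse(sel$flank == "preceding", grid$prec, grid$foll))
})

test_that("study-level pairing yields 3 differences per subject in stable order", {
  m <- make_study_measurements(33)
  d <- all_differences(m)
  expect_identical(as.integer(table(d$parameter)[c("sbp", "dbp", "hr")]),
                   rep(99L, 3))
  sbp <- d[d$parameter == "sbp", ]
  expect_identical(sbp$subject_id, rep(sprintf("S%03d", 1:33), each = 3))
  expect_identical(sbp$comparison_index, rep(1:3, 33))

  one <- all_differences(make_sequence(), "dbp")
  expect_identical(nrow(one), 3L)
})

test_that("identical test and reference readings give zero differences", {
  study <- simulate_study(physiology = physiology_model(within_sd = 0),
                          seed = 4)
  d <- all_differences(study$measurements)
  expect_true(all(d$signed_difference == 0))
  expect_true(all(d$abs_difference == 0))
})

test_that("flank choice is independent per parameter", {
  m <- make_sequence(values = list(
    BP1 = c(118, 80, 60), BP2 = c(120, 80, 72),
    BP3 = c(125, 80, 71), BP4 = c(120, 80, 70),
    BP5 = c(122, 80, 70), BP6 = c(120, 80, 70),
    BP7 = c(121, 80, 70)
  ))
  d <- all_differences(m)
  sbp_flanks <- d$flank[d$parameter == "sbp"]
  # permuting HR readings must not change SBP flank choices
  m2 <- m
  m2$hr <- rev(m2$hr)
  d2 <- all_differences(m2)
  expect_identical(d2$flank[d2$parameter == "sbp"], sbp_flanks)
})

test_that("joint mode forces SBP and DBP onto one flank by summed distance", {
  # SBP alone prefers the preceding flank, DBP strongly prefers following;
  # jointly the following flank wins on summed absolute difference.
  m <- make_sequence(values = list(
    BP1 = c(119, 90, 70), BP2 = c(120, 80, 70), BP3 = c(122, 80, 70)
  ))
  ind <- all_differences(m, selection_mode = "independent")
  expect_identical(ind$flank[ind$parameter == "sbp"][1], "preceding")
  expect_identical(ind$flank[ind$parameter == "dbp"][1], "following")

  joint <- all_differences(m, selection_mode = "joint")
  expect_identical(joint$flank[joint$parameter == "sbp"][1], "following")
  expect_identical(joint$flank[joint$parameter == "dbp"][1], "following")
  # HR keeps independent selection in joint mode
  expect_identical(joint$flank[joint$parameter == "hr"],
                   ind$flank[ind$parameter == "hr"])
})

test_that("malformed records are rejected with a reference to validation", {
  m <- make_sequence()
  expect_error(all_differences(m[m$slot != "BP5", ]), "validation")
  expect_error(candidate_pairs(m[m$slot != "BP1", ], "sbp"), "BP1")
})
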