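test_that("simulated cohorts have the configured deterministic sex split", {
  roster <- simulate_cohort(cohort_model(), seed = 1)
  expect_identical(nrow(roster), 33L)
  expect_identical(sum(roster$sex == "male"), 18L)
  expect_identical(sum(roster$sex == "female"), 15L)
  expect_identical(roster, simulate_cohort(cohort_model(), seed = 1))
  expect_false(identical(roster, simulate_cohort(cohort_model(), seed = 2)))
})

test_that("cohort draws respect bounds and recover the truncated-normal mean", {
  big <- cohort_model(n_male = 500L, n_female = 500L)
  roster <- simulate_cohort(big, seed = 3)
  traits <- default_cohort_traits()
  # closed-form truncated normal mean as the independent oracle
  trunc_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
  }
  cols <- c(age = "age", weight = "weight_kg", height = "height_cm",
            arm_circumference = "arm_circumference_mm")
  for (i in seq_len(nrow(traits))) {
    tr <- traits[i, ]
    x <- roster[[cols[[tr$trait]]]][roster$sex == tr$sex]
    expect_true(all(x >= tr$min - 0.5 & x <= tr$max + 0.5))
    expected <- trunc_mean(tr$mean, tr$sd, tr$min, tr$max)
    expect_lt(abs(mean(x) - expected), 4 * tr$sd / sqrt(length(x)))
  }
})

test_that("BMI is derived from weight and height, not drawn", {
  roster <- simulate_cohort(seed = 6)
  expect_true(all(abs(roster$bmi -
                        roster$weight_kg / (roster$height_cm / 100)^2) < 0.5))
})

test_that("infeasible truncation bounds are rejected", {
  traits <- default_cohort_traits()
  traits$min[traits$trait == "age"] <- 300
  traits$max[traits$trait == "age"] <- 310
  expect_error(simulate_cohort(cohort_model(traits = traits), seed = 1),
               "infeasible")
  expect_error(cohort_model(traits = dplyr::mutate(default_cohort_traits(),
                                                   min = max + 1)),
               "min < max")
})

test_that("sequence simulation is exact in the deterministic regimes", {
  truth <- list(sbp = rep(130, 9), dbp = rep(75, 9), hr = rep(70, 9))
  # zero error, zero variability: all slots identical, all differences zero
  s <- simulate_sequence(truth, seed = 1)
  expect_true(all(s$sbp == 130L))
  expect_true(all(s$dbp == 75L))
  expect_true(all(s$hr == 70L))
  d <- all_differences(s)
  expect_true(all(d$signed_difference == 0))
  # constant +20 mm Hg systolic test bias: every SBP difference is 20
  s2 <- simulate_sequence(truth, test_device = device_error_model(bias = c(sbp = 20)),
                          seed = 1)
  d2 <- all_differences(s2, "sbp")
  expect_true(all(d2$signed_difference == 20))
  # fixed seed reruns bitwise-identically
  s3 <- simulate_sequence(truth, test_device = device_error_model(noise_sd = 2),
                          seed = 99)
  s4 <- simulate_sequence(truth, test_device = device_error_model(noise_sd = 2),
                          seed = 99)
  expect_identical(s3, s4)
})

test_that("unreachable physiologic readings are rejected after bounded retries", {
  truth <- list(sbp = rep(130, 9), dbp = rep(75, 9), hr = rep(70, 9))
  broken <- device_error_model(bias = c(sbp = 400))
  expect_error(simulate_sequence(truth, test_device = broken, seed = 1),
               "physiologic")
})

test_that("simulated studies are valid, reproducible and gradeable", {
  for (seed in c(1, 17, 123)) {
    study <- simulate_study(seed = seed)
    expect_identical(nrow(validate_sequences(study$measurements)), 0L)
    expect_identical(nrow(study$measurements), 33L * 9L)
  }
  a <- simulate_study(seed = 5)
  b <- simulate_study(seed = 5)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$roster, b$roster)
  expect_identical(validation_report(grade_device(a$measurements)),
                   validation_report(grade_device(b$measurements)))
})

test_that("appending subjects never perturbs earlier subjects' draws", {
  base <- simulate_study(cohort = cohort_model(n_male = 18, n_female = 15),
                         seed = 21)
  bigger <- simulate_study(cohort = cohort_model(n_male = 18, n_female = 17),
                           seed = 21)
  first33 <- bigger$measurements[bigger$measurements$subject_id %in%
                                   base$roster$subject_id, ]
  expect_identical(as.data.frame(first33), as.data.frame(base$measurements))
})

test_that("the mean signed difference recovers the configured bias", {
  # no within-subject variability, no reference error: the favorable
  # selection is inert and the mean difference estimates the test bias
  study <- simulate_study(
    cohort = cohort_model(n_male = 167, n_female = 167),
    physiology = physiology_model(within_sd = 0),
    test_device = device_error_model(bias = c(sbp = 4), noise_sd = c(sbp = 3)),
    seed = 31
  )
  d <- all_differences(study$measurements, "sbp")
  se <- 3 / sqrt(nrow(d))
  # integer display rounding adds variance ~1/12 per reading
  expect_lt(abs(mean(d$signed_difference) - 4), 3 * sqrt(se^2 + 1 / 12 / nrow(d)) + 0.02)
})

test_that("pass probabilities hit the deterministic extremes with exact CIs", {
  phys0 <- physiology_model(within_sd = 0)
  pp <- pass_probability(physiology = phys0, n_replicates = 10, seed = 2)
  expect_true(all(pp$probability == 1))
  expect_true(all(pp$ci_lower <= 1 & pp$ci_upper == 1))

  biased <- device_error_model(bias = c(sbp = 20))
  pp2 <- pass_probability(physiology = phys0, test_device = biased,
                          n_replicates = 10, seed = 2)
  expect_identical(pp2$probability[pp2$part == "sbp_part1"], 0)
  expect_identical(pp2$probability[pp2$part == "bp_part3"], 0)
  expect_identical(pp2$probability[pp2$part == "dbp_part1"], 1)
  # exact binomial CI matches stats::binom.test
  k <- pp2$passes[pp2$part == "hr_part1"]
  ci <- stats::binom.test(k, 10)$conf.int
  expect_equal(pp2$ci_lower[pp2$part == "hr_part1"], ci[1])
  expect_equal(pp2$ci_upper[pp2$part == "hr_part1"], ci[2])
})
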