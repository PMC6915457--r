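#' Synthetic cohorts and nine-reading sequences
#'
#' The generator emulates the study conditions end to end: a 33-subject
#' cohort (18 male / 15 female) with the published demographic structure,
#' subject-level true blood pressure and heart rate, reading-to-reading
#' variability over the nine-slot schedule, and independent reference- and
#' test-device error models (additive bias, proportional bias, measurement
#' noise, integer display rounding). Random streams are split per subject,
#' so adding a subject never perturbs earlier subjects' draws.
#'
#' @name synthetic
NULL

#' Cohort demographic model
#'
#' Per-sex truncated-normal distributions for age, weight, height and arm
#' circumference. Defaults reproduce the study cohort's summary statistics
#' (means, SDs and observed ranges per sex); BMI is derived from weight and
#' height, never drawn.
#'
#' @param n_male,n_female Subjects per sex (defaults 18 and 15).
#' @param traits Tibble with columns `sex`, `trait`, `mean`, `sd`, `min`,
#'   `max`.
#' @param prob_left_arm Probability a subject is measured on the left arm
#'   (default 3/33, the study's rate of right-arm contraindications).
#' @return List of class `cohort_model`.
#' @export
cohort_model <- function(n_male = 18L, n_female = 15L,
                         traits = default_cohort_traits(),
                         prob_left_arm = 3 / 33) {
  stopifnot(n_male >= 0, n_female >= 0, n_male + n_female > 0)
  needed <- c("sex", "trait", "mean", "sd", "min", "max")
  stopifnot(all(needed %in% names(traits)))
  if (any(traits$min >= traits$max) || any(traits$sd < 0)) {
    stop("trait bounds must satisfy min < max and sd >= 0", call. = FALSE)
  }
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 traits = traits, prob_left_arm = prob_left_arm),
            class = "cohort_model")
}

#' @rdname cohort_model
#' @export
default_cohort_traits <- function() {
  tibble::tribble(
    ~sex,     ~trait,              ~mean,  ~sd,    ~min,  ~max,
    "male",   "age",                70.11, 11.11,  45.0,  90.0,
    "male",   "weight",             70.33, 13.66,  46.5, 100.0,
    "male",   "height",            166.61,  5.63, 155.0, 180.0,
    "male",   "arm_circumference", 262.50, 24.15, 220.0, 310.0,
    "female", "age",                72.13, 11.69,  48.0,  91.0,
    "female", "weight",             71.15, 18.31,  46.8, 101.0,
    "female", "height",            157.13, 10.77, 141.0, 174.0,
    "female", "arm_circumference", 273.00, 38.06, 215.0, 350.0
  )
}

#' Physiology model for true blood pressure and heart rate
#'
#' Subject-level true values are drawn from between-subject normal
#' distributions, with DBP correlated with SBP and constrained below it by
#' at least `min_pulse_pressure`. Within a subject, each of the nine reading
#' epochs gets independent jitter (30-60 s spacing) plus an optional linear
#' drift. The cohort-level BP/HR distributions are working defaults — the
#' study reports no BP or HR level distributions — chosen as typical of an
#' elderly hemodialysis population.
#'
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd,hr_mean,hr_sd Between-subject
#'   distributions (mm Hg, bpm).
#' @param dbp_sbp_cor Correlation between subject-level SBP and DBP.
#' @param within_sd Named vector of within-subject reading-to-reading SDs.
#' @param drift Named vector of per-epoch linear drift (units per reading).
#' @param min_pulse_pressure Minimum SBP - DBP for a true state (mm Hg).
#' @return List of class `physiology_model`.
#' @export
physiology_model <- function(sbp_mean = 135, sbp_sd = 20,
                             dbp_mean = 75, dbp_sd = 12,
                             dbp_sbp_cor = 0.6,
                             hr_mean = 72, hr_sd = 10,
                             within_sd = c(sbp = 4, dbp = 3, hr = 3),
                             drift = c(sbp = 0, dbp = 0, hr = 0),
                             min_pulse_pressure = 10) {
  within_sd <- fill_params(within_sd, 0)
  drift <- fill_params(drift, 0)
  stopifnot(all(within_sd >= 0), sbp_sd >= 0, dbp_sd >= 0, hr_sd >= 0,
            abs(dbp_sbp_cor) <= 1)
  structure(list(sbp_mean = sbp_mean, sbp_sd = sbp_sd,
                 dbp_mean = dbp_mean, dbp_sd = dbp_sd,
                 dbp_sbp_cor = dbp_sbp_cor,
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 within_sd = within_sd, drift = drift,
                 min_pulse_pressure = min_pulse_pressure),
            class = "physiology_model")
}

#' Device error model
#'
#' Observed reading = true value + bias + proportional * true value +
#' N(0, noise_sd), rounded to the integer the device displays. Reference and
#' test devices carry independent models; the default is an error-free
#' device.
#'
#' @param bias,proportional,noise_sd Named vectors over `sbp`, `dbp`, `hr`
#'   (unnamed scalars recycle to all three; missing names default to 0).
#' @return List of class `device_error_model`.
#' @examples
#' device_error_model(bias = c(sbp = 4, dbp = 2.4, hr = 1.9),
#'                    noise_sd = c(sbp = 3, dbp = 3, hr = 2))
#' @export
device_error_model <- function(bias = 0, proportional = 0, noise_sd = 0) {
  noise_sd <- fill_params(noise_sd, 0)
  stopifnot(all(noise_sd >= 0))
  structure(list(bias = fill_params(bias, 0),
                 proportional = fill_params(proportional, 0),
                 noise_sd = noise_sd),
            class = "device_error_model")
}

# Expand a scalar or partially named vector into a full (sbp, dbp, hr) vector.
fill_params <- function(x, default) {
  out <- c(sbp = default, dbp = default, hr = default)
  if (is.null(names(x)) || all(names(x) == "")) {
    stopifnot(length(x) %in% c(1L, 3L))
    out[] <- x
  } else {
    stopifnot(all(names(x) %in% names(out)))
    out[names(x)] <- x
  }
  out
}

# Deterministic per-subject, per-stream sub-seed from the master seed, so
# subject i's draws depend only on (seed, i) and never on other subjects.
subject_seed <- function(seed, i, stream) {
  stream_id <- match(stream, c("cohort", "sequence"))
  as.integer((as.double(seed) %% 1e6 * 4099 + i * 179 + stream_id * 7919) %%
               2147483629)
}

rnorm_truncated <- function(n, mean, sd, min, max, max_tries = 1000L,
                            what = "value") {
  if (sd == 0) {
    if (mean < min || mean > max) {
      stop("infeasible truncation bounds for ", what, call. = FALSE)
    }
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (j in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::rnorm(1, mean, sd)
      if (x >= min && x <= max) { out[j] <- x; ok <- TRUE; break }
    }
    if (!ok) stop("infeasible truncation bounds for ", what, call. = FALSE)
  }
  out
}

#' Simulate a subject roster
#'
#' Sex is allocated deterministically (exactly `n_male` then `n_female`
#' subjects); demographics are truncated-normal draws from the cohort model.
#' Reproducible given the seed.
#'
#' @param model A [cohort_model()].
#' @param seed Integer seed.
#' @return Roster tibble: `subject_id`, `sex`, `age`, `height_cm`,
#'   `weight_kg`, `bmi`, `arm_circumference_mm`, `arm`, `flags`.
#' @export
simulate_cohort <- function(model = cohort_model(), seed = 1L) {
  n <- model$n_male + model$n_female
  sexes <- rep(c("male", "female"), c(model$n_male, model$n_female))
  ids <- sprintf("S%03d", seq_len(n))
  age <- weight <- height <- arm_c <- numeric(n)
  arm <- character(n)
  for (i in seq_len(n)) {
    set.seed(subject_seed(seed, i, "cohort"))
    tr <- model$traits[model$traits$sex == sexes[i], , drop = FALSE]
    draw <- function(trait) {
      r <- tr[tr$trait == trait, , drop = FALSE]
      if (nrow(r) != 1) stop("cohort model lacks trait '", trait, "' for sex ",
                             sexes[i], call. = FALSE)
      rnorm_truncated(1, r$mean, r$sd, r$min, r$max, what = trait)
    }
    age[i] <- draw("age"); weight[i] <- draw("weight")
    height[i] <- draw("height"); arm_c[i] <- draw("arm_circumference")
    arm[i] <- if (stats::runif(1) < model$prob_left_arm) "left" else "right"
  }
  tibble::tibble(
    subject_id = ids, sex = sexes,
    age = round(age, 1), height_cm = round(height, 1),
    weight_kg = round(weight, 1),
    bmi = round(weight / (height / 100)^2, 2),
    arm_circumference_mm = round(arm_c),
    arm = arm, flags = ""
  )
}

# True (sbp, dbp, hr) state for the nine epochs of one subject, as a plain
# list of numeric vectors. Assumes the RNG has been seeded by the caller.
simulate_truth <- function(physiology, n_epochs = 9L, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
    sbp0 <- physiology$sbp_mean + physiology$sbp_sd * z1
    rho <- physiology$dbp_sbp_cor
    dbp0 <- physiology$dbp_mean +
      physiology$dbp_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    if (sbp0 - dbp0 >= physiology$min_pulse_pressure &&
        sbp0 >= 60 && sbp0 <= 280 && dbp0 >= 30 && dbp0 <= 180) break
    if (try == max_tries) stop("could not draw a valid subject BP state",
                               call. = FALSE)
  }
  hr0 <- rnorm_truncated(1, physiology$hr_mean, physiology$hr_sd, 25, 240,
                         what = "heart rate")
  epoch <- seq_len(n_epochs) - 1L
  truth <- list(
    sbp = sbp0 + physiology$drift[["sbp"]] * epoch +
      stats::rnorm(n_epochs, 0, physiology$within_sd[["sbp"]]),
    dbp = dbp0 + physiology$drift[["dbp"]] * epoch +
      stats::rnorm(n_epochs, 0, physiology$within_sd[["dbp"]]),
    hr = hr0 + physiology$drift[["hr"]] * epoch +
      stats::rnorm(n_epochs, 0, physiology$within_sd[["hr"]])
  )
  # Reading-to-reading jitter must not produce an unphysiologic true state:
  # keep each epoch's true SBP at least 2 mm Hg above DBP (so integer
  # display rounding can never invert them) and inside the plausible ranges.
  bad_epochs <- function(tr) {
    which(tr$sbp - tr$dbp < 2 |
            tr$sbp < 42 | tr$sbp > 298 | tr$dbp < 22 | tr$dbp > 198 |
            tr$hr < 22 | tr$hr > 248)
  }
  for (try in seq_len(max_tries)) {
    bad <- bad_epochs(truth)
    if (length(bad) == 0) return(truth)
    truth$sbp[bad] <- sbp0 + physiology$drift[["sbp"]] * epoch[bad] +
      stats::rnorm(length(bad), 0, physiology$within_sd[["sbp"]])
    truth$dbp[bad] <- dbp0 + physiology$drift[["dbp"]] * epoch[bad] +
      stats::rnorm(length(bad), 0, physiology$within_sd[["dbp"]])
    truth$hr[bad] <- hr0 + physiology$drift[["hr"]] * epoch[bad] +
      stats::rnorm(length(bad), 0, physiology$within_sd[["hr"]])
  }
  stop("could not draw a physiologic reading-to-reading trajectory",
       call. = FALSE)
}

# Observe one subject's nine slots as a 9 x 3 integer matrix (sbp, dbp, hr).
# Draws are vectorized per parameter; only slots violating physiologic
# constraints are re-drawn, so the bulk of the random stream is reproducible
# draw-for-draw across device-model variants (common random numbers).
observe_sequence <- function(truth, reference_device, test_device,
                             max_tries = 100L) {
  roles <- slot_role(SLOT_LABELS)
  is_ref <- roles == "reference"
  field <- function(what, p) {
    ifelse(is_ref, reference_device[[what]][[p]], test_device[[what]][[p]])
  }
  draw_param <- function(p, idx = seq_along(SLOT_LABELS)) {
    true <- truth[[p]][idx]
    round(true + field("bias", p)[idx] + field("proportional", p)[idx] * true +
            stats::rnorm(length(idx), 0, field("noise_sd", p)[idx]))
  }
  obs <- vapply(PARAMETERS, draw_param, numeric(length(SLOT_LABELS)))
  bad_slots <- function(o) {
    which(!(o[, "sbp"] >= READING_RANGES$sbp[1] & o[, "sbp"] <= READING_RANGES$sbp[2] &
            o[, "dbp"] >= READING_RANGES$dbp[1] & o[, "dbp"] <= READING_RANGES$dbp[2] &
            o[, "hr"] >= READING_RANGES$hr[1] & o[, "hr"] <= READING_RANGES$hr[2] &
            o[, "sbp"] > o[, "dbp"]))
  }
  for (try in seq_len(max_tries)) {
    bad <- bad_slots(obs)
    if (length(bad) == 0) return(obs)
    for (p in PARAMETERS) obs[bad, p] <- draw_param(p, bad)
  }
  stop("could not generate physiologic readings for slot(s) ",
       paste(SLOT_LABELS[bad_slots(obs)], collapse = ", "),
       " after ", max_tries, " attempts", call. = FALSE)
}

#' Simulate one nine-reading sequence from true values
#'
#' Applies the role-appropriate device error model to each epoch's true
#' state and rounds to the integers the devices display. Readings falling
#' outside physiologic ranges (or with SBP not above DBP) are resampled a
#' bounded number of times, then rejected.
#'
#' @param truth List or tibble with length-9 components `sbp`, `dbp`, `hr`
#'   (true values per epoch, slot order BPA, BPB, BP1..BP7).
#' @param reference_device,test_device [device_error_model()] objects.
#' @param subject_id Identifier written into the output.
#' @param seed Optional integer seed (omit when the caller manages the RNG
#'   stream).
#' @param max_tries Resampling cap per reading.
#' @return Long-format tibble of 9 rows: `subject_id`, `slot`, `role`,
#'   `sbp`, `dbp`, `hr`.
#' @export
simulate_sequence <- function(truth,
                              reference_device = device_error_model(),
                              test_device = device_error_model(),
                              subject_id = "S001", seed = NULL,
                              max_tries = 100L) {
  stopifnot(length(truth$sbp) == 9L, length(truth$dbp) == 9L,
            length(truth$hr) == 9L)
  if (!is.null(seed)) set.seed(seed)
  obs <- observe_sequence(truth, reference_device, test_device, max_tries)
  tibble::tibble(subject_id = subject_id, slot = SLOT_LABELS,
                 role = slot_role(SLOT_LABELS),
                 sbp = as.integer(obs[, "sbp"]), dbp = as.integer(obs[, "dbp"]),
                 hr = as.integer(obs[, "hr"]))
}

#' Simulate a complete validation study
#'
#' Draws a roster from the cohort model and one nine-reading sequence per
#' subject, using independent per-subject random streams derived from the
#' master seed. The result feeds directly into [grade_device()].
#'
#' @param cohort A [cohort_model()].
#' @param physiology A [physiology_model()].
#' @param reference_device,test_device [device_error_model()] objects.
#' @param seed Master integer seed.
#' @return List of class `esh_study`: `measurements` (long tibble),
#'   `roster`, and the `seed` used.
#' @examples
#' study <- simulate_study(seed = 7)
#' grade_device(study$measurements)$bp_part3$pass  # error-free device: TRUE
#' @export
simulate_study <- function(cohort = cohort_model(),
                           physiology = physiology_model(),
                           reference_device = device_error_model(),
                           test_device = device_error_model(),
                           seed = 1L) {
  roster <- simulate_cohort(cohort, seed = seed)
  n <- nrow(roster)
  obs <- matrix(0, n * 9L, 3L, dimnames = list(NULL, PARAMETERS))
  for (i in seq_len(n)) {
    set.seed(subject_seed(seed, i, "sequence"))
    truth <- simulate_truth(physiology)
    obs[(i - 1L) * 9L + 1:9, ] <- observe_sequence(truth, reference_device,
                                                   test_device)
  }
  measurements <- tibble::tibble(
    subject_id = rep(roster$subject_id, each = 9L),
    slot = rep(SLOT_LABELS, n),
    role = rep(slot_role(SLOT_LABELS), n),
    sbp = as.integer(obs[, "sbp"]), dbp = as.integer(obs[, "dbp"]),
    hr = as.integer(obs[, "hr"])
  )
  structure(list(measurements = measurements, roster = roster,
                 seed = as.integer(seed)),
            class = "esh_study")
}

#' Monte-Carlo pass probability of the protocol
#'
#' Replicates [simulate_study()] + [grade_device()] and reports the fraction
#' of replicates passing each part, with exact (Clopper-Pearson) binomial
#' confidence intervals. Replicate r uses a seed derived deterministically
#' from `seed` and r, so two calls with the same seed share random numbers
#' replicate-for-replicate — convenient for comparing device models with
#' common random numbers.
#'
#' @inheritParams simulate_study
#' @param n_replicates Number of simulated studies.
#' @param config Grading configuration.
#' @param conf_level Confidence level for the binomial intervals.
#' @return Tibble: `part`, `passes`, `n_replicates`, `probability`,
#'   `ci_lower`, `ci_upper`.
#' @export
pass_probability <- function(cohort = cohort_model(),
                             physiology = physiology_model(),
                             reference_device = device_error_model(),
                             test_device = device_error_model(),
                             n_replicates = 100L, seed = 1L,
                             config = validation_config(),
                             conf_level = 0.95) {
  stopifnot(n_replicates >= 1)
  parts <- c("sbp_part1", "dbp_part1", "hr_part1",
             "sbp_part2", "dbp_part2", "hr_part2",
             "bp_part3", "hr_part3", "all_parts")
  passes <- stats::setNames(integer(length(parts)), parts)
  for (r in seq_len(n_replicates)) {
    rep_seed <- as.integer((as.double(seed) * 1009 + r * 65537) %% 2147483629)
    study <- simulate_study(cohort, physiology, reference_device, test_device,
                            seed = rep_seed)
    v <- grade_device(study$measurements, config = config)
    res <- c(sbp_part1 = v$parameters$sbp$part1$pass,
             dbp_part1 = v$parameters$dbp$part1$pass,
             hr_part1 = v$parameters$hr$part1$pass,
             sbp_part2 = v$parameters$sbp$part2$pass,
             dbp_part2 = v$parameters$dbp$part2$pass,
             hr_part2 = v$parameters$hr$part2$pass,
             bp_part3 = v$bp_part3$pass,
             hr_part3 = v$hr_part3$pass)
    res <- c(res, all_parts = unname(res[["bp_part3"]] && res[["hr_part3"]]))
    passes <- passes + res[parts]
  }
  ci <- t(vapply(passes, function(k) {
    as.numeric(stats::binom.test(k, n_replicates,
                                 conf.level = conf_level)$conf.int)
  }, numeric(2)))
  tibble::tibble(part = parts, passes = unname(passes),
                 n_replicates = as.integer(n_replicates),
                 probability = unname(passes) / n_replicates,
                 ci_lower = unname(ci[, 1]), ci_upper = unname(ci[, 2]))
}
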