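#' Bland-Altman agreement summaries
#'
#' Signed differences are test minus reference; the mean signed difference
#' is the device bias and the limits of agreement are bias +/- 1.96 SD
#' (sample SD, n - 1 denominator). The mean absolute difference is reported
#' alongside because validation reports are sometimes read either way.
#'
#' @name agreement
NULL

#' Summarise paired differences
#'
#' @param differences Non-empty single-parameter paired differences (see
#'   [all_differences()]).
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96).
#' @return List of class `agreement_summary`: `parameter`, `n`,
#'   `mean_signed_difference`, `sd_signed_difference`,
#'   `mean_absolute_difference`, `loa_lower`, `loa_upper`.
#' @examples
#' d <- tibble::tibble(parameter = "sbp", signed_difference = c(-1, 1),
#'                     abs_difference = c(1, 1))
#' difference_summary(d)$sd_signed_difference  # sqrt(2)
#' @export
difference_summary <- function(differences, loa_multiplier = 1.96) {
  if (nrow(differences) == 0) {
    stop("cannot summarise an empty set of differences", call. = FALSE)
  }
  if (length(unique(differences$parameter)) > 1) {
    stop("difference_summary expects a single parameter", call. = FALSE)
  }
  d <- differences$signed_difference
  m <- mean(d)
  s <- stats::sd(d)
  if (is.na(s)) s <- 0  # single observation
  structure(list(
    parameter = differences$parameter[1],
    n = length(d),
    mean_signed_difference = m,
    sd_signed_difference = s,
    mean_absolute_difference = mean(differences$abs_difference),
    loa_lower = m - loa_multiplier * s,
    loa_upper = m + loa_multiplier * s,
    loa_multiplier = loa_multiplier
  ), class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("%s: bias %.2f (SD %.2f), |diff| mean %.2f, LoA [%.2f, %.2f] (n = %d)\n",
              toupper(x$parameter), x$mean_signed_difference,
              x$sd_signed_difference, x$mean_absolute_difference,
              x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' Bland-Altman points and summary
#'
#' One point per paired difference: abscissa the mean of test and reference
#' values, ordinate the signed difference, with the bias and limits of
#' agreement from [difference_summary()].
#'
#' @inheritParams difference_summary
#' @return List of class `bland_altman`: `points` (tibble `subject_id`,
#'   `comparison_index`, `parameter`, `mean`, `difference`) and `summary`.
#' @export
bland_altman <- function(differences, loa_multiplier = 1.96) {
  summary <- difference_summary(differences, loa_multiplier)
  points <- tibble::tibble(
    subject_id = differences$subject_id,
    comparison_index = differences$comparison_index,
    parameter = differences$parameter,
    mean = (differences$test_value + differences$reference_value) / 2,
    difference = differences$signed_difference
  )
  structure(list(points = points, summary = summary), class = "bland_altman")
}

#' Plot a Bland-Altman analysis
#'
#' Scatter of difference against mean with horizontal lines at the bias
#' (solid) and the limits of agreement (dashed).
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.bland_altman <- function(x, ...) {
  s <- x$summary
  units <- if (s$parameter == "hr") "bpm" else "mm Hg"
  ggplot2::ggplot(x$points, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = s$mean_signed_difference) +
    ggplot2::geom_hline(yintercept = c(s$loa_lower, s$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Mean of test and reference (%s)", units),
      y = sprintf("Test - reference (%s)", units),
      title = sprintf("Bland-Altman: %s", toupper(s$parameter)),
      subtitle = sprintf("bias %.2f, LoA [%.2f, %.2f]",
                         s$mean_signed_difference, s$loa_lower, s$loa_upper)
    ) +
    ggplot2::theme_minimal()
}
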