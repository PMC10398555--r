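# Sample-size planning: diagnostic-accuracy validation (sensitivity- and
# specificity-driven one-proportion formulas with the prevalence in the
# denominator) and prevalence surveys (design-effect-inflated), plus
# recruitment inflation for expected data loss. All sizes round up.

check_prop <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(what, " must lie strictly in (0, 1)")
  }
  invisible(x)
}

z_two_sided <- function(conf) {
  check_prop(conf, "confidence")
  stats::qnorm(1 - (1 - conf) / 2)
}

#' Sample size to estimate a test's sensitivity
#'
#' \deqn{n = \lceil z^2 \, Se (1 - Se) / (d^2 \, p) \rceil}
#' where `d` is the absolute tolerance on the estimate, `p` the expected
#' disease prevalence (diseased subjects are the informative fraction of
#' the cohort), and `z` the two-sided normal quantile.
#'
#' @param sensitivity expected sensitivity, in (0, 1).
#' @param prevalence expected disease prevalence, in (0, 1).
#' @param tolerance absolute tolerance `d`, in (0, 1).
#' @param conf confidence level (default 0.95, i.e. z = 1.96).
#' @return Integer minimum cohort size.
#' @export
n_for_sensitivity <- function(sensitivity, prevalence, tolerance,
                              conf = 0.95) {
  check_prop(sensitivity, "sensitivity")
  check_prop(prevalence, "prevalence")
  check_prop(tolerance, "tolerance")
  z <- z_two_sided(conf)
  as.integer(ceiling(z^2 * sensitivity * (1 - sensitivity) /
                       (tolerance^2 * prevalence)))
}

#' Sample size to estimate a test's specificity
#'
#' As [n_for_sensitivity()] but with `Spec(1 - Spec)` in the numerator
#' and `1 - prevalence` (the non-diseased fraction) in the denominator.
#'
#' @param specificity expected specificity, in (0, 1).
#' @inheritParams n_for_sensitivity
#' @return Integer minimum cohort size.
#' @export
n_for_specificity <- function(specificity, prevalence, tolerance,
                              conf = 0.95) {
  check_prop(specificity, "specificity")
  check_prop(prevalence, "prevalence")
  check_prop(tolerance, "tolerance")
  z <- z_two_sided(conf)
  as.integer(ceiling(z^2 * specificity * (1 - specificity) /
                       (tolerance^2 * (1 - prevalence))))
}

#' Sample size for a prevalence survey with a design effect
#'
#' \deqn{n = \lceil D \, z^2 \, p (1 - p) / d^2 \rceil}
#' with scalar design effect `D >= 1` inflating the simple-random-sampling
#' size for non-ideal (e.g. convenience) sampling.
#'
#' @param prevalence expected prevalence `p`, in (0, 1).
#' @param tolerance absolute tolerance `d`, in (0, 1).
#' @param design_effect variance inflation factor `D` (>= 1).
#' @param conf confidence level (default 0.95).
#' @return Integer minimum number of analyzable questionnaires.
#' @export
n_for_prevalence <- function(prevalence, tolerance, design_effect = 1,
                             conf = 0.95) {
  check_prop(prevalence, "prevalence")
  check_prop(tolerance, "tolerance")
  if (!is.numeric(design_effect) || design_effect < 1) {
    stop("design_effect must be >= 1")
  }
  z <- z_two_sided(conf)
  as.integer(ceiling(design_effect * z^2 * prevalence * (1 - prevalence) /
                       tolerance^2))
}

#' Recruitment target after expected survey losses
#'
#' Inflates a required analyzable sample for the expected ratio of
#' unqualified (excluded-at-cleaning) questionnaires and the expected
#' nonresponse rate, applied multiplicatively:
#' `ceiling(n / ((1 - unqualified) * (1 - nonresponse)))`. Never below
#' `n_required`.
#'
#' @param n_required analyzable questionnaires needed.
#' @param unqualified_ratio expected fraction of responses removed during
#'   cleaning, in \[0, 1).
#' @param nonresponse_rate expected fraction of recruited participants who
#'   never respond, in \[0, 1).
#' @return Integer recruitment target.
#' @export
recruitment_target <- function(n_required, unqualified_ratio = 0.05,
                               nonresponse_rate = 0.5) {
  stopifnot(is.numeric(n_required), length(n_required) == 1L,
            n_required >= 0, n_required == round(n_required))
  for (r in c(unqualified_ratio, nonresponse_rate)) {
    if (!is.numeric(r) || is.na(r) || r < 0 || r >= 1) {
      stop("loss ratios must lie in [0, 1)")
    }
  }
  as.integer(ceiling(n_required /
                       ((1 - unqualified_ratio) * (1 - nonresponse_rate))))
}

#' Full sample-size plan for a two-phase questionnaire study
#'
#' Combines the accuracy-driven sizes (validation phase) and the
#' design-effect prevalence size plus recruitment inflation (survey
#' phase).
#'
#' @inheritParams n_for_sensitivity
#' @param specificity expected specificity.
#' @param prevalence_tolerance absolute tolerance for the prevalence
#'   estimate.
#' @param design_effect variance inflation factor for the survey phase.
#' @param unqualified_ratio,nonresponse_rate expected survey losses.
#' @return Object of class `samplesize_plan` (a named list of integers).
#' @export
samplesize_plan <- function(sensitivity = 0.82, specificity = 0.89,
                            prevalence = 0.3048, tolerance = 0.10,
                            conf = 0.95, prevalence_tolerance = 0.05,
                            design_effect = 2, unqualified_ratio = 0.05,
                            nonresponse_rate = 0.5) {
  n_se <- n_for_sensitivity(sensitivity, prevalence, tolerance, conf)
  n_sp <- n_for_specificity(specificity, prevalence, tolerance, conf)
  n_prev <- n_for_prevalence(prevalence, prevalence_tolerance,
                             design_effect, conf)
  structure(list(n_sensitivity = n_se, n_specificity = n_sp,
                 n_validation = max(n_se, n_sp), n_prevalence = n_prev,
                 recruitment = recruitment_target(n_prev, unqualified_ratio,
                                                  nonresponse_rate)),
            class = "samplesize_plan")
}

#' @export
print.samplesize_plan <- function(x, ...) {
  cat("Sample-size plan\n")
  cat(sprintf("  validation: n >= %d (sensitivity-driven %d, specificity-driven %d)\n",
              x$n_validation, x$n_sensitivity, x$n_specificity))
  cat(sprintf("  prevalence survey: n >= %d analyzable; recruit >= %d\n",
              x$n_prevalence, x$recruitment))
  invisible(x)
}
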