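#' True/published preference parameters for the duration-interacted logit
#'
#' Bundles the parameters of the QALY-parameterised conditional logit: `alpha`,
#' the utility of one life year in full health, and `beta[d, l]`, the
#' coefficient on the (level-l-of-dimension-d dummy) x duration interaction.
#' Level 1 coefficients are fixed at 0 (reference). Under this
#' parameterisation the systematic utility of a state with duration `t` is
#' `t * (alpha + sum_d beta[d, l(d)])`.
#'
#' @param alpha Positive scalar, utility per life year in full health.
#' @param beta 8 x 5 matrix of coefficients (typically `<= 0`), rows named by
#'   [fact8d_dimensions()]; column 1 must be zero.
#' @param label Optional label.
#' @return Object of class `fact8d_preferences`.
#' @seealso [published_model_coefficients()], [choice_probability()],
#'   [simulate_choices()]
#' @export
true_preferences <- function(alpha, beta, label = "") {
  stopifnot(is.numeric(alpha), length(alpha) == 1)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  beta <- as.matrix(beta)
  if (is.null(rownames(beta))) rownames(beta) <- fact8d_dimensions()
  beta <- beta[fact8d_dimensions(), , drop = FALSE]
  stopifnot(ncol(beta) == 5)
  colnames(beta) <- paste0("L", 1:5)
  if (any(abs(beta[, 1]) > 1e-12)) {
    stop("level 1 is the reference: beta[, 1] must be 0", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, label = label),
            class = "fact8d_preferences")
}

#' @export
print.fact8d_preferences <- function(x, ...) {
  cat("FACT-8D preference parameters",
      if (nzchar(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  cat("alpha (utility / life year in full health):", x$alpha, "\n")
  print(x$beta)
  invisible(x)
}

#' Published Canadian conditional logit coefficients
#'
#' The coefficient tables of the three published Canadian FACT-8D valuation
#' models: Model 1 (unweighted, unconstrained), Model 2 (survey-weighted,
#' unconstrained) and Model 3 (survey-weighted, monotonicity imposed by level
#' collapsing; the model defining the Canadian value set). Coefficients are
#' the level x duration interactions; `alpha` is the linear duration term.
#' Useful as simulation truth and for demonstrating violation detection.
#'
#' @param model 1, 2 or 3.
#' @return A [true_preferences()] object.
#' @export
#' @examples
#' published_model_coefficients(3)
published_model_coefficients <- function(model = 3) {
  stopifnot(model %in% 1:3)
  if (model == 1) {
    alpha <- 0.331
    beta <- rbind(
      pain    = c(0,  0.003, -0.020, -0.060, -0.136),
      fatigue = c(0, -0.002, -0.021, -0.040, -0.050),
      nausea  = c(0, -0.032, -0.044, -0.061, -0.089),
      sleep   = c(0,  0.020,  0.015, -0.040, -0.006),
      work    = c(0, -0.009, -0.014, -0.034, -0.076),
      support = c(0, -0.023, -0.001, -0.045, -0.067),
      sadness = c(0, -0.009, -0.035, -0.038, -0.058),
      worry   = c(0, -0.031, -0.019, -0.039, -0.049)
    )
  } else if (model == 2) {
    alpha <- 0.345
    beta <- rbind(
      pain    = c(0,  0.014, -0.025, -0.062, -0.148),
      fatigue = c(0, -0.030, -0.038, -0.048, -0.069),
      nausea  = c(0, -0.036, -0.047, -0.063, -0.103),
      sleep   = c(0,  0.024,  0.036, -0.019,  0.010),
      work    = c(0, -0.026, -0.040, -0.039, -0.088),
      support = c(0, -0.034,  0.009, -0.038, -0.064),
      sadness = c(0,  0.001, -0.050, -0.035, -0.069),
      worry   = c(0, -0.046, -0.021, -0.050, -0.033)
    )
  } else {
    alpha <- 0.366
    beta <- rbind(
      pain    = c(0,  0.000, -0.021, -0.072, -0.149),
      fatigue = c(0, -0.020, -0.028, -0.053, -0.060),
      nausea  = c(0, -0.036, -0.055, -0.059, -0.109),
      sleep   = c(0,  0.000,  0.000, -0.028, -0.028),
      work    = c(0, -0.021, -0.033, -0.033, -0.085),
      support = c(0, -0.008, -0.008, -0.044, -0.072),
      sadness = c(0,  0.000, -0.047, -0.047, -0.068),
      worry   = c(0, -0.035, -0.035, -0.043, -0.043)
    )
  }
  true_preferences(alpha, beta,
                   label = paste0("published Canadian valuation, Model ", model))
}

#' Level-collapsing pattern of the published constrained model
#'
#' The merge pattern that turns the unconstrained 33-parameter specification
#' into the published 23-parameter monotone model: pain level 2 merged to the
#' reference; sleep levels 2-3 to the reference and 4 = 5; work 3 = 4;
#' support 2 = 3; sadness 2 to the reference and 3 = 4; worry 2 = 3 and
#' 4 = 5.
#'
#' @return A [model_spec()] with 23 free parameters.
#' @export
published_constrained_spec <- function() {
  spec <- default_model_spec()
  spec <- merge_to_reference(spec, "pain", 2)
  spec <- merge_to_reference(spec, "sleep", 2:3)
  spec <- merge_levels(spec, "sleep", 4:5)
  spec <- merge_levels(spec, "work", 3:4)
  spec <- merge_levels(spec, "support", 2:3)
  spec <- merge_to_reference(spec, "sadness", 2)
  spec <- merge_levels(spec, "sadness", 3:4)
  spec <- merge_levels(spec, "worry", 2:3)
  spec <- merge_levels(spec, "worry", 4:5)
  spec
}

#' Canadian census margin targets used for representativeness checks
#'
#' Population proportions for the demographic variables carried by the
#' simulated cohort: sex, age group, region (province/territory), primary
#' language spoken at home, education level, and self-rated general health.
#' Values follow the published census-based targets at 2 decimal places; each
#' margin is renormalised to sum exactly to 1 (the printed region and
#' education columns sum to 1.027 and 0.99 because of rounding).
#'
#' @return A [margin_targets()] object.
#' @export
canadian_margins <- function() {
  margin_targets(list(
    sex = c(male = 0.48, female = 0.52),
    age_group = c("18-29" = 0.20, "30-39" = 0.17, "40-49" = 0.21,
                  "50-59" = 0.18, "60-69" = 0.11, "70+" = 0.13),
    region = c(AB = 0.12, BC = 0.13, MB = 0.04, NB = 0.02, NL = 0.02,
               NS = 0.03, NT = 0.001, NU = 0.001, ON = 0.39, QC = 0.23,
               PE = 0.004, SK = 0.04, YT = 0.001),
    language = c(english = 0.58, french = 0.22, other = 0.20),
    education = c(none = 0.15, high_school = 0.24, trades = 0.12,
                  college = 0.20, below_bachelor = 0.05, bachelor_plus = 0.23),
    health = c(excellent = 0.22, very_good = 0.36, good = 0.29,
               fair = 0.11, poor = 0.02)
  ), normalise = TRUE)
}

#' Sampling skew emulating the Canadian valuation panel
#'
#' Per-variable sampling proportions for the non-quota variables, matching the
#' observed composition of the valuation sample: over-representation of
#' English speakers and of college-or-higher education, and poorer self-rated
#' health than the census targets. Used as the default `skew` of
#' [simulate_respondents()] so that raking is genuinely exercised.
#'
#' @return Named list of sampling proportions by variable.
#' @export
canadian_sample_skew <- function() {
  list(
    language = c(english = 0.78, french = 0.19, other = 0.03),
    education = c(none = 0.03, high_school = 0.20, trades = 0.07,
                  college = 0.25, below_bachelor = 0.13, bachelor_plus = 0.33)
      / 1.01,
    health = c(excellent = 0.12, very_good = 0.39, good = 0.33,
               fair = 0.13, poor = 0.03)
  )
}
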