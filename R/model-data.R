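#' Prepare the individual-year metrics table for model fitting
#'
#' Filters to model-stage subjects (age at least `min_age`), applies
#' within-individual age centering (after filtering, so `avg_age` is the
#' mean over the subject years entering the models), sets the rank factor
#' with `"medium"` as reference (effect sizes are conventionally quoted
#' for a mid-ranking female), and clamps the kin-availability offset away
#' from 0/1 for the logit transform.
#'
#' @param metrics Output of [individual_year_metrics()].
#' @param min_age Minimum subject age (default 10).
#' @param ka_eps Clamp for the kin-availability proportion.
#' @return A model-ready data frame.
#' @export
prepare_model_data <- function(metrics, min_age = 10, ka_eps = 0.02) {
  d <- metrics[metrics$age >= min_age, , drop = FALSE]
  d <- d[!is.na(d$rank), , drop = FALSE]
  d <- center_age(d)
  d$rank <- factor(d$rank, levels = c("medium", "low", "high"))
  d$kin_available_adj <- pmin(pmax(d$kin_available, ka_eps), 1 - ka_eps)
  d
}

#' Prepare the last-year dyadic table for the partner-choice models
#'
#' Codes the response and predictors for the Bernoulli partner-choice
#' models: `chosen` as 0/1, `stable_prior` and `kin` as no/yes factors,
#' partner rank with `"medium"` reference, and the subject's final-year
#' age centered at the sample mean (the age entering the
#' choice-by-age interactions). For the stability model, subset to
#' `eligible_stability` first.
#'
#' @param lastyear Output of [build_last_year_dataset()].
#' @return A model-ready data frame with a `year` column (the final
#'   year).
#' @export
prepare_dyadic_data <- function(lastyear) {
  d <- lastyear
  d$chosen <- as.integer(d$chosen)
  d$stable_prior <- factor(ifelse(d$stable_prior, "yes", "no"),
                           levels = c("no", "yes"))
  d$kin <- factor(ifelse(d$kin, "yes", "no"), levels = c("no", "yes"))
  d$partner_rank <- factor(d$partner_rank,
                           levels = c("medium", "low", "high"))
  d$subject_age_c <- d$subject_age - mean(d$subject_age)
  d$year <- d$final_year
  d <- d[!is.na(d$partner_rank), , drop = FALSE]
  d
}

#' Fit one prediction end to end
#'
#' Convenience wrapper: builds the [build_model_spec()] specification and
#' fits it with [fit_glmm()] on the appropriate prepared table.
#'
#' @param prediction_id See [build_model_spec()].
#' @param data A prepared individual-year table ([prepare_model_data()])
#'   for P1-P4a, or a prepared dyadic table ([prepare_dyadic_data()]) for
#'   P4b/P4c.
#' @param parameterization,... Passed to [build_model_spec()] /
#'   [fit_glmm()].
#' @inheritParams fit_glmm
#' @return A `social_glmm`.
#' @export
fit_prediction <- function(prediction_id, data, parameterization = "A",
                           ci_level = 0.95, prune_interaction = TRUE, ...) {
  spec <- build_model_spec(prediction_id, parameterization, ...)
  if (prediction_id == "P4a_kin") {
    data <- data[data$n_partners > 0, , drop = FALSE]
  }
  if (prediction_id %in% c("P2b_groom", "P2b_prox")) {
    data <- data[!is.na(data$partner_deaths_prev_year), , drop = FALSE]
  }
  if (prediction_id == "P4c_stable") {
    data <- data[data$eligible_stability, , drop = FALSE]
  }
  fit_glmm(spec, data, ci_level = ci_level,
           prune_interaction = prune_interaction)
}
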