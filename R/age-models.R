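#' Within-individual age centering
#'
#' Decomposes chronological age into a between-individual component
#' (`avg_age`, the mean age over the years an individual was observed) and
#' a within-individual component (`within_age = age - avg_age`). Per
#' individual, `within_age` sums to zero and `within_age + avg_age`
#' reconstructs chronological age exactly; individuals observed once get
#' `within_age = 0`.
#'
#' @param data A data frame with one row per individual-year.
#' @param id_col,age_col Column names of the individual id and
#'   chronological age.
#' @return `data` with `avg_age` and `within_age` columns appended.
#' @examples
#' d <- data.frame(id = c("a", "a", "a"), age = c(12, 13, 15))
#' center_age(d)$within_age   # -1.33, -0.33, +1.67
#' @export
center_age <- function(data, id_col = "id", age_col = "age") {
  stopifnot(id_col %in% names(data), age_col %in% names(data))
  if (!nrow(data)) {
    data$avg_age <- numeric(0); data$within_age <- numeric(0)
    return(data)
  }
  data$avg_age <- stats::ave(data[[age_col]], data[[id_col]], FUN = mean)
  data$within_age <- data[[age_col]] - data$avg_age
  data
}

prediction_ids <- function() {
  c("P1_groom_deg", "P1_prox_deg", "P2a_out", "P2a_in",
    "P2b_groom", "P2b_prox", "P3_outstr", "P3_instr", "P3_proxstr",
    "P4a_kin", "P4b_meandsi", "P4c_stable")
}

#' Build a model specification for one prediction
#'
#' Encodes the fixed-effect, random-effect, family, offset and interaction
#' structure for each tested prediction, in three parameterizations:
#' `"A"` (within-individual age + average age, random slope of
#' within-individual age over individual), `"B"` (chronological age +
#' average age, no random slope — the selective-disappearance contrast),
#' and `"naive"` (chronological age only). Count responses use Poisson
#' (log link); strengths use zero-inflated beta (logit); the
#' kin-proportion model uses binomial (logit) with a kin-availability
#' offset; the dyadic partner-choice models use Bernoulli (logit) with
#' crossed subject and partner random intercepts (the multimembership
#' structure) and are unaffected by the parameterization argument.
#'
#' @param prediction_id One of `prediction_ids()`.
#' @param parameterization `"A"`, `"B"` or `"naive"`.
#' @param random_slope `"auto"` (A: yes, B/naive: no), `TRUE` or `FALSE`.
#'   The slope variable is always `within_age`.
#' @param interaction Include the rank-by-age (or, for P2b, deaths-by-age;
#'   for P4b/c, choice-predictor-by-subject-age) interaction, subject to
#'   pruning at fit time.
#' @param effort_offset Add `log(focal_seconds)` as an offset to the
#'   degree models (off by default; the count metrics are not
#'   effort-adjusted unless requested).
#' @param kin_offset For P4a: `"logit"` adds `qlogis(kin_available)` to
#'   the linear predictor (null model: partners picked at random with
#'   respect to kinship); `"raw"` uses the untransformed proportion.
#' @return A `model_spec` object.
#' @export
build_model_spec <- function(prediction_id,
                             parameterization = c("A", "B", "naive"),
                             random_slope = "auto",
                             interaction = TRUE,
                             effort_offset = FALSE,
                             kin_offset = c("logit", "raw")) {
  parameterization <- match.arg(parameterization)
  kin_offset <- match.arg(kin_offset)
  if (!prediction_id %in% prediction_ids()) {
    stop("unknown prediction_id: ", prediction_id)
  }
  dyadic <- prediction_id %in% c("P4b_meandsi", "P4c_stable")
  age_term <- switch(parameterization, A = "within_age", B = "age",
                     naive = "age")
  use_slope <- if (identical(random_slope, "auto")) {
    parameterization == "A"
  } else isTRUE(random_slope)

  if (dyadic) {
    choice <- if (prediction_id == "P4b_meandsi") "mean_prior_dsi" else
      "stable_prior"
    fixed <- c(choice, "subject_age_c", "partner_age", "partner_rank", "kin")
    inter <- if (interaction) paste0(choice, ":subject_age_c") else character(0)
    random <- c("(1 | subject_id)", "(1 | partner_id)", "(1 | group)",
                "(1 | year)")
    spec <- list(prediction_id = prediction_id,
                 parameterization = parameterization,
                 response = "chosen", family = "bernoulli_logit",
                 fixed = fixed, interaction = inter, random = random,
                 offset = character(0), zi = FALSE)
  } else {
    response <- switch(prediction_id,
      P1_groom_deg = "groom_degree", P1_prox_deg = "prox_degree",
      P2a_out = "approach_outdegree", P2a_in = "approach_indegree",
      P2b_groom = "groom_degree", P2b_prox = "prox_degree",
      P3_outstr = "groom_outstrength", P3_instr = "groom_instrength",
      P3_proxstr = "prox_strength",
      P4a_kin = "cbind(n_kin_partners, n_nonkin_partners)",
      stop("unhandled prediction"))
    family <- if (prediction_id %in% c("P3_outstr", "P3_instr", "P3_proxstr"))
      "zero_inflated_beta_logit"
    else if (prediction_id == "P4a_kin") "binomial_logit_offset"
    else "poisson_log"

    fixed <- switch(parameterization,
      A = c("within_age", "avg_age", "rank"),
      B = c("age", "avg_age", "rank"),
      naive = c("age", "rank"))
    p2b <- prediction_id %in% c("P2b_groom", "P2b_prox")
    if (p2b) fixed <- c("partner_deaths_prev_year", fixed, "group")
    inter <- if (!interaction) character(0)
      else if (p2b) paste0("partner_deaths_prev_year:", age_term)
      else paste0("rank:", age_term)
    random <- c(if (use_slope) "(1 + within_age | id)" else "(1 | id)",
                if (!p2b) "(1 | group)", "(1 | year)")
    offset <- character(0)
    if (effort_offset && family == "poisson_log") {
      offset <- "log(focal_seconds)"
    }
    if (prediction_id == "P4a_kin") {
      offset <- if (kin_offset == "logit") "qlogis(kin_available_adj)" else
        "kin_available"
    }
    spec <- list(prediction_id = prediction_id,
                 parameterization = parameterization,
                 response = response, family = family, fixed = fixed,
                 interaction = inter, random = random, offset = offset,
                 zi = family == "zero_inflated_beta_logit")
  }
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec %s (parameterization %s, family %s)\n",
              x$prediction_id, x$parameterization, x$family))
  cat("  ", deparse(spec_formula(x)), "\n")
  invisible(x)
}

spec_formula <- function(spec, with_interaction = TRUE) {
  rhs <- c(spec$fixed,
           if (with_interaction) spec$interaction,
           if (length(spec$offset)) paste0("offset(", spec$offset, ")"),
           spec$random)
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

spec_glmmTMB_family <- function(spec) {
  switch(spec$family,
    poisson_log = stats::poisson(link = "log"),
    zero_inflated_beta_logit = glmmTMB::beta_family(link = "logit"),
    binomial_logit_offset = stats::binomial(link = "logit"),
    bernoulli_logit = stats::binomial(link = "logit"),
    stop("unknown family: ", spec$family))
}

check_response <- function(spec, data) {
  if (grepl("^cbind", spec$response)) {
    k <- data$n_kin_partners; nn <- data$n_nonkin_partners
    if (is.null(k) || is.null(nn)) {
      stop("kin-proportion model needs n_kin_partners and n_nonkin_partners")
    }
    if (any(is.na(k + nn)) || any(c(k, nn) < 0) ||
        any(c(k, nn) != round(c(k, nn))) || any(k + nn == 0)) {
      stop("kin partner counts must be nonnegative integers with >= 1 partner")
    }
    return(invisible(TRUE))
  }
  y <- data[[spec$response]]
  if (is.null(y)) stop("response column missing: ", spec$response)
  if (spec$family == "poisson_log") {
    if (any(is.na(y)) || any(y < 0) || any(y != round(y))) {
      stop("response for a Poisson model must be nonnegative counts: ",
           spec$response)
    }
  } else if (spec$family == "zero_inflated_beta_logit") {
    if (any(is.na(y)) || any(y < 0) || any(y >= 1)) {
      stop("response for a zero-inflated beta model must lie in [0, 1): ",
           spec$response)
    }
  } else if (spec$family == "bernoulli_logit") {
    if (!all(y %in% c(0, 1))) {
      stop("response for a Bernoulli model must be 0/1: ", spec$response)
    }
  }
  invisible(TRUE)
}

#' Fit a social-aging GLMM
#'
#' Fits the mixed model described by a [build_model_spec()] specification.
#' Estimation uses Laplace-approximate marginal likelihood (glmmTMB);
#' 95% Wald intervals play the role of the 95% credible intervals in the
#' interval-based significance rule (a fixed effect is "significant" when
#' its interval excludes zero). When the specification carries an
#' interaction term, the interaction-pruning protocol is applied: the
#' model is fitted with the interaction and refitted without it when no
#' interaction coefficient's interval excludes zero.
#'
#' @param spec A `model_spec`.
#' @param data A prepared data frame (see [prepare_model_data()] /
#'   [prepare_dyadic_data()]).
#' @param ci_level Interval coverage (default 0.95).
#' @param prune_interaction Apply the pruning protocol (default TRUE).
#' @return A `social_glmm` object: coefficient table with interval bounds
#'   and significance flags, random-effect variance shares, convergence
#'   diagnostics, the pruned/retained interaction status, and the
#'   underlying glmmTMB fit.
#' @export
fit_glmm <- function(spec, data, ci_level = 0.95, prune_interaction = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  check_response(spec, data)
  for (v in c("id", "group", "year", "subject_id", "partner_id")) {
    if (v %in% names(data)) data[[v]] <- factor(data[[v]])
  }
  msgs <- character(0)
  quiet_fit <- function(formula) {
    withCallingHandlers(
      glmmTMB::glmmTMB(formula, data = data,
                       family = spec_glmmTMB_family(spec),
                       ziformula = if (spec$zi) ~1 else ~0),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  has_inter <- length(spec$interaction) > 0
  dropped_terms <- character(0)
  # When a variance component collapses to the boundary the Laplace
  # Hessian can lose positive definiteness; the standard remedy is to
  # drop the collapsed random terms and refit. The simplification is
  # recorded in the diagnostics, never silent.
  fit_ok <- function(fit) {
    isTRUE(fit$sdr$pdHess) &&
      all(is.finite(summary(fit)$coefficients$cond[, "Std. Error"]))
  }
  fit_with_fallback <- function(sp, with_interaction) {
    fit <- quiet_fit(spec_formula(sp, with_interaction))
    for (round in 1:5) {
      if (fit_ok(fit)) break
      vc <- glmmTMB::VarCorr(fit)$cond
      new_random <- sp$random
      for (g in names(vc)) {
        S <- vc[[g]]
        pat <- paste0("| ", g, ")")
        idx <- which(vapply(new_random, grepl, TRUE, pattern = pat,
                            fixed = TRUE))
        if (!length(idx)) next
        term <- new_random[idx[1]]
        if (ncol(S) > 1) {
          corr <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
          degen <- S[2, 2] < 1e-7 || !is.finite(corr) || abs(corr) > 0.99
          if (!degen) next
          dropped_terms <<- c(dropped_terms, term)
          new_random[idx] <- if (!startsWith(term, "diag(") &&
                                   S[2, 2] >= 1e-7) {
            paste0("diag", term)
          } else paste0("(1 | ", g, ")")
        } else if (S[1, 1] < 1e-7) {
          dropped_terms <<- c(dropped_terms, term)
          new_random <- new_random[-idx]
        }
      }
      new_random <- unique(new_random)
      if (identical(new_random, sp$random)) break
      sp$random <- new_random
      if (!length(sp$random)) break
      fit <- quiet_fit(spec_formula(sp, with_interaction))
    }
    list(fit = fit, spec = sp)
  }
  res <- fit_with_fallback(spec, has_inter)
  fit <- res$fit
  pruned <- FALSE
  if (has_inter && prune_interaction) {
    ct <- coef_table(fit, ci_level)
    inter_rows <- grepl(":", ct$term)
    if (any(inter_rows) && !any(ct$significant[inter_rows])) {
      res <- fit_with_fallback(res$spec, FALSE)
      fit <- res$fit
      pruned <- TRUE
    }
  }
  ct <- coef_table(fit, ci_level)
  vp <- variance_partition_impl(fit, spec, data)
  sdr <- fit$sdr
  diagnostics <- list(
    backend = "glmmTMB (Laplace approximation, Wald intervals)",
    convergence = isTRUE(fit$fit$convergence == 0),
    pd_hessian = isTRUE(sdr$pdHess),
    wald_ok = all(is.finite(ct$se)),
    simplified_random_terms = dropped_terms,
    messages = unique(msgs)
  )
  if (!diagnostics$pd_hessian || !diagnostics$wald_ok) {
    warning("model ", spec$prediction_id, " (", spec$parameterization,
            "): optimizer did not fully converge; inspect diagnostics")
  }
  structure(list(spec = spec, coefficients = ct, varshares = vp,
                 diagnostics = diagnostics, interaction_pruned = pruned,
                 ci_level = ci_level, n_obs = nrow(fit$frame), fit = fit),
            class = "social_glmm")
}

coef_table <- function(fit, ci_level = 0.95) {
  s <- summary(fit)$coefficients$cond
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  est <- s[, "Estimate"]; se <- s[, "Std. Error"]
  lower <- est - z * se
  upper <- est + z * se
  data.frame(term = rownames(s), estimate = est, se = se,
             lower = lower, upper = upper,
             significant = is.finite(lower) & is.finite(upper) &
               (lower > 0 | upper < 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition model variance over random terms
#'
#' Computes, on the linear-predictor scale, the share of total variance
#' (fixed-effect variance + all random-term variances + a
#' distribution-specific residual variance) attributable to each random
#' term. Random-slope contributions use the average of
#' \eqn{z^\top \Sigma z} over the observed slope covariate; the residual
#' variance is the lognormal approximation \eqn{\ln(1 + 1/\bar\lambda)}
#' for log-link Poisson models and \eqn{\pi^2/3} for logit-link models.
#'
#' @param fit A `social_glmm` object.
#' @return A data frame with columns `term`, `variance`, `share_pct`.
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "social_glmm"))
  fit$varshares
}

variance_partition_impl <- function(fit, spec, data) {
  vc <- glmmTMB::VarCorr(fit)$cond
  fr <- fit$frame
  lp_fixed <- stats::predict(fit, type = "link", re.form = NA)
  var_fixed <- stats::var(lp_fixed)
  terms <- character(0); vars <- numeric(0)
  for (gname in names(vc)) {
    S <- vc[[gname]]
    cn <- colnames(S)
    if (length(cn) == 1L) {
      terms <- c(terms, paste0(gname, " (intercept)"))
      vars <- c(vars, S[1, 1])
    } else {
      x <- fr[[cn[2]]]
      terms <- c(terms, paste0(gname, " (intercept)"),
                 paste0(gname, " (slope ", cn[2], ")"))
      slope_var <- S[2, 2] * mean(x^2) + 2 * S[1, 2] * mean(x)
      vars <- c(vars, S[1, 1], max(0, slope_var))
    }
  }
  resid_var <- if (spec$family == "poisson_log") {
    lambda_bar <- exp(mean(lp_fixed) + 0.5 * sum(vars))
    log(1 + 1 / lambda_bar)
  } else {
    pi^2 / 3
  }
  total <- var_fixed + sum(vars) + resid_var
  data.frame(term = c(terms, "fixed effects", "residual"),
             variance = c(vars, var_fixed, resid_var),
             share_pct = 100 * c(vars, var_fixed, resid_var) / total,
             stringsAsFactors = FALSE)
}

#' Test for selective disappearance from a Model B fit
#'
#' In the Model B parameterization (chronological age + average age), the
#' average-age coefficient estimates the difference between the between-
#' and within-individual age slopes. An interval excluding zero indicates
#' that between-individual differences are not driven purely by
#' within-individual change, i.e. selective disappearance of individuals
#' with low (positive coefficient) or high (negative coefficient)
#' sociality.
#'
#' @param fitB A `social_glmm` fitted with parameterization `"B"`.
#' @return A list with `decision` (`"none"`, `"positive"` or
#'   `"negative"`), and the interval bounds `lower`, `upper`.
#' @export
test_selective_disappearance <- function(fitB) {
  stopifnot(inherits(fitB, "social_glmm"))
  if (!identical(fitB$spec$parameterization, "B")) {
    stop("selective-disappearance test requires a Model B fit")
  }
  ct <- fitB$coefficients
  row <- ct[ct$term == "avg_age", ]
  if (nrow(row) != 1L) stop("avg_age term not found in Model B fit")
  decision <- if (row$lower > 0) "positive" else if (row$upper < 0)
    "negative" else "none"
  list(decision = decision, lower = row$lower, upper = row$upper,
       estimate = row$estimate)
}

#' Express a slope as a percent change over a span of years
#'
#' For a log-link coefficient, the within-individual percent change over
#' `years` is `100 * (exp(beta * years) - 1)`. For a logit link, the
#' percent change in the predicted probability between a reference linear
#' predictor and the reference shifted by `beta * years` is returned.
#'
#' @param beta Per-year slope on the link scale.
#' @param years Span of years (default 8, the study window convention).
#' @param link `"log"` or `"logit"`.
#' @param ref Reference linear predictor (required for `"logit"`).
#' @return Percent change (e.g. `-38.1` for a 38.1% decline).
#' @examples
#' pct_change(-0.06, 8)          # -38.1
#' pct_change(log(2) / 8, 8)     # +100
#' @export
pct_change <- function(beta, years = 8, link = c("log", "logit"),
                       ref = NULL) {
  link <- match.arg(link)
  if (link == "log") return(100 * (exp(beta * years) - 1))
  if (is.null(ref)) stop("logit-link percent change needs a reference linear predictor")
  p0 <- stats::plogis(ref)
  p1 <- stats::plogis(ref + beta * years)
  100 * (p1 - p0) / p0
}
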