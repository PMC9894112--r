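#' Run the full social-aging analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate -> metrics -> dyadic
#' indices -> model fits -> report. Writes the intermediate and final
#' artifacts (`metrics_individual_year.csv`, `dyads_year.csv`,
#' `last_year_dyads.csv`, `model_coefficients.csv`, `summary.txt`,
#' `run_log.txt`) to `outdir` and returns them invisibly. Every
#' stochastic step derives from `seed` (synthetic mode), so a rerun with
#' the same configuration reproduces identical artifacts.
#'
#' @param params A [sim_params()] object (synthetic mode), or `NULL` when
#'   reading CSVs from `input_dir`.
#' @param input_dir Directory of observation CSVs (files mode); exactly
#'   one of `params` / `input_dir` must be given.
#' @param outdir Output directory; created if needed. `NULL` skips
#'   writing.
#' @param predictions Prediction ids to fit (see `prediction_ids()`).
#' @param parameterizations Which parameterizations to fit for the
#'   individual-level models (`"A"`, `"B"`, `"naive"`); dyadic models are
#'   fitted once.
#' @param seed Seed used in synthetic mode (overrides `params$seed`).
#' @param min_age Minimum subject age at the model stage.
#' @param r_min Kin threshold.
#' @param ... Passed to [fit_prediction()] (e.g. `prune_interaction`).
#' @return Invisibly, a list with the dataset, metrics, dyads, last-year
#'   table, fits, the per-prediction summary data frame, and the
#'   coefficient table.
#' @export
run_pipeline <- function(params = NULL, input_dir = NULL, outdir = NULL,
                         predictions = c("P1_groom_deg", "P1_prox_deg",
                                         "P2a_out", "P2a_in",
                                         "P3_outstr", "P4a_kin",
                                         "P4b_meandsi", "P4c_stable"),
                         parameterizations = c("A", "B"),
                         seed = NULL, min_age = NULL, r_min = 0.125, ...) {
  if (is.null(params) == is.null(input_dir)) {
    stop("give exactly one of `params` (synthetic mode) or `input_dir` (files mode)")
  }
  log_lines <- c(sprintf("socage pipeline, package version %s",
                         as.character(utils::packageVersion("socage"))),
                 sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  truth <- NULL
  if (!is.null(params)) {
    if (!is.null(seed)) params$seed <- as.integer(seed)
    sim <- simulate_dataset(params)
    ds <- sim$dataset; truth <- sim$truth
    log_lines <- c(log_lines, sprintf("mode: synthetic (seed %d)", params$seed))
  } else {
    ds <- read_dataset(input_dir)
    log_lines <- c(log_lines, sprintf("mode: files (%s)", input_dir))
  }
  validate_dataset(ds)
  if (is.null(min_age)) {
    min_age <- if (!is.null(ds$params)) ds$params$study_min_age else 10
  }
  log_lines <- c(log_lines, sprintf(
    "dataset: %d animals, %d focals, %d grooming bouts, %d proximity records",
    nrow(ds$animals), nrow(ds$focals), nrow(ds$grooming), nrow(ds$proximity)))

  metrics <- suppressMessages(individual_year_metrics(ds, r_min = r_min))
  log_lines <- c(log_lines, sprintf("metrics: %d individual-years", nrow(metrics)))
  effort <- suppressMessages(observation_effort(ds))
  dyads <- suppressMessages(dsi(dyadic_rates(ds, effort)))
  dyads <- add_dyad_kinship(dyads, ds$animals, r_min)
  log_lines <- c(log_lines, sprintf("dyads: %d dyad-years", nrow(dyads)))

  model_data <- prepare_model_data(metrics, min_age = min_age)
  log_lines <- c(log_lines, sprintf(
    "model-stage subjects (age >= %s): %d rows, %d females",
    min_age, nrow(model_data), length(unique(model_data$id))))

  need_dyadic <- any(c("P4b_meandsi", "P4c_stable") %in% predictions)
  lastyear <- NULL; dyadic_data <- NULL
  if (need_dyadic) {
    lastyear <- suppressMessages(
      build_last_year_dataset(dyads, model_data))
    dyadic_data <- prepare_dyadic_data(lastyear)
    log_lines <- c(log_lines, sprintf(
      "last-year dataset: %d dyads, %d subjects (%d eligible for stability)",
      nrow(lastyear), length(unique(lastyear$subject_id)),
      length(unique(lastyear$subject_id[lastyear$eligible_stability]))))
  }

  fits <- list()
  for (pid in predictions) {
    if (pid %in% c("P4b_meandsi", "P4c_stable")) {
      fits[[pid]] <- fit_prediction(pid, dyadic_data, "A", ...)
    } else {
      for (par in parameterizations) {
        fits[[paste(pid, par, sep = ".")]] <-
          fit_prediction(pid, model_data, par, ...)
      }
    }
  }

  coefs <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cbind(model = nm, prediction = f$spec$prediction_id,
          parameterization = f$spec$parameterization,
          f$coefficients,
          converged = f$diagnostics$convergence)
  }))

  summary_df <- pipeline_summary(fits)
  artifacts <- list(dataset = ds, truth = truth, metrics = metrics,
                    dyads = dyads, lastyear = lastyear, fits = fits,
                    coefficients = coefs, summary = summary_df,
                    log = log_lines)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(outdir, "metrics_individual_year.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(dyads, file.path(outdir, "dyads_year.csv"),
                     row.names = FALSE, na = "")
    if (!is.null(lastyear)) {
      utils::write.csv(lastyear, file.path(outdir, "last_year_dyads.csv"),
                       row.names = FALSE, na = "")
    }
    utils::write.csv(coefs, file.path(outdir, "model_coefficients.csv"),
                     row.names = FALSE, na = "")
    writeLines(format_summary(summary_df), file.path(outdir, "summary.txt"))
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  invisible(artifacts)
}

# One row per prediction: within-individual and average-age estimates,
# significance, and the selective-disappearance decision from Model B.
pipeline_summary <- function(fits) {
  preds <- unique(vapply(fits, function(f) f$spec$prediction_id, ""))
  rows <- lapply(preds, function(pid) {
    fA <- fits[[paste(pid, "A", sep = ".")]]
    fB <- fits[[paste(pid, "B", sep = ".")]]
    fD <- fits[[pid]]
    get_term <- function(f, term) {
      if (is.null(f)) return(rep(NA_real_, 3))
      ct <- f$coefficients
      r <- ct[ct$term == term, ]
      if (nrow(r) != 1) return(rep(NA_real_, 3))
      c(r$estimate, r$lower, r$upper)
    }
    wa <- get_term(fA, "within_age")
    aa <- get_term(fA, "avg_age")
    decision <- if (!is.null(fB)) {
      test_selective_disappearance(fB)$decision
    } else NA_character_
    choice_term <- if (!is.null(fD)) {
      if (pid == "P4b_meandsi") "mean_prior_dsi" else "stable_prioryes"
    } else NA_character_
    ch <- if (!is.null(fD)) get_term(fD, choice_term) else rep(NA_real_, 3)
    data.frame(prediction = pid,
               within_age = wa[1], within_lower = wa[2], within_upper = wa[3],
               within_significant = !is.na(wa[2]) &&
                 (wa[2] > 0 || wa[3] < 0),
               avg_age = aa[1],
               pct_change_8y = if (!is.na(wa[1]) &&
                                     !is.null(fA) &&
                                     fA$spec$family == "poisson_log")
                 pct_change(wa[1], 8) else NA_real_,
               selective_disappearance = decision,
               choice_estimate = ch[1], choice_lower = ch[2],
               choice_upper = ch[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

format_summary <- function(s) {
  lines <- c("Social-aging pipeline summary",
             "=============================", "")
  for (i in seq_len(nrow(s))) {
    r <- s[i, ]
    lines <- c(lines, sprintf("%s:", r$prediction))
    if (!is.na(r$within_age)) {
      lines <- c(lines, sprintf(
        "  within-individual age: %.3f [%.3f, %.3f]%s",
        r$within_age, r$within_lower, r$within_upper,
        if (isTRUE(r$within_significant)) " *" else ""))
      if (!is.na(r$pct_change_8y)) {
        lines <- c(lines, sprintf(
          "  expected change over 8 y (mid rank, mean avg age): %+.1f%%",
          r$pct_change_8y))
      }
      lines <- c(lines, sprintf("  average age (Model A): %.3f", r$avg_age),
                 sprintf("  selective disappearance (Model B): %s",
                         r$selective_disappearance))
    }
    if (!is.na(r$choice_estimate)) {
      lines <- c(lines, sprintf(
        "  partner-choice effect: %.3f [%.3f, %.3f]",
        r$choice_estimate, r$choice_lower, r$choice_upper))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Parameter-recovery and confounding-separation experiments
#'
#' Runs replicated simulation scenarios and fits the naive (age only),
#' Model A (within + average age) and Model B (age + average age) Poisson
#' grooming-degree models on each replicate:
#' \describe{
#'   \item{`"decline"`}{within-individual decline only
#'     (`beta_within = -0.06`, no selective disappearance);}
#'   \item{`"selective"`}{selective disappearance only (`beta_within = 0`,
#'     more-social females die sooner: `delta_select = -2` with a wider
#'     sociability distribution and larger cohort);}
#'   \item{`"null"`}{neither.}
#' }
#' Each replicate records the estimated slopes with intervals, whether
#' Model A's within-age interval covers the generating value, and the
#' selective-disappearance decision.
#'
#' @param scenario One of `"decline"`, `"selective"`, `"null"`.
#' @param n_replicates Number of replicate simulations.
#' @param params Base [sim_params()]; the scenario overrides
#'   `beta_within` / `delta_select`.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param min_age Model-stage minimum age.
#' @return A `recovery_report`: per-replicate results and scenario
#'   summaries (mean estimate, bias, interval coverage, significance and
#'   decision rates).
#' @export
recovery_experiment <- function(scenario = c("decline", "selective", "null"),
                                n_replicates = 20, params = sim_params(),
                                seed = 100, min_age = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(n_replicates >= 1)
  params$beta_within <- switch(scenario, decline = -0.06, selective = 0,
                               null = 0)
  params$delta_select <- switch(scenario, decline = 0, selective = -2,
                                null = 0)
  if (scenario == "selective") {
    # selection needs material between-female variance to act on, and a
    # cohort large enough that the induced between-individual gradient
    # (comparable in size to the within-individual declines under study)
    # is not power-starved
    params$sociability_sd <- 0.8
    params$n_matrilines <- max(params$n_matrilines, 45L)
  }
  truth_beta <- params$beta_within
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    p <- params
    p$seed <- as.integer(seed + r)
    sim <- suppressWarnings(simulate_dataset(p))
    metrics <- suppressMessages(degree_rank_metrics(sim$dataset))
    ma <- if (is.null(min_age)) p$study_min_age else min_age
    d <- metrics[metrics$age >= ma & !is.na(metrics$rank), , drop = FALSE]
    d <- center_age(d)
    d$rank <- factor(d$rank, levels = c("medium", "low", "high"))
    if (length(unique(d$id[duplicated(d$id)])) < 5) {
      stop("scenario infeasible: almost no females observed in > 1 year")
    }
    fits <- lapply(c(naive = "naive", A = "A", B = "B"), function(par) {
      fit_prediction("P1_groom_deg", d, par, prune_interaction = FALSE,
                     interaction = FALSE)
    })
    pull <- function(f, term) {
      ct <- f$coefficients
      r2 <- ct[ct$term == term, ]
      c(estimate = r2$estimate, lower = r2$lower, upper = r2$upper)
    }
    wA <- pull(fits$A, "within_age")
    aA <- pull(fits$A, "avg_age")
    nv <- pull(fits$naive, "age")
    sd_test <- test_selective_disappearance(fits$B)
    reps[[r]] <- data.frame(
      replicate = r, seed = p$seed,
      within_A = wA[1], within_A_lower = wA[2], within_A_upper = wA[3],
      avg_A = aA[1],
      naive_age = nv[1], naive_lower = nv[2], naive_upper = nv[3],
      avgB = sd_test$estimate, avgB_lower = sd_test$lower,
      avgB_upper = sd_test$upper,
      decision = sd_test$decision,
      within_covers_truth = wA[2] <= truth_beta & truth_beta <= wA[3],
      within_covers_zero = wA[2] <= 0 & 0 <= wA[3],
      naive_significant = nv[2] > 0 | nv[3] < 0,
      row.names = NULL)
  }
  repdf <- do.call(rbind, reps)
  summary <- list(
    scenario = scenario,
    truth_beta_within = truth_beta,
    n_replicates = n_replicates,
    mean_within_A = mean(repdf$within_A),
    bias_within_A = mean(repdf$within_A) - truth_beta,
    coverage_within_A = mean(repdf$within_covers_truth),
    within_covers_zero_rate = mean(repdf$within_covers_zero),
    naive_mean = mean(repdf$naive_age),
    naive_significant_rate = mean(repdf$naive_significant),
    decision_rates = table(factor(repdf$decision,
                                  c("none", "positive", "negative"))) /
      n_replicates)
  structure(list(replicates = repdf, summary = summary,
                 params = params, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Recovery experiment: scenario '%s', %d replicates\n",
              s$scenario, s$n_replicates))
  cat(sprintf("  true within-individual slope: %.3f\n", s$truth_beta_within))
  cat(sprintf("  mean Model A within-age estimate: %.4f (bias %+.4f)\n",
              s$mean_within_A, s$bias_within_A))
  cat(sprintf("  95%% interval covers truth in %.0f%% of replicates\n",
              100 * s$coverage_within_A))
  cat(sprintf("  naive age model: mean %.4f, significant in %.0f%%\n",
              s$naive_mean, 100 * s$naive_significant_rate))
  cat("  selective-disappearance decisions: ",
      paste(sprintf("%s %.0f%%", names(s$decision_rates),
                    100 * as.numeric(s$decision_rates)), collapse = ", "),
      "\n")
  invisible(x)
}
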