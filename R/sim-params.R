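#' Parameters for the synthetic cohort generator
#'
#' Builds a validated parameter set for [generate_pedigree()] and
#' [simulate_dataset()]. Defaults describe a multi-group population of
#' matrilineal adult females observed over several study years with
#' 10-minute focal samples and three proximity scans per focal, a
#' log-linear within-individual decline in expected partner number, an
#' age-invariant annual grooming budget, kin- and stability-biased partner
#' choice, and Gompertz-like adult mortality calibrated so the median adult
#' lifespan is about 18 years.
#'
#' @param n_matrilines Number of founding matrilines.
#' @param n_groups Number of social groups; matrilines are assigned to
#'   groups in round-robin order and females stay in their natal group.
#' @param n_years Number of study years (years `1..n_years`).
#' @param burnin_years Demographic burn-in years before the study window,
#'   so matrilines carry multiple adult generations at study start.
#' @param founders_age_range Length-2 numeric, age range (years) of
#'   matriline founders at the start of burn-in.
#' @param birth_rate Probability that an adult female recruits a daughter
#'   in a given year (daughters only; male and non-surviving births are
#'   not tracked).
#' @param maturity_age Age (years) at which females count as adults and
#'   enter group membership and observation.
#' @param study_min_age Minimum age (years) for inclusion as a model-stage
#'   subject; observation covers all adult females.
#' @param alpha_partners Baseline log expected partner count for a
#'   mid-ranking female of reference age with average sociability.
#' @param ref_age Reference age (years) at which `alpha_partners` applies;
#'   the within-individual age slope is centred here in the generator.
#' @param beta_within Log-scale slope of expected partner count on
#'   chronological age (per year); negative values give within-individual
#'   social narrowing.
#' @param beta_rank_interaction Additional age slope for low-ranking
#'   females (log scale, per year).
#' @param kin_pref_base Log partner-choice weight for kin dyads
#'   (relatedness `r >= kin_threshold`) at the reference age.
#' @param kin_pref_slope Increase in the kin log-weight per year of mean
#'   dyad age, producing a within-individual rise in kin bias.
#' @param w_prev_dsi Partner-choice log-weight per unit of the dyad's
#'   previous-year bond intensity.
#' @param w_stable Partner-choice log-weight for dyads bonded in two
#'   consecutive prior years.
#' @param kin_threshold Relatedness cutoff used inside the generator's
#'   kin-preference term.
#' @param total_groom_mean_s Mean total grooming given per female-year
#'   (seconds); age-invariant by construction.
#' @param groom_cv Coefficient of variation of the annual grooming budget.
#' @param groom_bout_mean_s Mean duration (seconds) of a grooming bout;
#'   bouts are exponential.
#' @param prox_neighbors_per_scan Expected number of bonded partners
#'   within two meters at any one proximity scan. Presence is allocated
#'   across a female's bonds (dyad probability `c0 / max(deg_i, deg_j)`),
#'   so time spent in proximity is age-invariant and effort-normalized
#'   proximity strength stays below 1.
#' @param approach_rate Mean number of approaches per ordered bonded pair
#'   per year (Poisson).
#' @param mortality_base Baseline annual mortality hazard at maturity.
#' @param mortality_age_slope Log-hazard increase per year of age past
#'   maturity (Gompertz slope).
#' @param delta_select Effect of latent sociability on survival:
#'   the annual hazard is multiplied by `exp(-delta_select * sociability)`,
#'   so `delta_select < 0` makes more-social females die sooner (the
#'   selective-disappearance mechanism) and `0` disables it.
#' @param sociability_sd SD of the latent per-female sociability on the
#'   log partner-count scale.
#' @param slope_sd SD of the per-female deviation in the within-individual
#'   age slope (between-individual variation in the rate of social
#'   aging; small, as observed in long-lived primates).
#' @param group_effect_sd,year_effect_sd SD of group- and year-level
#'   log-scale effects on expected partner counts (ecological and
#'   observation-year heterogeneity).
#' @param n_focals_per_subject_year Focal samples per subject per year.
#' @param focal_duration_s Duration of one focal sample (seconds).
#' @param scans_per_focal Proximity scans per focal sample.
#' @param seed Integer seed; every stochastic step in the generator is
#'   driven by it, so runs are bit-reproducible.
#'
#' @return An object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params(n_matrilines = 6, n_years = 3, seed = 1)
#' p$beta_within
#' @export
sim_params <- function(n_matrilines = 30,
                       n_groups = 6,
                       n_years = 6,
                       burnin_years = 20,
                       founders_age_range = c(6, 16),
                       birth_rate = 0.3,
                       maturity_age = 6,
                       study_min_age = 10,
                       alpha_partners = log(5),
                       ref_age = 14.3,
                       beta_within = -0.06,
                       beta_rank_interaction = 0,
                       kin_pref_base = 1.0,
                       kin_pref_slope = 0.06,
                       w_prev_dsi = 0.5,
                       w_stable = 0.5,
                       kin_threshold = 0.125,
                       total_groom_mean_s = 3000,
                       groom_cv = 0.2,
                       groom_bout_mean_s = 120,
                       prox_neighbors_per_scan = 0.6,
                       approach_rate = 2,
                       mortality_base = 0.02,
                       mortality_age_slope = 0.15,
                       delta_select = 0,
                       sociability_sd = 0.4,
                       slope_sd = 0.02,
                       group_effect_sd = 0.1,
                       year_effect_sd = 0.05,
                       n_focals_per_subject_year = 20,
                       focal_duration_s = 600,
                       scans_per_focal = 3,
                       seed = 1L) {
  p <- list(
    n_matrilines = as.integer(n_matrilines),
    n_groups = as.integer(n_groups),
    n_years = as.integer(n_years),
    burnin_years = as.integer(burnin_years),
    founders_age_range = as.numeric(founders_age_range),
    birth_rate = birth_rate,
    maturity_age = maturity_age,
    study_min_age = study_min_age,
    alpha_partners = alpha_partners,
    ref_age = ref_age,
    beta_within = beta_within,
    beta_rank_interaction = beta_rank_interaction,
    kin_pref_base = kin_pref_base,
    kin_pref_slope = kin_pref_slope,
    w_prev_dsi = w_prev_dsi,
    w_stable = w_stable,
    kin_threshold = kin_threshold,
    total_groom_mean_s = total_groom_mean_s,
    groom_cv = groom_cv,
    groom_bout_mean_s = groom_bout_mean_s,
    prox_neighbors_per_scan = prox_neighbors_per_scan,
    approach_rate = approach_rate,
    mortality_base = mortality_base,
    mortality_age_slope = mortality_age_slope,
    delta_select = delta_select,
    sociability_sd = sociability_sd,
    slope_sd = slope_sd,
    group_effect_sd = group_effect_sd,
    year_effect_sd = year_effect_sd,
    n_focals_per_subject_year = as.integer(n_focals_per_subject_year),
    focal_duration_s = focal_duration_s,
    scans_per_focal = as.integer(scans_per_focal),
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(
    "n_matrilines must be >= 1" = p$n_matrilines >= 1L,
    "n_groups must be >= 1" = p$n_groups >= 1L,
    "n_years must be >= 1" = p$n_years >= 1L,
    "burnin_years must be >= 0" = p$burnin_years >= 0L,
    "founders_age_range must be length 2, increasing" =
      length(p$founders_age_range) == 2 &&
        p$founders_age_range[1] <= p$founders_age_range[2]
  )
  probs <- c(birth_rate = p$birth_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  durs <- c(total_groom_mean_s = p$total_groom_mean_s,
            groom_bout_mean_s = p$groom_bout_mean_s,
            focal_duration_s = p$focal_duration_s)
  if (any(durs <= 0)) {
    stop("durations must be > 0: ",
         paste(names(durs)[durs <= 0], collapse = ", "))
  }
  stopifnot(
    "mortality_base must be >= 0" = p$mortality_base >= 0,
    "sociability_sd must be >= 0" = p$sociability_sd >= 0,
    "slope_sd must be >= 0" = p$slope_sd >= 0,
    "group_effect_sd must be >= 0" = p$group_effect_sd >= 0,
    "year_effect_sd must be >= 0" = p$year_effect_sd >= 0,
    "kin_threshold must be in (0, 1]" =
      p$kin_threshold > 0 && p$kin_threshold <= 1,
    "prox_neighbors_per_scan must be in (0, 0.9]" =
      p$prox_neighbors_per_scan > 0 && p$prox_neighbors_per_scan <= 0.9,
    "n_focals_per_subject_year must be >= 1" =
      p$n_focals_per_subject_year >= 1L,
    "scans_per_focal must be >= 1" = p$scans_per_focal >= 1L,
    "maturity_age must be < study_min_age" =
      p$maturity_age <= p$study_min_age
  )
  annual_focal_s <- p$n_focals_per_subject_year * p$focal_duration_s
  if (p$total_groom_mean_s > 0.5 * annual_focal_s) {
    warning("grooming budget exceeds half the annual focal time; ",
            "observed rates will saturate and strengths may exceed 1")
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  %d matrilines in %d groups, %d study years (+%d burn-in)\n",
              x$n_matrilines, x$n_groups, x$n_years, x$burnin_years))
  cat(sprintf("  partner model: log lambda = %.3f + %.3f * (age - %.1f), sociability SD %.2f\n",
              x$alpha_partners, x$beta_within, x$ref_age, x$sociability_sd))
  cat(sprintf("  mortality: base %.3f, age slope %.3f, delta_select %.2f\n",
              x$mortality_base, x$mortality_age_slope, x$delta_select))
  cat(sprintf("  observation: %d focals x %d s, %d scans/focal; seed %d\n",
              x$n_focals_per_subject_year, round(x$focal_duration_s),
              x$scans_per_focal, x$seed))
  invisible(x)
}
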