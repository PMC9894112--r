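# Shared fixtures and independent oracles for the test suite.

toy_pedigree <- function() {
  utils::read.csv(system.file("extdata", "toy_pedigree.csv",
                              package = "socage"),
                  stringsAsFactors = FALSE)
}

three_female_dataset <- function() {
  read_dataset(system.file("extdata", "three_female_group",
                           package = "socage"))
}

# Wright's path-counting relatedness, independent of the recursive
# kinship implementation: r = sum over common ancestors A and over pairs
# of ascending paths (a -> A, b -> A) sharing only A, of (1/2)^(n1 + n2),
# assuming non-inbred common ancestors (true for all fixtures here).
path_relatedness <- function(ped, a, b) {
  parents <- function(x) {
    row <- ped[ped$id == x, ]
    p <- c(row$mother_id, if ("father_id" %in% names(ped)) row$father_id)
    p[!is.na(p) & p != ""]
  }
  ascend <- function(x) {
    out <- list(x)
    for (p in parents(x)) {
      out <- c(out, lapply(ascend(p), function(path) c(x, path)))
    }
    out
  }
  pa <- ascend(a); pb <- ascend(b)
  r <- 0
  for (p1 in pa) {
    for (p2 in pb) {
      anc <- p1[length(p1)]
      if (!identical(anc, p2[length(p2)])) next
      shared <- intersect(p1, p2)
      if (!identical(shared, anc)) next
      r <- r + 0.5^((length(p1) - 1) + (length(p2) - 1))
    }
  }
  r
}

# Minimal hand-built observation dataset: `n` females in one group-year,
# with event tables supplied by the caller.
tiny_dataset <- function(ids = c("A", "B", "C"),
                         focals = NULL, grooming = NULL, proximity = NULL,
                         approaches = NULL, agonism = NULL,
                         birth_year = -10, year = 1) {
  empty <- function(...) {
    cols <- c(...)
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                  cols))
  }
  if (is.null(focals)) {
    focals <- data.frame(focal_id = paste0(ids, "_f1"), subject_id = ids,
                         group = 1, year = year, duration_s = 600)
  }
  structure(list(
    animals = data.frame(id = ids, sex = "F", birth_year = birth_year,
                         death_year = NA_integer_, mother_id = NA_character_),
    membership = data.frame(id = ids, group = 1, year = year),
    focals = focals,
    grooming = if (is.null(grooming))
      empty("focal_id", "actor_id", "receiver_id", "duration_s") else grooming,
    proximity = if (is.null(proximity))
      empty("focal_id", "scan_index", "subject_id", "neighbor_id") else proximity,
    approaches = if (is.null(approaches))
      empty("focal_id", "actor_id", "receiver_id") else approaches,
    agonism = if (is.null(agonism))
      empty("group", "year", "winner_id", "loser_id") else agonism
  ), class = "obs_dataset")
}

# Small but realistic simulated dataset, computed once per test run.
.fixture_env <- new.env()
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- suppressWarnings(simulate_dataset(
      sim_params(n_matrilines = 10, n_groups = 2, burnin_years = 14,
                 n_years = 3, n_focals_per_subject_year = 6,
                 total_groom_mean_s = 1500, seed = 421)))
  }
  .fixture_env$sim
}

small_metrics <- function() {
  if (is.null(.fixture_env$metrics)) {
    .fixture_env$metrics <- suppressMessages(
      individual_year_metrics(small_sim()$dataset))
  }
  .fixture_env$metrics
}

# A bare-bones intercept-only Poisson spec (no random effects).
intercept_only_spec <- function(response = "y") {
  structure(list(prediction_id = "custom", parameterization = "naive",
                 response = response, family = "poisson_log",
                 fixed = "1", interaction = character(0),
                 random = character(0), offset = character(0), zi = FALSE),
            class = "model_spec")
}

# Fabricate a social_glmm carrying just a coefficient table, for testing
# interval-based decision rules in isolation.
fake_fit <- function(term, estimate, lower, upper, parameterization = "B") {
  structure(list(
    spec = structure(list(prediction_id = "P1_groom_deg",
                          parameterization = parameterization),
                     class = "model_spec"),
    coefficients = data.frame(term = term, estimate = estimate,
                              se = (upper - lower) / (2 * 1.96),
                              lower = lower, upper = upper,
                              significant = lower > 0 | upper < 0)),
    class = "social_glmm")
}
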