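test_that("age centering satisfies its identities", {
  d <- data.frame(id = c("a", "a", "a", "b"), age = c(12, 13, 15, 20))
  out <- center_age(d)
  expect_equal(out$avg_age[1:3], rep(40 / 3, 3))
  expect_equal(out$within_age[1:3], c(12, 13, 15) - 40 / 3)
  expect_equal(out$within_age[4], 0)  # single observation
  # property: per-individual within_age sums to 0 and reconstructs age
  set.seed(5)
  for (k in 1:20) {
    n <- sample(3:40, 1)
    dd <- data.frame(id = sample(letters[1:6], n, replace = TRUE),
                     age = runif(n, 6, 30))
    cc <- center_age(dd)
    sums <- tapply(cc$within_age, cc$id, sum)
    expect_true(all(abs(sums) < 1e-10))
    expect_equal(cc$within_age + cc$avg_age, dd$age)
  }
})

test_that("model specs encode the prediction structures", {
  sA <- build_model_spec("P1_groom_deg", "A")
  expect_setequal(sA$fixed, c("within_age", "avg_age", "rank"))
  expect_true("(1 + within_age | id)" %in% sA$random)
  expect_equal(sA$interaction, "rank:within_age")
  expect_equal(sA$family, "poisson_log")
  sB <- build_model_spec("P1_groom_deg", "B")
  expect_setequal(sB$fixed, c("age", "avg_age", "rank"))
  expect_false(any(grepl("within_age \\|", sB$random)))
  sN <- build_model_spec("P1_groom_deg", "naive")
  expect_false("avg_age" %in% sN$fixed)
  s3 <- build_model_spec("P3_outstr", "A")
  expect_equal(s3$family, "zero_inflated_beta_logit")
  s4a <- build_model_spec("P4a_kin", "A")
  expect_equal(s4a$family, "binomial_logit_offset")
  expect_equal(s4a$offset, "qlogis(kin_available_adj)")
  expect_equal(build_model_spec("P4a_kin", "A", kin_offset = "raw")$offset,
               "kin_available")
  s4b <- build_model_spec("P4b_meandsi")
  expect_equal(s4b$family, "bernoulli_logit")
  expect_true(all(c("(1 | subject_id)", "(1 | partner_id)") %in% s4b$random))
  s2b <- build_model_spec("P2b_groom", "A")
  expect_true("group" %in% s2b$fixed)
  expect_false("(1 | group)" %in% s2b$random)
  expect_error(build_model_spec("P9_nothing"), "unknown prediction_id")
})

test_that("intercept-only Poisson fit recovers the closed-form MLE", {
  d <- data.frame(y = rep(5L, 40))
  f <- fit_glmm(intercept_only_spec(), d)
  expect_lt(abs(coef(f)[["(Intercept)"]] - log(5)), 1e-6)
})

test_that("response validation rejects non-conforming data", {
  spec <- build_model_spec("P1_groom_deg", "A")
  d <- small_metrics()
  d <- prepare_model_data(d)
  d$groom_degree[1] <- -1
  expect_error(fit_glmm(spec, d), "nonnegative counts")
  d2 <- prepare_model_data(small_metrics())
  d2$groom_outstrength[1] <- 1.5
  expect_error(fit_glmm(build_model_spec("P3_outstr", "A"), d2),
               "\\[0, 1\\)")
})

test_that("selective-disappearance decisions follow the interval rule", {
  dec <- function(lo, hi) {
    test_selective_disappearance(fake_fit("avg_age", (lo + hi) / 2, lo, hi))
  }
  expect_equal(dec(-0.02, 0.03)$decision, "none")
  expect_equal(dec(0.01, 0.05)$decision, "positive")
  expect_equal(dec(-0.05, -0.01)$decision, "negative")
  expect_error(
    test_selective_disappearance(
      fake_fit("avg_age", 0, -1, 1, parameterization = "A")),
    "Model B")
})

test_that("percent-change transformation matches its closed forms", {
  expect_equal(pct_change(0, 8), 0)
  expect_equal(pct_change(log(2) / 8, 8), 100)
  expect_equal(pct_change(-0.06, 8), 100 * (exp(-0.48) - 1))
  expect_lt(abs(pct_change(-0.06, 8) - (-38.1)), 0.1)
  # monotone in beta for the log link
  b <- seq(-0.2, 0.2, by = 0.01)
  expect_true(all(diff(pct_change(b, 8)) > 0))
  # logit link needs a reference; doubling check at ref 0
  expect_equal(pct_change(0.1, 8, link = "logit", ref = 0),
               100 * (plogis(0.8) - 0.5) / 0.5)
  expect_error(pct_change(0.1, 8, link = "logit"), "reference")
})

test_that("variance partition is a complete percentage decomposition", {
  d <- prepare_model_data(small_metrics())
  f <- suppressWarnings(fit_prediction("P1_groom_deg", d, "A",
                                       interaction = FALSE,
                                       prune_interaction = FALSE))
  vp <- variance_partition(f)
  expect_equal(sum(vp$share_pct), 100)
  expect_true(all(vp$share_pct >= 0 & vp$share_pct <= 100))
  expect_true("residual" %in% vp$term)
  fB <- suppressWarnings(fit_prediction("P1_groom_deg", d, "B",
                                        interaction = FALSE,
                                        prune_interaction = FALSE))
  expect_false(any(grepl("slope", fB$varshares$term)))
})

test_that("fit objects expose the standard S3 surface", {
  d <- prepare_model_data(small_metrics())
  f <- suppressWarnings(fit_prediction("P1_groom_deg", d, "A",
                                       interaction = FALSE,
                                       prune_interaction = FALSE))
  expect_s3_class(f, "social_glmm")
  expect_named(coef(f)[1], "(Intercept)")
  ci <- confint(f)
  expect_true(all(ci[, 1] <= ci[, 2], na.rm = TRUE))
  expect_equal(nrow(ci), nrow(f$coefficients))
  expect_equal(length(predict(f)), f$n_obs)
  expect_output(print(f), "within_age")
  expect_output(print(summary(f)), "Variance partition")
  sim1 <- simulate(f, nsim = 1, seed = 1)
  expect_equal(nrow(sim1), f$n_obs)
})

test_that("the partner-deaths model fits with group as a fixed effect", {
  m <- small_metrics()
  d <- prepare_model_data(m, min_age = 8)
  d <- d[!is.na(d$partner_deaths_prev_year), ]
  f <- suppressWarnings(fit_prediction("P2b_groom", prepare_model_data(m, min_age = 8),
                                       "A", interaction = FALSE,
                                       prune_interaction = FALSE))
  expect_true("partner_deaths_prev_year" %in% f$coefficients$term)
  expect_true(any(grepl("^group", f$coefficients$term)))
  expect_equal(f$n_obs, nrow(d))
})

test_that("the optional effort offset enters the degree model formula", {
  sp <- build_model_spec("P1_groom_deg", "A", effort_offset = TRUE)
  expect_equal(sp$offset, "log(focal_seconds)")
  expect_true(grepl("offset\\(log\\(focal_seconds\\)\\)",
                    deparse1(socage:::spec_formula(sp))))
})

test_that("the rank interaction is pruned when its interval covers zero", {
  d <- prepare_model_data(small_metrics())
  f <- suppressWarnings(fit_prediction("P1_groom_deg", d, "A"))
  # beta_rank_interaction = 0 in the generator, so pruning should trigger
  expect_true(f$interaction_pruned)
  expect_false(any(grepl(":", f$coefficients$term)))
})
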