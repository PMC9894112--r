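fixture_dsi <- function() {
  ds <- three_female_dataset()
  eff <- observation_effort(ds, scans_per_focal = 30)
  dsi(dyadic_rates(ds, eff))
}

test_that("dyadic rates match the hand-worked fixture table", {
  d <- fixture_dsi()
  key <- paste(d$id_a, d$id_b)
  expect_equal(d$groom_rate[key == "A B"], 0.05)    # 100 / 2000
  expect_equal(d$groom_rate[key == "B C"], 0.025)   # 50 / 2000
  expect_equal(d$groom_rate[key == "A C"], 0)
  expect_equal(d$prox_rate[key == "A B"], 0.1)      # 6 / 60
  expect_equal(d$prox_rate[key == "A C"], 0.05)
  expect_equal(d$prox_rate[key == "B C"], 0)
})

test_that("DSI standardizes to the hand-computed values with mean exactly 1", {
  d <- fixture_dsi()
  key <- paste(d$id_a, d$id_b)
  expect_equal(d$dsi[key == "A B"], 2.0)
  expect_equal(d$dsi[key == "A C"], 0.5)
  expect_equal(d$dsi[key == "B C"], 0.5)
  expect_equal(mean(d$dsi), 1)
})

test_that("identical nonzero rates give DSI 1 everywhere; no interaction gives 0", {
  rates <- data.frame(id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                      group = 1, year = 1,
                      groom_seconds = 10, prox_scans = 2,
                      groom_rate = 0.01, prox_rate = 0.02)
  expect_equal(dsi(rates)$dsi, rep(1, 3))
  rates$groom_rate[1] <- 0; rates$prox_rate[1] <- 0
  rates$groom_seconds[1] <- 0; rates$prox_scans[1] <- 0
  expect_equal(dsi(rates)$dsi[1], 0)
})

test_that("DSI is invariant to rescaling all observation effort", {
  ds <- three_female_dataset()
  eff <- observation_effort(ds, scans_per_focal = 30)
  eff2 <- eff
  eff2$focal_seconds <- eff2$focal_seconds * 7
  eff2$scan_count <- eff2$scan_count * 7
  expect_equal(dsi(dyadic_rates(ds, eff))$dsi,
               dsi(dyadic_rates(ds, eff2))$dsi)
})

test_that("group-year mean DSI is 1 in every simulated group-year with interaction", {
  ds <- small_sim()$dataset
  d <- suppressMessages(dsi(dyadic_rates(ds)))
  means <- tapply(d$dsi, paste(d$group, d$year), mean)
  active <- tapply(d$groom_seconds + d$prox_scans, paste(d$group, d$year),
                   sum) > 0
  expect_true(all(abs(means[active] - 1) < 1e-12))
})

test_that("grooming degree equals the count of dyads with pooled grooming", {
  ds <- small_sim()$dataset
  deg <- degree_metrics(ds)
  d <- suppressMessages(dsi(dyadic_rates(ds)))
  pos <- d[d$groom_seconds > 0, ]
  cnt <- table(paste(c(pos$id_a, pos$id_b), c(pos$year, pos$year)))
  got <- setNames(deg$groom_degree, paste(deg$id, deg$year))
  expect_equal(as.integer(got[names(cnt)]), as.integer(cnt))
})

test_that("partner deaths are counted from previous-year DSI partners", {
  dyads <- data.frame(
    id_a = c("S", "S", "S", "S"), id_b = c("B", "C", "B", "D"),
    group = 1, year = c(1, 1, 2, 2),
    dsi = c(0.5, 0.2, 0.4, 1))
  animals <- data.frame(id = c("S", "B", "C", "D"),
                        death_year = c(NA, NA, 1, NA))
  expect_equal(partner_deaths(dyads, animals, "S", 2), 1L)  # C died in year 1
  expect_equal(partner_deaths(dyads, animals, "S", 3), 0L)  # no deaths in year 2
  expect_true(is.na(partner_deaths(dyads, animals, "S", 5)))  # year 4 unobserved
  # no partners: positive-DSI filter leaves nothing
  dy0 <- transform(dyads, dsi = 0)
  expect_equal(partner_deaths(dy0, animals, "S", 2), 0L)
  tab <- partner_deaths_table(dyads, animals)
  expect_equal(tab$partner_deaths_prev_year[tab$id == "S" & tab$year == 2], 1L)
  expect_true(is.na(tab$partner_deaths_prev_year[tab$id == "S" & tab$year == 1]))
})

test_that("stability requires two consecutive positive-DSI years before the final year", {
  expect_true(stable_partner_flag(2014:2016, c(0, 0.4, 0.7), 2017))
  expect_false(stable_partner_flag(2014:2016, c(0.5, 0, 0.6), 2017))
  expect_false(stable_partner_flag(2016, 0.2, 2017))      # a single prior year
  expect_false(stable_partner_flag(2014:2016, c(0.5, 0.9, 0), 2015))  # final-year cut
  expect_true(stable_partner_flag(2014:2016, c(0.5, 0.9, 0), 2017))
})

test_that("last-year dataset applies the 2-year and 3-year eligibility filters", {
  # S1: years 1-3; S2: years 2-3; S3: year 3 only; P: year 3 only
  metrics <- data.frame(
    id = c("S1", "S1", "S1", "S2", "S2", "S3", "P"),
    group = 1,
    year = c(1, 2, 3, 2, 3, 3, 3),
    age = c(10, 11, 12, 14, 15, 20, 13),
    rank = "medium")
  dyads <- expand.grid(a = c("S1", "S2", "S3", "P"),
                       b = c("S1", "S2", "S3", "P"),
                       year = 1:3, stringsAsFactors = FALSE)
  dyads <- dyads[dyads$a < dyads$b, ]
  names(dyads)[1:2] <- c("id_a", "id_b")
  dyads$group <- 1
  dyads$dsi <- 0
  dyads$dsi[dyads$id_a == "S1" & dyads$id_b == "S2" & dyads$year >= 2] <- 1
  dyads$r <- 0; dyads$kin <- FALSE
  expect_message(
    ly <- build_last_year_dataset(dyads, metrics),
    "single year of data")
  # subjects: S1 and S2 (>= 2 years); final year 3 has 4 residents -> 3
  # partners each
  expect_setequal(unique(ly$subject_id), c("S1", "S2"))
  expect_equal(nrow(ly), 2 * 3)
  expect_true(all(ly$eligible_stability == (ly$subject_id == "S1")))
  # partner first present in the final year: no prior co-residence
  p_row <- ly[ly$subject_id == "S1" & ly$partner_id == "P", ]
  expect_equal(p_row$mean_prior_dsi, 0)
  expect_equal(p_row$n_prior_years, 0)
  expect_false(p_row$stable_prior)
  # S1-S2 were co-resident in year 2 only before the final year
  s12 <- ly[ly$subject_id == "S1" & ly$partner_id == "S2", ]
  expect_equal(s12$n_prior_years, 1)
  expect_equal(s12$mean_prior_dsi, 1)
  expect_true(s12$chosen)
})

test_that("prior DSI averaging pools zero and positive years", {
  metrics <- data.frame(id = rep(c("S", "Q"), each = 3), group = 1,
                        year = rep(1:3, 2), age = 12, rank = "low")
  dyads <- data.frame(id_a = "Q", id_b = "S", group = 1, year = 1:3,
                      dsi = c(0.6, 0, 0.4), r = 0, kin = FALSE)
  ly <- build_last_year_dataset(dyads, metrics)
  srow <- ly[ly$subject_id == "S", ]
  expect_equal(srow$mean_prior_dsi, 0.3)   # (0.6 + 0) / 2
  expect_equal(srow$n_prior_years, 2)
})

test_that("last-year row count equals the enumeration oracle on simulated data", {
  m <- small_metrics()
  m2 <- m[!is.na(m$rank), ]
  ds <- small_sim()$dataset
  dyads <- suppressMessages(dsi(dyadic_rates(ds)))
  dyads <- add_dyad_kinship(dyads, ds$animals)
  ly <- suppressMessages(build_last_year_dataset(dyads, m2))
  nyears <- tapply(m2$year, m2$id, function(y) length(unique(y)))
  eligible <- names(nyears)[nyears >= 2]
  oracle <- sum(vapply(eligible, function(s) {
    fy <- max(m2$year[m2$id == s])
    g <- m2$group[m2$id == s & m2$year == fy][1]
    sum(m2$group == g & m2$year == fy) - 1L
  }, 1L))
  expect_equal(nrow(ly), oracle)
})
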