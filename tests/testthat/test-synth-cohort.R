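fast_params <- function(...) {
  sim_params(n_matrilines = 8, n_groups = 2, burnin_years = 10,
             n_years = 3, n_focals_per_subject_year = 4,
             total_groom_mean_s = 1000, seed = 99, ...)
}

test_that("parameter validation rejects invalid settings", {
  expect_error(sim_params(n_matrilines = 0), "n_matrilines")
  expect_error(sim_params(birth_rate = 1.5), "probabilities")
  expect_error(sim_params(focal_duration_s = -1), "durations")
  expect_error(sim_params(kin_threshold = 0), "kin_threshold")
})

test_that("no reproduction leaves exactly the founders without mother links", {
  ped <- generate_pedigree(fast_params(birth_rate = 0))
  expect_equal(nrow(ped$animals), 8)
  expect_true(all(is.na(ped$animals$mother_id)))
})

test_that("zero hazard means no deaths", {
  ped <- generate_pedigree(fast_params(mortality_base = 0,
                                       delta_select = 0))
  expect_true(all(is.na(ped$animals$death_year)))
})

test_that("seeded pedigree and dataset generation is bit-reproducible", {
  p <- fast_params()
  expect_identical(generate_pedigree(p), generate_pedigree(p))
  s1 <- suppressWarnings(simulate_dataset(p))
  s2 <- suppressWarnings(simulate_dataset(p))
  expect_identical(s1$dataset$grooming, s2$dataset$grooming)
  expect_identical(s1$dataset$proximity, s2$dataset$proximity)
  expect_identical(s1$truth$years, s2$truth$years)
})

test_that("every adult female appears in membership while alive", {
  ped <- generate_pedigree(fast_params())
  a <- ped$animals
  for (y in 1:3) {
    adults <- a$id[(y - a$birth_year) >= 6 &
                     (is.na(a$death_year) | a$death_year >= y)]
    expect_setequal(ped$membership$id[ped$membership$year == y], adults)
  }
})

test_that("generated datasets satisfy the structural invariants", {
  ds <- small_sim()$dataset
  expect_silent(validate_dataset(ds))
  tot <- tapply(ds$grooming$duration_s, ds$grooming$focal_id, sum)
  cap <- ds$focals$duration_s[match(names(tot), ds$focals$focal_id)]
  expect_true(all(tot <= cap))
  expect_true(all(ds$proximity$scan_index %in%
                    1:ds$params$scans_per_focal))
})

test_that("truth lambda declines with within-individual age at the generating slope", {
  tr <- small_sim()$truth
  ty <- merge(tr$years, tr$individuals, by = "id")
  # strip the known latents: remaining log-lambda structure is the age
  # slope plus rank and group/year effects
  ty <- ty[ty$rank != "low", ]
  ty$resid <- log(ty$lambda) - ty$sociability
  fit <- lm(resid ~ age + factor(group) + factor(year), data = ty)
  expect_lt(abs(coef(fit)[["age"]] - (-0.06)), 0.015)
})

test_that("annual grooming budgets are age-invariant across tertiles", {
  sim <- small_sim()
  ds <- sim$dataset
  fy <- setNames(paste(ds$focals$subject_id, ds$focals$year),
                 ds$focals$focal_id)
  given <- tapply(ds$grooming$duration_s, fy[ds$grooming$focal_id], sum)
  age <- with(sim$truth$years, setNames(age, paste(id, year)))
  bonds <- with(sim$truth$years, setNames(n_bonds, paste(id, year)))
  keep <- names(given)[bonds[names(given)] > 0]
  a <- age[keep]; g <- given[keep]
  ter <- cut(a, quantile(a, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE)
  m <- tapply(g, ter, mean)
  expect_lt(abs(m[[1]] - m[[3]]) / mean(g), 0.06)
})

test_that("without selection, latent sociability is uncorrelated with lifespan", {
  p <- sim_params(n_matrilines = 150, n_groups = 6, burnin_years = 25,
                  n_years = 10, delta_select = 0, seed = 77)
  ped <- generate_pedigree(p)
  a <- merge(ped$animals, ped$sociability, by = "id")
  dead <- a[!is.na(a$death_year), ]
  expect_gt(nrow(dead), 500)
  expect_lt(abs(cor(dead$sociability, dead$death_year - dead$birth_year)),
            0.05)
})

test_that("selection couples sociability to lifespan in the expected direction", {
  p <- sim_params(n_matrilines = 120, n_groups = 6, burnin_years = 25,
                  n_years = 10, delta_select = -2, sociability_sd = 0.6,
                  seed = 78)
  ped <- generate_pedigree(p)
  a <- merge(ped$animals, ped$sociability, by = "id")
  dead <- a[!is.na(a$death_year), ]
  expect_lt(cor(dead$sociability, dead$death_year - dead$birth_year), -0.1)
})

test_that("dataset CSV round-trip preserves the tables", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir, truth = sim$truth)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  ds2 <- read_dataset(dir)
  expect_equal(ds2$grooming$duration_s, sim$dataset$grooming$duration_s)
  expect_equal(ds2$animals$death_year, sim$dataset$animals$death_year)
  expect_identical(ds2$membership$id, sim$dataset$membership$id)
})

test_that("validation names the offending table, row and column", {
  ds <- small_sim()$dataset
  ds$grooming$duration_s[1] <- ds$params$focal_duration_s + 100
  expect_error(validate_dataset(ds),
               "grooming.csv, row 1, column duration_s")
  ds2 <- small_sim()$dataset
  ds2$approaches$receiver_id[2] <- ds2$approaches$actor_id[2]
  expect_error(validate_dataset(ds2), "approaches.csv, row 2")
  ds3 <- small_sim()$dataset
  ds3$membership$id[5] <- "GHOST"
  expect_error(validate_dataset(ds3), "membership.csv, row 5")
})
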