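test_that("observation effort sums focal seconds and scan counts", {
  ids <- c("A", "B")
  focals <- data.frame(
    focal_id = paste0(rep(ids, each = 10), "_f", 1:10),
    subject_id = rep(ids, each = 10), group = 1, year = 1,
    duration_s = 600)
  ds <- tiny_dataset(ids, focals = focals)
  eff <- observation_effort(ds, scans_per_focal = 3)
  expect_equal(eff$focal_seconds, c(6000, 6000))
  expect_equal(eff$scan_count, c(30, 30))
  expect_false(any(eff$no_focals))
})

test_that("membership rows without focals get flagged zero-effort records", {
  ds <- tiny_dataset(c("A", "B", "C"))
  ds$focals <- ds$focals[ds$focals$subject_id != "C", ]
  expect_message(eff <- observation_effort(ds, scans_per_focal = 3),
                 "no focal samples")
  expect_equal(eff$focal_seconds[eff$id == "C"], 0)
  expect_true(eff$no_focals[eff$id == "C"])
  expect_error(observation_effort(tiny_dataset("A", focals = data.frame(
    focal_id = character(0), subject_id = character(0), group = integer(0),
    year = integer(0), duration_s = numeric(0)))), "empty")
})

test_that("degrees count unique partners, directionally for approaches", {
  gr <- data.frame(focal_id = c("A_f1", "A_f1", "C_f1"),
                   actor_id = c("A", "A", "C"),
                   receiver_id = c("B", "B", "A"),
                   duration_s = c(10, 20, 5))
  ap <- data.frame(focal_id = c("A_f1", "B_f1"),
                   actor_id = c("A", "B"), receiver_id = c("B", "A"))
  ds <- tiny_dataset(c("A", "B", "C"), grooming = gr, approaches = ap)
  deg <- degree_metrics(ds)
  expect_equal(deg$groom_degree[deg$id == "A"], 2L)  # B (given twice) + C
  expect_equal(deg$groom_degree[deg$id == "B"], 1L)
  expect_equal(deg$approach_outdegree[deg$id == "A"], 1L)
  expect_equal(deg$approach_indegree[deg$id == "A"], 1L)
  expect_equal(deg$approach_outdegree[deg$id == "B"], 1L)
  expect_equal(deg$approach_indegree[deg$id == "B"], 1L)
})

test_that("degrees match an independent edge-list dedup oracle on simulated data", {
  ds <- small_sim()$dataset
  deg <- degree_metrics(ds)
  # oracle: dedup (id, partner, year) edges from raw tables
  fy <- setNames(ds$focals$year, ds$focals$focal_id)
  gr <- ds$grooming
  gr$year <- fy[gr$focal_id]
  edges <- unique(rbind(
    data.frame(id = gr$actor_id, partner = gr$receiver_id, year = gr$year),
    data.frame(id = gr$receiver_id, partner = gr$actor_id, year = gr$year)))
  oracle <- table(paste(edges$id, edges$year))
  got <- setNames(deg$groom_degree, paste(deg$id, deg$year))
  common <- names(oracle)
  expect_equal(as.integer(got[common]), as.integer(oracle))
})

test_that("strengths follow the combined-effort formula on the shipped fixture", {
  ds <- three_female_dataset()
  eff <- observation_effort(ds, scans_per_focal = 30)
  s <- strength_metrics(ds, eff)
  # A gives B 100 s; both observed 1000 s -> 100/2000 = 0.05
  expect_equal(s$groom_outstrength[s$id == "A"], 0.05)
  expect_equal(s$groom_instrength[s$id == "B"], 0.05)
  expect_equal(s$groom_outstrength[s$id == "B"], 0.025)
  expect_equal(s$groom_instrength[s$id == "C"], 0.025)
  expect_equal(s$groom_outstrength[s$id == "C"], 0)
  # proximity: AB 6/(30+30), AC 3/60 -> A: 0.15, B: 0.1, C: 0.05
  expect_equal(s$prox_strength[s$id == "A"], 0.15)
  expect_equal(s$prox_strength[s$id == "B"], 0.1)
  expect_equal(s$prox_strength[s$id == "C"], 0.05)
})

test_that("no interactions means zero strengths", {
  ds <- tiny_dataset(c("A", "B"))
  s <- strength_metrics(ds, observation_effort(ds, scans_per_focal = 3))
  expect_true(all(s$groom_outstrength == 0))
  expect_true(all(s$prox_strength == 0))
})

test_that("rank categories follow the percent-dominated bins", {
  ids <- sprintf("R%02d", 1:10)
  # R01 beats 8 others (88.9% -> high), R02 beats 5 (55.6% -> medium),
  # R03 beats 4 (44.4% -> low); remaining decided links keep everyone
  # connected
  win <- function(w, l) data.frame(group = 1, year = 1,
                                   winner_id = w, loser_id = l)
  ag <- rbind(win(rep("R01", 8), ids[2:9]),
              win(rep("R02", 5), ids[c(4:8)]),
              win(rep("R03", 4), ids[c(5:8)]),
              win("R10", "R01"),
              win(rep("R04", 3), ids[c(5, 9, 10)]))
  rk <- assign_ranks(ag, 1, 1, roster = ids)
  expect_equal(rk$rank[rk$id == "R01"], "high")    # 8/9 = 88.9%
  expect_equal(rk$rank[rk$id == "R02"], "medium")  # 5/9 = 55.6%
  expect_equal(rk$rank[rk$id == "R03"], "low")     # 4/9 = 44.4%
})

test_that("females without decided relationships get a missing rank", {
  ag <- data.frame(group = 1, year = 1, winner_id = "A", loser_id = "B")
  expect_message(rk <- assign_ranks(ag, 1, 1, roster = c("A", "B", "C")),
                 "no decided relationships")
  expect_true(is.na(rk$rank[rk$id == "C"]))
  expect_error(assign_ranks(ag, 1, 1, roster = "A"), "at least two")
})

test_that("simulated ranks recover the matrilineal hierarchy", {
  sim <- small_sim()
  m <- small_metrics()
  tr <- sim$truth$years
  mm <- merge(m, tr[, c("id", "year", "rank")], by = c("id", "year"),
              suffixes = c("", "_truth"))
  expect_true(mean(mm$rank == mm$rank_truth, na.rm = TRUE) > 0.99)
})

test_that("effort aggregation equals a brute-force group-by", {
  ds <- small_sim()$dataset
  eff <- suppressMessages(observation_effort(ds))
  brute <- tapply(ds$focals$duration_s,
                  paste(ds$focals$subject_id, ds$focals$group, ds$focals$year),
                  sum)
  got <- setNames(eff$focal_seconds, paste(eff$id, eff$group, eff$year))
  expect_equal(as.numeric(got[names(brute)]), as.numeric(brute))
})

test_that("metric conservation: out-approaches equal in-approaches in total", {
  deg <- degree_metrics(small_sim()$dataset)
  expect_equal(sum(deg$approach_outdegree), sum(deg$approach_indegree))
})

test_that("removing one female's events zeroes her metrics and clips partners by at most one", {
  ds <- small_sim()$dataset
  deg0 <- degree_metrics(ds)
  victim <- deg0$id[which.max(deg0$groom_degree)]
  ds2 <- ds
  for (tab in c("grooming", "approaches")) {
    keep <- !(ds2[[tab]]$actor_id == victim | ds2[[tab]]$receiver_id == victim)
    ds2[[tab]] <- ds2[[tab]][keep, ]
  }
  ds2$proximity <- ds2$proximity[!(ds2$proximity$subject_id == victim |
                                     ds2$proximity$neighbor_id == victim), ]
  deg1 <- degree_metrics(ds2)
  expect_true(all(deg1$groom_degree[deg1$id == victim] == 0))
  key0 <- paste(deg0$id, deg0$year)
  drop <- deg0$groom_degree - deg1$groom_degree[match(key0,
                                                      paste(deg1$id, deg1$year))]
  expect_true(all(drop[deg0$id != victim] %in% 0:1))
})
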