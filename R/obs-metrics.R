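#' Observation effort per subject and group-year
#'
#' Sums focal seconds and proximity-scan counts per subject per
#' group-year. Membership rows without any focal sample get a zero-effort
#' record with `no_focals = TRUE` so downstream stages can exclude or
#' flag them.
#'
#' @param ds An `obs_dataset`.
#' @param scans_per_focal Scans taken per focal sample; taken from the
#'   simulation parameters when present, else inferred from the maximum
#'   recorded scan index.
#' @return A data frame: id, group, year, focal_seconds, scan_count,
#'   no_focals.
#' @export
observation_effort <- function(ds, scans_per_focal = NULL) {
  if (is.null(scans_per_focal)) {
    scans_per_focal <- if (!is.null(ds$params)) ds$params$scans_per_focal
      else if (nrow(ds$proximity)) max(ds$proximity$scan_index) else 3L
  }
  if (!nrow(ds$focals)) stop("focals table is empty")
  key <- interaction(ds$focals$subject_id, ds$focals$group, ds$focals$year,
                     drop = TRUE)
  agg <- stats::aggregate(
    list(focal_seconds = ds$focals$duration_s,
         n_focals = rep(1L, nrow(ds$focals))),
    by = list(id = ds$focals$subject_id, group = ds$focals$group,
              year = ds$focals$year), FUN = sum)
  agg$scan_count <- agg$n_focals * scans_per_focal
  agg$n_focals <- NULL
  out <- merge(ds$membership, agg, by = c("id", "group", "year"),
               all.x = TRUE)
  out$no_focals <- is.na(out$focal_seconds)
  out$focal_seconds[out$no_focals] <- 0
  out$scan_count[out$no_focals] <- 0L
  if (any(out$no_focals)) {
    message(sum(out$no_focals),
            " membership rows have no focal samples (zero effort, flagged)")
  }
  out[order(out$group, out$year, out$id), ]
}

# Attach group/year from the focals table to an event table.
event_context <- function(ds, focal_ids, table_name) {
  m <- match(focal_ids, ds$focals$focal_id)
  if (anyNA(m)) {
    stop("event in ", table_name, " refers to unknown focal_id: ",
         focal_ids[which(is.na(m))[1]])
  }
  data.frame(group = ds$focals$group[m], year = ds$focals$year[m])
}

# Keep only events whose two members are both adult females co-resident
# in the event's group-year (per the membership table).
restrict_to_members <- function(ev, ds, a_col, b_col) {
  memkey <- paste(ds$membership$id, ds$membership$group, ds$membership$year)
  ok <- paste(ev[[a_col]], ev$group, ev$year) %in% memkey &
    paste(ev[[b_col]], ev$group, ev$year) %in% memkey
  ev[ok, , drop = FALSE]
}

unique_partner_counts <- function(ev, subj_col, part_col) {
  if (!nrow(ev)) {
    return(data.frame(id = character(0), group = integer(0),
                      year = integer(0), n = integer(0)))
  }
  dd <- unique(ev[, c(subj_col, part_col, "group", "year")])
  out <- stats::aggregate(list(n = rep(1L, nrow(dd))),
                          by = list(id = dd[[subj_col]], group = dd$group,
                                    year = dd$year), FUN = sum)
  out
}

#' Network degree metrics per individual and group-year
#'
#' Grooming degree counts the unique adult females an individual gave
#' grooming to or received grooming from; proximity degree the unique
#' adult females she was scanned in proximity to (either as subject or as
#' recorded neighbor); approach out-/in-degree the unique receivers of /
#' actors of approaches. Partners are restricted to adult females
#' co-resident in the same group-year.
#'
#' @param ds An `obs_dataset`.
#' @return A data frame keyed by id, group, year with groom_degree,
#'   prox_degree, approach_outdegree, approach_indegree.
#' @export
degree_metrics <- function(ds) {
  base <- ds$membership[, c("id", "group", "year")]

  gr <- cbind(ds$grooming, event_context(ds, ds$grooming$focal_id, "grooming"))
  gr <- restrict_to_members(gr, ds, "actor_id", "receiver_id")
  groom_pairs <- rbind(
    data.frame(id = gr$actor_id, partner = gr$receiver_id,
               group = gr$group, year = gr$year),
    data.frame(id = gr$receiver_id, partner = gr$actor_id,
               group = gr$group, year = gr$year))
  gdeg <- unique_partner_counts(groom_pairs, "id", "partner")

  px <- cbind(ds$proximity,
              event_context(ds, ds$proximity$focal_id, "proximity"))
  px <- restrict_to_members(px, ds, "subject_id", "neighbor_id")
  prox_pairs <- rbind(
    data.frame(id = px$subject_id, partner = px$neighbor_id,
               group = px$group, year = px$year),
    data.frame(id = px$neighbor_id, partner = px$subject_id,
               group = px$group, year = px$year))
  pdeg <- unique_partner_counts(prox_pairs, "id", "partner")

  ap <- cbind(ds$approaches,
              event_context(ds, ds$approaches$focal_id, "approaches"))
  ap <- restrict_to_members(ap, ds, "actor_id", "receiver_id")
  odeg <- unique_partner_counts(ap, "actor_id", "receiver_id")
  ideg <- unique_partner_counts(ap, "receiver_id", "actor_id")

  out <- base
  for (nm in c("gdeg", "pdeg", "odeg", "ideg")) {
    d <- get(nm)
    names(d)[names(d) == "n"] <- nm
    out <- merge(out, d, by = c("id", "group", "year"), all.x = TRUE)
  }
  names(out)[match(c("gdeg", "pdeg", "odeg", "ideg"), names(out))] <-
    c("groom_degree", "prox_degree", "approach_outdegree",
      "approach_indegree")
  for (col in c("groom_degree", "prox_degree", "approach_outdegree",
                "approach_indegree")) {
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out[order(out$group, out$year, out$id), ]
}

# Pooled directed grooming seconds per (giver, receiver, group, year).
directed_groom_totals <- function(ds) {
  gr <- cbind(ds$grooming, event_context(ds, ds$grooming$focal_id, "grooming"))
  gr <- restrict_to_members(gr, ds, "actor_id", "receiver_id")
  if (!nrow(gr)) {
    return(data.frame(actor_id = character(0), receiver_id = character(0),
                      group = integer(0), year = integer(0),
                      seconds = numeric(0)))
  }
  stats::aggregate(list(seconds = gr$duration_s),
                   by = list(actor_id = gr$actor_id,
                             receiver_id = gr$receiver_id,
                             group = gr$group, year = gr$year), FUN = sum)
}

# Joint proximity scan counts per unordered dyad and group-year.
joint_prox_counts <- function(ds) {
  px <- cbind(ds$proximity,
              event_context(ds, ds$proximity$focal_id, "proximity"))
  px <- restrict_to_members(px, ds, "subject_id", "neighbor_id")
  if (!nrow(px)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      group = integer(0), year = integer(0),
                      scans = integer(0)))
  }
  a <- pmin(px$subject_id, px$neighbor_id)
  b <- pmax(px$subject_id, px$neighbor_id)
  stats::aggregate(list(scans = rep(1L, nrow(px))),
                   by = list(id_a = a, id_b = b, group = px$group,
                             year = px$year), FUN = sum)
}

#' Strength metrics per individual and group-year
#'
#' Dyadic rates divide interaction amounts by the combined observation
#' effort of the two members (focal seconds for grooming, scan counts for
#' proximity); an individual's strength is the sum of its dyadic rates
#' over partners, computed separately for grooming given, grooming
#' received, and proximity.
#'
#' @param ds An `obs_dataset`.
#' @param effort Output of [observation_effort()].
#' @return A data frame keyed by id, group, year with groom_outstrength,
#'   groom_instrength, prox_strength.
#' @export
strength_metrics <- function(ds, effort = observation_effort(ds)) {
  fs <- stats::setNames(effort$focal_seconds,
                        paste(effort$id, effort$group, effort$year))
  sc <- stats::setNames(effort$scan_count,
                        paste(effort$id, effort$group, effort$year))
  gg <- directed_groom_totals(ds)
  if (nrow(gg)) {
    ea <- fs[paste(gg$actor_id, gg$group, gg$year)]
    eb <- fs[paste(gg$receiver_id, gg$group, gg$year)]
    if (any(is.na(ea + eb)) || any(ea + eb == 0)) {
      stop("grooming recorded for a dyad with zero combined focal effort")
    }
    gg$rate <- gg$seconds / (ea + eb)
  }
  jp <- joint_prox_counts(ds)
  if (nrow(jp)) {
    sa <- sc[paste(jp$id_a, jp$group, jp$year)]
    sb <- sc[paste(jp$id_b, jp$group, jp$year)]
    if (any(is.na(sa + sb)) || any(sa + sb == 0)) {
      stop("proximity recorded for a dyad with zero combined scan effort")
    }
    jp$rate <- jp$scans / (sa + sb)
  }
  out <- ds$membership[, c("id", "group", "year")]
  sum_by <- function(df, id_col) {
    if (!nrow(df)) {
      return(data.frame(id = character(0), group = integer(0),
                        year = integer(0), s = numeric(0)))
    }
    stats::aggregate(list(s = df$rate),
                     by = list(id = df[[id_col]], group = df$group,
                               year = df$year), FUN = sum)
  }
  outs <- sum_by(gg, "actor_id")
  ins <- sum_by(gg, "receiver_id")
  prx <- rbind(sum_by(jp, "id_a"), sum_by(jp, "id_b"))
  if (nrow(prx)) {
    prx <- stats::aggregate(list(s = prx$s),
                            by = list(id = prx$id, group = prx$group,
                                      year = prx$year), FUN = sum)
  }
  for (nm in c("outs", "ins", "prx")) {
    d <- get(nm)
    names(d)[names(d) == "s"] <- nm
    out <- merge(out, d, by = c("id", "group", "year"), all.x = TRUE)
  }
  names(out)[match(c("outs", "ins", "prx"), names(out))] <-
    c("groom_outstrength", "groom_instrength", "prox_strength")
  for (col in c("groom_outstrength", "groom_instrength", "prox_strength")) {
    out[[col]][is.na(out[[col]])] <- 0
  }
  out[order(out$group, out$year, out$id), ]
}

#' Dominance rank categories from agonistic outcomes
#'
#' For each female in a group-year, computes the percent of other females
#' she dominates, where she dominates another female when she won the
#' majority of their decided interactions. Percents map to categories:
#' high (>= 80%), medium (50 to < 80%), low (< 50%). Females with no
#' decided relationship get a missing rank and are flagged.
#'
#' @param agonism Agonism table (group, year, winner_id, loser_id).
#' @param group,year Group-year to rank.
#' @param roster Optional full roster of adult females in the group-year;
#'   defaults to the females appearing in the agonism records.
#' @return A data frame: id, pct_dominated, rank.
#' @export
assign_ranks <- function(agonism, group, year, roster = NULL) {
  ag <- agonism[agonism$group == group & agonism$year == year, ,
                drop = FALSE]
  if (is.null(roster)) roster <- unique(c(ag$winner_id, ag$loser_id))
  n <- length(roster)
  if (n < 2) stop("need at least two females with decided interactions")
  wins <- table(factor(ag$winner_id, roster), factor(ag$loser_id, roster))
  dominates <- wins > t(wins)        # majority of decided outcomes
  decided <- (wins + t(wins)) > 0
  has_rel <- rowSums(decided) > 0
  pct <- rowSums(dominates) / (n - 1)
  pct[!has_rel] <- NA_real_
  if (any(!has_rel)) {
    message(sum(!has_rel), " females have no decided relationships in group ",
            group, " year ", year, "; rank missing")
  }
  data.frame(id = roster, pct_dominated = as.numeric(pct),
             rank = ifelse(is.na(pct), NA_character_, rank_category(pct)),
             stringsAsFactors = FALSE)
}

# Attach the rank category per group-year to a metrics table.
add_rank_column <- function(out, ds) {
  ranks <- do.call(rbind, lapply(
    split(out, list(out$group, out$year), drop = TRUE),
    function(d) {
      roster <- d$id
      rk <- tryCatch(
        suppressMessages(assign_ranks(ds$agonism, d$group[1], d$year[1],
                                      roster)),
        error = function(e) data.frame(id = roster,
                                       pct_dominated = NA_real_,
                                       rank = NA_character_))
      cbind(rk, group = d$group[1], year = d$year[1])
    }))
  merge(out, ranks[, c("id", "group", "year", "rank")],
        by = c("id", "group", "year"), all.x = TRUE)
}

# Lean metrics for the recovery experiments: degrees, age and rank only.
degree_rank_metrics <- function(ds) {
  out <- degree_metrics(ds)
  out$age <- out$year - ds$animals$birth_year[match(out$id, ds$animals$id)]
  add_rank_column(out, ds)
}

#' Individual-year social metrics table
#'
#' Orchestrates [observation_effort()], [degree_metrics()],
#' [strength_metrics()], [assign_ranks()] and the dyadic-index module
#' into the per-female per-group-year analysis table: age, rank,
#' degrees, strengths, kin-partner proportion (partners are dyads with
#' DSI > 0), kin availability in the group, and the count of partners
#' that died the previous year.
#'
#' @param ds An `obs_dataset`.
#' @param r_min Kin threshold on relatedness.
#' @return A data frame with one row per female per group-year.
#' @export
individual_year_metrics <- function(ds, r_min = 0.125) {
  effort <- suppressMessages(observation_effort(ds))
  deg <- degree_metrics(ds)
  str <- strength_metrics(ds, effort)
  out <- merge(deg, str, by = c("id", "group", "year"))
  out$age <- out$year - ds$animals$birth_year[match(out$id, ds$animals$id)]

  out <- add_rank_column(out, ds)

  dyads <- dsi(dyadic_rates(ds, effort))
  dyads <- add_dyad_kinship(dyads, ds$animals, r_min)
  partners <- rbind(
    data.frame(id = dyads$id_a, partner = dyads$id_b, group = dyads$group,
               year = dyads$year, dsi = dyads$dsi, kin = dyads$kin),
    data.frame(id = dyads$id_b, partner = dyads$id_a, group = dyads$group,
               year = dyads$year, dsi = dyads$dsi, kin = dyads$kin))
  partners <- partners[partners$dsi > 0, , drop = FALSE]
  if (nrow(partners)) {
    pk <- stats::aggregate(
      list(n_partners = rep(1L, nrow(partners)),
           n_kin_partners = as.integer(partners$kin)),
      by = list(id = partners$id, group = partners$group,
                year = partners$year), FUN = sum)
  } else {
    pk <- data.frame(id = character(0), group = integer(0),
                     year = integer(0), n_partners = integer(0),
                     n_kin_partners = integer(0))
  }
  out <- merge(out, pk, by = c("id", "group", "year"), all.x = TRUE)
  out$n_partners[is.na(out$n_partners)] <- 0L
  out$n_kin_partners[is.na(out$n_kin_partners)] <- 0L
  out$n_nonkin_partners <- out$n_partners - out$n_kin_partners
  out$prop_kin_partners <- ifelse(out$n_partners > 0,
                                  out$n_kin_partners / out$n_partners,
                                  NA_real_)

  K <- kinship_matrix(ds$animals)
  out$kin_available <- NA_real_
  for (gy in split(seq_len(nrow(out)), paste(out$group, out$year))) {
    roster <- out$id[gy]
    if (length(roster) < 2) next
    Rsub <- 2 * K[roster, roster, drop = FALSE]
    kin <- Rsub >= r_min
    diag(kin) <- FALSE
    out$kin_available[gy] <- rowSums(kin) / (length(roster) - 1)
  }

  pd <- partner_deaths_table(dyads, ds$animals)
  out <- merge(out, pd, by = c("id", "year"), all.x = TRUE)
  out <- merge(out, effort[, c("id", "group", "year", "focal_seconds",
                               "scan_count")],
               by = c("id", "group", "year"), all.x = TRUE)
  out[order(out$group, out$year, out$id), ]
}
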