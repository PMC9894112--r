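#' Effort-normalized dyadic interaction rates
#'
#' For every unordered pair of observed subjects co-resident in a
#' group-year (never-interacting pairs included), computes the pooled
#' bidirectional grooming rate (seconds of grooming divided by the two
#' members' combined focal seconds) and the joint proximity rate (scans
#' in proximity divided by combined scan counts). Dyads whose combined
#' effort is zero are excluded with a message.
#'
#' @param ds An `obs_dataset`.
#' @param effort Output of [observation_effort()].
#' @return A data frame: id_a, id_b (a < b), group, year, groom_seconds,
#'   prox_scans, groom_rate, prox_rate.
#' @export
dyadic_rates <- function(ds, effort = observation_effort(ds)) {
  eff <- effort[!effort$no_focals, , drop = FALSE]
  gg <- directed_groom_totals(ds)
  if (nrow(gg)) {
    a <- pmin(gg$actor_id, gg$receiver_id)
    b <- pmax(gg$actor_id, gg$receiver_id)
    gg <- stats::aggregate(list(groom_seconds = gg$seconds),
                           by = list(id_a = a, id_b = b, group = gg$group,
                                     year = gg$year), FUN = sum)
  }
  jp <- joint_prox_counts(ds)

  out <- do.call(rbind, lapply(
    split(eff, list(eff$group, eff$year), drop = TRUE),
    function(d) {
      n <- nrow(d)
      if (n < 2) return(NULL)
      ids <- sort(d$id)
      pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      data.frame(id_a = ids[pr[, 1]], id_b = ids[pr[, 2]],
                 group = d$group[1], year = d$year[1],
                 stringsAsFactors = FALSE)
    }))
  if (is.null(out)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      group = integer(0), year = integer(0),
                      groom_seconds = numeric(0), prox_scans = integer(0),
                      groom_rate = numeric(0), prox_rate = numeric(0)))
  }
  if (nrow(gg)) {
    out <- merge(out, gg, by = c("id_a", "id_b", "group", "year"),
                 all.x = TRUE)
  } else out$groom_seconds <- 0
  if (nrow(jp)) {
    out <- merge(out, jp, by = c("id_a", "id_b", "group", "year"),
                 all.x = TRUE)
    names(out)[names(out) == "scans"] <- "prox_scans"
  } else out$prox_scans <- 0L
  out$groom_seconds[is.na(out$groom_seconds)] <- 0
  out$prox_scans[is.na(out$prox_scans)] <- 0L

  fs <- stats::setNames(eff$focal_seconds, paste(eff$id, eff$group, eff$year))
  sc <- stats::setNames(eff$scan_count, paste(eff$id, eff$group, eff$year))
  ka <- paste(out$id_a, out$group, out$year)
  kb <- paste(out$id_b, out$group, out$year)
  joint_fs <- fs[ka] + fs[kb]
  joint_sc <- sc[ka] + sc[kb]
  zero <- joint_fs == 0 & joint_sc == 0
  if (any(zero)) {
    message(sum(zero), " dyads with zero combined effort excluded")
    out <- out[!zero, , drop = FALSE]
    joint_fs <- joint_fs[!zero]; joint_sc <- joint_sc[!zero]
  }
  out$groom_rate <- ifelse(joint_fs > 0, out$groom_seconds / joint_fs, 0)
  out$prox_rate <- ifelse(joint_sc > 0, out$prox_scans / joint_sc, 0)
  rownames(out) <- NULL
  out[order(out$group, out$year, out$id_a, out$id_b), ]
}

#' Dyadic sociality index
#'
#' Standardizes each behavior's dyadic rate by the mean rate over all
#' subject dyads in the same group-year (zeros included) and averages the
#' standardized grooming and proximity rates:
#' `dsi = (groom_std + prox_std) / 2`. A DSI of 0 marks a dyad that never
#' interacted; 1 is the average dyad; the group-year mean DSI is exactly
#' 1 whenever any interaction occurred. If one behavior was never
#' observed in a group-year its standardized term is defined as 0 for all
#' dyads (with a message).
#'
#' @param rates Output of [dyadic_rates()].
#' @param behaviors Which behaviors enter the index (default both).
#' @return `rates` with groom_std, prox_std and dsi columns appended.
#' @export
dsi <- function(rates, behaviors = c("groom", "prox")) {
  behaviors <- match.arg(behaviors, several.ok = TRUE)
  if (!nrow(rates)) {
    rates$groom_std <- numeric(0); rates$prox_std <- numeric(0)
    rates$dsi <- numeric(0)
    return(rates)
  }
  key <- paste(rates$group, rates$year)
  std_one <- function(rate) {
    m <- stats::ave(rate, key, FUN = mean)
    ifelse(m > 0, rate / m, 0)
  }
  rates$groom_std <- if ("groom" %in% behaviors) std_one(rates$groom_rate)
    else 0
  rates$prox_std <- if ("prox" %in% behaviors) std_one(rates$prox_rate)
    else 0
  none_groom <- tapply(rates$groom_rate, key, function(x) all(x == 0))
  if ("groom" %in% behaviors && any(none_groom)) {
    message(sum(none_groom),
            " group-years with no grooming: grooming term set to 0")
  }
  rates$dsi <- (rates$groom_std + rates$prox_std) / length(behaviors)
  rates
}

#' Attach pedigree kinship to a dyad table
#'
#' @param dyads A table with id_a, id_b columns.
#' @param animals Pedigree table.
#' @param r_min Kin threshold.
#' @param K Optional precomputed kinship matrix.
#' @return `dyads` with `r` and `kin` columns.
#' @export
add_dyad_kinship <- function(dyads, animals, r_min = 0.125, K = NULL) {
  if (is.null(K)) K <- kinship_matrix(animals)
  if (!nrow(dyads)) {
    dyads$r <- numeric(0); dyads$kin <- logical(0)
    return(dyads)
  }
  dyads$r <- 2 * K[cbind(dyads$id_a, dyads$id_b)]
  dyads$kin <- is_kin(dyads$r, r_min)
  dyads
}

#' Partners that died the previous year
#'
#' A female's partners in year \eqn{t-1} are the individuals with whom she
#' had DSI > 0 that year; the count is how many of them have
#' `death_year == t - 1`. The count is missing (not zero) when the female
#' was not observed in year \eqn{t-1}.
#'
#' @param dyads A DSI table (see [dsi()]) covering the study years.
#' @param animals Pedigree/roster table with death_year.
#' @param subject,year Subject id and focal year \eqn{t} for the scalar
#'   form.
#' @return `partner_deaths`: an integer count or `NA`.
#'   `partner_deaths_table`: a data frame id, year,
#'   partner_deaths_prev_year covering all subject-years in `dyads`.
#' @export
partner_deaths <- function(dyads, animals, subject, year) {
  obs_years <- unique(c(dyads$year[dyads$id_a == subject],
                        dyads$year[dyads$id_b == subject]))
  if (!(year - 1) %in% obs_years) return(NA_integer_)
  prev <- dyads[dyads$year == year - 1 &
                  (dyads$id_a == subject | dyads$id_b == subject) &
                  dyads$dsi > 0, , drop = FALSE]
  if (!nrow(prev)) return(0L)
  partners <- ifelse(prev$id_a == subject, prev$id_b, prev$id_a)
  dy <- animals$death_year[match(partners, animals$id)]
  sum(!is.na(dy) & dy == year - 1)
}

#' @rdname partner_deaths
#' @export
partner_deaths_table <- function(dyads, animals) {
  subj_years <- unique(rbind(
    data.frame(id = dyads$id_a, year = dyads$year),
    data.frame(id = dyads$id_b, year = dyads$year)))
  obs_key <- paste(subj_years$id, subj_years$year)
  prev <- dyads[dyads$dsi > 0, , drop = FALSE]
  long <- rbind(
    data.frame(id = prev$id_a, partner = prev$id_b, year = prev$year),
    data.frame(id = prev$id_b, partner = prev$id_a, year = prev$year))
  dyr <- animals$death_year[match(long$partner, animals$id)]
  long$died <- !is.na(dyr) & dyr == long$year
  counts <- stats::aggregate(list(deaths = as.integer(long$died)),
                             by = list(id = long$id, year = long$year),
                             FUN = sum)
  out <- subj_years
  m <- match(paste(out$id, out$year - 1), paste(counts$id, counts$year))
  out$partner_deaths_prev_year <- ifelse(
    paste(out$id, out$year - 1) %in% obs_key,
    ifelse(is.na(m), 0L, counts$deaths[m]),
    NA_integer_)
  out
}

#' Stable-partner flag for one dyad
#'
#' A dyad counts as stable before `final_year` when it had DSI > 0 in at
#' least two consecutive years strictly before `final_year`. A single
#' year of prior data can never yield a stable flag.
#'
#' @param years Years with DSI records for the dyad.
#' @param dsi_values DSI values matching `years`.
#' @param final_year The dyad's final (choice) year.
#' @return Logical.
#' @examples
#' stable_partner_flag(2014:2016, c(0, 0.4, 0.7), 2017)   # TRUE
#' stable_partner_flag(2014:2016, c(0.5, 0, 0.6), 2017)   # FALSE
#' @export
stable_partner_flag <- function(years, dsi_values, final_year) {
  keep <- years < final_year
  years <- years[keep]; dsi_values <- dsi_values[keep]
  if (length(years) < 2) return(FALSE)
  pos <- years[dsi_values > 0]
  any(diff(sort(pos)) == 1)
}

#' Build the last-year dyadic dataset for partner-choice models
#'
#' Subsets each subject to her final observed group-year and pairs her
#' with every potential partner present there. For each dyad the mean
#' prior DSI is averaged over the years both members were co-resident
#' subjects before the final year (zero when there are none, including
#' partners first observed in the final year), the stable-partner flag
#' follows [stable_partner_flag()], and `chosen` records whether the
#' final-year DSI was positive. Subjects need at least 2 years of data to
#' enter at all (dropped with a message otherwise) and at least 3 for the
#' stability analysis (`eligible_stability`); dropped subjects remain
#' available as partners of others.
#'
#' @param dyads DSI table over all study years (see [dsi()]), with
#'   kinship attached or an `animals` table supplied.
#' @param metrics Individual-year metrics table (id, group, year, age,
#'   rank) defining who was an observed subject where and when.
#' @param animals Pedigree table (used if `dyads` lacks kinship columns).
#' @param r_min Kin threshold.
#' @return A data frame with one row per subject x potential partner.
#' @export
build_last_year_dataset <- function(dyads, metrics, animals = NULL,
                                    r_min = 0.125) {
  if (!all(c("r", "kin") %in% names(dyads))) {
    if (is.null(animals)) stop("need kinship columns in dyads or an animals table")
    dyads <- add_dyad_kinship(dyads, animals, r_min)
  }
  n_years_obs <- tapply(metrics$year, metrics$id,
                        function(y) length(unique(y)))
  final_year <- tapply(metrics$year, metrics$id, max)
  eligible <- names(n_years_obs)[n_years_obs >= 2]
  dropped <- sum(n_years_obs < 2)
  if (dropped) {
    message(dropped,
            " subjects with a single year of data excluded as subjects ",
            "(retained as partners)")
  }
  memkey <- paste(metrics$id, metrics$group, metrics$year)
  dkey_a <- paste(dyads$id_a, dyads$year)
  dget <- function(s, p, yrs) {
    sel <- (dyads$id_a == pmin(s, p) & dyads$id_b == pmax(s, p) &
              dyads$year %in% yrs)
    dyads[sel, c("year", "dsi"), drop = FALSE]
  }

  rows <- lapply(eligible, function(s) {
    fy <- final_year[[s]]
    sg <- metrics$group[metrics$id == s & metrics$year == fy][1]
    roster <- metrics$id[metrics$group == sg & metrics$year == fy]
    partners <- setdiff(roster, s)
    if (!length(partners)) return(NULL)
    # co-residence years before the final year, per partner
    s_years <- metrics$year[metrics$id == s]
    prior <- lapply(partners, function(p) {
      p_rows <- metrics$id == p
      co <- intersect(
        paste(metrics$group[metrics$id == s],
              metrics$year[metrics$id == s]),
        paste(metrics$group[p_rows], metrics$year[p_rows]))
      co_years <- as.integer(sub("^\\S+ ", "", co))
      co_years[co_years < fy]
    })
    sub <- dyads[(dyads$id_a == s | dyads$id_b == s), , drop = FALSE]
    other <- ifelse(sub$id_a == s, sub$id_b, sub$id_a)
    out <- do.call(rbind, lapply(seq_along(partners), function(k) {
      p <- partners[k]
      yrs <- prior[[k]]
      hist <- sub[other == p & sub$year %in% yrs, , drop = FALSE]
      dsi_by_year <- stats::setNames(rep(0, length(yrs)), yrs)
      dsi_by_year[as.character(hist$year)] <- hist$dsi
      final_row <- sub[other == p & sub$year == fy, , drop = FALSE]
      data.frame(
        subject_id = s, partner_id = p, group = sg, final_year = fy,
        n_prior_years = length(yrs),
        mean_prior_dsi = if (length(yrs)) mean(dsi_by_year) else 0,
        stable_prior = stable_partner_flag(as.integer(names(dsi_by_year)),
                                           as.numeric(dsi_by_year), fy),
        chosen = nrow(final_row) == 1 && final_row$dsi > 0,
        kin = if (nrow(final_row)) final_row$kin else NA,
        r = if (nrow(final_row)) final_row$r else NA_real_,
        stringsAsFactors = FALSE)
    }))
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no eligible subjects for the last-year dataset")
  # subject and partner attributes from the metrics table
  mkey <- paste(metrics$id, metrics$year)
  ms <- match(paste(out$subject_id, out$final_year), mkey)
  mp <- match(paste(out$partner_id, out$final_year), mkey)
  out$subject_age <- metrics$age[ms]
  out$partner_age <- metrics$age[mp]
  out$partner_rank <- metrics$rank[mp]
  out$subject_years_of_data <- as.integer(n_years_obs[out$subject_id])
  out$eligible_stability <- out$subject_years_of_data >= 3
  rownames(out) <- NULL
  out
}
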