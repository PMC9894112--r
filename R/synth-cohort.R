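#' Generate a synthetic matrilineal pedigree and group membership
#'
#' Simulates demography only: matriline founders, yearly daughter
#' recruitment, and mortality from a Gompertz-like hazard that can depend
#' on a latent per-female sociability (the selective-disappearance
#' mechanism, see [sim_params()]). Burn-in years before the study window
#' let matrilines accumulate several adult generations, so the pedigree
#' carries mothers, sisters, aunts and cousins at study start. Juvenile
#' survival to maturity is deterministic; the hazard applies from
#' maturity onward.
#'
#' @param params A [sim_params()] object.
#' @return A list with `animals` (id, sex, birth_year, death_year,
#'   mother_id, matriline, group), `membership` (id, group, year; one row
#'   per adult female per study year alive), and `sociability` (id,
#'   sociability) carrying the latent trait used by the hazard.
#' @examples
#' ped <- generate_pedigree(sim_params(n_matrilines = 6, n_years = 3))
#' head(ped$animals)
#' @export
generate_pedigree <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  generate_pedigree_impl(params)
}

generate_pedigree_impl <- function(params) {
  p <- params
  y0 <- 1L - p$burnin_years                # first simulated year
  founder_age <- sample(seq(p$founders_age_range[1], p$founders_age_range[2]),
                        p$n_matrilines, replace = TRUE)
  ids <- sprintf("F%04d", seq_len(p$n_matrilines))
  animals <- data.frame(
    id = ids, sex = "F",
    birth_year = y0 - founder_age,
    death_year = NA_integer_,
    mother_id = NA_character_,
    matriline = seq_len(p$n_matrilines),
    group = ((seq_len(p$n_matrilines) - 1L) %% p$n_groups) + 1L,
    stringsAsFactors = FALSE
  )
  soc <- stats::rnorm(p$n_matrilines, 0, p$sociability_sd)
  slp <- stats::rnorm(p$n_matrilines, 0, p$slope_sd)
  next_id <- p$n_matrilines + 1L

  for (y in y0:p$n_years) {
    alive <- is.na(animals$death_year)
    age <- y - animals$birth_year
    # births: adult females may recruit a daughter this year
    mothers <- which(alive & age >= p$maturity_age)
    if (length(mothers) && p$birth_rate > 0) {
      gets <- mothers[stats::runif(length(mothers)) < p$birth_rate]
      if (length(gets)) {
        k <- length(gets)
        kids <- data.frame(
          id = sprintf("F%04d", next_id:(next_id + k - 1L)),
          sex = "F", birth_year = y, death_year = NA_integer_,
          mother_id = animals$id[gets],
          matriline = animals$matriline[gets],
          group = animals$group[gets],
          stringsAsFactors = FALSE
        )
        next_id <- next_id + k
        animals <- rbind(animals, kids)
        soc <- c(soc, stats::rnorm(k, 0, p$sociability_sd))
        slp <- c(slp, stats::rnorm(k, 0, p$slope_sd))
        alive <- c(alive, rep(TRUE, k))
        age <- c(age, rep(0L, k))
      }
    }
    # deaths: hazard applies to adults; sociability shifts survival
    adults <- which(alive & age >= p$maturity_age)
    if (length(adults) && p$mortality_base > 0) {
      h <- p$mortality_base *
        exp(p$mortality_age_slope * (age[adults] - p$maturity_age) -
              p$delta_select * soc[adults])
      dies <- adults[stats::runif(length(adults)) < (1 - exp(-h))]
      animals$death_year[dies] <- y
    }
  }

  # membership: adult females present in each study year
  mem <- do.call(rbind, lapply(seq_len(p$n_years), function(y) {
    age <- y - animals$birth_year
    present <- age >= p$maturity_age &
      (is.na(animals$death_year) | animals$death_year >= y)
    if (!any(present)) return(NULL)
    data.frame(id = animals$id[present], group = animals$group[present],
               year = y, stringsAsFactors = FALSE)
  }))
  if (is.null(mem)) {
    mem <- data.frame(id = character(0), group = integer(0), year = integer(0))
  }
  list(animals = animals, membership = mem,
       sociability = data.frame(id = animals$id, sociability = soc,
                                slope_dev = slp, stringsAsFactors = FALSE))
}

# Matriline dominance order with youngest ascendancy: daughters sit
# immediately below their mother, youngest daughter (and her descendants)
# above older sisters; matrilines ranked by founder index.
rank_order_group <- function(animals, group) {
  ga <- animals[animals$group == group, , drop = FALSE]
  kids_of <- split(ga$id[!is.na(ga$mother_id)],
                   ga$mother_id[!is.na(ga$mother_id)])
  by <- stats::setNames(ga$birth_year, ga$id)
  visit <- function(id) {
    kids <- kids_of[[id]]
    if (is.null(kids)) return(id)
    kids <- kids[order(-by[kids])]
    c(id, unlist(lapply(kids, visit), use.names = FALSE))
  }
  founders <- ga$id[is.na(ga$mother_id)]
  founders <- founders[order(ga$matriline[match(founders, ga$id)])]
  unlist(lapply(founders, visit), use.names = FALSE)
}

rank_category <- function(pct_dominated) {
  ifelse(pct_dominated >= 0.80, "high",
         ifelse(pct_dominated >= 0.50, "medium", "low"))
}

#' Simulate a full event-level behavioral observation dataset
#'
#' Runs the demographic model of [generate_pedigree()], then generates,
#' for every group-year, a symmetric set of dyadic bonds among the adult
#' females and realizes them as focal-sample event records: grooming bouts
#' (each female's age-invariant annual grooming budget split over her
#' bonds), proximity scans, approach events, and decided agonistic
#' interactions consistent with the matrilineal hierarchy.
#'
#' The bond model gives female *i* in a group with target rates
#' \eqn{\lambda_k = \exp(\alpha + \beta_w (age_k - ref) + s_k + rank terms)}
#' a bond with female *j* with probability
#' \eqn{p_{ij} = \lambda_i \lambda_j w_{ij} / \sum_k \lambda_k} (capped),
#' where the dyadic weight \eqn{w_{ij}} (normalized to mean 1 in the
#' group-year) is multiplicative in kin preference, previous-year bond
#' intensity, and stability. Each female's expected bond count is then
#' \eqn{\lambda_i}, so her observed grooming degree is approximately
#' Poisson with log-linear age structure matching the generating slope.
#'
#' @param params A [sim_params()] object.
#' @return A list with `dataset` (an `obs_dataset`: animals, membership,
#'   focals, grooming, proximity, approaches, agonism tables) and `truth`
#'   (a `truth_record`: per-female latent sociability, per-female-year
#'   expected partner count lambda, realized bonds, rank, and the
#'   parameters used).
#' @examples
#' sim <- simulate_dataset(sim_params(n_matrilines = 6, n_years = 2,
#'                                    n_focals_per_subject_year = 5))
#' names(sim$dataset)
#' @export
simulate_dataset <- function(params) {
  validate_sim_params(params)
  p <- params
  set.seed(p$seed)
  ped <- generate_pedigree_impl(p)
  animals <- ped$animals
  soc <- stats::setNames(ped$sociability$sociability, ped$sociability$id)
  slp <- stats::setNames(ped$sociability$slope_dev, ped$sociability$id)
  K <- kinship_matrix(animals)
  R <- 2 * K

  groups <- sort(unique(animals$group))
  u_group <- stats::setNames(stats::rnorm(length(groups), 0, p$group_effect_sd),
                             groups)
  u_year <- stats::rnorm(p$n_years, 0, p$year_effect_sd)
  dom_order <- lapply(groups, function(g) rank_order_group(animals, g))
  names(dom_order) <- as.character(groups)

  # per-group memory of last two years' bonds and last year's intensity
  grp_ids <- lapply(groups, function(g) animals$id[animals$group == g])
  names(grp_ids) <- as.character(groups)
  mem_u <- lapply(grp_ids, function(ids)
    matrix(0, length(ids), length(ids), dimnames = list(ids, ids)))
  mem_b1 <- lapply(grp_ids, function(ids)
    matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids)))
  mem_b2 <- mem_b1

  focals <- list(); grooming <- list(); proximity <- list()
  approaches <- list(); agonism <- list(); truth_years <- list()
  n_scans <- p$n_focals_per_subject_year * p$scans_per_focal
  capacity_warn <- FALSE

  for (y in seq_len(p$n_years)) {
    for (g in groups) {
      ids <- ped$membership$id[ped$membership$year == y &
                                 ped$membership$group == g]
      n <- length(ids)
      if (n == 0L) next
      age <- y - animals$birth_year[match(ids, animals$id)]
      # dominance: restrict the static matriline order to this year's adults
      ord <- dom_order[[as.character(g)]]
      pos <- match(ids, ord)
      pct_dom <- if (n > 1) (rank(-pos) - 1) / (n - 1) else rep(NA_real_, n)
      rcat <- rank_category(pct_dom)

      lam <- exp(p$alpha_partners +
                   (p$beta_within + slp[ids] +
                      p$beta_rank_interaction * (rcat %in% "low")) *
                   (age - p$ref_age) + soc[ids] +
                   u_group[as.character(g)] + u_year[y])
      if (any(lam > n - 1)) {
        if (!capacity_warn) {
          warning("group ", g, " year ", y,
                  ": target partner count exceeds group size - 1; truncated")
          capacity_warn <- TRUE
        }
        lam <- pmin(lam, n - 1)
      }

      # focal sessions for every adult female (all are subjects)
      fid <- outer(seq_len(p$n_focals_per_subject_year), ids,
                   function(k, id) sprintf("%s_y%02d_f%03d", id, y, k))
      focals[[length(focals) + 1L]] <- data.frame(
        focal_id = as.vector(fid),
        subject_id = rep(ids, each = p$n_focals_per_subject_year),
        group = g, year = y, duration_s = p$focal_duration_s,
        stringsAsFactors = FALSE)

      # agonism: one decided interaction per pair, winner = higher rank
      if (n > 1) {
        pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        hi <- ifelse(pos[pr[, 1]] < pos[pr[, 2]], pr[, 1], pr[, 2])
        lo <- ifelse(pos[pr[, 1]] < pos[pr[, 2]], pr[, 2], pr[, 1])
        agonism[[length(agonism) + 1L]] <- data.frame(
          group = g, year = y, winner_id = ids[hi], loser_id = ids[lo],
          stringsAsFactors = FALSE)
      }

      if (n < 2) {
        truth_years[[length(truth_years) + 1L]] <- data.frame(
          id = ids, year = y, group = g, age = age, lambda = lam,
          rank = rcat, n_bonds = 0L, stringsAsFactors = FALSE)
        next
      }

      # dyadic weights: kin preference rising with mean dyad age,
      # previous-year intensity, stability over two consecutive years
      u_prev <- mem_u[[as.character(g)]][ids, ids, drop = FALSE]
      b1 <- mem_b1[[as.character(g)]][ids, ids, drop = FALSE]
      b2 <- mem_b2[[as.character(g)]][ids, ids, drop = FALSE]
      kin <- R[ids, ids] >= p$kin_threshold
      mean_age <- outer(age, age, `+`) / 2
      logw <- kin * (p$kin_pref_base +
                       p$kin_pref_slope * (mean_age - p$ref_age)) +
        p$w_prev_dsi * u_prev + p$w_stable * (b1 & b2)
      W <- exp(logw)
      ut <- upper.tri(W)
      W <- W / mean(W[ut])
      P <- calibrate_bond_probs(lam, W)
      B <- matrix(FALSE, n, n, dimnames = list(ids, ids))
      B[ut] <- stats::runif(sum(ut)) < P[ut]
      B <- B | t(B)

      deg <- rowSums(B)
      truth_years[[length(truth_years) + 1L]] <- data.frame(
        id = ids, year = y, group = g, age = age, lambda = lam,
        rank = rcat, n_bonds = as.integer(deg), stringsAsFactors = FALSE)

      edges <- which(B & ut, arr.ind = TRUE)   # i < j in position order
      if (nrow(edges)) {
        ev <- simulate_events_group(p, ids, y, edges, B, deg, n_scans)
        grooming[[length(grooming) + 1L]] <- ev$grooming
        proximity[[length(proximity) + 1L]] <- ev$proximity
        approaches[[length(approaches) + 1L]] <- ev$approaches
        # update dyadic memory for next year's partner choice
        U <- matrix(0, n, n, dimnames = list(ids, ids))
        pooled <- ev$pooled   # data.frame a, b, seconds
        ix <- cbind(match(pooled$a, ids), match(pooled$b, ids))
        U[ix] <- pooled$seconds; U[ix[, c(2, 1), drop = FALSE]] <- pooled$seconds
        if (any(U > 0)) U <- U / mean(U[ut][B[ut]])
        mem_u[[as.character(g)]][ids, ids] <- U
      } else {
        mem_u[[as.character(g)]][ids, ids] <- 0
      }
      mem_b2[[as.character(g)]][ids, ids] <- b1
      mem_b1[[as.character(g)]][ids, ids] <- B
    }
  }

  ds <- structure(list(
    animals = animals[, c("id", "sex", "birth_year", "death_year", "mother_id")],
    membership = ped$membership,
    focals = do.call(rbind, focals),
    grooming = rbind_or_empty(grooming,
      c("focal_id", "actor_id", "receiver_id", "duration_s")),
    proximity = rbind_or_empty(proximity,
      c("focal_id", "scan_index", "subject_id", "neighbor_id")),
    approaches = rbind_or_empty(approaches,
      c("focal_id", "actor_id", "receiver_id")),
    agonism = rbind_or_empty(agonism,
      c("group", "year", "winner_id", "loser_id")),
    params = p
  ), class = "obs_dataset")

  truth <- structure(list(
    individuals = ped$sociability,
    years = do.call(rbind, truth_years),
    params = p
  ), class = "truth_record")

  list(dataset = ds, truth = truth)
}

# Symmetric bond-probability matrix whose expected row sums match the
# target partner counts. Starts from p_ij = lambda_i lambda_j w_ij /
# sum(lambda) and applies symmetric iterative proportional scaling under
# a probability cap, so the cap does not bias each female's expected
# degree away from her lambda.
calibrate_bond_probs <- function(lam, W, cap = 0.95, iters = 25) {
  n <- length(lam)
  P <- outer(lam, lam) * W / sum(lam)
  diag(P) <- 0
  P <- pmin(P, cap)
  for (k in seq_len(iters)) {
    rs <- rowSums(P)
    a <- sqrt(lam / pmax(rs, 1e-12))
    P <- P * outer(a, a)
    diag(P) <- 0
    P <- pmin(P, cap)
  }
  P
}

# Realize one group-year's bonds as grooming bouts, proximity scans and
# approaches. `edges` indexes bonded pairs (i < j) into `ids`.
simulate_events_group <- function(p, ids, y, edges, B, deg, n_scans) {
  n <- length(ids)
  budget <- stats::rgamma(n, shape = 1 / p$groom_cv^2,
                          scale = p$total_groom_mean_s * p$groom_cv^2)
  # directed giving: each female splits her budget over her bonds
  give_actor <- integer(0); give_recv <- integer(0); give_s <- numeric(0)
  for (i in seq_len(n)) {
    part <- which(B[i, ])
    if (!length(part)) next
    sh <- stats::rgamma(length(part), shape = 2)
    sh <- sh / sum(sh)
    give_actor <- c(give_actor, rep(i, length(part)))
    give_recv <- c(give_recv, part)
    give_s <- c(give_s, budget[i] * sh)
  }
  # cut directed totals into exponential-ish bouts
  nb <- pmax(1L, stats::rpois(length(give_s), give_s / p$groom_bout_mean_s))
  bout_edge <- rep(seq_along(give_s), nb)
  raw <- stats::rgamma(length(bout_edge), shape = 1)
  tot <- stats::ave(raw, bout_edge, FUN = sum)
  bout_s <- raw / tot * give_s[bout_edge]
  actor <- give_actor[bout_edge]
  # place bouts in random focals of the actor; rescale overfull focals
  fk <- sample.int(p$n_focals_per_subject_year, length(bout_edge),
                   replace = TRUE)
  key <- actor * 1000L + fk
  fsum <- stats::ave(bout_s, key, FUN = sum)
  over <- fsum > 0.95 * p$focal_duration_s
  bout_s[over] <- bout_s[over] * 0.95 * p$focal_duration_s / fsum[over]
  grooming <- data.frame(
    focal_id = sprintf("%s_y%02d_f%03d", ids[actor], y, fk),
    actor_id = ids[actor],
    receiver_id = ids[give_recv[bout_edge]],
    duration_s = round(bout_s, 1),
    stringsAsFactors = FALSE)
  grooming <- grooming[grooming$duration_s > 0, , drop = FALSE]

  # pooled seconds per unordered bond (for the dyadic memory)
  a <- pmin(give_actor, give_recv); b <- pmax(give_actor, give_recv)
  pk <- paste(a, b)
  pooled_s <- tapply(give_s, pk, sum)
  pab <- do.call(rbind, strsplit(names(pooled_s), " "))
  pooled <- data.frame(a = ids[as.integer(pab[, 1])],
                       b = ids[as.integer(pab[, 2])],
                       seconds = as.numeric(pooled_s),
                       stringsAsFactors = FALSE)

  # proximity: expected neighbors per scan is held constant, shared
  # across a female's bonds, so proximity time does not scale with
  # partner number and strengths stay bounded
  ne <- nrow(edges)
  side <- rbind(edges, edges[, c(2, 1), drop = FALSE])  # subject, neighbor
  p_dyad <- pmin(0.9, p$prox_neighbors_per_scan /
                   pmax(deg[side[, 1]], deg[side[, 2]], 1))
  hits <- matrix(stats::runif(2 * ne * n_scans) < p_dyad,
                 nrow = 2 * ne)
  hit_ix <- which(hits, arr.ind = TRUE)
  subj <- side[hit_ix[, 1], 1]
  neigh <- side[hit_ix[, 1], 2]
  slot <- hit_ix[, 2]
  fk2 <- ((slot - 1L) %/% p$scans_per_focal) + 1L
  sc <- ((slot - 1L) %% p$scans_per_focal) + 1L
  proximity <- data.frame(
    focal_id = sprintf("%s_y%02d_f%03d", ids[subj], y, fk2),
    scan_index = sc,
    subject_id = ids[subj],
    neighbor_id = ids[neigh],
    stringsAsFactors = FALSE)

  # approaches: Poisson count per ordered bonded pair, in actor's focals
  napp <- stats::rpois(2 * ne, p$approach_rate)
  arow <- rep(seq_len(2 * ne), napp)
  aact <- side[arow, 1]; arecv <- side[arow, 2]
  afk <- sample.int(p$n_focals_per_subject_year, length(arow), replace = TRUE)
  approaches <- data.frame(
    focal_id = sprintf("%s_y%02d_f%03d", ids[aact], y, afk),
    actor_id = ids[aact],
    receiver_id = ids[arecv],
    stringsAsFactors = FALSE)

  list(grooming = grooming, proximity = proximity,
       approaches = approaches, pooled = pooled)
}

rbind_or_empty <- function(lst, cols) {
  lst <- Filter(Negate(is.null), lst)
  lst <- Filter(nrow, lst)
  if (!length(lst)) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    return(out)
  }
  do.call(rbind, lst)
}

#' @export
print.obs_dataset <- function(x, ...) {
  cat("Behavioral observation dataset\n")
  cat(sprintf("  %d animals, %d membership rows, %d focals\n",
              nrow(x$animals), nrow(x$membership), nrow(x$focals)))
  cat(sprintf("  %d grooming bouts, %d proximity records, %d approaches, %d agonistic outcomes\n",
              nrow(x$grooming), nrow(x$proximity), nrow(x$approaches),
              nrow(x$agonism)))
  invisible(x)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("Simulation ground truth:", nrow(x$individuals), "females,",
      nrow(x$years), "female-years\n")
  invisible(x)
}
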