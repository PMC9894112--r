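#' Pedigree kinship and kin classification
#'
#' Kinship coefficients are computed with the standard recursive
#' algorithm: ordering individuals so parents precede offspring,
#' \eqn{\phi(a,b) = \frac{1}{2}[\phi(m_a,b) + \phi(f_a,b)]} for a later-born
#' than b, and \eqn{\phi(x,x) = \frac{1}{2}[1 + \phi(m_x,f_x)]}. An unknown
#' parent contributes zero, so purely matrilineal pedigrees (no father
#' links) are supported; paternal kin are then invisible, as in many field
#' pedigrees. Relatedness is \eqn{r = 2\phi} and the kin/nonkin
#' classification uses the inclusive cutoff \eqn{r \ge 0.125} by default,
#' the level at which kin discrimination is typically observed in
#' cercopithecine affiliative behavior.
#'
#' @param animals A data frame with columns `id`, `mother_id`, and
#'   optionally `father_id` and `birth_year`. Missing parents are `NA`.
#' @return For `kinship_matrix`, a symmetric numeric matrix of kinship
#'   coefficients with dimnames = ids.
#' @examples
#' ped <- data.frame(id = c("M", "A"), mother_id = c(NA, "M"),
#'                   father_id = NA, birth_year = c(0, 5))
#' kinship_matrix(ped)["M", "A"]   # 0.25
#' relatedness(ped, "M", "A")      # 0.5
#' @name pedigree_kin
NULL

as_pedigree <- function(animals) {
  stopifnot(is.data.frame(animals), "id" %in% names(animals),
            "mother_id" %in% names(animals))
  if (!"father_id" %in% names(animals)) animals$father_id <- NA_character_
  animals$mother_id[animals$mother_id %in% ""] <- NA_character_
  animals$father_id[animals$father_id %in% ""] <- NA_character_
  if (anyDuplicated(animals$id)) stop("duplicate ids in pedigree")
  known <- function(p) !is.na(p) & !(p %in% animals$id)
  if (any(known(animals$mother_id)) || any(known(animals$father_id))) {
    stop("pedigree refers to parent ids that are not in the animal table")
  }
  animals
}

# Topological order: parents before offspring. Uses birth_year when
# present, otherwise Kahn's algorithm; cycles are a pedigree error.
pedigree_order <- function(animals) {
  ids <- animals$id
  if ("birth_year" %in% names(animals) && !anyNA(animals$birth_year)) {
    ord <- order(animals$birth_year)
    pos <- match(ids, ids[ord])
    mi <- match(animals$mother_id, ids)
    fi <- match(animals$father_id, ids)
    bad <- (!is.na(mi) & pos[mi] >= pos) | (!is.na(fi) & pos[fi] >= pos)
    if (any(bad)) stop("pedigree error: parent does not precede offspring by birth year")
    return(ids[ord])
  }
  mi <- match(animals$mother_id, ids)
  fi <- match(animals$father_id, ids)
  # children depend on parents: count unresolved parents per individual
  unresolved <- (!is.na(mi)) + (!is.na(fi))
  placed <- character(0)
  done <- rep(FALSE, length(ids))
  repeat {
    ready <- which(!done & unresolved == 0L)
    if (!length(ready)) break
    placed <- c(placed, ids[ready])
    done[ready] <- TRUE
    for (r in ready) {
      unresolved[which(mi == r)] <- unresolved[which(mi == r)] - 1L
      unresolved[which(fi == r)] <- unresolved[which(fi == r)] - 1L
    }
  }
  if (!all(done)) stop("pedigree error: cycle detected")
  placed
}

#' @rdname pedigree_kin
#' @export
kinship_matrix <- function(animals) {
  animals <- as_pedigree(animals)
  ord <- pedigree_order(animals)
  n <- length(ord)
  K <- matrix(0, n, n, dimnames = list(ord, ord))
  mo <- animals$mother_id[match(ord, animals$id)]
  fa <- animals$father_id[match(ord, animals$id)]
  mi <- match(mo, ord)
  fi <- match(fa, ord)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    if (i > 1L) {
      row <- numeric(i - 1L)
      if (!is.na(mi[i])) row <- row + 0.5 * K[mi[i], prev]
      if (!is.na(fi[i])) row <- row + 0.5 * K[fi[i], prev]
      K[i, prev] <- row
      K[prev, i] <- row
    }
    phi_mf <- if (!is.na(mi[i]) && !is.na(fi[i])) K[mi[i], fi[i]] else 0
    K[i, i] <- 0.5 * (1 + phi_mf)
  }
  K
}

#' @rdname pedigree_kin
#' @param a,b Individual ids present in the pedigree.
#' @export
kinship_coefficient <- function(animals, a, b) {
  animals <- as_pedigree(animals)
  if (!a %in% animals$id) stop("id not in pedigree: ", a)
  if (!b %in% animals$id) stop("id not in pedigree: ", b)
  K <- kinship_matrix(animals)
  unname(K[a, b])
}

#' @rdname pedigree_kin
#' @export
relatedness <- function(animals, a, b) {
  if (identical(a, b)) stop("relatedness is defined between distinct individuals")
  2 * kinship_coefficient(animals, a, b)
}

#' Classify a relatedness value as kin or nonkin
#'
#' Boundary-inclusive: `r` exactly at the threshold counts as kin.
#'
#' @param r Relatedness value(s) in \[0, 1\].
#' @param r_min Kin threshold (default 0.125).
#' @return Logical vector.
#' @examples
#' is_kin(c(0.5, 0.125, 0.0625))  # TRUE TRUE FALSE
#' @export
is_kin <- function(r, r_min = 0.125) {
  stopifnot(r_min > 0, r_min <= 1)
  if (any(r < 0 | r > 1, na.rm = TRUE)) stop("r must lie in [0, 1]")
  r >= r_min
}

#' Proportion of kin available to a focal female in a group-year roster
#'
#' The fraction of roster members, excluding the focal herself, whose
#' relatedness to the focal meets the kin threshold. Used as the
#' availability offset in the kin-proportion model.
#'
#' @param animals Pedigree table (see [kinship_matrix()]).
#' @param focal Focal id; must be in `roster`.
#' @param roster Character vector of adult-female ids co-resident with the
#'   focal in the group-year.
#' @param r_min Kin threshold.
#' @param K Optional precomputed kinship matrix covering all roster ids.
#' @return A proportion in \[0, 1\].
#' @export
kin_availability <- function(animals, focal, roster, r_min = 0.125, K = NULL) {
  roster <- unique(roster)
  if (!focal %in% roster) stop("focal must be part of the roster")
  others <- setdiff(roster, focal)
  if (!length(others)) stop("roster of size 1: kin availability undefined")
  if (is.null(K)) K <- kinship_matrix(animals)
  r <- 2 * K[focal, others]
  mean(is_kin(r, r_min))
}
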