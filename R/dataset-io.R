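#' Read and write observation datasets as CSV tables
#'
#' An observation dataset is stored as seven plain CSV files in one
#' directory: `animals.csv`, `membership.csv`, `focals.csv`,
#' `grooming.csv`, `proximity.csv`, `approaches.csv`, `agonism.csv`.
#' A missing `death_year` is written as an empty field. When a simulation
#' truth record is supplied, `truth.csv` (one row per female-year with the
#' latent sociability and expected partner count) is written alongside.
#'
#' @param ds An `obs_dataset` (see [simulate_dataset()]).
#' @param dir Directory to write to / read from; created if needed.
#' @param truth Optional `truth_record` to write as `truth.csv`.
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns
#'   a validated `obs_dataset`.
#' @export
write_dataset <- function(ds, dir, truth = NULL) {
  stopifnot(inherits(ds, "obs_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in dataset_tables()) {
    utils::write.csv(ds[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE, na = "")
  }
  if (!is.null(truth)) {
    ty <- merge(truth$years, truth$individuals, by = "id", sort = FALSE)
    utils::write.csv(ty, file.path(dir, "truth.csv"), row.names = FALSE,
                     na = "")
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @param validate Run [validate_dataset()] after reading (default TRUE).
#' @export
read_dataset <- function(dir, validate = TRUE) {
  paths <- file.path(dir, paste0(dataset_tables(), ".csv"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing dataset files: ", paste(basename(paths[missing]),
                                          collapse = ", "))
  }
  tabs <- lapply(paths, function(f)
    utils::read.csv(f, stringsAsFactors = FALSE))
  names(tabs) <- dataset_tables()
  tabs$animals$death_year <- suppressWarnings(
    as.integer(tabs$animals$death_year))
  tabs$animals$mother_id[tabs$animals$mother_id %in% ""] <- NA_character_
  ds <- structure(tabs, class = "obs_dataset")
  if (validate) validate_dataset(ds)
  ds
}

dataset_tables <- function() {
  c("animals", "membership", "focals", "grooming", "proximity",
    "approaches", "agonism")
}

#' Validate the structural invariants of an observation dataset
#'
#' Checks that every id in the event tables exists in the animal roster,
#' that event years fall within each subject's lifespan, that grooming
#' durations fit inside their focal sessions (both per bout and summed per
#' focal), that scan indices are positive integers, and that no
#' interaction pairs an animal with itself. Errors name the offending
#' table, row and column.
#'
#' @param ds An `obs_dataset`.
#' @return The dataset, invisibly, if valid; otherwise an error.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "obs_dataset") || is.list(ds))
  an <- ds$animals
  ids <- an$id
  fail <- function(tab, row, col, msg) {
    stop(sprintf("validation error in %s.csv, row %d, column %s: %s",
                 tab, row, col, msg), call. = FALSE)
  }
  check_ids <- function(tab, col) {
    v <- ds[[tab]][[col]]
    bad <- which(!v %in% ids)
    if (length(bad)) fail(tab, bad[1], col, paste("unknown id", v[bad[1]]))
  }
  check_ids("membership", "id")
  check_ids("focals", "subject_id")
  for (col in c("actor_id", "receiver_id")) check_ids("grooming", col)
  for (col in c("subject_id", "neighbor_id")) check_ids("proximity", col)
  for (col in c("actor_id", "receiver_id")) check_ids("approaches", col)
  for (col in c("winner_id", "loser_id")) check_ids("agonism", col)

  # event year within subject lifespan
  by <- an$birth_year[match(ds$focals$subject_id, ids)]
  dy <- an$death_year[match(ds$focals$subject_id, ids)]
  bad <- which(ds$focals$year < by | (!is.na(dy) & ds$focals$year > dy))
  if (length(bad)) {
    fail("focals", bad[1], "year", "focal outside subject's lifespan")
  }

  # grooming fits inside its focal
  fdur <- ds$focals$duration_s[match(ds$grooming$focal_id, ds$focals$focal_id)]
  orphan <- which(is.na(fdur))
  if (length(orphan)) fail("grooming", orphan[1], "focal_id", "unknown focal")
  bad <- which(ds$grooming$duration_s > fdur + 1e-9)
  if (length(bad)) {
    fail("grooming", bad[1], "duration_s",
         "bout longer than its focal session")
  }
  tot <- tapply(ds$grooming$duration_s, ds$grooming$focal_id, sum)
  cap <- ds$focals$duration_s[match(names(tot), ds$focals$focal_id)]
  if (any(tot > cap + 1e-6)) {
    f <- names(tot)[which(tot > cap + 1e-6)[1]]
    fail("grooming", which(ds$grooming$focal_id == f)[1], "duration_s",
         "summed grooming exceeds focal duration")
  }

  if (nrow(ds$proximity)) {
    si <- ds$proximity$scan_index
    bad <- which(is.na(si) | si < 1 | si != round(si))
    if (length(bad)) fail("proximity", bad[1], "scan_index", "invalid scan index")
  }
  selfpair <- function(tab, c1, c2) {
    bad <- which(ds[[tab]][[c1]] == ds[[tab]][[c2]])
    if (length(bad)) fail(tab, bad[1], c1, "actor equals receiver")
  }
  selfpair("grooming", "actor_id", "receiver_id")
  selfpair("proximity", "subject_id", "neighbor_id")
  selfpair("approaches", "actor_id", "receiver_id")
  selfpair("agonism", "winner_id", "loser_id")
  invisible(ds)
}
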