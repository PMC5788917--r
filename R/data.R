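#' @keywords internal
CONDITIONS <- c("face", "hand", "art")
#' @keywords internal
SOCIAL_RULES <- c("all", "top2", "bottom2")

TRIAL_COLUMNS <- c("participant_id", "group_id", "block_index", "condition",
                   "image_id", "social_rule", "initial_raw", "social_raw",
                   "final_raw")
PARTICIPANT_COLUMNS <- c("participant_id", "group_id", "orientation_score")

validate_trials <- function(trials) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing)) {
    stop(sprintf("trial table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("initial_raw", "social_raw", "final_raw")) {
    v <- trials[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop(sprintf("column %s is not numeric (first bad row: %d)",
                   col, if (length(bad)) bad[1] else 1L), call. = FALSE)
    }
    out <- which(v < 0 | v > 100)
    if (length(out)) {
      stop(sprintf("column %s has rating(s) outside [0, 100] at row(s): %s",
                   col, paste(utils::head(out, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  badc <- which(!trials$condition %in% CONDITIONS)
  if (length(badc)) {
    stop(sprintf("unknown condition at row(s) %s (allowed: %s)",
                 paste(utils::head(badc, 5), collapse = ", "),
                 paste(CONDITIONS, collapse = "|")), call. = FALSE)
  }
  badr <- which(!trials$social_rule %in% SOCIAL_RULES)
  if (length(badr)) {
    stop(sprintf("unknown social_rule at row(s) %s (allowed: %s)",
                 paste(utils::head(badr, 5), collapse = ", "),
                 paste(SOCIAL_RULES, collapse = "|")), call. = FALSE)
  }
  if (any(trials$block_index < 1)) {
    stop("block_index must be >= 1", call. = FALSE)
  }
  invisible(trials)
}

validate_participants <- function(participants) {
  missing <- setdiff(PARTICIPANT_COLUMNS, names(participants))
  if (length(missing)) {
    stop(sprintf("participant table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  s <- participants$orientation_score
  if (anyNA(s) || any(s != as.integer(s)) || any(s < 0 | s > 6)) {
    stop("orientation_score must be an integer in 0..6", call. = FALSE)
  }
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant_id in participant table", call. = FALSE)
  }
  invisible(participants)
}

#' Bundle trial and participant tables into a validated dataset
#'
#' A `social_dataset` holds one row per (participant, image) trial together
#' with the participant roster. Construction checks the trial schema
#' (columns, rating ranges, condition and rule labels), that every trial's
#' participant appears in the roster, and that no participant rated the same
#' image twice.
#'
#' @param trials Data frame with columns `participant_id`, `group_id`,
#'   `block_index`, `condition` (`face|hand|art`), `image_id`,
#'   `social_rule` (`all|top2|bottom2`), `initial_raw`, `social_raw`,
#'   `final_raw` (all ratings in `[0, 100]`).
#' @param participants Data frame with columns `participant_id`, `group_id`,
#'   `orientation_score` (integer 0--6; 0 = exclusively heterosexual).
#' @return An object of class `social_dataset`: a list with elements
#'   `trials` and `participants`.
#' @export
social_dataset <- function(trials, participants) {
  trials <- as.data.frame(trials)
  participants <- as.data.frame(participants)
  validate_trials(trials)
  validate_participants(participants)
  orphan <- setdiff(trials$participant_id, participants$participant_id)
  if (length(orphan)) {
    stop(sprintf("trials refer to unknown participant(s): %s",
                 paste(utils::head(orphan, 5), collapse = ", ")),
         call. = FALSE)
  }
  key <- paste(trials$participant_id, trials$image_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, image_id) pair in trials", call. = FALSE)
  }
  rownames(trials) <- NULL
  rownames(participants) <- NULL
  structure(list(trials = trials, participants = participants),
            class = "social_dataset")
}

#' @export
print.social_dataset <- function(x, ...) {
  cat(sprintf("social_dataset: %d trials, %d participants, %d groups\n",
              nrow(x$trials), nrow(x$participants),
              length(unique(x$participants$group_id))))
  tab <- table(x$trials$condition)
  cat("  trials per condition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read or write trial and participant tables as CSV
#'
#' `read_trials()`/`read_participants()` load and validate a table,
#' reporting the offending column or row on failure; `write_trials()`/
#' `write_participants()` write the exact column schema back, so that a
#' write--read round trip reproduces the table field for field.
#' `read_dataset()`/`write_dataset()` do both halves of a
#' [social_dataset()] at once.
#'
#' @param path File path of the CSV.
#' @param trials,participants Data frames as in [social_dataset()].
#' @param dataset A `social_dataset`.
#' @param trials_path,participants_path File paths for the two CSVs.
#' @return The readers return validated data frames (or a `social_dataset`);
#'   the writers return their input invisibly.
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(participant_id = "character",
                                           group_id = "character",
                                           image_id = "character"))
  for (col in c("initial_raw", "social_raw", "final_raw")) {
    if (col %in% names(trials)) trials[[col]] <- as.numeric(trials[[col]])
  }
  if ("block_index" %in% names(trials)) {
    trials$block_index <- as.integer(trials$block_index)
  }
  validate_trials(trials)
  trials
}

#' @rdname trial_io
#' @export
write_trials <- function(trials, path) {
  validate_trials(as.data.frame(trials))
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(trials)
}

#' @rdname trial_io
#' @export
read_participants <- function(path) {
  participants <- utils::read.csv(path, stringsAsFactors = FALSE,
                                  colClasses = c(participant_id = "character",
                                                 group_id = "character"))
  if ("orientation_score" %in% names(participants)) {
    participants$orientation_score <- as.integer(participants$orientation_score)
  }
  validate_participants(participants)
  participants
}

#' @rdname trial_io
#' @export
write_participants <- function(participants, path) {
  validate_participants(as.data.frame(participants))
  utils::write.csv(participants[, PARTICIPANT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(participants)
}

#' @rdname trial_io
#' @export
read_dataset <- function(trials_path, participants_path) {
  social_dataset(read_trials(trials_path), read_participants(participants_path))
}

#' @rdname trial_io
#' @export
write_dataset <- function(dataset, trials_path, participants_path) {
  stopifnot(inherits(dataset, "social_dataset"))
  write_trials(dataset$trials, trials_path)
  write_participants(dataset$participants, participants_path)
  invisible(dataset)
}

#' Restrict a dataset to (near-)heterosexual participants
#'
#' Keeps participants whose self-reported orientation score (7-point scale,
#' 0 = exclusively heterosexual, 6 = exclusively homosexual) is at most
#' `max_score`, together with their trials. The default `max_score = 1`
#' corresponds to the "exclusively or near-exclusively heterosexual"
#' inclusion rule of mate-choice-copying studies; `max_score = 6` keeps
#' everyone.
#'
#' @param dataset A [social_dataset()].
#' @param max_score Integer in 0..6; participants with
#'   `orientation_score <= max_score` are retained.
#' @return A new `social_dataset`; the input is unchanged.
#' @export
filter_heterosexual <- function(dataset, max_score = 1) {
  stopifnot(inherits(dataset, "social_dataset"))
  if (!is.numeric(max_score) || length(max_score) != 1 ||
      max_score < 0 || max_score > 6) {
    stop("max_score must be a single integer in 0..6", call. = FALSE)
  }
  keep <- dataset$participants$orientation_score <= max_score
  participants <- dataset$participants[keep, , drop = FALSE]
  trials <- dataset$trials[
    dataset$trials$participant_id %in% participants$participant_id, ,
    drop = FALSE]
  rownames(participants) <- NULL
  rownames(trials) <- NULL
  structure(list(trials = trials, participants = participants),
            class = "social_dataset")
}

# Adds initial_u/social_u/final_u columns (the transformed scale used by
# the likelihood).
transform_trials <- function(trials) {
  trials$initial_u <- rating_to_unit(trials$initial_raw)
  trials$social_u <- rating_to_unit(trials$social_raw)
  trials$final_u <- rating_to_unit(trials$final_raw)
  trials
}
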