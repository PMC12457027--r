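TRIAL_COLS <- c("subject_id", "t", "trait_id", "valence",
                "self", "role", "feedback")

#' Load a trial table from CSV
#'
#' Reads the fixed-schema trial CSV (`subject_id,t,trait_id,valence,self,
#' role,feedback`, raw 1-100 ratings, NA role = missed trial), validates it,
#' and reverse-codes all ratings of negative-valence traits onto the common
#' adaptive orientation.  All downstream model math operates on the recoded
#' scale.
#'
#' @param path CSV path.
#' @return trial tibble with an added logical `missing` column, recoded.
#' @export
load_trials <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(TRIAL_COLS, hdr)
  if (length(missing_cols)) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_integer(),
    t = readr::col_integer(),
    trait_id = readr::col_integer(),
    valence = readr::col_integer(),
    self = readr::col_double(),
    role = readr::col_double(),
    feedback = readr::col_double()
  ))
  row <- seq_len(nrow(df)) + 1L # header is line 1
  if (!all(df$valence %in% c(-1L, 1L))) {
    abort(sprintf("invalid valence at row %d", row[!df$valence %in% c(-1L, 1L)][1]))
  }
  for (col in c("self", "role", "feedback")) {
    x <- df[[col]]
    bad <- !is.na(x) & (x < RATING_MIN | x > RATING_MAX)
    if (any(bad)) {
      abort(sprintf("rating out of [1, 100] in `%s` at row %d", col, row[bad][1]))
    }
  }
  dup <- duplicated(df[, c("subject_id", "trait_id")])
  if (any(dup)) {
    abort(sprintf("duplicate (subject_id, trait_id) at row %d", row[dup][1]))
  }
  df$missing <- is.na(df$role)
  for (col in c("self", "role", "feedback")) {
    df[[col]] <- reverse_code(df[[col]], df$valence)
  }
  dplyr::arrange(tibble::as_tibble(df), .data$subject_id, .data$t)
}

#' Write a trial table to CSV in the raw (un-recoded) schema
#'
#' Inverse of [load_trials()]: ratings of negative-valence traits are mapped
#' back to the raw direction before writing, so `load_trials(write_trials(x))`
#' round-trips.
#'
#' @param trials recoded trial tibble.
#' @param path CSV path.
#' @return `trials`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- tibble::as_tibble(trials)
  for (col in c("self", "role", "feedback")) {
    out[[col]] <- reverse_code(out[[col]], out$valence)
  }
  readr::write_csv(out[, TRIAL_COLS], path, na = "")
  invisible(trials)
}

#' Apply the pre-registered exclusion rules to a cohort
#'
#' Excludes subjects that (i) missed strictly more than `max_missing` of the
#' designed trials (no role response), or (ii) gave one identical role rating
#' on strictly more than `max_identical` of their answered trials
#' (invariant responding).
#'
#' @param trials recoded trial tibble for the whole cohort.
#' @param max_missing maximal tolerated missing fraction (default 0.20).
#' @param max_identical maximal tolerated modal-rating share (default 0.80).
#' @return list with `kept` (trial tibble) and `excluded` (tibble of
#'   `subject_id`, `reason`, `value`).
#' @export
apply_exclusions <- function(trials, max_missing = 0.20, max_identical = 0.80) {
  stopifnot(max_missing > 0, max_missing <= 1,
            max_identical > 0, max_identical <= 1)
  per <- trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      frac_missing = mean(.data$missing),
      modal_share = {
        r <- .data$role[!.data$missing]
        if (length(r) == 0) 1 else max(table(r)) / length(r)
      },
      .groups = "drop"
    )
  excl <- dplyr::bind_rows(
    per |>
      dplyr::filter(.data$frac_missing > max_missing) |>
      dplyr::transmute(.data$subject_id, reason = "missing",
                       value = .data$frac_missing),
    per |>
      dplyr::filter(.data$frac_missing <= max_missing,
                    .data$modal_share > max_identical) |>
      dplyr::transmute(.data$subject_id, reason = "invariant responding",
                       value = .data$modal_share)
  )
  kept <- dplyr::filter(trials, !.data$subject_id %in% excl$subject_id)
  if (nrow(kept) == 0) abort("no subjects left after exclusion.")
  list(kept = kept, excluded = excl)
}
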