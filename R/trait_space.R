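#' Reverse-code a rating on the 1-100 slider
#'
#' Ratings attached to negative trait adjectives are mapped onto the positive
#' direction of the scale (`101 - x`) so that every trait shares one
#' "role-adaptive" orientation; positive-trait ratings pass through
#' unchanged.  The map is an involution: applying it twice returns the input.
#'
#' @param rating numeric vector of ratings in `[1, 100]` (NA allowed for
#'   missed responses).
#' @param valence integer vector of `+1` (positive adjective) or `-1`
#'   (negative adjective), recycled against `rating`.
#' @return numeric vector on the common recoded scale.
#' @examples
#' reverse_code(100, -1) # 1
#' reverse_code(30, +1)  # 30
#' @export
reverse_code <- function(rating, valence) {
  if (!all(valence %in% c(-1, 1))) {
    abort("`valence` must be +1 or -1.")
  }
  ok <- is.na(rating) | (rating >= RATING_MIN & rating <= RATING_MAX)
  if (!all(ok)) {
    abort(sprintf(
      "ratings outside [1, 100]: first offender %s",
      format(rating[!ok][1])
    ))
  }
  ifelse(rep_len(valence, length(rating)) == -1, 101 - rating, rating)
}

#' Construct a trait space from an external rater pool
#'
#' The trait space is the task's fixed scaffolding: the trait lexicon, the
#' inter-trait similarity matrix `SIM` (Pearson correlations between trait
#' columns of the rater pool, after reverse coding), the per-trait feedback
#' values (column means, standing in for the reference group's average
#' ratings), and the column moments from which initial-expectation
#' regressions are derived.
#'
#' @param pool numeric matrix or data frame, raters in rows and traits in
#'   columns, raw (pre-recoding) ratings in `[1, 100]`.  Column order must
#'   match `traits`.
#' @param traits data frame with columns `trait_id` (contiguous integers from
#'   0), `label`, and `valence` (+1/-1).
#' @return an object of class `trait_space`: a list with elements `traits`
#'   (tibble), `sim` (K x K correlation matrix), `feedback_mean`, `col_mean`,
#'   `col_sd` (length-K, recoded scale), `init_reg` (K x 2 OLS intercept and
#'   slope of every trait on trait 0), and `n_raters`.
#' @seealso [init_reg_for()], [simulate_rater_pool()]
#' @export
build_trait_space <- function(pool, traits) {
  traits <- tibble::as_tibble(traits)
  stopifnot(all(c("trait_id", "label", "valence") %in% names(traits)))
  traits <- dplyr::arrange(traits, .data$trait_id)
  K <- nrow(traits)
  if (K < 2) abort("need at least 2 traits.")
  if (!identical(as.integer(traits$trait_id), 0:(K - 1L))) {
    abort("trait_id must be unique and contiguous from 0 to K-1.")
  }
  if (!all(traits$valence %in% c(-1, 1))) abort("valence must be +1 or -1.")

  pool <- as.matrix(pool)
  if (nrow(pool) < 3) abort("need at least 3 raters.")
  if (ncol(pool) != K) abort("pool has one column per trait.")
  if (anyNA(pool) || any(!is.finite(pool))) abort("rater pool must be finite.")
  if (any(pool < RATING_MIN | pool > RATING_MAX)) {
    abort("rater pool entries must lie in [1, 100].")
  }

  # one common adaptive orientation before any correlation is taken
  recoded <- sweep_reverse(pool, traits$valence)
  sds <- apply(recoded, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "constant rater column for trait '%s': correlation undefined",
      traits$label[which(sds == 0)[1]]
    ))
  }

  sim <- cor(recoded)
  dimnames(sim) <- list(traits$label, traits$label)
  mu <- colMeans(recoded)
  reg <- init_reg_matrix(sim, mu, sds, ref = 1L)

  structure(
    list(
      traits = traits,
      sim = sim,
      feedback_mean = unname(mu),
      col_mean = unname(mu),
      col_sd = unname(sds),
      init_reg = reg,
      n_raters = nrow(pool)
    ),
    class = "trait_space"
  )
}

sweep_reverse <- function(pool, valence) {
  neg <- valence == -1
  pool[, neg] <- 101 - pool[, neg]
  pool
}

# OLS of every trait column on the column `ref` (1-based index), from the
# correlation matrix and column moments: slope = r * sd_k / sd_ref.
init_reg_matrix <- function(sim, mu, sds, ref) {
  slope <- sim[ref, ] * sds / sds[ref]
  intercept <- mu - slope * mu[ref]
  cbind(intercept = unname(intercept), slope = unname(slope))
}

#' Initial-expectation regression coefficients for a reference trait
#'
#' Returns, for every trait, the OLS intercept and slope of its (recoded)
#' rater-pool column regressed on the column of `ref_trait`.  These
#' coefficients turn the free first-trait expectation into initial
#' expectations for all later traits.
#'
#' @param space a [trait_space][build_trait_space] object.
#' @param ref_trait trait_id of the reference (usually the first presented)
#'   trait.
#' @return tibble with columns `trait_id`, `intercept`, `slope`.
#' @export
init_reg_for <- function(space, ref_trait) {
  stopifnot(inherits(space, "trait_space"))
  ref <- match(ref_trait, space$traits$trait_id)
  if (is.na(ref)) abort("unknown reference trait id.")
  reg <- init_reg_matrix(space$sim, space$col_mean, space$col_sd, ref)
  tibble::tibble(
    trait_id = space$traits$trait_id,
    intercept = reg[, "intercept"],
    slope = reg[, "slope"]
  )
}

#' Build a trait space directly from known quantities
#'
#' Bypasses the rater pool: useful for hand-set similarity structures in
#' examples and tests.  Column moments default to the feedback means and a
#' common spread of 10 rating points.
#'
#' @param sim K x K symmetric correlation matrix with unit diagonal.
#' @param feedback_mean length-K vector of per-trait feedback values.
#' @param traits optional trait table as in [build_trait_space()]; defaults
#'   to all-positive traits labelled `T0..T(K-1)`.
#' @param col_mean,col_sd optional pool column moments on the recoded scale.
#' @return a `trait_space` object.
#' @export
trait_space <- function(sim, feedback_mean, traits = NULL,
                        col_mean = feedback_mean,
                        col_sd = rep(10, length(feedback_mean))) {
  sim <- as.matrix(sim)
  K <- nrow(sim)
  stopifnot(ncol(sim) == K, length(feedback_mean) == K)
  if (max(abs(sim - t(sim))) > 1e-8 || max(abs(diag(sim) - 1)) > 1e-8 ||
      any(abs(sim) > 1 + 1e-8)) {
    abort("`sim` must be symmetric with unit diagonal and entries in [-1, 1].")
  }
  if (any(feedback_mean < RATING_MIN | feedback_mean > RATING_MAX)) {
    abort("feedback_mean entries must lie in [1, 100].")
  }
  if (is.null(traits)) {
    traits <- tibble::tibble(
      trait_id = 0:(K - 1L),
      label = paste0("T", 0:(K - 1L)),
      valence = 1
    )
  }
  structure(
    list(
      traits = tibble::as_tibble(traits),
      sim = sim,
      feedback_mean = feedback_mean,
      col_mean = col_mean,
      col_sd = col_sd,
      init_reg = init_reg_matrix(sim, col_mean, col_sd, 1L),
      n_raters = NA_integer_
    ),
    class = "trait_space"
  )
}

#' @export
print.trait_space <- function(x, ...) {
  K <- nrow(x$traits)
  cat(sprintf(
    "<trait_space> %d traits (%d positive, %d negative), %s raters\n",
    K, sum(x$traits$valence == 1), sum(x$traits$valence == -1),
    ifelse(is.na(x$n_raters), "synthetic/no", x$n_raters)
  ))
  off <- x$sim[upper.tri(x$sim)]
  cat(sprintf(
    "  SIM off-diagonal: mean %.3f, range [%.3f, %.3f]\n",
    mean(off), min(off), max(off)
  ))
  invisible(x)
}

#' Read a rater pool from CSV
#'
#' Expects a header row of trait labels and one numeric row per rater.
#'
#' @param path CSV file path.
#' @return numeric matrix raters x traits.
#' @export
read_rater_pool <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as.matrix(df)
}

#' Read a trait lexicon from CSV
#'
#' @param path CSV with columns `trait_id`, `label`, `valence`.
#' @return tibble.
#' @export
read_trait_lexicon <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trait_id = readr::col_integer(),
    label = readr::col_character(),
    valence = readr::col_integer()
  ))
}

#' Export a trait space
#'
#' Writes traits, feedback means and init_reg to JSON and the similarity
#' matrix to CSV.
#'
#' @param space a `trait_space`.
#' @param json_path,sim_csv_path output paths.
#' @return `space`, invisibly.
#' @export
write_trait_space <- function(space, json_path, sim_csv_path) {
  jsonlite::write_json(
    list(
      traits = space$traits,
      feedback_mean = space$feedback_mean,
      col_mean = space$col_mean,
      col_sd = space$col_sd,
      init_reg = as.data.frame(space$init_reg),
      n_raters = space$n_raters
    ),
    json_path,
    digits = NA, auto_unbox = TRUE
  )
  readr::write_csv(tibble::as_tibble(space$sim, .name_repair = "minimal"),
                   sim_csv_path)
  invisible(space)
}
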