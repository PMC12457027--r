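#' The five candidate learning models
#'
#' @description
#' Model predictions of a subject's trial-by-trial role estimates `P(t)` on
#' the recoded 1-100 scale:
#'
#' * **Model 1 (no learning)** — a linear transformation of self-ratings:
#'   `P(t) = beta0 + beta1 * S(t)`.
#' * **Model 2 (fine granularity)** — the prediction for the trait presented
#'   at position `t` is its initial expectation plus every earlier trial's
#'   prediction error, scaled by the learning rate `alpha` and the similarity
#'   between that trial's trait and the current one:
#'   `P(t) = E(t) + sum_{i<t} alpha * PE(i) * SIM(i, t)`.
#' * **Model 3** — as model 2 with two learning rates: `alpha_plus` when the
#'   trial's feedback reduced self-role dissonance (`|F - S| <= |P - S|`),
#'   `alpha_minus` when it amplified it.
#' * **Model 4 (self-adjusted)** — the model-2 accumulator `Pm(t)` is mixed
#'   with the current self-rating: `P(t) = gamma * S(t) + (1 - gamma) * Pm(t)`.
#' * **Model 5** — model 4 with model 3's dual learning rates.
#'
#' `PE(t) = F(t) - P(t)` for all models, with `P` the emitted prediction (for
#' models 4/5 an `pe_source = "accumulator"` switch uses `F - Pm` instead).
#' Initial expectations: the first presented trait's expectation `E1` is a
#' free parameter; every later trait's expectation is the OLS prediction of
#' its rater-pool column from the first trait's column evaluated at `E1`,
#' clipped to the rating scale.
#'
#' @name learning-models
NULL

MODEL_PAR_NAMES <- list(
  `1` = c("beta0", "beta1", "sigma"),
  `2` = c("alpha", "E1", "sigma"),
  `3` = c("alpha_plus", "alpha_minus", "E1", "sigma"),
  `4` = c("alpha", "gamma", "E1", "sigma"),
  `5` = c("alpha_plus", "alpha_minus", "gamma", "E1", "sigma")
)

#' Free parameter names of a model
#'
#' @param model model id in 1..5.
#' @return character vector of parameter names (observation noise `sigma`
#'   included; it is part of every model's likelihood).
#' @export
model_par_names <- function(model) {
  model <- as.character(model)
  if (is.null(MODEL_PAR_NAMES[[model]])) abort("model must be one of 1..5.")
  MODEL_PAR_NAMES[[model]]
}

#' Validate a named parameter list for a model
#'
#' @param model model id in 1..5.
#' @param ... named parameter values (see [model_par_names()]).  `sigma` may
#'   be omitted for pure prediction.
#' @return a named list of class `model_params`.
#' @export
model_params <- function(model, ...) {
  p <- list(...)
  need <- setdiff(model_par_names(model), "sigma")
  if (!all(need %in% names(p))) {
    abort(sprintf(
      "model %s needs parameters: %s", model, paste(need, collapse = ", ")
    ))
  }
  extra <- setdiff(names(p), model_par_names(model))
  if (length(extra)) {
    abort(sprintf("parameters not in model %s: %s", model,
                  paste(extra, collapse = ", ")))
  }
  for (nm in intersect(names(p), c("alpha", "alpha_plus", "alpha_minus"))) {
    if (p[[nm]] < 0 || p[[nm]] > 1) abort(sprintf("%s must be in [0, 1].", nm))
  }
  if (!is.null(p$gamma) && (p$gamma < 0 || p$gamma > 1)) {
    abort("gamma must be in [0, 1].")
  }
  if (!is.null(p$E1) && (p$E1 < RATING_MIN || p$E1 > RATING_MAX)) {
    abort("E1 must be in [1, 100].")
  }
  if (!is.null(p$sigma) && p$sigma <= 0) abort("sigma must be positive.")
  structure(c(p, list(model = as.integer(model))), class = "model_params")
}

# ---- transforms between natural and unconstrained space -------------------

par_to_unconstrained <- function(name, x) {
  switch(name,
    alpha = , alpha_plus = , alpha_minus = , gamma = stats::qlogis(x),
    E1 = stats::qlogis((x - RATING_MIN) / (RATING_MAX - RATING_MIN)),
    sigma = log(x),
    x # beta0, beta1 stay natural
  )
}

par_from_unconstrained <- function(name, theta) {
  switch(name,
    alpha = , alpha_plus = , alpha_minus = , gamma = stats::plogis(theta),
    E1 = RATING_MIN + (RATING_MAX - RATING_MIN) * stats::plogis(theta),
    sigma = exp(theta),
    theta
  )
}

transform_pars <- function(p, names) {
  vapply(names, function(nm) par_to_unconstrained(nm, p[[nm]]), numeric(1))
}

untransform_pars <- function(theta, names) {
  setNames(
    lapply(seq_along(names),
           function(i) par_from_unconstrained(names[i], theta[[i]])),
    names
  )
}

# ---- trial-table plumbing -------------------------------------------------

# Ensure a single-subject trial table, sorted by t, with a missing flag.
check_subject_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  need <- c("t", "trait_id", "self", "feedback")
  if (!all(need %in% names(trials))) {
    abort(sprintf("trials need columns: %s", paste(need, collapse = ", ")))
  }
  if ("subject_id" %in% names(trials) &&
      dplyr::n_distinct(trials$subject_id) > 1) {
    abort("expected a single subject's trials.")
  }
  if (!("missing" %in% names(trials))) {
    trials$missing <- if ("role" %in% names(trials)) is.na(trials$role) else FALSE
  }
  if (anyDuplicated(trials$trait_id)) {
    abort("each trait may appear at most once per subject.")
  }
  dplyr::arrange(trials, .data$t)
}

# Per-position quantities needed by the C++ core: initial-expectation OLS
# coefficients (a, b) w.r.t. the first presented trait and the trial-order
# similarity submatrix.
subject_design <- function(trials, space) {
  idx <- match(trials$trait_id, space$traits$trait_id)
  if (anyNA(idx)) abort("trials contain a trait_id missing from the trait space.")
  reg <- init_reg_matrix(space$sim, space$col_mean, space$col_sd, idx[1])
  a <- reg[idx, "intercept"]
  b <- reg[idx, "slope"]
  a[1] <- 0; b[1] <- 1 # E for the first presented trait is E1 itself
  list(a = a, b = b, simt = space$sim[idx, idx, drop = FALSE])
}

#' Initial feedback expectations along a presentation order
#'
#' The expectation for the first presented trait is the free parameter `E1`;
#' each later trait's expectation is the OLS prediction of its rater-pool
#' column from the first trait's column, evaluated at `E1` and clipped to
#' `[1, 100]`.
#'
#' @param space a [trait_space][build_trait_space].
#' @param order integer vector: trait ids in presentation order.
#' @param E1 expectation for the first presented trait, in `[1, 100]`.
#' @return numeric vector `E(t)` along `order`.
#' @export
initial_expectations <- function(space, order, E1) {
  stopifnot(E1 >= RATING_MIN, E1 <= RATING_MAX)
  idx <- match(order, space$traits$trait_id)
  if (anyNA(idx)) abort("`order` contains unknown trait ids.")
  reg <- init_reg_matrix(space$sim, space$col_mean, space$col_sd, idx[1])
  e <- reg[idx, "intercept"] + reg[idx, "slope"] * E1
  e[1] <- E1
  clip_rating(e)
}

#' Trial-by-trial model trajectory
#'
#' Computes the latent trajectory of one model for one subject: initial
#' expectations `E`, the feedback-based accumulator `Pm`, the emitted
#' prediction `P`, and the prediction error `PE = F - P`.  Latent values are
#' never clipped.
#'
#' @param trials single-subject trial tibble with columns `t`, `trait_id`,
#'   `self`, `feedback` (recoded scale) and optionally `missing`/`role`.
#' @param space a [trait_space][build_trait_space] (not needed for model 1).
#' @param model model id in 1..5.
#' @param params named list of natural-scale parameters (see
#'   [model_params()]).
#' @param pe_source `"mixed"` (default; `PE = F - P`) or `"accumulator"`
#'   (`PE = F - Pm`), relevant to models 4/5 only.
#' @return tibble with columns `t`, `trait_id`, `E`, `Pm`, `P`, `PE`.
#' @export
predict_trajectory <- function(trials, space = NULL, model, params,
                               pe_source = c("mixed", "accumulator")) {
  pe_source <- match.arg(pe_source)
  trials <- check_subject_trials(trials)
  model <- as.integer(model)

  if (model == 1L) {
    P <- params$beta0 + params$beta1 * trials$self
    return(tibble::tibble(
      t = trials$t, trait_id = trials$trait_id,
      E = NA_real_, Pm = P, P = P,
      PE = ifelse(trials$missing, NA_real_, trials$feedback - P)
    ))
  }

  if (is.null(space)) abort("models 2-5 need a trait space.")
  d <- subject_design(trials, space)
  E <- clip_rating(d$a + d$b * params$E1)
  ap <- params$alpha_plus %||% params$alpha
  am <- params$alpha_minus %||% params$alpha
  g <- params$gamma %||% 0
  tr <- traj_core(E, trials$self, trials$feedback, d$simt,
                  ap, am, g, pe_source == "mixed",
                  as.logical(trials$missing))
  tibble::tibble(
    t = trials$t, trait_id = trials$trait_id,
    E = E, Pm = tr$Pm, P = tr$P, PE = tr$PE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian observation log-likelihood of one subject under one model
#'
#' Sums, over non-missing trials, the log density of the observed role
#' rating around the model's latent prediction with SD `sigma`.  Missed
#' trials contribute nothing and their PE is not accumulated.
#'
#' @inheritParams predict_trajectory
#' @param params natural-scale parameters including `sigma > 0`.
#' @return scalar log-likelihood.
#' @export
model_loglik <- function(trials, space = NULL, model, params,
                         pe_source = c("mixed", "accumulator")) {
  pe_source <- match.arg(pe_source)
  trials <- check_subject_trials(trials)
  if (!("role" %in% names(trials))) abort("trials need a `role` column.")
  if (is.null(params$sigma) || params$sigma <= 0) {
    abort("sigma must be positive.")
  }
  obs <- !trials$missing
  if (!any(obs)) abort("subject has no non-missing trials.")
  traj <- predict_trajectory(trials, space, model, params, pe_source)
  sum(dnorm(trials$role[obs], traj$P[obs], params$sigma, log = TRUE))
}
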