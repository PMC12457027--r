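#' Simulate an external rater pool with latent factor structure
#'
#' Stands in for the separate groups of raters from which the similarity
#' matrix and feedback values are computed.  Ratings follow a latent factor
#' model on the recoded (common-orientation) scale: per-trait mean drawn
#' uniformly, plus factor loadings times standard-normal rater factors, plus
#' Gaussian noise; values are clipped to the 1-100 slider and negative-trait
#' columns are mapped back to the raw (un-recoded) direction so the pool
#' looks like genuine raw data.
#'
#' The default loadings give every trait a positive loading on one general
#' factor plus smaller loadings on `n_factors - 1` secondary factors: after
#' adaptive-orientation recoding, trait ratings exhibit a positive manifold
#' (a halo-like general dimension) with block structure, and the per-trait
#' means default to the high (adaptive) end of the scale, as expected when
#' external raters describe a well-adapted role profile.
#'
#' @param traits trait table (`trait_id`, `label`, `valence`); see
#'   [make_trait_lexicon()].
#' @param n_raters number of raters (>= 3, default 30).
#' @param n_factors latent factors (default 3: one general + two secondary).
#' @param factor_strength SD of the factor contribution in rating points
#'   (default 10).
#' @param noise_sd rater idiosyncratic noise SD (default 5).
#' @param mean_range range of per-trait mean ratings on the recoded scale
#'   (default `c(65, 90)`).
#' @param loadings optional K x n_factors loading matrix; overrides the
#'   default structure.
#' @param round_ratings round emitted ratings to integer slider values
#'   (default TRUE).
#' @param seed integer seed; the pool is deterministic given the seed.
#' @return numeric matrix `n_raters x K` of raw ratings in `[1, 100]`.
#' @export
simulate_rater_pool <- function(traits, n_raters = 30, n_factors = 3,
                                factor_strength = 10, noise_sd = 5,
                                mean_range = c(65, 90), loadings = NULL,
                                round_ratings = TRUE, seed = 1L) {
  traits <- tibble::as_tibble(traits)
  K <- nrow(traits)
  if (K < 2) abort("need at least 2 traits.")
  if (n_raters < 3) abort("need at least 3 raters.")
  if (factor_strength <= 0 && noise_sd <= 0) {
    abort("degenerate pool: no factor signal and no noise.")
  }
  set.seed(seed)
  if (is.null(loadings)) {
    loadings <- cbind(
      runif(K, 0.4, 0.9),
      matrix(rnorm(K * max(0L, n_factors - 1L), sd = 0.35), K)
    )
  }
  mu <- runif(K, mean_range[1], mean_range[2])
  eta <- matrix(rnorm(n_raters * ncol(loadings)), n_raters)
  x <- matrix(mu, n_raters, K, byrow = TRUE) +
    factor_strength * eta %*% t(loadings) +
    matrix(rnorm(n_raters * K, sd = noise_sd), n_raters)
  x <- clip_rating(x)
  if (round_ratings) x <- round(x)
  # emit raw orientation for negative adjectives
  x <- sweep_reverse(x, traits$valence)
  colnames(x) <- traits$label
  x
}

#' Default trait lexicon for the simulated task
#'
#' @param n_pos,n_neg counts of positive and negative trait adjectives
#'   (defaults 25/25, the task's design).
#' @return tibble with `trait_id` (0-based), opaque `label`, `valence`.
#' @export
make_trait_lexicon <- function(n_pos = 25, n_neg = 25) {
  K <- n_pos + n_neg
  lab <- character(0)
  if (n_pos > 0) lab <- paste0("pos", seq_len(n_pos))
  if (n_neg > 0) lab <- c(lab, paste0("neg", seq_len(n_neg)))
  tibble::tibble(
    trait_id = 0:(K - 1L),
    label = lab,
    valence = rep(c(1L, -1L), c(n_pos, n_neg))
  )
}

# Parameter sampling ranges.  "default" matches the recovery study; the
# "separated" set keeps models tellable apart in the confusion study
# (asymmetric rates genuinely asymmetric, gamma bounded away from 0/1).
default_ranges <- function() {
  list(
    alpha = c(0, 1), alpha_plus = c(0, 1), alpha_minus = c(0, 1),
    gamma = c(0, 1), beta0 = c(0, 50), beta1 = c(0, 1.5), E1 = c(20, 80)
  )
}

separated_ranges <- function() {
  list(
    alpha = c(0.3, 0.8), alpha_plus = c(0.55, 0.9),
    alpha_minus = c(0.05, 0.3), gamma = c(0.3, 0.7),
    beta0 = c(5, 30), beta1 = c(0.6, 1.2), E1 = c(30, 70)
  )
}

resolve_ranges <- function(ranges) {
  if (is.character(ranges)) {
    ranges <- switch(match.arg(ranges, c("default", "separated")),
      default = default_ranges(),
      separated = separated_ranges()
    )
  }
  modifyList(default_ranges(), ranges)
}

#' Draw random generating parameters for a model
#'
#' @param model model id in 1..5.
#' @param n number of draws.
#' @param ranges `"default"`, `"separated"`, or a named list of `c(lo, hi)`
#'   ranges overriding the defaults.
#' @param seed integer seed.
#' @return tibble, one row per draw, one column per model parameter
#'   (excluding `sigma`).
#' @export
sample_model_params <- function(model, n, ranges = "default", seed = 1L) {
  rg <- resolve_ranges(ranges)
  nms <- setdiff(model_par_names(model), "sigma")
  set.seed(seed)
  out <- lapply(nms, function(nm) runif(n, rg[[nm]][1], rg[[nm]][2]))
  tibble::as_tibble(setNames(out, nms))
}

#' Simulation configuration
#'
#' Bundles the study conditions for a synthetic cohort: 50 traits (25
#' positive / 25 negative), randomized trait order, feedback shown as the
#' reference group's average, Gaussian observation noise of 8 rating points
#' added to emitted role estimates, and integer slider emission.
#'
#' @param n_subjects cohort size.
#' @param model generating model id in 1..5 (recycled per subject if a
#'   vector).
#' @param K,n_pos,n_neg trait counts (`K = n_pos + n_neg`).
#' @param n_raters external raters behind the similarity matrix.
#' @param sigma_sim observation-noise SD in rating points (default 8).
#' @param ranges parameter sampling ranges (see [sample_model_params()]).
#' @param self_cor target correlation between self-ratings and feedback
#'   means (default 0.3).
#' @param self_sd between-trait SD of self-ratings (default 15).
#' @param round_ratings emit integer slider values (default TRUE).
#' @param feedback_noise_sd optional rater-sampling noise on shown feedback
#'   (default 0: feedback is deterministic at the reference-group mean).
#' @param seed master seed; recorded in every manifest.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects, model, K = 50, n_pos = 25, n_neg = 25,
                       n_raters = 30, sigma_sim = 8, ranges = "default",
                       self_cor = 0.3, self_sd = 15, round_ratings = TRUE,
                       feedback_noise_sd = 0, seed = 1L) {
  if (K != n_pos + n_neg) abort("K must equal n_pos + n_neg.")
  if (sigma_sim < 0) abort("sigma_sim must be >= 0.")
  if (!all(model %in% 1:5)) abort("model must be in 1..5.")
  structure(
    list(
      n_subjects = n_subjects, model = model, K = K, n_pos = n_pos,
      n_neg = n_neg, n_raters = n_raters, sigma_sim = sigma_sim,
      ranges = ranges, self_cor = self_cor, self_sd = self_sd,
      round_ratings = round_ratings, feedback_noise_sd = feedback_noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Self-ratings: one draw per subject, Gaussian around a subject-level mean
# with a configurable correlation to the feedback means, clipped to [1,100].
simulate_self_ratings <- function(space, self_cor, self_sd) {
  fm <- space$feedback_mean
  fz <- (fm - mean(fm)) / sd(fm)
  mu_s <- runif(1, 35, 65)
  s <- mu_s + self_cor * self_sd * fz +
    sqrt(max(0, 1 - self_cor^2)) * self_sd * rnorm(length(fm))
  clip_rating(s)
}

#' Simulate one subject performing the task under a given model
#'
#' Trait order is a seeded permutation; self-ratings are drawn once per
#' subject; feedback is the reference-group mean (plus optional sampling
#' noise); the observed role estimate is the model's latent prediction plus
#' Gaussian observation noise, clipped (and by default rounded) on emission.
#' Latent predictions are never clipped.
#'
#' @param space a [trait_space][build_trait_space].
#' @param model model id in 1..5.
#' @param params natural-scale generating parameters (no `sigma` needed).
#' @param order_seed,noise_seed seeds of the order and noise substreams.
#' @param sigma_sim observation-noise SD (>= 0).
#' @param self optional length-K numeric of self-ratings (by trait_id order);
#'   generated if NULL.
#' @param self_cor,self_sd self-rating generator settings.
#' @param round_ratings emit integer slider values.
#' @param feedback_noise_sd SD of optional feedback sampling noise.
#' @param subject_id id stored in the output.
#' @param pe_source see [predict_trajectory()].
#' @return trial tibble (`subject_id`, `t`, `trait_id`, `valence`, `self`,
#'   `role`, `feedback`, `missing`) on the recoded scale.
#' @export
simulate_subject <- function(space, model, params, order_seed = 1L,
                             noise_seed = 2L, sigma_sim = 8, self = NULL,
                             self_cor = 0.3, self_sd = 15,
                             round_ratings = TRUE, feedback_noise_sd = 0,
                             subject_id = 1L,
                             pe_source = c("mixed", "accumulator")) {
  if (sigma_sim < 0) abort("sigma_sim must be >= 0.")
  model <- as.integer(model)
  if (!model %in% 1:5) abort("model must be in 1..5.")
  K <- nrow(space$traits)

  set.seed(order_seed)
  ord <- sample(space$traits$trait_id)

  set.seed(noise_seed)
  if (is.null(self)) self <- simulate_self_ratings(space, self_cor, self_sd)
  idx <- match(ord, space$traits$trait_id)
  fb <- space$feedback_mean[idx]
  if (feedback_noise_sd > 0) {
    fb <- clip_rating(fb + rnorm(K, sd = feedback_noise_sd))
  }
  s <- self[idx]
  if (round_ratings) {
    s <- round(s)
    fb <- round(fb)
  }

  trials <- tibble::tibble(
    subject_id = subject_id,
    t = seq_len(K),
    trait_id = ord,
    valence = space$traits$valence[idx],
    self = s,
    feedback = fb,
    missing = FALSE
  )
  traj <- predict_trajectory(trials, space, model, params,
                             pe_source = match.arg(pe_source))
  role <- traj$P + if (sigma_sim > 0) rnorm(K, sd = sigma_sim) else 0
  role <- clip_rating(role)
  if (round_ratings) role <- round(role)
  trials$role <- role
  trials[, c("subject_id", "t", "trait_id", "valence",
             "self", "role", "feedback", "missing")]
}

#' Simulate a full cohort
#'
#' Applies [simulate_subject()] per subject with independent, named
#' sub-seeds derived from the master seed, drawing each subject's generating
#' parameters from the configured ranges.
#'
#' @param cfg a [sim_config()].
#' @param space optional shared [trait_space][build_trait_space]; generated
#'   from a seeded rater pool if NULL.
#' @return object of class `role_cohort`: list with `trials` (long tibble
#'   over subjects), `params` (manifest of true parameters, seeds and model
#'   ids), `space`, and `config`.
#' @export
simulate_cohort <- function(cfg, space = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(space)) {
    traits <- make_trait_lexicon(cfg$n_pos, cfg$n_neg)
    pool <- simulate_rater_pool(traits, n_raters = cfg$n_raters,
                                seed = derive_seed(cfg$seed, "pool"))
    space <- build_trait_space(pool, traits)
  }
  models <- as.integer(rep_len(cfg$model, cfg$n_subjects))
  draws <- lapply(unique(models), function(m) {
    sample_model_params(m, sum(models == m), cfg$ranges,
                        seed = derive_seed(cfg$seed, "params", m))
  })
  names(draws) <- as.character(unique(models))
  counter <- setNames(rep(0L, length(draws)), names(draws))

  trials <- vector("list", cfg$n_subjects)
  manifest <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    m <- as.character(models[i])
    counter[m] <- counter[m] + 1L
    p <- as.list(draws[[m]][counter[m], ])
    os <- derive_seed(cfg$seed, "order", i)
    ns <- derive_seed(cfg$seed, "noise", i)
    trials[[i]] <- simulate_subject(
      space, models[i], p, order_seed = os, noise_seed = ns,
      sigma_sim = cfg$sigma_sim, self_cor = cfg$self_cor,
      self_sd = cfg$self_sd, round_ratings = cfg$round_ratings,
      feedback_noise_sd = cfg$feedback_noise_sd, subject_id = i
    )
    manifest[[i]] <- tibble::as_tibble(c(
      list(subject_id = i, model = models[i]), p,
      list(sigma_sim = cfg$sigma_sim, order_seed = os, noise_seed = ns,
           master_seed = cfg$seed)
    ))
  }
  structure(
    list(
      trials = dplyr::bind_rows(trials),
      params = dplyr::bind_rows(manifest),
      space = space,
      config = cfg
    ),
    class = "role_cohort"
  )
}

#' @export
print.role_cohort <- function(x, ...) {
  cat(sprintf(
    "<role_cohort> %d subjects x %d trials, generating model(s): %s, seed %d\n",
    dplyr::n_distinct(x$trials$subject_id), max(x$trials$t),
    paste(sort(unique(x$params$model)), collapse = ","), x$config$seed
  ))
  invisible(x)
}

#' Write / read a true-parameter manifest with bit-exact round-trip
#'
#' Doubles are serialized with 17 significant digits so that
#' `read_manifest(write_manifest(x))` reproduces them bit-exactly.
#'
#' @param params manifest tibble (e.g. `cohort$params`).
#' @param path CSV path.
#' @return the input (write) or the parsed tibble (read).
#' @export
write_manifest <- function(params, path) {
  out <- params
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path)
  invisible(params)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  # base read.csv: strtod parsing is correctly rounded, so 17-digit decimals
  # reproduce the original doubles bit-exactly
  df <- tibble::as_tibble(utils::read.csv(path))
  int_cols <- intersect(
    c("subject_id", "model", "order_seed", "noise_seed", "master_seed"),
    names(df)
  )
  df[int_cols] <- lapply(df[int_cols], as.integer)
  dbl <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], int_cols)
  df[dbl] <- lapply(df[dbl], as.double)
  df
}
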