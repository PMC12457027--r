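#' Parameter recovery study
#'
#' Simulates `n_sims` single-subject datasets with parameters drawn from the
#' configured ranges, adds Gaussian observation noise in the final step,
#' refits the same model per dataset by MAP under the wide priors, and
#' reports the Pearson correlation between generating and recovered values
#' per parameter (natural scale).
#'
#' @param model model id in 1..5.
#' @param n_sims number of simulated datasets (>= 20).
#' @param space optional shared [trait_space][build_trait_space]; a default
#'   50-trait task space is generated if NULL.
#' @param sigma_sim observation-noise SD of the simulations (default 8).
#' @param ranges parameter sampling ranges (see [sample_model_params()]).
#' @param n_restarts optimizer restarts per fit.
#' @param seed master seed.
#' @inheritParams simulate_subject
#' @return object of class `recovery_report` with `estimates` (one row per
#'   simulation x parameter: `true`, `recovered`) and metadata; `tidy()`
#'   gives the per-parameter correlations.
#' @export
run_parameter_recovery <- function(model, n_sims = 200, space = NULL,
                                   sigma_sim = 8, ranges = "default",
                                   n_restarts = 3, seed = 1L,
                                   self_cor = 0.3, self_sd = 15) {
  if (n_sims < 20) abort("n_sims must be at least 20.")
  model <- as.integer(model)
  if (is.null(space)) {
    traits <- make_trait_lexicon()
    pool <- simulate_rater_pool(traits, seed = derive_seed(seed, "pool"))
    space <- build_trait_space(pool, traits)
  }
  truths <- sample_model_params(model, n_sims, ranges,
                                seed = derive_seed(seed, "params", model))
  nms <- names(truths)

  rows <- vector("list", n_sims)
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    p <- as.list(truths[i, ])
    tr <- simulate_subject(
      space, model, p,
      order_seed = derive_seed(seed, "order", i),
      noise_seed = derive_seed(seed, "noise", i),
      sigma_sim = sigma_sim, self_cor = self_cor, self_sd = self_sd,
      subject_id = i
    )
    fit <- tryCatch(
      fit_subject(tr, space, model, n_restarts = n_restarts,
                  seed = derive_seed(seed, "fit", i)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[i]] <- tibble::tibble(
      sim = i, term = nms,
      true = unlist(p[nms]),
      recovered = unlist(fit$params[nms])
    )
  }
  estimates <- dplyr::bind_rows(rows)
  structure(list(
    estimates = estimates, model = model, n_sims = n_sims,
    n_failed = n_failed, sigma_sim = sigma_sim, seed = seed
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> model %d, %d simulations (%d failed fits)\n",
              x$model, x$n_sims, x$n_failed))
  s <- tidy(x)
  cat(paste(sprintf("  %s: r = %.3f", s$term, s$r), collapse = "\n"), "\n")
  invisible(x)
}

#' Model confusion study
#'
#' For each generating model, simulates replicate cohorts with
#' well-separated parameter draws, fits all candidate models hierarchically
#' to each cohort, and averages the exceedance probabilities into a
#' generator-by-candidate confusion matrix (each row sums to 1 up to MC
#' error; an identity-like matrix means the models are distinguishable).
#'
#' @param models candidate (and generating) model ids.
#' @param n_cohorts replicate cohorts per generating model.
#' @param n_subjects subjects per cohort.
#' @param space optional shared trait space.
#' @param sigma_sim observation-noise SD.
#' @param ranges parameter ranges (default `"separated"`).
#' @param max_iter,n_restarts,warm_restarts,n_mc hierarchical-fit settings
#'   (kept light: the study needs many refits).
#' @param seed master seed.
#' @return object of class `confusion_report` with the `ep` matrix and
#'   metadata.
#' @export
run_confusion <- function(models = 1:5, n_cohorts = 50, n_subjects = 20,
                          space = NULL, sigma_sim = 8, ranges = "separated",
                          max_iter = 4, n_restarts = 2, warm_restarts = 1,
                          n_mc = 10000, seed = 1L) {
  if (length(models) < 2) abort("need at least 2 models.")
  M <- length(models)
  if (is.null(space)) {
    traits <- make_trait_lexicon()
    pool <- simulate_rater_pool(traits, seed = derive_seed(seed, "pool"))
    space <- build_trait_space(pool, traits)
  }
  ep <- matrix(0, M, M, dimnames = list(
    paste0("gen_m", models), paste0("sel_m", models)
  ))
  n_ok <- integer(M)
  for (g in seq_len(M)) {
    for (cc in seq_len(n_cohorts)) {
      cfg <- sim_config(
        n_subjects, model = models[g], sigma_sim = sigma_sim,
        ranges = ranges, seed = derive_seed(seed, "cohort", g * 100000L + cc)
      )
      cohort <- simulate_cohort(cfg, space)
      h <- tryCatch(
        fit_hierarchical(
          cohort$trials, space, models, max_iter = max_iter, tol = 1e-3,
          n_restarts = n_restarts, warm_restarts = warm_restarts,
          n_mc = n_mc, keep_fits = FALSE,
          seed = derive_seed(seed, "hfit", g * 100000L + cc)
        ),
        error = function(e) NULL
      )
      if (is.null(h)) next
      ep[g, ] <- ep[g, ] + h$ep
      n_ok[g] <- n_ok[g] + 1L
    }
    ep[g, ] <- ep[g, ] / max(n_ok[g], 1L)
  }
  structure(list(
    ep = ep, models = models, n_cohorts = n_cohorts,
    n_ok = n_ok, n_subjects = n_subjects, seed = seed
  ), class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf(
    "<confusion_report> %d cohorts x %d subjects per generating model\n",
    x$n_cohorts, x$n_subjects
  ))
  print(round(x$ep, 3))
  invisible(x)
}

#' Feedback-optimal ("learning-optimal") parameters for one subject
#'
#' Fits a model's parameters to predict the feedback itself rather than the
#' subject's ratings: minimizes the squared error between the model's latent
#' predictions and the shown feedback, with the subject's self-ratings and
#' trial order fixed.  Uses the same unconstrained transforms as MAP
#' fitting; the observation noise is not part of the objective.  Where the
#' objective leaves a parameter unidentified the estimate stays at the prior
#' mode (the first optimizer start).
#'
#' @inheritParams fit_subject
#' @param model model id in 2..5 (model 1 has no learning channel).
#' @return one-row tibble of optimal natural-scale parameters plus the
#'   residual `sse`.
#' @export
fit_optimal_parameters <- function(trials, space, model, n_restarts = 3,
                                   seed = 1L,
                                   pe_source = c("mixed", "accumulator")) {
  pe_source <- match.arg(pe_source)
  model <- as.integer(model)
  if (!model %in% 2:5) abort("optimal-parameter fits are defined for models 2..5.")
  trials <- check_subject_trials(trials)
  free <- setdiff(model_par_names(model), "sigma")
  d <- subject_design(trials, space)
  miss <- as.logical(trials$missing)
  mixed <- pe_source == "mixed"

  obj <- function(theta) {
    p <- untransform_pars(theta, free)
    feedback_sse_core(
      d$a, d$b, p$E1, trials$self, trials$feedback, d$simt,
      p$alpha_plus %||% p$alpha, p$alpha_minus %||% p$alpha,
      p$gamma %||% 0, mixed, miss
    )
  }

  set.seed(seed)
  nd <- length(free)
  starts <- c(list(rep(0, nd)),
              lapply(seq_len(max(0, n_restarts - 1)),
                     function(i) rnorm(nd, sd = 1.5)))
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      optim(st, obj, method = "L-BFGS-B",
            lower = rep(-10, nd), upper = rep(10, nd),
            control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value - 1e-9) best <- res
  }
  if (is.null(best)) abort("all optimizer restarts failed.")

  # a parameter the feedback objective does not identify stays at the prior
  # mode: snap each coordinate back to 0 when doing so costs nothing
  theta <- best$par
  val <- best$value
  for (j in seq_len(nd)) {
    if (theta[j] == 0) next
    cand <- theta
    cand[j] <- 0
    v2 <- obj(cand)
    if (v2 <= val + 1e-9 * (1 + abs(val))) {
      theta <- cand
      val <- min(val, v2)
    }
  }

  p <- untransform_pars(setNames(theta, free), free)
  dplyr::bind_cols(tibble::as_tibble(p), tibble::tibble(sse = val))
}

#' Empirical-minus-optimal parameter deviations with a group contrast
#'
#' Joins matched per-subject empirical and feedback-optimal parameter
#' tables, computes per-subject deviations (empirical minus optimal) for
#' every shared parameter, and contrasts the deviations between two labelled
#' groups with Welch t-tests.
#'
#' @param empirical,optimal tibbles with a `subject_id` column and one
#'   column per parameter; subjects must match one-to-one.
#' @param groups tibble with columns `subject_id` and `group` (exactly two
#'   levels), or NULL to skip the contrast.
#' @return object of class `deviation_report` with `deviations` (long
#'   tibble) and `contrasts` (one row per parameter, or NULL).
#' @export
deviation_analysis <- function(empirical, optimal, groups = NULL) {
  empirical <- tibble::as_tibble(empirical)
  optimal <- tibble::as_tibble(optimal)
  if (!setequal(empirical$subject_id, optimal$subject_id) ||
      nrow(empirical) != nrow(optimal)) {
    abort("empirical and optimal fits must cover the same subjects.")
  }
  terms <- intersect(setdiff(names(empirical), "subject_id"),
                     setdiff(names(optimal), "subject_id"))
  terms <- terms[vapply(empirical[terms], is.numeric, logical(1))]
  if (!length(terms)) abort("no shared parameter columns.")

  dev <- dplyr::inner_join(
    tidyr::pivot_longer(empirical[, c("subject_id", terms)], -"subject_id",
                        names_to = "term", values_to = "empirical"),
    tidyr::pivot_longer(optimal[, c("subject_id", terms)], -"subject_id",
                        names_to = "term", values_to = "optimal"),
    by = c("subject_id", "term")
  ) |>
    dplyr::mutate(deviation = .data$empirical - .data$optimal)

  contrasts <- NULL
  if (!is.null(groups)) {
    groups <- tibble::as_tibble(groups)
    lev <- sort(unique(groups$group))
    if (length(lev) != 2) abort("`groups` must have exactly two levels.")
    dev <- dplyr::left_join(dev, groups, by = "subject_id")
    if (anyNA(dev$group)) abort("every subject needs a group label.")
    contrasts <- purrr::map_dfr(terms, function(tm) {
      d <- dplyr::filter(dev, .data$term == tm)
      a <- d$deviation[d$group == lev[1]]
      b <- d$deviation[d$group == lev[2]]
      if (sd(a) == 0 && sd(b) == 0) {
        return(tibble::tibble(
          term = tm, estimate = mean(a) - mean(b), t = NA_real_,
          df = NA_real_, p.value = NA_real_, d = NA_real_,
          conf.low = NA_real_, conf.high = NA_real_,
          note = "no variance in deviations"
        ))
      }
      ct <- group_contrast(a, b)
      dplyr::bind_cols(tibble::tibble(term = tm), ct,
                       tibble::tibble(note = NA_character_))
    })
  }
  structure(list(deviations = dev, contrasts = contrasts,
                 group_levels = if (is.null(groups)) NULL
                 else sort(unique(groups$group))),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> %d subjects, %d parameter(s)\n",
              dplyr::n_distinct(x$deviations$subject_id),
              dplyr::n_distinct(x$deviations$term)))
  if (!is.null(x$contrasts)) print(x$contrasts)
  invisible(x)
}

#' Posterior-predictive check of the cohort-mean trajectory
#'
#' For each posterior draw, samples every subject's parameters from their
#' Laplace posterior (mode and curvature), simulates a new trajectory with
#' observation noise, and averages the simulated role estimates across
#' subjects per trial position.  Reports the pointwise credible band of that
#' cohort-mean trajectory, its posterior-predictive mean, and the fraction
#' of trial positions at which the observed mean lies inside the band.
#'
#' @param trials the observed (or reference) cohort trial tibble.
#' @param space the task's trait space.
#' @param fits a [cohort_fit][fit_cohort] for the checked model, or an
#'   [hbi_fit][fit_hierarchical] fitted with `keep_fits = TRUE` plus `model`.
#' @param model model id (required when `fits` is an `hbi_fit`).
#' @param n_draws posterior draws (>= 100).
#' @param level credible level of the pointwise band (default 0.95).
#' @param seed MC seed.
#' @inheritParams predict_trajectory
#' @return object of class `ppc_report` with `by_trial` (per-position
#'   observed mean, predictive mean and band) and `coverage`.
#' @export
run_ppc <- function(trials, space, fits, model = NULL, n_draws = 200,
                    level = 0.95, seed = 1L,
                    pe_source = c("mixed", "accumulator")) {
  pe_source <- match.arg(pe_source)
  if (n_draws < 100) abort("n_draws must be at least 100.")
  if (inherits(fits, "hbi_fit")) {
    if (is.null(model)) abort("give `model` when passing an hbi_fit.")
    if (is.null(fits$fits)) abort("hbi_fit was run with keep_fits = FALSE.")
    subject_fits <- fits$fits[[paste0("m", model)]]
  } else if (inherits(fits, "cohort_fit")) {
    model <- fits$model
    subject_fits <- fits$fits
  } else {
    abort("`fits` must be a cohort_fit or hbi_fit.")
  }
  model <- as.integer(model)

  by_subj <- split(trials, trials$subject_id)
  ids <- names(by_subj)
  nS <- length(ids)
  if (length(subject_fits) != nS) abort("fits and trials cover different subjects.")
  Tn <- max(trials$t)

  # per-subject posterior Cholesky factors (nearest-PD repair by eigenvalue
  # clamping where the Laplace covariance is numerically indefinite)
  chols <- lapply(subject_fits, function(f) {
    cv <- (f$cov + t(f$cov)) / 2
    ch <- tryCatch(chol(cv), error = function(e) NULL)
    if (is.null(ch)) {
      eg <- eigen(cv, symmetric = TRUE)
      cv <- eg$vectors %*% diag(pmax(eg$values, 1e-8),
                                length(eg$values)) %*% t(eg$vectors)
      ch <- chol(cv)
    }
    ch
  })
  free <- names(subject_fits[[1]]$theta_mode)

  obs_mean <- trials |>
    dplyr::filter(!.data$missing) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(observed = mean(.data$role), .groups = "drop")

  set.seed(derive_seed(seed, "ppc"))
  draws <- matrix(NA_real_, n_draws, Tn)
  for (dd in seq_len(n_draws)) {
    acc <- matrix(NA_real_, nS, Tn)
    for (n in seq_len(nS)) {
      f <- subject_fits[[n]]
      theta <- f$theta_mode + drop(rnorm(length(free)) %*% chols[[n]])
      p <- untransform_pars(setNames(theta, free), free)
      tr <- by_subj[[n]]
      traj <- predict_trajectory(tr, space, model, p, pe_source)
      role <- clip_rating(traj$P + rnorm(nrow(tr), sd = p$sigma))
      acc[n, tr$t] <- role
    }
    draws[dd, ] <- colMeans(acc, na.rm = TRUE)
  }
  qs <- apply(draws, 2, quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  by_trial <- tibble::tibble(
    t = seq_len(Tn),
    predictive_mean = colMeans(draws),
    lower = qs[1, ], upper = qs[2, ]
  ) |>
    dplyr::left_join(obs_mean, by = "t") |>
    dplyr::mutate(inside = .data$observed >= .data$lower &
                    .data$observed <= .data$upper)

  structure(list(
    by_trial = by_trial,
    coverage = mean(by_trial$inside, na.rm = TRUE),
    n_draws = n_draws, level = level, model = model
  ), class = "ppc_report")
}

#' @export
print.ppc_report <- function(x, ...) {
  cat(sprintf(
    "<ppc_report> model %d, %d draws: observed mean inside the %d%% band at %.1f%% of trial positions\n",
    x$model, x$n_draws, round(100 * x$level), 100 * x$coverage
  ))
  invisible(x)
}
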