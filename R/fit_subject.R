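#' Default wide Gaussian prior in unconstrained space
#'
#' Mean 0 and variance 6.25 for every logit/log-transformed parameter
#' (learning rates, gamma, E1, sigma).  Model 1's regression coefficients
#' stay on their natural scale, with variance 625 for the intercept and 6.25
#' for the slope.
#'
#' @param model model id in 1..5.
#' @return list with named numeric vectors `mean` and `var`.
#' @export
default_prior <- function(model) {
  nms <- model_par_names(model)
  v <- setNames(rep(6.25, length(nms)), nms)
  if ("beta0" %in% nms) v["beta0"] <- 625
  list(mean = setNames(rep(0, length(nms)), nms), var = v)
}

# Build the negative log posterior over the free (unconstrained) parameters
# of one subject x model.  Everything inside is precomputed once; each
# optimizer evaluation is one transform + one C++ call.
make_negpost <- function(trials, space, model, free, fixed,
                         prior_mean, prior_var, pe_source) {
  obs <- !trials$missing
  S <- trials$self
  Fb <- trials$feedback
  Pobs <- trials$role
  psd <- sqrt(prior_var)
  n_obs <- sum(obs)
  LOG2PI <- log(2 * pi)
  mixed <- pe_source == "mixed"

  if (model == 1L) {
    So <- S[obs]; Po <- Pobs[obs]
    function(theta) {
      p <- c(untransform_pars(theta, free), fixed)
      r <- Po - (p$beta0 + p$beta1 * So)
      nll <- 0.5 * (sum((r / p$sigma)^2) + n_obs * LOG2PI) +
        n_obs * log(p$sigma)
      nll - sum(dnorm(theta, prior_mean, psd, log = TRUE))
    }
  } else {
    d <- subject_design(trials, space)
    miss <- as.logical(trials$missing)
    function(theta) {
      p <- c(untransform_pars(theta, free), fixed)
      nll <- negll_core(
        d$a, d$b, p$E1, S, Fb, d$simt, Pobs,
        p$alpha_plus %||% p$alpha, p$alpha_minus %||% p$alpha,
        p$gamma %||% 0, mixed, p$sigma, miss
      )
      nll - sum(dnorm(theta, prior_mean, psd, log = TRUE))
    }
  }
}

#' Fit one subject by MAP with a Laplace approximation to the evidence
#'
#' Maximizes log-likelihood plus log Gaussian prior in unconstrained space
#' from several seeded restarts; the log evidence is the Laplace
#' approximation `logpost(mode) + d/2 log(2 pi) - 1/2 log det(H)`, with `H`
#' the Hessian of the negative log posterior at the mode.
#'
#' @inheritParams predict_trajectory
#' @param prior_mean,prior_var named numeric vectors over the model's
#'   parameters in unconstrained space (defaults: [default_prior()]).
#' @param n_restarts optimizer restarts (first start at the prior mean /
#'   `init`, remaining jittered).
#' @param seed seed of the restart jitter.
#' @param fixed named list of parameters held at fixed natural-scale values
#'   (excluded from optimization and evidence dimensionality).
#' @param init optional named unconstrained start vector (warm start).
#' @return object of class `subject_fit` with elements `theta_mode`,
#'   `params` (natural scale, fixed values included), `hessian`, `cov`,
#'   `log_evidence`, `log_posterior`, `converged`, `hessian_repaired`,
#'   `n_restarts_used`.
#' @export
fit_subject <- function(trials, space = NULL, model, prior_mean = NULL,
                        prior_var = NULL, n_restarts = 5, seed = 1L,
                        fixed = list(), init = NULL,
                        pe_source = c("mixed", "accumulator")) {
  pe_source <- match.arg(pe_source)
  trials <- check_subject_trials(trials)
  if (!any(!trials$missing)) abort("subject has no non-missing trials.")
  model <- as.integer(model)
  nms <- model_par_names(model)
  free <- setdiff(nms, names(fixed))
  pr <- default_prior(model)
  pm <- (prior_mean %||% pr$mean)[free]
  pv <- (prior_var %||% pr$var)[free]
  if (any(pv <= 0)) abort("prior variances must be positive.")
  d <- length(free)

  negpost <- make_negpost(trials, space, model, free, fixed, pm, pv, pe_source)

  if (d == 0L) {
    lp <- -negpost(numeric(0))
    return(structure(list(
      subject_id = trials$subject_id[1] %||% NA, model = model,
      theta_mode = numeric(0), params = fixed, hessian = NULL, cov = NULL,
      log_evidence = lp, log_posterior = lp, converged = TRUE,
      hessian_repaired = FALSE, n_restarts_used = 0L
    ), class = "subject_fit"))
  }

  set.seed(seed)
  starts <- list(if (!is.null(init)) init[free] else pm)
  if (n_restarts > 1) {
    for (i in 2:n_restarts) {
      starts[[i]] <- pm + rnorm(d, sd = 0.8 * sqrt(pv))
    }
  }

  best <- NULL
  used <- 0L
  for (st in starts) {
    res <- tryCatch(
      optim(st, negpost, method = "BFGS", control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    used <- used + 1L
    if (is.null(best) || res$value < best$value - 1e-9) best <- res
  }
  if (is.null(best)) abort("all optimizer restarts failed.")

  H <- tryCatch(optimHess(best$par, negpost), error = function(e) NULL)
  repaired <- FALSE
  if (is.null(H) || anyNA(H)) {
    H <- diag(1, d)
    repaired <- TRUE
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8 || min(ev) <= max(ev) * 1e-12) {
    # not positive-definite (or hopelessly ill-conditioned, e.g. sigma
    # collapsing on noise-free data): diagonal regularization, flagged
    H <- H + diag(abs(min(ev)) + max(ev) * 1e-12 + 1e-6, d)
    repaired <- TRUE
  }
  cov <- solve(H)
  lp <- -best$value
  log_evidence <- lp + d / 2 * log(2 * pi) -
    0.5 * determinant(H, logarithm = TRUE)$modulus[1]

  theta <- setNames(best$par, free)
  params <- c(untransform_pars(theta, free), fixed)

  structure(list(
    subject_id = trials$subject_id[1] %||% NA, model = model,
    theta_mode = theta, params = params[nms[nms %in% names(params)]],
    hessian = H, cov = cov,
    log_evidence = as.numeric(log_evidence), log_posterior = lp,
    converged = best$convergence == 0, hessian_repaired = repaired,
    n_restarts_used = used
  ), class = "subject_fit")
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf(
    "<subject_fit> model %d, log evidence %.2f (%d free parameters)\n",
    x$model, x$log_evidence, length(x$theta_mode)
  ))
  p <- unlist(x$params)
  cat("  ", paste(sprintf("%s = %.3f", names(p), p), collapse = ", "), "\n")
  invisible(x)
}

#' Fit every subject of a cohort with one model (independent MAP fits)
#'
#' @param trials cohort trial tibble (recoded).
#' @inheritParams fit_subject
#' @return object of class `cohort_fit`: list of `subject_fit` plus metadata.
#' @export
fit_cohort <- function(trials, space = NULL, model, prior_mean = NULL,
                       prior_var = NULL, n_restarts = 3, seed = 1L,
                       pe_source = c("mixed", "accumulator")) {
  pe_source <- match.arg(pe_source)
  ids <- unique(trials$subject_id)
  fits <- purrr::imap(split(trials, trials$subject_id)[as.character(ids)],
    function(tr, id) {
      fit_subject(tr, space, model, prior_mean, prior_var, n_restarts,
                  seed = derive_seed(seed, "subject", match(id, as.character(ids))),
                  pe_source = pe_source)
    })
  structure(list(fits = fits, model = as.integer(model),
                 subject_ids = ids), class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("<cohort_fit> model %d, %d subjects, total log evidence %.2f\n",
              x$model, length(x$fits),
              sum(vapply(x$fits, `[[`, numeric(1), "log_evidence"))))
  invisible(x)
}
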