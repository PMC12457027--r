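#' Hierarchical fit with model identity as a random effect
#'
#' Iterates between (1) per-subject MAP fits with Laplace evidence under the
#' current Gaussian population priors for every candidate model, (2) a
#' responsibility update that combines subject evidences with the current
#' Dirichlet model weights, (3) responsibility-weighted updates of each
#' model's population mean and variance (with a curvature correction from
#' the Laplace covariances and one pseudo-subject at the initial prior for
#' stability), and (4) a Dirichlet count update from the summed
#' responsibilities.  Convergence is declared when responsibilities change
#' by less than `tol`.
#'
#' @param trials recoded trial tibble for the whole cohort (>= 2 subjects).
#' @param space a [trait_space][build_trait_space].
#' @param models candidate model ids.
#' @param max_iter maximum outer iterations.
#' @param tol convergence tolerance on the responsibility matrix.
#' @param n_restarts optimizer restarts in the first iteration.
#' @param warm_restarts restarts in later iterations (warm-started at the
#'   previous mode).
#' @param dirichlet_prior prior Dirichlet count per model (default 1,
#'   uniform).
#' @param n_mc Monte-Carlo samples for exceedance probabilities and BOR.
#' @param seed master seed (optimizer jitter and MC).
#' @param keep_fits keep the per-subject fit objects (needed for
#'   posterior-predictive checks).
#' @inheritParams predict_trajectory
#' @return object of class `hbi_fit` with responsibilities, Dirichlet counts,
#'   model frequencies, exceedance probabilities (`ep`), `bor`, protected
#'   exceedance probabilities (`pxp`), population summaries, the
#'   subject-by-model log-evidence matrix, and (optionally) all fits.
#' @export
fit_hierarchical <- function(trials, space, models = 1:5, max_iter = 8,
                             tol = 1e-3, n_restarts = 3, warm_restarts = 1,
                             dirichlet_prior = 1, n_mc = 10000, seed = 1L,
                             keep_fits = TRUE,
                             pe_source = c("mixed", "accumulator")) {
  pe_source <- match.arg(pe_source)
  ids <- unique(trials$subject_id)
  nS <- length(ids)
  if (nS < 2) abort("hierarchical fitting needs at least 2 subjects.")
  M <- length(models)
  by_subj <- split(trials, trials$subject_id)[as.character(ids)]

  priors <- lapply(models, default_prior)
  prior0 <- priors
  fits <- lapply(seq_len(M), function(m) vector("list", nS))
  L <- matrix(NA_real_, nS, M, dimnames = list(ids, paste0("m", models)))
  alpha <- rep(dirichlet_prior, M)
  r_prev <- matrix(1 / M, nS, M)
  converged <- FALSE
  it <- 0L

  while (it < max_iter) {
    it <- it + 1L
    for (m in seq_len(M)) {
      for (n in seq_len(nS)) {
        prev <- fits[[m]][[n]]
        fits[[m]][[n]] <- fit_subject(
          by_subj[[n]], space, models[m],
          prior_mean = priors[[m]]$mean, prior_var = priors[[m]]$var,
          n_restarts = if (it == 1L) n_restarts else warm_restarts,
          seed = derive_seed(seed, "hbi", it * 100000L + m * 1000L + n),
          init = if (!is.null(prev)) prev$theta_mode else NULL,
          pe_source = pe_source
        )
        L[n, m] <- fits[[m]][[n]]$log_evidence
      }
    }

    # responsibilities: evidence + expected log Dirichlet weight
    lw <- digamma(alpha) - digamma(sum(alpha))
    lr <- sweep(L, 2, lw, `+`)
    r <- exp(lr - apply(lr, 1, logsumexp))
    alpha <- dirichlet_prior + colSums(r)

    # population update: the mean is the pure responsibility-weighted mean of
    # the subject modes; the variance is curvature-corrected and stabilized
    # by one pseudo-subject at the initial prior (so a model with near-zero
    # responsibility keeps a usable prior instead of collapsing)
    for (m in seq_len(M)) {
      th <- do.call(rbind, lapply(fits[[m]], `[[`, "theta_mode"))
      vg <- do.call(rbind, lapply(fits[[m]], function(f) diag(f$cov)))
      w <- r[, m]
      sw <- sum(w)
      if (sw > 1e-3) {
        mu <- colSums(w * th) / sw
      } else {
        mu <- priors[[m]]$mean
      }
      v <- (colSums(w * (sweep(th, 2, mu)^2 + vg)) +
              (prior0[[m]]$mean - mu)^2 + prior0[[m]]$var) / (sw + 1)
      priors[[m]]$mean <- mu
      priors[[m]]$var <- pmax(v, 1e-2)
    }

    if (max(abs(r - r_prev)) < tol) {
      converged <- TRUE
      r_prev <- r
      break
    }
    r_prev <- r
  }
  r <- r_prev

  px <- compute_pxp(alpha, log_evidence = L, n_samples = n_mc,
                    seed = derive_seed(seed, "pxp"))

  population <- purrr::map_dfr(seq_len(M), function(m) {
    tibble::tibble(
      model = models[m],
      term = names(priors[[m]]$mean),
      mean = unname(priors[[m]]$mean),
      var = unname(priors[[m]]$var),
      mean_natural = vapply(
        names(priors[[m]]$mean),
        function(nm) par_from_unconstrained(nm, priors[[m]]$mean[[nm]]),
        numeric(1)
      )
    )
  })

  structure(list(
    models = models, subject_ids = ids,
    responsibilities = `dimnames<-`(r, list(ids, paste0("m", models))),
    alpha = setNames(alpha, paste0("m", models)),
    model_frequency = setNames(alpha / sum(alpha), paste0("m", models)),
    ep = px$ep, bor = px$bor, pxp = px$pxp,
    log_evidence = L, population = population,
    fits = if (keep_fits) setNames(fits, paste0("m", models)) else NULL,
    n_iter = it, converged = converged
  ), class = "hbi_fit")
}

#' @export
print.hbi_fit <- function(x, ...) {
  cat(sprintf(
    "<hbi_fit> %d subjects, models {%s}, %d iteration(s)%s\n",
    length(x$subject_ids), paste(x$models, collapse = ","), x$n_iter,
    if (x$converged) "" else " (not converged)"
  ))
  cat(sprintf("  frequency: %s\n",
              paste(sprintf("%.3f", x$model_frequency), collapse = " ")))
  cat(sprintf("  pxp:       %s  (bor %.3f)\n",
              paste(sprintf("%.3f", x$pxp), collapse = " "), x$bor))
  invisible(x)
}

#' Exceedance and protected exceedance probabilities
#'
#' Exceedance probabilities are Monte-Carlo estimates of the probability
#' that each model's population frequency is the largest under the Dirichlet
#' posterior.  The Bayes omnibus risk (BOR) is the posterior probability of
#' the null that all model frequencies are equal, computed by comparing the
#' marginal likelihood of the subject evidences under a uniform-frequency
#' null with a Monte-Carlo integral over the Dirichlet prior.  The protected
#' exceedance probability is `pxp = ep * (1 - bor) + bor / M`.
#'
#' @param alpha posterior Dirichlet counts (length M, all >= the prior
#'   counts).
#' @param log_evidence optional subjects x models matrix of log evidences;
#'   required for `bor` (without it `bor` is `NA` and `pxp` equals the
#'   unprotected `ep`).
#' @param n_samples Monte-Carlo samples (>= 1e4 recommended).
#' @param seed MC seed.
#' @param dirichlet_prior prior count per model used in the BOR integral.
#' @return list with `ep`, `bor`, `pxp` and `mc_se` (MC standard error of
#'   `ep`).
#' @export
compute_pxp <- function(alpha, log_evidence = NULL, n_samples = 10000,
                        seed = 1L, dirichlet_prior = 1) {
  M <- length(alpha)
  if (any(alpha < dirichlet_prior - 1e-12)) {
    abort("Dirichlet counts must be at least the prior counts.")
  }
  if (n_samples < 10000) {
    warn("n_samples < 1e4: Monte-Carlo standard error may be large.")
  }
  set.seed(seed)
  g <- matrix(rgamma(n_samples * M, shape = rep(alpha, each = n_samples)),
              n_samples, M)
  ep <- tabulate(max.col(g, ties.method = "random"), M) / n_samples
  mc_se <- sqrt(ep * (1 - ep) / n_samples)

  if (is.null(log_evidence)) {
    return(list(ep = ep, bor = NA_real_, pxp = ep, mc_se = mc_se))
  }
  L <- as.matrix(log_evidence)
  stopifnot(ncol(L) == M)
  # H0: all frequencies equal 1/M
  f0 <- sum(apply(L, 1, logsumexp) - log(M))
  # H1: frequencies ~ Dirichlet(prior); MC integral over the prior.
  # p(y | r) = prod_n sum_m r_m exp(L_nm), stabilized by the row maxima.
  rp <- matrix(rgamma(n_samples * M, shape = dirichlet_prior), n_samples, M)
  rp <- rp / rowSums(rp)
  rmax <- apply(L, 1, max)
  B <- exp(L - rmax) # subjects x models
  logp <- colSums(log(B %*% t(rp))) + sum(rmax)
  f1 <- logsumexp(logp) - log(n_samples)
  bor <- stats::plogis(f0 - f1)
  list(ep = ep, bor = bor, pxp = ep * (1 - bor) + bor / M, mc_se = mc_se)
}

#' Export a hierarchical fit
#'
#' Writes population statistics, model frequencies, exceedance summaries and
#' metadata to JSON, and the responsibility matrix to CSV.
#'
#' @param fit an `hbi_fit`.
#' @param json_path,resp_csv_path output paths.
#' @return `fit`, invisibly.
#' @export
write_hbi_fit <- function(fit, json_path, resp_csv_path) {
  jsonlite::write_json(
    list(
      models = fit$models,
      model_frequency = unname(fit$model_frequency),
      alpha = unname(fit$alpha),
      ep = fit$ep, bor = fit$bor, pxp = fit$pxp,
      population = fit$population,
      n_iter = fit$n_iter, converged = fit$converged
    ),
    json_path, digits = NA, auto_unbox = TRUE
  )
  resp <- tibble::as_tibble(fit$responsibilities)
  resp <- dplyr::bind_cols(tibble::tibble(subject_id = fit$subject_ids), resp)
  readr::write_csv(resp, resp_csv_path)
  invisible(fit)
}
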