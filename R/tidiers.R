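#' Tidy a single-subject fit
#'
#' One row per free parameter with the natural-scale estimate and a
#' delta-method standard error from the Laplace covariance.
#'
#' @param x a [subject_fit][fit_subject].
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.subject_fit <- function(x, ...) {
  free <- names(x$theta_mode)
  if (!length(free)) {
    return(tibble::tibble(term = character(), estimate = double(),
                          std.error = double()))
  }
  se_theta <- sqrt(diag(x$cov))
  jac <- vapply(seq_along(free), function(i) {
    nm <- free[i]; th <- x$theta_mode[i]
    switch(nm,
      alpha = , alpha_plus = , alpha_minus = , gamma =
        stats::plogis(th) * (1 - stats::plogis(th)),
      E1 = 99 * stats::plogis(th) * (1 - stats::plogis(th)),
      sigma = exp(th),
      1
    )
  }, numeric(1))
  tibble::tibble(
    term = free,
    estimate = vapply(free, function(nm) x$params[[nm]], numeric(1)),
    std.error = se_theta * jac
  )
}

#' @export
glance.subject_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    log_evidence = x$log_evidence,
    log_posterior = x$log_posterior,
    n_parameters = length(x$theta_mode),
    converged = x$converged,
    hessian_repaired = x$hessian_repaired,
    n_restarts_used = x$n_restarts_used
  )
}

#' Tidy a cohort fit: one row per subject and parameter
#'
#' @param x a [cohort_fit][fit_cohort].
#' @param ... unused.
#' @export
tidy.cohort_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    dplyr::bind_cols(tibble::tibble(subject_id = f$subject_id), tidy(f))
  })
}

#' @export
glance.cohort_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_subjects = length(x$fits),
    total_log_evidence = sum(vapply(x$fits, `[[`, numeric(1), "log_evidence")),
    n_not_converged = sum(!vapply(x$fits, `[[`, logical(1), "converged"))
  )
}

#' Tidy a hierarchical fit: one row per candidate model
#'
#' @param x an [hbi_fit][fit_hierarchical].
#' @param ... unused.
#' @return tibble with model frequencies, exceedance and protected
#'   exceedance probabilities.
#' @export
tidy.hbi_fit <- function(x, ...) {
  tibble::tibble(
    model = x$models,
    frequency = unname(x$model_frequency),
    ep = x$ep,
    pxp = x$pxp,
    alpha = unname(x$alpha)
  )
}

#' @export
glance.hbi_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subject_ids),
    n_models = length(x$models),
    bor = x$bor,
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Tidy a recovery report: per-parameter recovery correlations
#'
#' @param x a [recovery_report][run_parameter_recovery].
#' @param ... unused.
#' @return tibble with `term`, `r`, `n`.
#' @export
tidy.recovery_report <- function(x, ...) {
  x$estimates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      r = if (sd(.data$true) == 0) NA_real_ else
        cor(.data$true, .data$recovered),
      n = dplyr::n(), .groups = "drop"
    )
}

#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(model = x$model, n_sims = x$n_sims, n_failed = x$n_failed,
                 sigma_sim = x$sigma_sim, seed = x$seed)
}

#' Tidy a confusion report into long format
#'
#' @param x a [confusion_report][run_confusion].
#' @param ... unused.
#' @return tibble with `generator`, `candidate`, `ep`.
#' @export
tidy.confusion_report <- function(x, ...) {
  tibble::as_tibble(as.table(x$ep), .name_repair = "minimal") |>
    setNames(c("generator", "candidate", "ep")) |>
    tibble::as_tibble()
}

#' @export
glance.confusion_report <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$models), n_cohorts = x$n_cohorts,
    n_subjects = x$n_subjects,
    mean_diagonal_ep = mean(diag(x$ep)),
    min_diagonal_ep = min(diag(x$ep))
  )
}

#' Tidy a deviation report: the group contrasts per parameter
#'
#' @param x a [deviation_report][deviation_analysis].
#' @param ... unused.
#' @export
tidy.deviation_report <- function(x, ...) {
  if (is.null(x$contrasts)) {
    x$deviations |>
      dplyr::group_by(.data$term) |>
      dplyr::summarise(mean_deviation = mean(.data$deviation),
                       sd_deviation = sd(.data$deviation), .groups = "drop")
  } else {
    x$contrasts
  }
}

#' Tidy a posterior-predictive check: one row per trial position
#'
#' @param x a [ppc_report][run_ppc].
#' @param ... unused.
#' @export
tidy.ppc_report <- function(x, ...) x$by_trial

#' @export
glance.ppc_report <- function(x, ...) {
  tibble::tibble(model = x$model, n_draws = x$n_draws, level = x$level,
                 coverage = x$coverage)
}

#' @export
tidy.model_free_summary <- function(x, ...) x$subjects

#' @export
glance.model_free_summary <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    mean_pe_slope = mean(x$subjects$pe_slope, na.rm = TRUE),
    mean_self_role_r = mean(x$subjects$self_role_r, na.rm = TRUE)
  )
}
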