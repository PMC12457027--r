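#' Linear trend of absolute prediction errors over trials
#'
#' OLS slope of `|feedback - role|` on trial index for one subject: a
#' model-free learning check (a negative slope means role estimates converge
#' on the feedback over the task).
#'
#' @param trials single-subject trial tibble (recoded).
#' @return the slope, or `NA` (with a warning) for fewer than 3 non-missing
#'   trials.
#' @export
pe_trend <- function(trials) {
  trials <- check_subject_trials(trials)
  ok <- !trials$missing
  if (sum(ok) < 3) {
    warn("fewer than 3 non-missing trials: slope undefined.")
    return(NA_real_)
  }
  abs_pe <- abs(trials$feedback[ok] - trials$role[ok])
  unname(coef(lm(abs_pe ~ trials$t[ok]))[2])
}

#' Pearson correlation between self-ratings and role estimates
#'
#' @param trials single-subject trial tibble (recoded).
#' @return Pearson r over non-missing trials, or `NA` (with a warning) when
#'   undefined (fewer than 3 trials or a constant series).
#' @export
self_role_correlation <- function(trials) {
  trials <- check_subject_trials(trials)
  ok <- !trials$missing
  if (sum(ok) < 3) {
    warn("fewer than 3 non-missing trials: correlation undefined.")
    return(NA_real_)
  }
  s <- trials$self[ok]
  r <- trials$role[ok]
  if (sd(s) == 0 || sd(r) == 0) {
    warn("constant series: correlation undefined.")
    return(NA_real_)
  }
  cor(s, r)
}

#' Welch two-sample contrast with effect size
#'
#' Welch t statistic with Satterthwaite degrees of freedom, the 95% CI of
#' the mean difference, and Cohen's d with the pooled SD.
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @return one-row tibble: `estimate` (mean difference), `t`, `df`,
#'   `p.value`, `d`, `conf.low`, `conf.high`.
#' @export
group_contrast <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values.")
  }
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    abort("zero variance in both groups: contrast undefined.")
  }
  tt <- t.test(values_a, values_b)
  na <- length(values_a); nb <- length(values_b)
  sp <- sqrt(((na - 1) * sd(values_a)^2 + (nb - 1) * sd(values_b)^2) /
               (na + nb - 2))
  tibble::tibble(
    estimate = mean(values_a) - mean(values_b),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    d = (mean(values_a) - mean(values_b)) / sp,
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2]
  )
}

#' Model-free summary of a cohort
#'
#' Per subject: the [pe_trend()] slope and the [self_role_correlation()];
#' optionally Welch contrasts of both measures between two labelled groups.
#'
#' @param trials cohort trial tibble (recoded).
#' @param groups optional tibble (`subject_id`, `group`, two levels).
#' @return object of class `model_free_summary` with `subjects` (one row per
#'   subject) and `contrasts` (or NULL).
#' @export
model_free_summary <- function(trials, groups = NULL) {
  subjects <- purrr::map_dfr(split(trials, trials$subject_id), function(tr) {
    tibble::tibble(
      subject_id = tr$subject_id[1],
      pe_slope = suppressWarnings(pe_trend(tr)),
      self_role_r = suppressWarnings(self_role_correlation(tr))
    )
  })
  contrasts <- NULL
  if (!is.null(groups)) {
    groups <- tibble::as_tibble(groups)
    lev <- sort(unique(groups$group))
    if (length(lev) != 2) abort("`groups` must have exactly two levels.")
    subjects <- dplyr::left_join(subjects, groups, by = "subject_id")
    contrasts <- purrr::map_dfr(c("pe_slope", "self_role_r"), function(m) {
      a <- subjects[[m]][subjects$group == lev[1]]
      b <- subjects[[m]][subjects$group == lev[2]]
      dplyr::bind_cols(tibble::tibble(measure = m),
                       group_contrast(a[!is.na(a)], b[!is.na(b)]))
    })
  }
  structure(list(subjects = subjects, contrasts = contrasts),
            class = "model_free_summary")
}

#' @export
print.model_free_summary <- function(x, ...) {
  cat(sprintf(
    "<model_free_summary> %d subjects: mean |PE| slope %.3f, mean self-role r %.3f\n",
    nrow(x$subjects), mean(x$subjects$pe_slope, na.rm = TRUE),
    mean(x$subjects$self_role_r, na.rm = TRUE)
  ))
  if (!is.null(x$contrasts)) print(x$contrasts)
  invisible(x)
}
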