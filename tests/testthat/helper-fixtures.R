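# Fixtures are built in code; no data files.

# A fixed 5-rater x 3-trait raw pool, small enough to hand-check.
fixed_pool <- function() {
  matrix(c(
    40, 62, 55,
    55, 70, 48,
    35, 58, 61,
    60, 80, 42,
    50, 66, 50
  ), nrow = 5, byrow = TRUE)
}

fixed_traits <- function(valence = c(1, 1, 1)) {
  tibble::tibble(trait_id = 0:2, label = c("A", "B", "C"), valence = valence)
}

tiny_space <- function(valence = c(1, 1, 1)) {
  build_trait_space(fixed_pool(), fixed_traits(valence))
}

# Hand-set trait space for worked examples (identity-free SIM control).
hand_space <- function(sim, feedback_mean = rep(60, nrow(sim)),
                       col_mean = rep(50, nrow(sim)),
                       col_sd = rep(10, nrow(sim))) {
  trait_space(sim, feedback_mean, col_mean = col_mean, col_sd = col_sd)
}

make_trials <- function(trait_id, self, feedback, role = NA_real_,
                        valence = 1L, subject_id = 1L, missing = NULL) {
  n <- length(trait_id)
  tibble::tibble(
    subject_id = subject_id, t = seq_len(n), trait_id = trait_id,
    valence = rep_len(valence, n), self = self,
    role = rep_len(role, n), feedback = feedback,
    missing = missing %||% rep(FALSE, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent step-by-step reimplementation of the learning recursion, used
# as a spreadsheet-style oracle.  Deliberately plain loops; shares no code
# with the package's compiled path.
oracle_trajectory <- function(trials, space, params, pe_source = "mixed") {
  Tn <- nrow(trials)
  idx <- match(trials$trait_id, space$traits$trait_id)
  E <- initial_expectations(space, trials$trait_id, params$E1)
  P <- Pm <- PE <- w <- numeric(Tn)
  g <- params$gamma %||% 0
  for (t in seq_len(Tn)) {
    acc <- 0
    if (t > 1) {
      for (i in seq_len(t - 1)) {
        acc <- acc + w[i] * PE[i] * space$sim[idx[i], idx[t]]
      }
    }
    Pm[t] <- E[t] + acc
    P[t] <- g * trials$self[t] + (1 - g) * Pm[t]
    if (isTRUE(trials$missing[t])) {
      PE[t] <- 0
      w[t] <- 0
      next
    }
    base <- if (pe_source == "mixed") P[t] else Pm[t]
    PE[t] <- trials$feedback[t] - base
    ap <- params$alpha_plus %||% params$alpha
    am <- params$alpha_minus %||% params$alpha
    w[t] <- if (abs(trials$feedback[t] - trials$self[t]) <=
                abs(P[t] - trials$self[t])) ap else am
  }
  list(P = P, Pm = Pm, PE = PE, E = E)
}

# Textbook Pearson correlation, used as the independent oracle for SIM.
pearson_by_formula <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

default_task_space <- function(seed = 11) {
  traits <- make_trait_lexicon()
  pool <- simulate_rater_pool(traits, seed = seed)
  build_trait_space(pool, traits)
}
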