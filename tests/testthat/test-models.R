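test_that("model 1 is a pure linear transformation of self-ratings", {
  tr <- make_trials(0:1, self = c(40, 60), feedback = c(50, 50))
  expect_equal(predict_trajectory(tr, NULL, 1,
                                  list(beta0 = 0, beta1 = 1))$P, c(40, 60))
  expect_equal(predict_trajectory(tr, NULL, 1,
                                  list(beta0 = 50, beta1 = 0))$P, c(50, 50))
  tr2 <- make_trials(0L, self = 30, feedback = 50)
  expect_equal(predict_trajectory(tr2, NULL, 1,
                                  list(beta0 = 10, beta1 = 0.5))$P, 25)
})

test_that("initial expectations follow the pool regressions, with identity and reversal limits", {
  # every trait identical to the reference: E(t) = E1 throughout
  sid <- matrix(1, 3, 3)
  sp <- hand_space(sid, col_mean = c(50, 50, 50), col_sd = c(8, 8, 8))
  expect_equal(initial_expectations(sp, 0:2, 37), rep(37, 3))

  # perfect mirror: E = 101 - E1 (recoded mirror of the first trait)
  smir <- matrix(c(1, -1, -1, 1), 2)
  sp2 <- trait_space(smir, feedback_mean = c(60, 41),
                     col_mean = c(60, 41), col_sd = c(8, 8))
  expect_equal(initial_expectations(sp2, 0:1, 30), c(30, 101 - 30))

  # hand OLS on the fixed 5 x 3 pool, presentation order 2, 0, 1
  pool <- fixed_pool()
  space <- tiny_space()
  ord <- c(2L, 0L, 1L)
  E1 <- 45
  e <- initial_expectations(space, ord, E1)
  expect_equal(e[1], E1)
  for (k in 2:3) {
    fit <- lm(pool[, ord[k] + 1] ~ pool[, 3])
    expect_equal(e[k],
                 min(100, max(1, unname(coef(fit)[1] + coef(fit)[2] * E1))),
                 tolerance = 1e-10)
  }
})

test_that("a prediction error spreads to an upcoming trait in proportion to their similarity", {
  # PE of 30 on the first trait, similarity 0.5, learning rate 1:
  # the second trait's prediction moves 15 points above its expectation
  sim <- matrix(c(1, 0.5, 0.5, 1), 2)
  sp <- hand_space(sim, col_mean = c(50, 50), col_sd = c(10, 10))
  E1 <- 50
  tr <- make_trials(0:1, self = c(50, 50), feedback = c(E1 + 30, 70))
  traj <- predict_trajectory(tr, sp, 2, list(alpha = 1, E1 = E1))
  expect_equal(traj$PE[1], 30)
  expect_equal(traj$P[2] - traj$E[2], 15)
  # and the update scales with the learning rate
  traj_half <- predict_trajectory(tr, sp, 2, list(alpha = 0.5, E1 = E1))
  expect_equal(traj_half$P[2] - traj_half$E[2], 7.5)
})

test_that("with alpha = 0 or an identity similarity matrix, predictions stay at the expectations", {
  space <- tiny_space()
  tr <- make_trials(c(1L, 0L, 2L), self = c(40, 55, 62),
                    feedback = c(80, 20, 65))
  traj <- predict_trajectory(tr, space, 2, list(alpha = 0, E1 = 44))
  expect_equal(traj$P, traj$E)

  spI <- hand_space(diag(3), col_mean = c(40, 50, 60), col_sd = c(9, 9, 9))
  trajI <- predict_trajectory(tr, spI, 2, list(alpha = 0.9, E1 = 44))
  expect_equal(trajI$P, trajI$E)
})

test_that("the model family collapses along its reduction lattice", {
  space <- default_task_space()
  set.seed(77)
  for (rep in 1:12) {
    alpha <- runif(1)
    gamma <- runif(1, 0.05, 0.95)
    E1 <- runif(1, 10, 90)
    tr <- simulate_subject(space, 5,
                           list(alpha_plus = runif(1), alpha_minus = runif(1),
                                gamma = 0.4, E1 = 50),
                           order_seed = rep, noise_seed = 100 + rep,
                           sigma_sim = 8)
    p2 <- predict_trajectory(tr, space, 2, list(alpha = alpha, E1 = E1))
    p3 <- predict_trajectory(tr, space, 3,
                             list(alpha_plus = alpha, alpha_minus = alpha,
                                  E1 = E1))
    p4 <- predict_trajectory(tr, space, 4,
                             list(alpha = alpha, gamma = gamma, E1 = E1))
    p4g0 <- predict_trajectory(tr, space, 4,
                               list(alpha = alpha, gamma = 1e-12, E1 = E1))
    p5 <- predict_trajectory(tr, space, 5,
                             list(alpha_plus = alpha, alpha_minus = alpha,
                                  gamma = gamma, E1 = E1))
    p5g0 <- predict_trajectory(tr, space, 5,
                               list(alpha_plus = alpha, alpha_minus = alpha,
                                    gamma = 1e-12, E1 = E1))
    expect_equal(p3$P, p2$P, tolerance = 1e-10)
    expect_equal(p4g0$P, p2$P, tolerance = 1e-8)
    expect_equal(p5$P, p4$P, tolerance = 1e-10)
    expect_equal(p5g0$P, p2$P, tolerance = 1e-8)
  }
})

test_that("trajectories match an independent step-by-step oracle on fixture subjects", {
  space <- tiny_space()
  tr <- make_trials(c(2L, 0L, 1L), self = c(45, 60, 38),
                    feedback = c(72, 30, 55))
  cases <- list(
    list(model = 2, params = list(alpha = 0.6, E1 = 40)),
    list(model = 3, params = list(alpha_plus = 0.8, alpha_minus = 0.2,
                                  E1 = 40)),
    list(model = 4, params = list(alpha = 0.6, gamma = 0.35, E1 = 40)),
    list(model = 5, params = list(alpha_plus = 0.8, alpha_minus = 0.2,
                                  gamma = 0.35, E1 = 40))
  )
  for (cs in cases) {
    got <- predict_trajectory(tr, space, cs$model, cs$params)
    want <- oracle_trajectory(tr, space, cs$params)
    expect_equal(got$P, want$P, tolerance = 1e-10)
    expect_equal(got$Pm, want$Pm, tolerance = 1e-10)
    expect_equal(got$PE, want$PE, tolerance = 1e-10)
    expect_equal(got$E, want$E, tolerance = 1e-10)
  }
  # larger random fixture against the oracle, both PE conventions
  space2 <- default_task_space()
  p <- list(alpha_plus = 0.7, alpha_minus = 0.15, gamma = 0.45, E1 = 62)
  tr2 <- simulate_subject(space2, 5, p, order_seed = 12, noise_seed = 13,
                          sigma_sim = 8)
  for (src in c("mixed", "accumulator")) {
    got <- predict_trajectory(tr2, space2, 5, p, pe_source = src)
    want <- oracle_trajectory(tr2, space2, p, pe_source = src)
    expect_equal(got$P, want$P, tolerance = 1e-10)
  }
})

test_that("dissonance-based rate selection applies the plus rate to ties", {
  # first trial: P(1) = E1 = 40, S = 50, F = 60 -> |F-S| = |P-S| = 10 (tie)
  sim <- matrix(c(1, 0.5, 0.5, 1), 2)
  sp <- hand_space(sim, col_mean = c(40, 50), col_sd = c(10, 10))
  tr <- make_trials(0:1, self = c(50, 50), feedback = c(60, 55))
  base <- predict_trajectory(tr, sp, 3,
                             list(alpha_plus = 0.8, alpha_minus = 0.8,
                                  E1 = 40))
  tie_plus <- predict_trajectory(tr, sp, 3,
                                 list(alpha_plus = 0.8, alpha_minus = 0.1,
                                      E1 = 40))
  # the tied trial must use alpha_plus, so lowering alpha_minus changes nothing
  expect_equal(tie_plus$P[2], base$P[2], tolerance = 1e-12)

  # dissonance-amplifying trial (F farther from S than P) takes alpha_minus
  tr2 <- make_trials(0:1, self = c(50, 50), feedback = c(10, 55))
  lo <- predict_trajectory(tr2, sp, 3,
                           list(alpha_plus = 0.8, alpha_minus = 0.1, E1 = 40))
  hi <- predict_trajectory(tr2, sp, 3,
                           list(alpha_plus = 0.8, alpha_minus = 0.6, E1 = 40))
  expect_equal(lo$P[2] - lo$E[2], 0.1 * (10 - 40) * 0.5, tolerance = 1e-12)
  expect_equal(hi$P[2] - hi$E[2], 0.6 * (10 - 40) * 0.5, tolerance = 1e-12)
})

test_that("trajectories are covariant under a consistent trait relabelling", {
  space <- tiny_space()
  p <- list(alpha = 0.5, gamma = 0.3, E1 = 45)
  tr <- make_trials(c(0L, 1L, 2L), self = c(45, 60, 38),
                    feedback = c(72, 30, 55))
  traj <- predict_trajectory(tr, space, 4, p)

  # relabel traits 0,1,2 -> 2,0,1 everywhere (space columns and trial ids)
  perm <- c(2L, 0L, 1L) # new id of old trait k = perm[k+1]
  ord <- order(perm)
  pool <- fixed_pool()[, ord]
  space2 <- build_trait_space(pool, fixed_traits())
  tr2 <- tr
  tr2$trait_id <- perm[tr$trait_id + 1]
  traj2 <- predict_trajectory(tr2, space2, 4, p)
  expect_equal(traj2$P, traj$P, tolerance = 1e-10)
  expect_equal(traj2$PE, traj$PE, tolerance = 1e-10)
})

test_that("missing trials contribute no prediction error and no likelihood", {
  space <- tiny_space()
  p <- list(alpha = 0.7, E1 = 40, sigma = 6)
  tr <- make_trials(c(0L, 1L, 2L), self = c(45, 60, 38),
                    feedback = c(72, 30, 55), role = c(50, NA, 60),
                    missing = c(FALSE, TRUE, FALSE))
  got <- predict_trajectory(tr, space, 2, p)
  want <- oracle_trajectory(tr, space, p)
  expect_equal(got$P, want$P, tolerance = 1e-12)
  expect_true(is.na(got$PE[2]))

  ll <- model_loglik(tr, space, 2, p)
  resid <- tr$role[c(1, 3)] - got$P[c(1, 3)]
  ll_hand <- -0.5 * sum((resid / p$sigma)^2) -
    2 * log(p$sigma * sqrt(2 * pi))
  expect_equal(ll, ll_hand, tolerance = 1e-10)
})

test_that("the observation log-likelihood obeys Gaussian closed forms", {
  space <- tiny_space()
  p <- list(alpha = 0.4, E1 = 50)
  tr <- make_trials(c(0L, 1L, 2L), self = c(45, 60, 38),
                    feedback = c(72, 30, 55))
  traj <- predict_trajectory(tr, space, 2, p)
  tr$role <- traj$P # zero residuals
  for (sig in c(2, 8)) {
    expect_equal(model_loglik(tr, space, 2, c(p, sigma = sig)),
                 3 * log(1 / (sig * sqrt(2 * pi))), tolerance = 1e-10)
  }
  # doubling sigma with fixed residuals: ll(2s) = ll(s) - T log 2 + (3/8) sum z^2
  tr$role <- traj$P + c(3, -5, 2)
  s <- 4
  z2 <- sum((c(3, -5, 2) / s)^2)
  expect_equal(model_loglik(tr, space, 2, c(p, sigma = 2 * s)),
               model_loglik(tr, space, 2, c(p, sigma = s)) -
                 3 * log(2) + (3 / 8) * z2,
               tolerance = 1e-10)
  expect_error(model_loglik(tr, space, 2, c(p, sigma = 0)), "sigma")
})

test_that("parameter validation rejects out-of-range and misplaced parameters", {
  expect_error(model_params(2, alpha = 1.2, E1 = 50), "alpha")
  expect_error(model_params(4, alpha = 0.5, gamma = -0.1, E1 = 50), "gamma")
  expect_error(model_params(2, alpha = 0.5, E1 = 120), "E1")
  expect_error(model_params(2, alpha = 0.5), "needs parameters")
  expect_error(model_params(2, alpha = 0.5, E1 = 50, beta0 = 1), "not in model")
  expect_error(model_params(6, alpha = 0.5), "1..5")
  ok <- model_params(5, alpha_plus = 0.8, alpha_minus = 0.2, gamma = 0.5,
                     E1 = 50, sigma = 4)
  expect_s3_class(ok, "model_params")
})
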