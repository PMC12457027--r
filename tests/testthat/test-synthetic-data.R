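test_that("pool and cohort generation are deterministic given seeds", {
  traits <- make_trait_lexicon(5, 5)
  p1 <- simulate_rater_pool(traits, seed = 42)
  p2 <- simulate_rater_pool(traits, seed = 42)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_rater_pool(traits, seed = 43)))

  cfg <- sim_config(3, model = 4, K = 10, n_pos = 5, n_neg = 5, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$params, c2$params)
})

test_that("emitted ratings stay on the 1-100 slider and the manifest is complete", {
  cfg <- sim_config(3, model = 5, K = 10, n_pos = 5, n_neg = 5,
                    sigma_sim = 25, seed = 4)
  co <- simulate_cohort(cfg)
  for (col in c("self", "role", "feedback")) {
    expect_true(all(co$trials[[col]] >= 1 & co$trials[[col]] <= 100))
    expect_false(anyNA(co$trials[[col]]))
  }
  expect_equal(nrow(co$params), 3)
  expect_true(all(c("alpha_plus", "alpha_minus", "gamma", "E1",
                    "sigma_sim", "order_seed", "noise_seed",
                    "master_seed") %in% names(co$params)))
  # each trait exactly once per subject, contiguous trial index
  per <- dplyr::count(co$trials, subject_id, trait_id)
  expect_true(all(per$n == 1))
  expect_equal(sort(unique(co$trials$t)), 1:10)
})

test_that("a single-factor noise-free pool gives rank-1 similarity (all +-1)", {
  traits <- make_trait_lexicon(3, 0)
  ld <- matrix(c(0.8, -0.5, 0.6), 3, 1)
  pool <- simulate_rater_pool(traits, n_raters = 10, loadings = ld,
                              factor_strength = 5, noise_sd = 0,
                              mean_range = c(45, 55), round_ratings = FALSE,
                              seed = 2)
  space <- build_trait_space(pool, traits)
  off <- space$sim[upper.tri(space$sim)]
  expect_equal(abs(off), rep(1, length(off)), tolerance = 1e-10)
  expect_equal(sign(space$sim[1, 2]), -1)
  expect_equal(sign(space$sim[1, 3]), 1)
})

test_that("the true-parameter manifest round-trips through CSV bit-exactly", {
  cfg <- sim_config(4, model = 2, K = 6, n_pos = 3, n_neg = 3, seed = 13)
  co <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(co$params, path)
  back <- read_manifest(path)
  expect_identical(as.data.frame(back), as.data.frame(co$params))
})

test_that("noise-free simulation reduces to the documented identities", {
  space <- default_task_space()
  # model 1 with the identity regression emits the self-ratings
  tr <- simulate_subject(space, 1, list(beta0 = 0, beta1 = 1),
                         order_seed = 3, noise_seed = 4, sigma_sim = 0)
  expect_equal(tr$role, tr$self)
  # model 4 with full self-anchoring (gamma = 1) also emits the self-ratings
  tr <- simulate_subject(space, 4, list(alpha = 0.7, gamma = 1, E1 = 40),
                         order_seed = 3, noise_seed = 4, sigma_sim = 0)
  expect_equal(tr$role, tr$self)
  # model 2 with alpha = 0 emits the initial-expectation trajectory
  tr <- simulate_subject(space, 2, list(alpha = 0, E1 = 35),
                         order_seed = 5, noise_seed = 6, sigma_sim = 0,
                         round_ratings = FALSE)
  expect_equal(tr$role, initial_expectations(space, tr$trait_id, 35),
               tolerance = 1e-12)
})

test_that("noise-free data are maximally likely at the generating parameters", {
  space <- default_task_space()
  p <- list(alpha = 0.45, gamma = 0.35, E1 = 55)
  tr <- simulate_subject(space, 4, p, order_seed = 8, noise_seed = 9,
                         sigma_sim = 0, round_ratings = FALSE)
  sig <- 5
  ll_true <- model_loglik(tr, space, 4, c(p, sigma = sig))
  expect_equal(ll_true, nrow(tr) * log(1 / (sig * sqrt(2 * pi))),
               tolerance = 1e-9)
  grid <- expand.grid(alpha = seq(0.05, 0.95, by = 0.1),
                      gamma = seq(0.05, 0.95, by = 0.1))
  lls <- apply(grid, 1, function(g) {
    model_loglik(tr, space, 4,
                 list(alpha = g[1], gamma = g[2], E1 = 55, sigma = sig))
  })
  expect_true(all(ll_true >= lls))
})

test_that("a planted two-factor pool is recovered by eigendecomposition of the generating covariance", {
  traits <- make_trait_lexicon(4, 4)
  ld <- cbind(c(0.9, 0.9, 0.9, 0.9, 0, 0, 0, 0),
              c(0, 0, 0, 0, 0.6, 0.6, 0.6, 0.6))
  pool <- simulate_rater_pool(traits, n_raters = 30, loadings = ld,
                              noise_sd = 2, mean_range = c(45, 55),
                              seed = 31)
  space <- build_trait_space(pool, traits)
  # oracle: eigenvectors of the noise-free generating covariance LL' + v I
  gen_cov <- ld %*% t(ld) * 100 + diag(4, 8) # strength^2 LL' + noise_sd^2 I
  gen_v <- eigen(cov2cor(gen_cov), symmetric = TRUE)$vectors[, 1:2]
  emp_v <- eigen(space$sim, symmetric = TRUE)$vectors[, 1:2]
  gen_block <- apply(abs(gen_v), 1, which.max)
  emp_block <- apply(abs(emp_v), 1, which.max)
  # same partition of traits into factor blocks (up to factor relabelling)
  expect_true(identical(gen_block == gen_block[1], emp_block == emp_block[1]))
})
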