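test_that("similarity, feedback means and init_reg match hand computation on a fixed pool", {
  pool <- fixed_pool()
  space <- tiny_space()

  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(space$sim[i, j], pearson_by_formula(pool[, i], pool[, j]),
                   tolerance = 1e-12)
    }
  }
  expect_equal(space$feedback_mean, colMeans(pool), tolerance = 1e-12)

  # OLS of each trait on trait 0, against lm()
  for (k in 1:3) {
    fit <- lm(pool[, k] ~ pool[, 1])
    expect_equal(unname(space$init_reg[k, "intercept"]),
                 unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(unname(space$init_reg[k, "slope"]),
                 unname(coef(fit)[2]), tolerance = 1e-10)
  }
})

test_that("reverse coding maps endpoints, fixes the midpoint and is an involution", {
  expect_equal(reverse_code(100, -1), 1)
  expect_equal(reverse_code(1, -1), 100)
  expect_equal(reverse_code(50.5, -1), 50.5)
  expect_equal(reverse_code(30, +1), 30)
  x <- c(1, 17.25, 50.5, 99, 100)
  expect_equal(reverse_code(reverse_code(x, -1), -1), x)
  expect_error(reverse_code(0, -1), "outside")
  expect_error(reverse_code(100.5, 1), "outside")
  expect_error(reverse_code(50, 2), "valence")
})

test_that("identical and mirrored trait columns give correlations of +1 and -1", {
  base <- c(40, 55, 35, 60, 50)
  pool <- cbind(base, base, 101 - base)
  space <- build_trait_space(pool, fixed_traits())
  expect_equal(space$sim[1, 2], 1)
  expect_equal(space$sim[1, 3], -1)
  # negative-valence mirror column is recoded back onto the original
  space2 <- build_trait_space(pool, fixed_traits(valence = c(1, 1, -1)))
  expect_equal(space2$sim[1, 3], 1)
})

test_that("degenerate pools are rejected with informative errors", {
  pool <- fixed_pool()
  pool[, 2] <- 50
  expect_error(build_trait_space(pool, fixed_traits()), "constant.*B")
  expect_error(build_trait_space(fixed_pool()[, 1, drop = FALSE],
                                 fixed_traits()[1, ]), "2 traits")
  expect_error(build_trait_space(fixed_pool()[1:2, ], fixed_traits()),
               "3 raters")
  expect_error(
    build_trait_space(fixed_pool(),
                      tibble::tibble(trait_id = c(0, 2, 3),
                                     label = c("A", "B", "C"),
                                     valence = 1)),
    "contiguous"
  )
})

test_that("a planted two-block factor structure is recovered in the similarity matrix", {
  traits <- make_trait_lexicon(n_pos = 10, n_neg = 10)
  # unequal block strengths keep the leading eigenvalues non-degenerate
  ld <- cbind(c(rep(0.9, 10), rep(0, 10)), c(rep(0, 10), rep(0.6, 10)))
  pool <- simulate_rater_pool(traits, n_raters = 60, loadings = ld,
                              noise_sd = 3, mean_range = c(45, 55),
                              seed = 21)
  space <- build_trait_space(pool, traits)
  block <- rep(1:2, each = 10)
  within <- space$sim[outer(block, block, "==") & upper.tri(space$sim)]
  between <- space$sim[outer(block, block, "!=") & upper.tri(space$sim)]
  expect_gt(mean(within), mean(between) + 0.3)

  # leading eigenvectors separate the blocks
  eg <- eigen(space$sim, symmetric = TRUE)
  v <- eg$vectors[, 1:2]
  dominant <- apply(abs(v), 1, which.max)
  expect_true(all(dominant[1:10] == dominant[1]))
  expect_true(all(dominant[11:20] == dominant[11]))
  expect_true(dominant[1] != dominant[11])
})

test_that("similarity is invariant to location shifts of trait columns", {
  pool <- fixed_pool()
  shifted <- pool
  shifted[, 2] <- shifted[, 2] + 7
  s1 <- build_trait_space(pool, fixed_traits())
  s2 <- build_trait_space(shifted, fixed_traits())
  expect_equal(s1$sim, s2$sim, tolerance = 1e-12)
  expect_equal(s2$feedback_mean[2], s1$feedback_mean[2] + 7)
})

test_that("init_reg_for re-anchors the regression on any reference trait", {
  pool <- fixed_pool()
  space <- tiny_space()
  reg <- init_reg_for(space, ref_trait = 2L)
  for (k in 1:3) {
    fit <- lm(pool[, k] ~ pool[, 3])
    expect_equal(reg$intercept[k], unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(reg$slope[k], unname(coef(fit)[2]), tolerance = 1e-10)
  }
})

test_that("trait space round-trips through JSON/CSV export", {
  space <- tiny_space()
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_trait_space(space, jp, cp)
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$feedback_mean, space$feedback_mean, tolerance = 1e-9)
  sim <- as.matrix(readr::read_csv(cp, show_col_types = FALSE))
  expect_equal(unname(sim), unname(space$sim), tolerance = 1e-9)
})
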