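test_that("a perfectly separating summary drives prior error to 0 and posterior to 1", {
  set.seed(121)
  n <- 200
  X <- cbind(sep = c(rnorm(n, -5), rnorm(n, 5)),
             noise = rnorm(2 * n))
  rt <- manual_reference_table(rep(c("a", "b"), each = n), X)
  obs <- c(sep = 5, noise = 0)
  mc <- model_choice(rt, obs, n_trees = 300, add_lda = FALSE, seed = 1)
  expect_equal(mc$selected, "b")
  expect_lt(mc$prior_error_rate, 0.02)
  expect_gt(mc$posterior_probability, 0.95)
})

test_that("identical scenarios split the votes and the error approaches one half", {
  set.seed(122)
  n <- 250
  X <- matrix(rnorm(2 * n * 6), ncol = 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  rt <- manual_reference_table(rep(c("a", "b"), each = n), X)
  obs <- setNames(rnorm(6), paste0("s", 1:6))
  mc <- model_choice(rt, obs, n_trees = 400, add_lda = FALSE, seed = 2)
  expect_equal(mc$prior_error_rate, 0.5, tolerance = 0.1)
  expect_lt(abs(mc$vote_fractions[1] - 0.5), 0.2)
})

test_that("with pure-noise summaries over k scenarios the prior error is about (k-1)/k", {
  set.seed(123)
  for (k in c(3, 4)) {
    n <- 150
    X <- matrix(rnorm(k * n * 5), ncol = 5,
                dimnames = list(NULL, paste0("s", 1:5)))
    rt <- manual_reference_table(rep(letters[1:k], each = n), X)
    obs <- setNames(rnorm(5), paste0("s", 1:5))
    mc <- model_choice(rt, obs, n_trees = 300, add_lda = FALSE, seed = k)
    expect_equal(mc$prior_error_rate, (k - 1) / k, tolerance = 0.05)
  }
})

test_that("vote fractions sum to one and schema mismatches are rejected", {
  set.seed(124)
  n <- 60
  X <- matrix(rnorm(2 * n * 4), ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  rt <- manual_reference_table(rep(c("a", "b"), each = n), X)
  obs <- setNames(rnorm(4), paste0("s", 1:4))
  mc <- model_choice(rt, obs, n_trees = 100, add_lda = FALSE, seed = 9)
  expect_equal(sum(mc$vote_fractions), 1, tolerance = 1e-12)
  expect_error(model_choice(rt, obs[1:3], n_trees = 50, add_lda = FALSE),
               "schema")
})

test_that("RF regression recovers an informative parameter and respects degenerate priors", {
  set.seed(125)
  n <- 400
  theta <- runif(n, 0, 10)
  X <- cbind(signal = theta + rnorm(n, sd = 0.5), junk = rnorm(n))
  rt <- manual_reference_table(rep("m", n), X,
                               params = data.frame(theta = theta,
                                                   fixed = rep(3, n)))
  obs <- c(signal = 7, junk = 0)
  pp <- estimate_parameters(rt, obs, n_trees = 300, seed = 3)
  est <- pp$estimates
  th <- est[est$parameter == "theta", ]
  expect_equal(th$mean, 7, tolerance = 0.5)
  expect_lte(th$q_lo, th$median); expect_lte(th$median, th$q_hi)
  fx <- est[est$parameter == "fixed", ]
  expect_equal(fx$mean, 3)
  expect_equal(fx$q_hi - fx$q_lo, 0)
})

test_that("weighted 95% intervals achieve reasonable coverage on repeated pseudo-observations", {
  set.seed(126)
  n <- 300
  theta <- runif(n, 0, 10)
  X <- cbind(sig = theta + rnorm(n, sd = 1), jk = rnorm(n))
  rt <- manual_reference_table(rep("m", n), X,
                               params = data.frame(theta = theta))
  hits <- 0; reps <- 40
  for (r in seq_len(reps)) {
    truth <- runif(1, 1, 9)
    obs <- c(sig = truth + rnorm(1, sd = 1), jk = rnorm(1))
    est <- estimate_parameters(rt, obs, n_trees = 100,
                               seed = 100 + r)$estimates
    if (est$q_lo <= truth && truth <= est$q_hi) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.80)
})

test_that("generation-time conversion is exact and invertible", {
  expect_equal(convert_units(5620, 6), 33720)
  expect_equal(convert_units(0), 0)
  x <- 1234.5
  expect_equal(convert_units(convert_units(x, 6) / 6, 6) / 6, x)
  expect_error(convert_units(10, 0))
})
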