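test_that("a degenerate prior always returns its single value", {
  sc <- toy_split_scenario("deg", c(100, 100), n_range = c(5000, 5000))
  set.seed(1)
  d <- sample_prior(sc, 20)
  expect_true(all(d$t_split == 100))
  expect_true(all(d$N_A == 5000))
})

test_that("order constraints are always satisfied and marginals stay uniform", {
  sc <- scenario_from_list(list(
    name = "cons", populations = c("A", "B", "C"),
    ne = list(A = 10000, B = 10000, C = 10000),
    events = list(
      list(type = "admix", time = "t_adm", target = "C", source1 = "A",
           source2 = "B", rate = 0.5),
      list(type = "merge", time = "t_split", source = "B", dest = "A")),
    priors = list(
      t_adm = list(dist = "uniform", min = 100, max = 2000),
      t_split = list(dist = "uniform", min = 500, max = 2500)),
    constraints = c("t_adm < t_split")))
  set.seed(2)
  d <- sample_prior(sc, 10000)
  expect_equal(sum(d$t_adm >= d$t_split), 0L)
  # an unconstrained parameter keeps its nominal uniform marginal
  sc2 <- toy_split_scenario("u", c(100, 1100))
  set.seed(3)
  d2 <- sample_prior(sc2, 2000)
  ks <- suppressWarnings(stats::ks.test((d2$t_split - 100) / 1000, "punif"))
  expect_gt(ks$p.value, 0.01)
  # log-uniform draws respect their bounds and skew low
  sc3 <- scenario_from_list(list(
    name = "lu", populations = "A", ne = list(A = "N_A"), events = list(),
    priors = list(N_A = list(dist = "loguniform", min = 100, max = 100000))))
  d3 <- sample_prior(sc3, 2000)
  expect_true(all(d3$N_A >= 100 & d3$N_A <= 100000))
  expect_lt(median(d3$N_A), mean(d3$N_A))
})

test_that("infeasible constraints raise an error instead of looping forever", {
  sc <- toy_split_scenario("bad", c(100, 200))
  sc$constraints <- c("t_split > 1000")
  expect_error(sample_prior(sc, 1, max_tries = 200), "infeasible")
})

test_that("scenario validation rejects histories that cannot coalesce", {
  expect_error(scenario_from_list(list(
    name = "split-only", populations = c("A", "B"),
    ne = list(A = 1000, B = 1000),
    events = list(), priors = list())), "single root")
  expect_error(scenario_from_list(list(
    name = "dead-source", populations = c("A", "B", "C"),
    ne = list(A = 1000, B = 1000, C = 1000),
    events = list(
      list(type = "merge", time = 100, source = "B", dest = "A"),
      list(type = "merge", time = 200, source = "B", dest = "C"),
      list(type = "merge", time = 300, source = "C", dest = "A")),
    priors = list())), "dead deme")
  expect_error(scenario_from_list(list(
    name = "undeclared", populations = c("A", "B"),
    ne = list(A = 1000, B = 1000),
    events = list(list(type = "merge", time = "t_mystery",
                       source = "B", dest = "A")),
    priors = list())), "without priors")
})

test_that("all shipped scenario fixtures load, validate, and draw consistent priors", {
  fx <- scenario_fixtures()
  expect_gte(length(fx), 5)
  expect_true("step2_best" %in% names(fx))
  set.seed(4)
  for (nm in names(fx)) {
    sc <- scenario_load(fx[[nm]])
    expect_s3_class(sc, "abc_scenario")
    d <- sample_prior(sc, 5)
    expect_equal(nrow(d), 5)
    expect_false(anyNA(d))
  }
  # the flagship fixture carries point estimates that satisfy its constraints
  sc <- scenario_load(fx[["step2_best"]])
  pe <- unlist(sc$point_estimates)
  expect_true(all(vapply(sc$constraints, function(s)
    isTRUE(eval(parse(text = s), envir = as.list(pe))), logical(1))))
  expect_silent(scenario_validate(sc, pe))
})
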