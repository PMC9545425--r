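test_that("panmictic data give near-zero pairwise F_ST and central admixture coefficients", {
  set.seed(111)
  sc <- scenario_from_list(list(
    name = "pan", populations = c("A", "B", "C"),
    ne = list(A = 5000, B = 5000, C = 5000),
    events = list(list(type = "merge", time = 1, source = "B", dest = "A"),
                  list(type = "merge", time = 1, source = "C", dest = "A")),
    priors = list()))
  sim <- simulate_genotypes(sc, params = numeric(0),
                            sample_sizes = c(A = 10, B = 10, C = 10),
                            n_loci = 1000, missingness = 0)
  v <- summarize(sim$genotypes, sim$popmap,
                 trios = list(list(target = "C", source1 = "A", source2 = "B")))
  expect_lt(abs(v[["fstmean.A.B"]]), 0.02)
  expect_lt(abs(v[["fstmean.A.C"]]), 0.02)
  expect_lt(abs(v[["admmean.C.A.B"]] - 0.5), 0.1)
})

test_that("a 50/50 admixed target yields a trio coefficient near 0.5, a cloned source near 1", {
  set.seed(112)
  mk <- function(rate) scenario_from_list(list(
    name = "adm", populations = c("A", "B", "C"),
    ne = list(A = 5000, B = 5000, C = 5000),
    events = list(
      list(type = "admix", time = 50, target = "C", source1 = "A",
           source2 = "B", rate = rate),
      list(type = "merge", time = 8000, source = "B", dest = "A")),
    priors = list()))
  trio <- list(list(target = "C", source1 = "A", source2 = "B"))
  sim <- simulate_genotypes(mk(0.5), params = numeric(0),
                            sample_sizes = c(A = 10, B = 10, C = 10),
                            n_loci = 2000, missingness = 0)
  v <- summarize(sim$genotypes, sim$popmap, trio)
  expect_equal(unname(v["admmean.C.A.B"]), 0.5, tolerance = 0.05)
  # a target that is literally a copy of source1 gives a coefficient of 1
  sc2 <- toy_split_scenario("cp", c(100, 100000))
  sim2 <- simulate_genotypes(sc2, c(N_A = 5000, N_B = 5000, t_split = 50000),
                             c(A = 10, B = 10), n_loci = 500, missingness = 0)
  gg <- sim2$genotypes
  clone <- genotype_matrix(rbind(gg$calls, gg$calls[1:10, ]),
                           gg$variant_meta,
                           c(gg$sample_ids, paste0("C_", 1:10)))
  pm2 <- population_map(setNames(c(sim2$popmap$assignments[gg$sample_ids],
                                   rep("C", 10)), clone$sample_ids))
  v2 <- summarize(clone, pm2, trio)
  expect_gt(unname(v2["admmean.C.A.B"]), 0.95)
})

test_that("the summary schema is fixed, named, and free of NaN", {
  set.seed(113)
  g <- random_gm(24, 100, miss = 0.2)
  pm <- even_popmap(g, c("A", "B", "C"))
  trios <- list(list(target = "C", source1 = "A", source2 = "B"))
  v <- summarize(g, pm, trios)
  expect_identical(names(v), summary_schema(c("A", "B", "C"), trios))
  expect_false(anyNA(v))
  # 3 per-pop stats, 4 per-pair stats, 2 per-trio stats
  expect_length(v, 3 * 3 + 4 * 3 + 2 * 1)
  # consistent allele-polarity flip leaves the vector unchanged
  g2 <- genotype_matrix(2L - g$calls, g$variant_meta, g$sample_ids)
  expect_equal(summarize(g2, pm, trios), v, tolerance = 1e-12)
})

test_that("LDA appends k-1 separating axes fit on the reference table only", {
  set.seed(114)
  # two well-separated synthetic scenario clouds
  n <- 150; p <- 8
  X1 <- matrix(rnorm(n * p), n); X1[, 1] <- X1[, 1] + 7
  X2 <- matrix(rnorm(n * p), n)
  X <- rbind(X1, X2)
  colnames(X) <- paste0("s", 1:p)
  rt <- manual_reference_table(rep(c("a", "b"), each = n), X)
  proj <- fit_lda(rt)
  expect_equal(ncol(proj$rotation), 1L)           # k - 1 axes
  aug <- apply_lda(proj, X)
  expect_identical(colnames(aug)[p + 1], "LDA1")
  # 1D projection separates the training clouds almost perfectly
  ax <- aug[, p + 1]
  thr <- mean(c(mean(ax[1:n]), mean(ax[(n + 1):(2 * n)])))
  acc <- max(mean((ax > thr) == rep(c(TRUE, FALSE), each = n)),
             mean((ax < thr) == rep(c(TRUE, FALSE), each = n)))
  expect_gte(acc, 0.99)
  # permuting labels collapses the discriminant eigenvalues
  set.seed(115)
  rt_perm <- manual_reference_table(sample(rep(c("a", "b"), each = n)), X)
  proj_perm <- fit_lda(rt_perm)
  expect_lt(abs(proj_perm$eigenvalues[1]), abs(proj$eigenvalues[1]) / 10)
})
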