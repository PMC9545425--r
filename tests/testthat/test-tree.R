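test_that("Nei minimum distance matches hand computation on a 3-population toy", {
  # one site; exact frequencies 0.2 / 0.5 / 0.9 by construction
  X <- matrix(c(1L, 1L, 0L, 0L, 0L,    # pop X: p = 0.2
                2L, 2L, 1L, 0L, 0L,    # pop Y: p = 0.5
                2L, 2L, 2L, 2L, 1L),   # pop Z: p = 0.9
              ncol = 1)
  ids <- paste0("i", 1:15)
  g <- genotype_matrix(X, data.frame(contig = "c1", pos = 1L,
                                     ref = "A", alt = "T"), ids)
  pm <- population_map(setNames(rep(c("X", "Y", "Z"), each = 5), ids))
  D <- nei_distance(g, pm)
  # Dm(X,Y) = (0.68+0.50)/2 - 0.50 = 0.09, etc.
  expect_equal(D["X", "Y"], 0.09, tolerance = 1e-12)
  expect_equal(D["X", "Z"], 0.49, tolerance = 1e-12)
  expect_equal(D["Y", "Z"], 0.16, tolerance = 1e-12)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), setNames(rep(0, 3), c("X", "Y", "Z")))
})

test_that("identical populations have zero distance; opposite fixation gives 1 per site", {
  X <- rbind(matrix(c(0L, 1L, 2L, 1L), 4, 10), matrix(c(0L, 1L, 2L, 1L), 4, 10))
  g <- genotype_matrix(X, data.frame(contig = sprintf("c%02d", 1:10),
                                     pos = 1L, ref = "A", alt = "T"))
  pm <- population_map(setNames(rep(c("A", "B"), each = 4), g$sample_ids))
  expect_lt(nei_distance(g, pm)["A", "B"], 1e-12)
  Xf <- rbind(matrix(0L, 4, 10), matrix(2L, 4, 10))
  gf <- genotype_matrix(Xf, g$variant_meta)
  pmf <- population_map(setNames(rep(c("A", "B"), each = 4), gf$sample_ids))
  expect_equal(nei_distance(gf, pmf)["A", "B"], 1, tolerance = 1e-12)
  # the standard (1972) distance is also available and positive here
  expect_gt(nei_distance(gf, pmf, method = "standard")["A", "B"], 1)
})

test_that("NJ recovers additive trees exactly, for 4 to 8 taxa", {
  set.seed(91)
  for (ntax in c(4, 6, 8)) {
    # build a random additive matrix from a random tree with known lengths
    tr <- ape::rtree(ntax, br = function(n) runif(n, 0.1, 1))
    tr <- ape::unroot(tr)
    D <- ape::cophenetic.phylo(tr)
    fit <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(fit), tr)), 0)
    # branch lengths: pairwise path distances reproduce D exactly
    Dfit <- ape::cophenetic.phylo(fit)[rownames(D), colnames(D)]
    expect_equal(Dfit, D, tolerance = 1e-10)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("bootstrap support approaches 100% for a strongly supported split", {
  set.seed(92)
  # two clean 2+2 population clusters separated by many fixed differences
  n_per <- 6; L <- 150
  base <- rbinom(L, 2, 0.5)
  make_pop <- function(shift) {
    t(replicate(n_per, pmin(pmax(base + shift + rbinom(L, 1, 0.1) - rbinom(L, 1, 0.1), 0), 2)))
  }
  X <- rbind(make_pop(0), make_pop(0), make_pop(-2), make_pop(-2))
  storage.mode(X) <- "integer"
  ids <- paste0("i", seq_len(nrow(X)))
  g <- genotype_matrix(X, data.frame(contig = sprintf("c%03d", 1:L), pos = 1L,
                                     ref = "A", alt = "T"), ids)
  pm <- population_map(setNames(rep(c("A", "B", "C", "D"), each = n_per), ids))
  res <- nj_bootstrap(g, pm, n_boot = 100)
  expect_equal(length(res$support), res$tree$Nnode)
  # the AB|CD bipartition is the single internal edge of a 4-taxon tree
  expect_gte(max(res$support), 99)
})
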