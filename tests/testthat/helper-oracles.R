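# Independent oracles and small fixture builders used across the suite.
# Every oracle is coded from first principles, by a different route than the
# implementation it checks.

# random genotype matrix with given dimensions and missingness
random_gm <- function(n_samples, n_variants, miss = 0, maf = c(0.05, 0.5),
                      n_loci = n_variants) {
  p <- runif(n_variants, maf[1], maf[2])
  X <- t(replicate(n_samples, rbinom(n_variants, 2, p)))
  if (miss > 0) X[matrix(runif(length(X)) < miss, nrow(X))] <- NA
  locus <- sprintf("L%05d", rep(seq_len(n_loci), length.out = n_variants))
  meta <- data.frame(contig = locus,
                     pos = as.integer(stats::ave(seq_len(n_variants),
                                                 locus, FUN = seq_along)),
                     ref = "A", alt = "T", locus_id = locus,
                     is_indel = FALSE)
  genotype_matrix(X, meta, paste0("s", seq_len(n_samples)))
}

# two-column popmap splitting samples evenly over labels
even_popmap <- function(g, labels) {
  population_map(setNames(rep(labels, length.out = n_samples(g)),
                          g$sample_ids))
}

# Weir-Cockerham theta via the nested-ANOVA route (mean squares for
# populations / individuals-within-populations / gametes-within-individuals),
# a distinct computational path from the component formulas. Ratio of sums
# across sites.
wc_fst_anova_oracle <- function(g, idxA, idxB) {
  num <- den <- 0
  for (s in seq_len(n_variants(g))) {
    ga <- g$calls[idxA, s]; gb <- g$calls[idxB, s]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    nA <- length(ga); nB <- length(gb)
    if (nA < 1 || nB < 1 || (nA + nB) / 2 <= 1) next
    r <- 2; ntot <- nA + nB
    pA <- mean(ga) / 2; pB <- mean(gb) / 2
    pbar <- (nA * pA + nB * pB) / ntot
    SSP <- 2 * nA * (pA - pbar)^2 + 2 * nB * (pB - pbar)^2
    SSI <- sum(2 * (ga / 2 - pA)^2) + sum(2 * (gb / 2 - pB)^2)
    SSG <- sum(ga == 1) * 0.5 + sum(gb == 1) * 0.5
    MSP <- SSP / (r - 1)
    MSI <- SSI / (ntot - r)
    MSG <- SSG / ntot
    nc <- (ntot - (nA^2 + nB^2) / ntot) / (r - 1)
    a <- (MSP - MSI) / (2 * nc)
    b <- (MSI - MSG) / 2
    cc <- MSG
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# exact HWE p-value by direct closed-form enumeration of all heterozygote
# counts (multinomial probability of each configuration given the allele
# counts), summing configurations no more probable than the observed one
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- vapply(hs, function(h) {
    exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((na - h) / 2) + h * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, numeric(1))
  obs <- pr[hs == nAa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Monte-Carlo oracle for the site-frequency spectrum of a single mutation
# placed uniformly on a standard-coalescent tree of n haploid lineages:
# estimates E[L_i / L_total] by simulating coalescent epochs directly
sfs_single_mutation_oracle <- function(n, reps) {
  probs <- numeric(n - 1)
  for (r in seq_len(reps)) {
    sizes <- rep(1L, n)
    L <- numeric(n - 1)
    k <- n
    while (k > 1) {
      dt <- rexp(1, k * (k - 1) / 2)
      for (sz in sizes) L[sz] <- L[sz] + dt
      pair <- sample.int(k, 2)
      sizes <- c(sizes[-pair], sum(sizes[pair]))
      k <- k - 1
    }
    probs <- probs + L / sum(L)
  }
  probs / reps
}

# minimal vertex cover by exhaustive search (<= 12 nodes): smallest sample
# set whose removal leaves no related pair
min_vertex_cover_oracle <- function(adj) {
  ids <- rownames(adj)
  n <- length(ids)
  for (k in 0:n) {
    for (comb in utils::combn(n, k, simplify = FALSE)) {
      rest <- setdiff(seq_len(n), comb)
      if (!any(adj[rest, rest])) return(k)
    }
  }
  n
}

# tiny n-population island scenarios used by the ABC tests
toy_split_scenario <- function(name, t_range, n_range = c(2000, 20000)) {
  scenario_from_list(list(
    name = name, populations = c("A", "B"),
    ne = list(A = "N_A", B = "N_B"),
    events = list(list(type = "merge", time = "t_split",
                       source = "B", dest = "A")),
    priors = list(
      N_A = list(dist = "uniform", min = n_range[1], max = n_range[2]),
      N_B = list(dist = "uniform", min = n_range[1], max = n_range[2]),
      t_split = list(dist = "uniform", min = t_range[1], max = t_range[2]))))
}

# reference_table constructed directly from components (for RF tests on
# synthetic summaries)
manual_reference_table <- function(labels, sumstats, params = NULL) {
  if (is.null(params))
    params <- data.frame(dummy = rep(NA_real_, length(labels)))
  structure(list(scenario = factor(labels), params = params,
                 sumstats = sumstats, schema = colnames(sumstats),
                 meta = list()),
            class = "reference_table")
}
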