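# Weir-Cockerham F_ST for two populations: per-site variance components
# (a, b, c) from sample sizes, allele frequencies and heterozygote
# proportions, aggregated across sites as a ratio of sums (the standard
# multi-locus estimator; mean-of-ratios is biased for low-information sites).

# internal: per-site W&C (1984) components for two populations.
# n1, n2: called diploid counts; p1, p2: ALT frequencies; h1, h2: observed
# heterozygote proportions. Vectors over sites. Sites unusable (a population
# with no calls, or mean sample size <= 1) come back as NA components.
.wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- n1 >= 1 & n2 >= 1 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; c_[!ok] <- NA_real_
  list(a = a, b = b, c = c_)
}

# internal: per-site components for a pair of sample index sets
.wc_pair <- function(g, idxA, idxB) {
  acA <- .allele_counts(g, idxA)
  acB <- .allele_counts(g, idxB)
  nA <- acA$n / 2; nB <- acB$n / 2
  pA <- ifelse(acA$n > 0, acA$alt / acA$n, NA_real_)
  pB <- ifelse(acB$n > 0, acB$alt / acB$n, NA_real_)
  hA <- ifelse(nA > 0, acA$het / nA, NA_real_)
  hB <- ifelse(nB > 0, acB$het / nB, NA_real_)
  .wc_components(nA, pA, hA, nB, pB, hB)
}

#' Weir-Cockerham F_ST between two populations
#'
#' Multi-locus theta: per-site variance components a (among populations),
#' b (among individuals within populations) and c (within individuals) are
#' summed across sites and theta = sum(a) / sum(a + b + c). Sites monomorphic
#' across both populations contribute zero to both sums; negative estimates
#' are retained (not clamped).
#'
#' @param g a [genotype_matrix()]
#' @param pm a [population_map()]
#' @param popA,popB population labels
#' @return point estimate theta (numeric scalar)
#' @export
wc_fst <- function(g, pm, popA, popB) {
  idxA <- pop_samples(g, pm, popA)
  idxB <- pop_samples(g, pm, popB)
  if (length(idxA) < 2 || length(idxB) < 2)
    stop("each population needs at least 2 samples")
  comp <- .wc_pair(g, idxA, idxB)
  sum(comp$a, na.rm = TRUE) /
    sum(comp$a + comp$b + comp$c, na.rm = TRUE)
}

#' Bootstrap confidence interval for pairwise F_ST
#'
#' Resamples RAD loci (not sites, not samples) with replacement, so linked
#' SNPs on one fragment resample together, and reports the percentile
#' interval of the multi-locus theta.
#'
#' @inheritParams wc_fst
#' @param n_boot number of bootstrap replicates
#' @param conf confidence level (default 0.95)
#' @return list with `theta` (point estimate), `ci` (length-2 vector),
#'   `boot` (replicate values)
#' @export
fst_bootstrap_ci <- function(g, pm, popA, popB, n_boot = 500, conf = 0.95) {
  idxA <- pop_samples(g, pm, popA)
  idxB <- pop_samples(g, pm, popB)
  comp <- .wc_pair(g, idxA, idxB)
  num <- ifelse(is.na(comp$a), 0, comp$a)
  den <- ifelse(is.na(comp$a), 0, comp$a + comp$b + comp$c)
  loc <- factor(g$variant_meta$locus_id)
  lnum <- rowsum(num, loc)
  lden <- rowsum(den, loc)
  L <- nrow(lnum)
  theta <- sum(lnum) / sum(lden)
  boot <- vapply(seq_len(n_boot), function(i) {
    k <- sample.int(L, L, replace = TRUE)
    sum(lnum[k]) / sum(lden[k])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(theta = theta,
       ci = unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
       boot = boot)
}

#' Permutation p-value for pairwise F_ST
#'
#' Permutes individuals' population labels within the pooled pair and
#' reports p = (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1).
#'
#' @inheritParams wc_fst
#' @param n_perm number of label permutations
#' @return list with `theta`, `p`, `perm` (permuted values)
#' @export
fst_permutation_p <- function(g, pm, popA, popB, n_perm = 1000) {
  idxA <- pop_samples(g, pm, popA)
  idxB <- pop_samples(g, pm, popB)
  pool <- c(idxA, idxB)
  nA <- length(idxA)
  obs <- wc_fst(g, pm, popA, popB)
  perm <- vapply(seq_len(n_perm), function(i) {
    s <- sample(pool)
    comp <- .wc_pair(g, s[seq_len(nA)], s[-seq_len(nA)])
    sum(comp$a, na.rm = TRUE) / sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  }, numeric(1))
  list(theta = obs, p = (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1),
       perm = perm)
}

#' All pairwise F_ST with bootstrap CIs and permutation p-values
#'
#' @param g a [genotype_matrix()]
#' @param pm a [population_map()]
#' @param n_boot bootstrap replicates for the CI (0 to skip)
#' @param n_perm label permutations for the p-value (0 to skip)
#' @param conf confidence level
#' @return data.frame with one row per population pair: `popA`, `popB`,
#'   `theta`, `ci_lo`, `ci_hi`, `p`
#' @export
pairwise_fst <- function(g, pm, n_boot = 500, n_perm = 1000, conf = 0.95) {
  pops <- pm$populations
  rows <- list()
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    th <- wc_fst(g, pm, pops[i], pops[j])
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0)
      ci <- fst_bootstrap_ci(g, pm, pops[i], pops[j], n_boot, conf)$ci
    p <- NA_real_
    if (n_perm > 0)
      p <- fst_permutation_p(g, pm, pops[i], pops[j], n_perm)$p
    rows[[length(rows) + 1]] <-
      data.frame(popA = pops[i], popB = pops[j], theta = th,
                 ci_lo = ci[1], ci_hi = ci[2], p = p,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
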