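#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test for a biallelic SNP, conditioning on the observed
#' allele counts and enumerating every heterozygote count consistent with
#' them. The p-value is the total probability of configurations whose exact
#' HWE probability is less than or equal to that of the observed configuration
#' (probability-mass ordering). Monomorphic input returns `p = 1` by
#' convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers)
#' @return two-sided exact p-value in (0, 1]
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  if (n_A == 0L || n_a == 0L) return(1)
  rare <- min(n_A, n_a)
  # heterozygote counts share the parity of the rare-allele count
  hs <- seq(rare %% 2L, rare, by = 2L)
  # log P(h het | allele counts) up to a constant:
  #   1 / ( ((nA-h)/2)! * h! * ((na-h)/2)! ) * 2^h
  logp <- hs * log(2) - lfactorial((n_A - hs) / 2) - lfactorial(hs) -
    lfactorial((n_a - hs) / 2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Hardy-Weinberg filter across populations
#'
#' Removes a variant when its exact HWE test ([hwe_exact_test()]) rejects at
#' level `alpha` in at least `min_pops` of the populations. A population with
#' fewer than two called genotypes at a variant contributes "no deviation".
#'
#' @param g a [genotype_matrix()]
#' @param pm a [population_map()]
#' @param alpha per-test significance level
#' @param min_pops minimum number of deviating populations for removal;
#'   default `NULL` means "all but one" (e.g. 6 of 7).
#' @return list with `genotypes`, `stage`, and `p_values` (populations x
#'   variants matrix of exact p-values)
#' @export
hwe_filter <- function(g, pm, alpha = 0.05, min_pops = NULL) {
  check_popmap(g, pm)
  pops <- pm$populations
  if (is.null(min_pops)) min_pops <- max(1L, length(pops) - 1L)
  stopifnot(min_pops <= length(pops))
  pv <- matrix(1, nrow = length(pops), ncol = n_variants(g),
               dimnames = list(pops, NULL))
  for (p in pops) {
    sub <- g$calls[pop_samples(g, pm, p), , drop = FALSE]
    nAA <- colSums(sub == 0L, na.rm = TRUE)
    nAa <- colSums(sub == 1L, na.rm = TRUE)
    naa <- colSums(sub == 2L, na.rm = TRUE)
    ntot <- nAA + nAa + naa
    for (j in which(ntot >= 2L))
      pv[p, j] <- hwe_exact_test(nAA[j], nAa[j], naa[j])
  }
  n_dev <- colSums(pv < alpha)
  keep <- n_dev < min_pops
  list(genotypes = gm_subset(g, variants = keep),
       stage = qc_stage("hwe", "variant", n_variants(g), sum(!keep),
                        list(alpha = alpha, min_pops = min_pops)),
       p_values = pv)
}
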