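# Diversity statistics: nucleotide diversity, heterozygosity / F_IS,
# Tajima's D. All work on the ALT-dosage matrix of a genotype_matrix and a
# sample subset (a population); allele frequencies always come from called
# alleles only.

# internal: per-variant called-allele count, ALT count, het count for a
# sample subset
.allele_counts <- function(g, idx) {
  sub <- g$calls[idx, , drop = FALSE]
  list(n = 2L * colSums(!is.na(sub)),
       alt = colSums(sub, na.rm = TRUE),
       het = colSums(sub == 1L, na.rm = TRUE))
}

#' Per-site nucleotide diversity
#'
#' For each site with at least two called alleles, pi = 2 * n_minor * n_major
#' / (n * (n - 1)) where n is the number of called alleles; sites with fewer
#' than two called alleles are excluded. The mean is taken across included
#' sites.
#'
#' @param g a [genotype_matrix()]
#' @param samples optional sample index (e.g. one population); default all
#' @return list with `per_site` (numeric, `NA` for excluded sites) and `mean`
#' @export
site_pi <- function(g, samples = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(g))
  ac <- .allele_counts(g, samples)
  ok <- ac$n >= 2L
  minor <- pmin(ac$alt, ac$n - ac$alt)
  pi <- rep(NA_real_, n_variants(g))
  pi[ok] <- 2 * minor[ok] * (ac$n[ok] - minor[ok]) / (ac$n[ok] * (ac$n[ok] - 1))
  list(per_site = pi, mean = mean(pi, na.rm = TRUE))
}

#' Observed heterozygosity and individual inbreeding coefficients
#'
#' `H_obs` is the fraction of called genotypes that are heterozygous. The
#' per-individual inbreeding coefficient is F = (O_hom - E_hom) /
#' (N - E_hom), with the expected homozygous count E_hom summed over the
#' individual's called sites as 1 - 2*p*q*n/(n-1) (small-sample-corrected
#' expected heterozygosity from the allele frequencies of the supplied sample
#' set). Individuals with no called sites are excluded with a warning.
#'
#' @param g a [genotype_matrix()]
#' @param samples optional sample index; default all
#' @return list with `h_obs` (overall), `h_obs_ind` (per individual), `fis`
#'   (per individual) and `mean_fis`
#' @export
heterozygosity_fis <- function(g, samples = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(g))
  sub <- g$calls[samples, , drop = FALSE]
  ac <- .allele_counts(g, samples)
  p <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
  # expected heterozygosity per site with small-sample correction
  eh <- ifelse(ac$n >= 2, 2 * p * (1 - p) * ac$n / (ac$n - 1), NA_real_)
  called <- !is.na(sub)
  ncall <- rowSums(called)
  if (any(ncall == 0)) {
    warning(sum(ncall == 0), " individual(s) with no called sites excluded")
  }
  het <- !is.na(sub) & sub == 1L
  o_hom <- rowSums(called & !het)
  e_hom <- (called + 0) %*% ifelse(is.na(eh), 0, 1 - eh)
  e_hom <- as.vector(e_hom)
  fis <- ifelse(ncall > 0 & ncall - e_hom != 0,
                (o_hom - e_hom) / (ncall - e_hom), NA_real_)
  h_ind <- ifelse(ncall > 0, rowSums(het) / ncall, NA_real_)
  list(h_obs = sum(het) / sum(called),
       h_obs_ind = setNames(h_ind, g$sample_ids[samples]),
       fis = setNames(fis, g$sample_ids[samples]),
       mean_fis = mean(fis, na.rm = TRUE))
}

#' Tajima's D per RAD locus
#'
#' Standard Tajima's D contrasting the mean pairwise difference with the
#' segregating-site count, computed per locus within a sample set. The
#' constants (a1, a2, b1, b2, c1, c2, e1, e2) use the locus' allele number n,
#' taken as the rounded mean called-allele count over its sites; loci with
#' n < 4 or with no segregating site are excluded (D undefined).
#'
#' @param g a [genotype_matrix()]
#' @param samples optional sample index; default all
#' @return data.frame per locus: `locus_id`, `n` (alleles), `S` (segregating
#'   sites), `pi` (mean pairwise difference), `D`; attribute `mean_D`.
#' @export
tajimas_d <- function(g, samples = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(g))
  ac <- .allele_counts(g, samples)
  p <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
  seg <- !is.na(p) & p > 0 & p < 1 & ac$n >= 2
  pi_site <- ifelse(ac$n >= 2,
                    2 * ac$alt * (ac$n - ac$alt) / (ac$n * (ac$n - 1)), 0)
  loci <- unique(g$variant_meta$locus_id)
  res <- lapply(loci, function(L) {
    j <- which(g$variant_meta$locus_id == L)
    n <- round(mean(ac$n[j]))
    S <- sum(seg[j])
    k <- sum(pi_site[j])
    D <- NA_real_
    if (n >= 4 && S >= 1) D <- .tajima_D(k, S, n)
    data.frame(locus_id = L, n = n, S = S, pi = k, D = D,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "mean_D") <- mean(out$D, na.rm = TRUE)
  out
}

# Tajima's D from mean pairwise difference k, segregating sites S, and allele
# number n, with the standard constants.
.tajima_D <- function(k, S, n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Per-population diversity summary
#'
#' Convenience wrapper computing mean nucleotide diversity, observed
#' heterozygosity, mean F_IS and mean Tajima's D for every population.
#'
#' @param g a [genotype_matrix()]
#' @param pm a [population_map()]
#' @return data.frame, one row per population
#' @export
population_stats <- function(g, pm) {
  check_popmap(g, pm)
  do.call(rbind, lapply(pm$populations, function(p) {
    idx <- pop_samples(g, pm, p)
    hf <- heterozygosity_fis(g, idx)
    td <- tajimas_d(g, idx)
    data.frame(population = p, n = length(idx),
               pi = site_pi(g, idx)$mean,
               h_obs = hf$h_obs,
               mean_fis = hf$mean_fis,
               mean_tajima_d = attr(td, "mean_D"),
               stringsAsFactors = FALSE)
  }))
}
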