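#' Pairwise relatedness (PI-HAT) by method-of-moments IBD
#'
#' Estimates, for every sample pair, the probabilities of sharing 0, 1 or 2
#' alleles identical by descent from identity-by-state counts and sample
#' allele frequencies (frequencies estimated from all samples, not per
#' population), truncates the estimates to the probability simplex, and
#' reports PI-HAT = P(IBD=2) + P(IBD=1)/2.
#'
#' @param g a [genotype_matrix()]
#' @param min_overlap pairs with fewer co-called variants than this are
#'   flagged low-confidence (attribute `low_confidence`)
#' @return a symmetric samples x samples matrix of class `relatedness_matrix`
#'   with values in `[0, 1]`, diagonal 1, and attribute `low_confidence`
#'   (logical matrix).
#' @export
pihat <- function(g, min_overlap = 50) {
  X <- g$calls
  n <- nrow(X)
  C <- !is.na(X)
  A0 <- (!is.na(X) & X == 0L) + 0
  A1 <- (!is.na(X) & X == 1L) + 0
  A2 <- (!is.na(X) & X == 2L) + 0
  Ncc <- tcrossprod(C + 0)
  IBS0 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  IBS2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  IBS1 <- Ncc - IBS0 - IBS2
  # Expected IBS probabilities conditional on IBD state, with finite-sample
  # correction: the pair's 4 (IBD0) or 3 (IBD1) non-shared alleles are drawn
  # without replacement from the observed allele pool of each variant
  # (factorial-moment forms), which removes the upward bias of plug-in
  # frequency products at small n. Summed over the co-called variants of
  # each pair.
  A <- colSums(X, na.rm = TRUE)           # ALT allele count
  T_ <- 2 * colSums(C)                    # called allele pool size
  B <- T_ - A
  D4 <- T_ * (T_ - 1) * (T_ - 2) * (T_ - 3)
  D3 <- T_ * (T_ - 1) * (T_ - 2)
  safe <- function(x) ifelse(is.finite(x) & x >= 0, x, 0)
  f00 <- safe(2 * A * (A - 1) * B * (B - 1) / D4)
  f10 <- safe((4 * A * (A - 1) * (A - 2) * B +
                 4 * B * (B - 1) * (B - 2) * A) / D4)
  f20 <- pmin(pmax(1 - f00 - f10, 0), 1)
  f11 <- safe((2 * A * (A - 1) * B + 2 * A * B * (B - 1)) / D3)
  f21 <- pmin(pmax(1 - f11, 0), 1)
  esum <- function(f) tcrossprod(t(t(C + 0) * f), C + 0)
  E00 <- esum(f00)                        # P(IBS0 | IBD0)
  E10 <- esum(f10)                        # P(IBS1 | IBD0)
  E20 <- esum(f20)                        # P(IBS2 | IBD0)
  E11 <- esum(f11)                        # P(IBS1 | IBD1)
  E21 <- esum(f21)                        # P(IBS2 | IBD1)
  z0 <- ifelse(E00 > 0, IBS0 / E00, 0)
  z1 <- ifelse(E11 > 0, (IBS1 - z0 * E10) / E11, 0)
  z2 <- ifelse(Ncc > 0, (IBS2 - z0 * E20 - z1 * E21) / Ncc, 1)
  z0 <- pmax(z0, 0); z1 <- pmax(z1, 0); z2 <- pmax(z2, 0)
  tot <- z0 + z1 + z2
  tot[tot == 0] <- 1
  pi_hat <- pmin(pmax((z2 + z1 / 2) / tot, 0), 1)
  diag(pi_hat) <- 1
  dimnames(pi_hat) <- list(g$sample_ids, g$sample_ids)
  lowconf <- Ncc < min_overlap
  diag(lowconf) <- FALSE
  structure(pi_hat, low_confidence = lowconf, class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  v <- x[upper.tri(x)]
  cat(sprintf("relatedness_matrix: %d samples; PI-HAT range %.3f-%.3f (off-diagonal)\n",
              nrow(x), min(v), max(v)))
  invisible(x)
}

#' Resolve related samples
#'
#' Iteratively removes the sample involved in the most pairs with PI-HAT
#' strictly above `threshold` until no such pair remains. Ties are broken by
#' higher missingness, then by lexicographically smaller sample id; the rule
#' is deterministic.
#'
#' @param rm a [pihat()] relatedness matrix
#' @param threshold PI-HAT threshold in (0, 1); pairs strictly above are
#'   considered related
#' @param missingness named per-sample missing fraction
#'   ([individual_missingness()]); defaults to zeros
#' @return character vector of removed sample ids (possibly empty)
#' @export
resolve_related <- function(rm, threshold = 0.20, missingness = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  ids <- rownames(rm)
  if (is.null(missingness)) missingness <- setNames(numeric(length(ids)), ids)
  adj <- unclass(rm) > threshold
  diag(adj) <- FALSE
  removed <- character(0)
  while (any(adj)) {
    deg <- rowSums(adj)
    cand <- ids[deg == max(deg)]
    if (length(cand) > 1) {
      mx <- missingness[cand]
      cand <- cand[mx == max(mx)]
    }
    victim <- sort(cand)[1]
    removed <- c(removed, victim)
    k <- match(victim, ids)
    adj <- adj[-k, -k, drop = FALSE]
    ids <- ids[-k]
  }
  removed
}
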