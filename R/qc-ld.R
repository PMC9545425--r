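#' Linkage-disequilibrium pruning
#'
#' Sliding-window greedy pruning of SNPs in LD. Within each window of
#' `window` SNPs (advancing by `step`), while any retained pair has squared
#' dosage correlation r^2 strictly above `r2_max` (pairwise-complete
#' genotypes), the pair with the largest r^2 is located and the member with
#' the lower call rate is removed (ties: the higher variant index). After
#' pruning, no retained within-window pair exceeds `r2_max`.
#'
#' @param g a [genotype_matrix()]
#' @param r2_max maximum tolerated r^2, in (0, 1]
#' @param window window size in SNPs (>= 2)
#' @param step window step in SNPs
#' @return list with `genotypes` and `stage`
#' @export
ld_prune <- function(g, r2_max = 0.20, window = 50, step = 5) {
  stopifnot(r2_max > 0, r2_max <= 1)
  if (window < 2) stop("window must span at least 2 SNPs")
  stopifnot(step >= 1)
  nv <- n_variants(g)
  keep <- rep(TRUE, nv)
  callrate <- colMeans(!is.na(g$calls))
  starts <- seq(1L, max(1L, nv - 1L), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1L, nv)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(
      cor(g$calls[, idx, drop = FALSE], use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 0
    while (max(r2) > r2_max) {
      hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      pair <- idx[c(hit[1], hit[2])]
      drop_v <- if (callrate[pair[1]] < callrate[pair[2]]) pair[1]
                else if (callrate[pair[2]] < callrate[pair[1]]) pair[2]
                else max(pair)
      keep[drop_v] <- FALSE
      k <- which(idx == drop_v)
      r2 <- r2[-k, -k, drop = FALSE]
      idx <- idx[-k]
      if (length(idx) < 2) break
    }
  }
  list(genotypes = gm_subset(g, variants = keep),
       stage = qc_stage("ld_prune", "variant", nv, sum(!keep),
                        list(r2_max = r2_max, window = window, step = step)))
}
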