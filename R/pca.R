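#' Principal component analysis of genotypes
#'
#' Patterson-normalised PCA: each variant is centred at its mean dosage and
#' scaled by sqrt(p*(1-p)) with p the sample ALT-allele frequency; missing
#' calls are mean-imputed (0 after centring); monomorphic variants are
#' dropped before scaling. Computed by SVD of the normalised matrix, which is
#' equivalent to eigendecomposing the sample x sample covariance.
#'
#' @param g a [genotype_matrix()]
#' @param k number of axes to return scores for (default 10, capped at the
#'   available rank)
#' @return object of class `pca_result`: list with `scores` (samples x k),
#'   `varfrac` (explained-variance fraction per axis, all axes, summing
#'   to 1), `values` (eigenvalues of the covariance), `k`
#' @export
pca <- function(g, k = 10) {
  if (n_samples(g) < 2 || n_variants(g) < 2)
    stop("need at least 2 samples and 2 variants")
  X <- g$calls
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(X, 2, 2 * p)
  X <- sweep(X, 2, sqrt(p * (1 - p)), "/")
  X[is.na(X)] <- 0
  L <- ncol(X)
  sv <- svd(X)
  values <- sv$d^2 / L                      # eigenvalues of X X^T / L
  pos <- values > max(values) * 1e-12
  varfrac <- values / sum(values[pos])
  varfrac[!pos] <- 0
  k <- min(k, sum(pos))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)] / sqrt(L), k, k)
  dimnames(scores) <- list(g$sample_ids, paste0("PC", seq_len(k)))
  structure(list(scores = scores, varfrac = varfrac, values = values, k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d axes returned; PC1-%d explain %.1f%% of variance\n",
              nrow(x$scores), x$k, x$k, 100 * sum(x$varfrac[seq_len(x$k)])))
  invisible(x)
}
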