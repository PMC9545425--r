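#' Summary-statistic vector for ABC
#'
#' Computes the fixed, named summary vector comparing observed and simulated
#' SNP datasets. Per population: proportion of monomorphic loci, mean and
#' variance across loci of gene diversity (unbiased expected heterozygosity
#' 2*p*(1-p)*n/(n-1) over called alleles). Per population pair: mean and
#' variance of per-locus Weir-Cockerham F_ST (loci where the pooled pair is
#' polymorphic), mean Nei minimum distance, and the proportion of loci
#' monomorphic in the pooled pair. Per declared trio (target | source1,
#' source2): mean and variance across loci of the least-squares admixture
#' coefficient, the a in [0, 1] minimising (p_T - a*p_1 - (1-a)*p_2)^2 at
#' each locus (loci with p_1 = p_2 are uninformative and excluded; a trio
#' with no informative locus falls back to mean 0.5, variance 0).
#'
#' The vector is deterministic, invariant to sample order, and its schema is
#' fixed given (populations, trios).
#'
#' @param g a [genotype_matrix()] (each SNP treated as one locus unit)
#' @param pm a [population_map()]
#' @param trios list of trios, each a list/record with `target`, `source1`,
#'   `source2`
#' @return named numeric vector
#' @export
summarize <- function(g, pm, trios = NULL) {
  check_popmap(g, pm)
  pops <- pm$populations
  if (length(pops) < 2) stop("need at least 2 populations")
  L <- n_variants(g)
  P <- N <- H <- matrix(NA_real_, length(pops), L, dimnames = list(pops, NULL))
  for (p in pops) {
    ac <- .allele_counts(g, pop_samples(g, pm, p))
    N[p, ] <- ac$n
    P[p, ] <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
    H[p, ] <- ifelse(ac$n > 0, ac$het / (ac$n / 2), NA_real_)
  }
  out <- c()
  vz <- function(x) if (length(x) > 1) var(x) else 0
  for (p in pops) {
    ok <- N[p, ] >= 2
    pp <- P[p, ok]
    nn <- N[p, ok]
    gd <- 2 * pp * (1 - pp) * nn / (nn - 1)
    mono <- pp == 0 | pp == 1
    out <- c(out, setNames(
      c(if (any(ok)) mean(mono) else 0,
        if (any(ok)) mean(gd) else 0,
        if (any(ok)) vz(gd) else 0),
      paste0(c("mono.", "gdmean.", "gdvar."), p)))
  }
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    a <- pops[i]; b <- pops[j]
    ok <- N[a, ] >= 2 & N[b, ] >= 2
    pool <- (P[a, ] * N[a, ] + P[b, ] * N[b, ]) / (N[a, ] + N[b, ])
    pooled_mono <- ok & (pool == 0 | pool == 1)
    comp <- .wc_components(N[a, ] / 2, P[a, ], H[a, ],
                           N[b, ] / 2, P[b, ], H[b, ])
    den <- comp$a + comp$b + comp$c
    use <- ok & !pooled_mono & !is.na(den) & den != 0
    fst <- comp$a[use] / den[use]
    jx <- P[a, ok]^2 + (1 - P[a, ok])^2
    jy <- P[b, ok]^2 + (1 - P[b, ok])^2
    jxy <- P[a, ok] * P[b, ok] + (1 - P[a, ok]) * (1 - P[b, ok])
    out <- c(out, setNames(
      c(if (length(fst)) mean(fst) else 0,
        if (length(fst)) vz(fst) else 0,
        if (any(ok)) mean((jx + jy) / 2 - jxy) else 0,
        if (any(ok)) mean(pooled_mono[ok]) else 0),
      paste0(c("fstmean.", "fstvar.", "nei.", "pairmono."), a, ".", b)))
  }
  for (tr in trios) {
    tg <- tr$target; s1 <- tr$source1; s2 <- tr$source2
    if (!all(c(tg, s1, s2) %in% pops))
      stop("trio references unknown population")
    ok <- N[tg, ] >= 2 & N[s1, ] >= 2 & N[s2, ] >= 2 &
      abs(P[s1, ] - P[s2, ]) > 1e-9
    aa <- (P[tg, ok] - P[s2, ok]) / (P[s1, ok] - P[s2, ok])
    aa <- pmin(pmax(aa, 0), 1)
    out <- c(out, setNames(
      c(if (length(aa)) mean(aa) else 0.5,
        if (length(aa)) vz(aa) else 0),
      paste0(c("admmean.", "admvar."), tg, ".", s1, ".", s2)))
  }
  out
}

#' Names of the summary-statistic schema
#' @param populations ordered population labels
#' @param trios trio list as in [summarize()]
#' @return character vector of statistic names
#' @export
summary_schema <- function(populations, trios = NULL) {
  out <- c()
  for (p in populations)
    out <- c(out, paste0(c("mono.", "gdmean.", "gdvar."), p))
  for (i in seq_along(populations)) for (j in seq_along(populations)) {
    if (j <= i) next
    out <- c(out, paste0(c("fstmean.", "fstvar.", "nei.", "pairmono."),
                         populations[i], ".", populations[j]))
  }
  for (tr in trios)
    out <- c(out, paste0(c("admmean.", "admvar."),
                         tr$target, ".", tr$source1, ".", tr$source2))
  out
}

#' Linear discriminant projector over a reference table
#'
#' Fits LDA axes separating the scenarios of a reference table, to be
#' appended to the raw summaries as additional statistics. Inputs are
#' standardised (zero-variance columns dropped), the pooled within-class
#' covariance is ridge-stabilised, and the n_scenarios - 1 leading
#' discriminant axes are retained. The projector is fit on the reference
#' table only, never on the observed vector, and both are projected
#' identically.
#'
#' @param rt a [generate_reference_table()] result with >= 2 scenarios
#' @param ridge relative ridge added to the within-class covariance diagonal
#' @return object of class `lda_projector`
#' @export
fit_lda <- function(rt, ridge = 1e-6) {
  y <- rt$scenario
  if (nlevels(y) < 2) stop("need at least 2 scenarios for LDA")
  X <- rt$sumstats
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  k <- nlevels(y)
  mu <- rowsum(Xs, y) / as.vector(table(y))
  gm <- colMeans(Xs)
  W <- matrix(0, ncol(Xs), ncol(Xs))
  for (cl in levels(y)) {
    Z <- sweep(Xs[y == cl, , drop = FALSE], 2, mu[cl, ])
    W <- W + crossprod(Z)
  }
  W <- W / (nrow(Xs) - k)
  W <- W + diag(ridge * mean(diag(W)), ncol(W))
  B <- crossprod(sweep(mu, 2, gm) * sqrt(as.vector(table(y))))
  eg <- eigen(solve(W, B))
  rot <- Re(eg$vectors[, seq_len(k - 1), drop = FALSE])
  structure(list(center = ctr[keep], scale = scl[keep], keep = keep,
                 rotation = rot, eigenvalues = Re(eg$values[seq_len(k - 1)])),
            class = "lda_projector")
}

#' @rdname fit_lda
#' @param projector an `lda_projector`
#' @param v a summary vector or a matrix of summary rows
#' @return the input with `LDA1..LDA(k-1)` axis scores appended
#' @export
apply_lda <- function(projector, v) {
  one <- is.null(dim(v))
  M <- if (one) matrix(v, 1, dimnames = list(NULL, names(v))) else v
  Xs <- sweep(sweep(M[, projector$keep, drop = FALSE], 2, projector$center),
              2, projector$scale, "/")
  ax <- Xs %*% projector$rotation
  colnames(ax) <- paste0("LDA", seq_len(ncol(ax)))
  out <- cbind(M, ax)
  if (one) setNames(as.vector(out), colnames(out)) else out
}
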