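#' Nei genetic distance between populations
#'
#' From per-population ALT-allele frequencies at each biallelic site
#' (estimated from called alleles, i.e. missing data replaced by the
#' population mean allele counts). The default is Nei's minimum distance,
#' Dm = mean over sites of (Jx + Jy)/2 - Jxy with Jx = sum(p^2) over the two
#' alleles and Jxy = sum(p_x * p_y); the standard (1972) distance
#' D = -ln( sum Jxy / sqrt(sum Jx * sum Jy) ) over all sites is available by
#' option. Sites where either population has no called alleles are excluded
#' for that pair.
#'
#' @param g a [genotype_matrix()]
#' @param pm a [population_map()]
#' @param method `"minimum"` (default) or `"standard"`
#' @return symmetric populations x populations distance matrix
#' @export
nei_distance <- function(g, pm, method = c("minimum", "standard")) {
  method <- match.arg(method)
  check_popmap(g, pm)
  pops <- pm$populations
  P <- matrix(NA_real_, length(pops), n_variants(g), dimnames = list(pops, NULL))
  for (p in pops) {
    ac <- .allele_counts(g, pop_samples(g, pm, p))
    P[p, ] <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
  }
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    px <- P[i, ]; py <- P[j, ]
    ok <- !is.na(px) & !is.na(py)
    jx <- px[ok]^2 + (1 - px[ok])^2
    jy <- py[ok]^2 + (1 - py[ok])^2
    jxy <- px[ok] * py[ok] + (1 - px[ok]) * (1 - py[ok])
    d <- if (method == "minimum") mean((jx + jy) / 2 - jxy)
         else -log(sum(jxy) / sqrt(sum(jx) * sum(jy)))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining population tree
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]) on a population distance
#' matrix. Exact on additive matrices (topology and branch lengths).
#'
#' @param D symmetric distance matrix (>= 3 populations)
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(D) {
  if (nrow(as.matrix(D)) < 3) stop("need at least 3 populations for a tree")
  ape::nj(stats::as.dist(D))
}

#' Bootstrap support for the NJ population tree
#'
#' Resamples RAD loci with replacement, recomputes the Nei distance matrix
#' and NJ tree for each replicate, and reports for each internal edge of the
#' reference tree the percentage of replicates containing the same
#' bipartition.
#'
#' @param g a [genotype_matrix()]
#' @param pm a [population_map()]
#' @param n_boot number of bootstrap replicates
#' @param method distance variant, as in [nei_distance()]
#' @return list with `tree` (reference NJ tree), `support` (per internal
#'   node, in %, aligned with `tree$node.label`), and `n_boot`
#' @export
nj_bootstrap <- function(g, pm, n_boot = 1000, method = "minimum") {
  tree <- nj_tree(nei_distance(g, pm, method))
  loc <- factor(g$variant_meta$locus_id)
  lev <- levels(loc)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    k <- sample(lev, length(lev), replace = TRUE)
    vidx <- unlist(lapply(k, function(L) which(loc == L)), use.names = FALSE)
    gb <- gm_subset(g, variants = sort(vidx))
    boots[[b]] <- nj_tree(nei_distance(gb, pm, method))
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_boot
  tree$node.label <- sprintf("%.1f", support)
  list(tree = tree, support = support, n_boot = n_boot)
}
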