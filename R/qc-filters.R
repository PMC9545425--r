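#' Variant call-rate filter
#'
#' Removes variants genotyped in strictly fewer than `min_rate` of the current
#' samples (a variant called in exactly `min_rate` of samples is kept).
#'
#' @param g a [genotype_matrix()]
#' @param min_rate minimum fraction of samples with a call, in (0, 1]
#' @return list with `genotypes` (filtered matrix) and `stage` (a [qc_stage()]
#'   record)
#' @export
filter_call_rate <- function(g, min_rate = 0.80) {
  stopifnot(min_rate > 0, min_rate <= 1)
  rate <- colMeans(!is.na(g$calls))
  keep <- rate >= min_rate
  list(genotypes = gm_subset(g, variants = keep),
       stage = qc_stage("call_rate", "variant", n_variants(g), sum(!keep),
                        list(min_rate = min_rate)))
}

#' Minor-allele-count filter
#'
#' Removes variants whose minor-allele count over called genotypes is strictly
#' below `min_count`. Monomorphic variants (count 0) are always removed for
#' `min_count >= 1`.
#'
#' @param g a [genotype_matrix()]
#' @param min_count minimum minor-allele count (integer >= 1)
#' @return list with `genotypes` and `stage`
#' @export
filter_mac <- function(g, min_count = 10) {
  stopifnot(min_count >= 1)
  alt <- colSums(g$calls, na.rm = TRUE)
  n <- 2L * colSums(!is.na(g$calls))
  mac <- pmin(alt, n - alt)
  keep <- mac >= min_count
  list(genotypes = gm_subset(g, variants = keep),
       stage = qc_stage("mac", "variant", n_variants(g), sum(!keep),
                        list(min_count = min_count)))
}

#' Drop indel variants
#'
#' Removes variants flagged `is_indel` (set at read time from ref/alt length
#' mismatch, or supplied in the metadata).
#'
#' @param g a [genotype_matrix()]
#' @return list with `genotypes` and `stage`
#' @export
drop_indels <- function(g) {
  keep <- !g$variant_meta$is_indel
  list(genotypes = gm_subset(g, variants = keep),
       stage = qc_stage("indels", "variant", n_variants(g), sum(!keep)))
}

#' Per-sample missingness and sample filter
#'
#' `individual_missingness()` returns the fraction of missing calls per
#' sample; `drop_samples()` removes samples whose missing fraction is strictly
#' above `max_missing`.
#'
#' @param g a [genotype_matrix()]
#' @return `individual_missingness()`: named numeric vector of missing
#'   fractions.
#' @export
individual_missingness <- function(g) {
  setNames(rowMeans(is.na(g$calls)), g$sample_ids)
}

#' @param max_missing maximum tolerated missing fraction (samples strictly
#'   above are removed)
#' @param stage_name label for the report record
#' @rdname individual_missingness
#' @return `drop_samples()`: list with `genotypes` and `stage`
#' @export
drop_samples <- function(g, max_missing = 0.25, stage_name = "missingness") {
  miss <- individual_missingness(g)
  keep <- miss <= max_missing
  list(genotypes = gm_subset(g, samples = keep),
       stage = qc_stage(stage_name, "sample", n_samples(g), sum(!keep),
                        list(max_missing = max_missing)))
}
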