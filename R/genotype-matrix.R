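#' Genotype matrix of biallelic SNP dosages
#'
#' The central data container of the package: a samples x variants matrix of
#' diploid ALT-allele dosages in `{0, 1, 2}` with `NA` for missing calls, plus
#' per-variant metadata. Dosages always count the ALT allele as written in the
#' source VCF; minor-allele frequencies are computed downstream and never by
#' re-polarizing storage. Variants are kept sorted by (contig, position), and
#' `locus_id` groups the SNPs of one RAD fragment (by default one locus per
#' contig, matching a de novo RAD reference).
#'
#' @param calls integer matrix (samples x variants) with values in
#'   `{0, 1, 2, NA}`.
#' @param variant_meta data.frame with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `locus_id` (default: the contig) and
#'   `is_indel` (default: ref/alt length mismatch).
#' @param sample_ids character vector of sample identifiers; defaults to
#'   `rownames(calls)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variant_meta`, `sample_ids`.
#' @export
genotype_matrix <- function(calls, variant_meta, sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(calls))
    stop("sample_ids must match the number of rows of calls")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  variant_meta <- as.data.frame(variant_meta, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(variant_meta)))
    stop("variant_meta needs columns: ", paste(need, collapse = ", "))
  if (nrow(variant_meta) != ncol(calls))
    stop("variant_meta rows must match the number of variant columns")
  if (is.null(variant_meta$locus_id)) variant_meta$locus_id <- variant_meta$contig
  if (is.null(variant_meta$is_indel))
    variant_meta$is_indel <- nchar(variant_meta$ref) != 1L |
      nchar(variant_meta$alt) != 1L
  ord <- order(variant_meta$contig, variant_meta$pos)
  calls <- calls[, ord, drop = FALSE]
  variant_meta <- variant_meta[ord, , drop = FALSE]
  rownames(variant_meta) <- NULL
  rownames(calls) <- sample_ids
  colnames(calls) <- NULL
  structure(list(calls = calls, variant_meta = variant_meta,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d loci), %.1f%% missing\n",
              n_samples(x), n_variants(x),
              length(unique(x$variant_meta$locus_id)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param g a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname n_samples
#' @export
n_variants <- function(g) ncol(g$calls)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param g a `genotype_matrix`
#' @param samples logical/integer/character index over samples (default: all)
#' @param variants logical/integer index over variants (default: all)
#' @return the subsetted `genotype_matrix`
#' @export
gm_subset <- function(g, samples = NULL, variants = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(g))
  if (is.character(samples)) samples <- match(samples, g$sample_ids)
  if (is.null(variants)) variants <- seq_len(n_variants(g))
  genotype_matrix(g$calls[samples, variants, drop = FALSE],
                  g$variant_meta[variants, , drop = FALSE],
                  g$sample_ids[samples])
}

#' Population map: sample to population assignment
#'
#' @param assignments named character vector (names = sample ids, values =
#'   population labels) or a two-column data.frame (sample, population).
#' @return object of class `population_map` with fields `assignments` (named
#'   character) and `populations` (ordered unique labels).
#' @export
population_map <- function(assignments) {
  if (is.data.frame(assignments)) {
    a <- as.character(assignments[[2]])
    names(a) <- as.character(assignments[[1]])
    assignments <- a
  }
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("assignments must be named by sample id")
  if (anyDuplicated(names(assignments)))
    stop("duplicated sample in population map")
  structure(list(assignments = assignments,
                 populations = unique(unname(assignments))),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(factor(x$assignments, levels = x$populations))
  cat("population_map:", length(x$assignments), "samples in",
      length(x$populations), "populations\n")
  print(tab)
  invisible(x)
}

#' Sample indices of one population
#' @param g a `genotype_matrix`
#' @param pm a `population_map`
#' @param pop population label
#' @return integer indices into the samples of `g`
#' @export
pop_samples <- function(g, pm, pop) {
  ids <- names(pm$assignments)[pm$assignments == pop]
  idx <- match(ids, g$sample_ids)
  idx[!is.na(idx)]
}

# internal: check that pm covers g exactly
check_popmap <- function(g, pm) {
  missing <- setdiff(g$sample_ids, names(pm$assignments))
  if (length(missing))
    stop("samples missing from population map: ",
         paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}
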