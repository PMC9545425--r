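#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (optionally gzip-compressed) with GT fields into a
#' [genotype_matrix()]. Dosages count ALT alleles; `./.` becomes `NA`.
#' Multiallelic records are dropped with a message. The RAD locus of each
#' variant defaults to its contig (one 150-bp fragment per contig in a de novo
#' RAD reference); a `LOCUS=` INFO tag, when present, overrides it. Depth
#' fields (DP/DPR) are parsed by the underlying reader but ignored.
#'
#' @param path VCF file path (`.vcf` or `.vcf.gz`)
#' @param keep_indels if `FALSE`, indels (ref/alt length mismatch) are dropped
#'   at read time; if `TRUE` (default) they are kept and flagged `is_indel`
#'   for [drop_indels()].
#' @return a [genotype_matrix()]
#' @export
read_vcf <- function(path, keep_indels = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  info <- vcf@fix[, "INFO"]
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) dropped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
    info <- info[!multi]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  # normalise phased separators, then count ALT alleles
  gtv <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  known <- is.na(gtv) | gtv %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (!all(known)) {
    bad <- unique(gtv[!known])
    stop("unsupported (non-diploid?) GT value(s): ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  dos <- rep(NA_integer_, length(gtv))
  dos[gtv %in% "0/0"] <- 0L
  dos[gtv %in% c("0/1", "1/0")] <- 1L
  dos[gtv %in% "1/1"] <- 2L
  calls <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  locus <- sub(".*LOCUS=([^;]+).*", "\\1", info)
  locus[!grepl("LOCUS=", info)] <- NA
  meta <- data.frame(contig = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"],
                     alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  meta$locus_id <- ifelse(is.na(locus), meta$contig, locus)
  meta$is_indel <- nchar(meta$ref) != 1L | nchar(meta$alt) != 1L
  g <- genotype_matrix(t(calls), meta, sample_ids = colnames(gt))
  if (!keep_indels) g <- gm_subset(g, variants = !g$variant_meta$is_indel)
  g
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a GT-only VCF with records in deterministic (contig, position) order
#' (the storage order of a [genotype_matrix()]). The ALT allele of each record
#' is the allele whose dosage is stored, so `write_vcf()` followed by
#' [read_vcf()] is the identity on (sample ids, variant metadata, calls).
#' A `LOCUS=` INFO tag records the RAD locus of each SNP. Output is
#' gzip-compressed when `path` ends in `.gz`.
#'
#' @param g a [genotype_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vcf <- function(g, path) {
  m <- g$variant_meta
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radabc",
    "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"RAD locus identifier\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_variants(g), ncol = n_samples(g))
  ok <- !is.na(t(g$calls))
  gt[ok] <- code[t(g$calls)[ok] + 1L]
  body <- character(0)
  if (n_variants(g) > 0) {
    left <- paste(m$contig, m$pos, ".", m$ref, m$alt, ".", "PASS",
                  paste0("LOCUS=", m$locus_id), "GT", sep = "\t")
    body <- paste(left, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    if (n_samples(g) == 0) body <- left
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a sample-to-population map (two-column TSV)
#'
#' @param path TSV file with columns sample, population (no header required;
#'   a header line `sample<TAB>population` is tolerated).
#' @param g optional [genotype_matrix()]; when given, coverage is checked both
#'   ways: every sample of `g` must be mapped and every mapped sample must be
#'   in `g`.
#' @return a [population_map()]
#' @export
read_popmap <- function(path, g = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "population"))
  if (nrow(df) && identical(tolower(df$sample[1]), "sample"))
    df <- df[-1, , drop = FALSE]
  pm <- population_map(df)
  if (!is.null(g)) {
    check_popmap(g, pm)
    extra <- setdiff(names(pm$assignments), g$sample_ids)
    if (length(extra))
      stop("popmap contains unknown sample(s): ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  pm
}

#' Write a population map as TSV
#' @param pm a [population_map()]
#' @param path output path
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(data.frame(sample = names(pm$assignments),
                                population = unname(pm$assignments)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
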