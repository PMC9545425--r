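#' Default QC configuration
#'
#' Thresholds of the full SNP QC chain. The defaults are the standard
#' RAD-seq values used throughout the package: call rate >= 80%,
#' minor-allele count >= 10, exact-HWE rejection (p < 0.05) in all-but-one
#' populations, LD pruning at r^2 > 0.20 (window 50 SNPs, step 5), sample
#' missingness <= 25% (with a separate 90% "failed to sequence" stage run
#' before HWE), and PI-HAT > 0.20 for relatedness removal.
#'
#' @param ... overrides for individual entries
#' @return named list of thresholds
#' @export
qc_config <- function(...) {
  cfg <- list(min_call_rate = 0.80, min_mac = 10,
              hwe_alpha = 0.05, hwe_min_pops = NULL,
              ld_r2 = 0.20, ld_window = 50, ld_step = 5,
              fail_missing = 0.90, max_missing = 0.25,
              pihat_max = 0.20, pihat_min_overlap = 50)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown qc_config entries: ",
                            paste(unknown, collapse = ", "))
  modifyList(cfg, over)
}

#' Run the full SNP QC chain
#'
#' Executes, in order: variant call-rate and minor-allele-count filters (the
#' genotype-table-creation filters), indel removal, removal of failed samples
#' (missingness above `fail_missing`), the across-population Hardy-Weinberg
#' filter, LD pruning, removal of high-missingness samples, and removal of
#' related samples (PI-HAT). Returns the analysis-ready genotype matrix plus
#' a [qc_report()] whose stages telescope from the initial to the final
#' variant and sample counts.
#'
#' @param g a [genotype_matrix()]
#' @param pm a [population_map()] covering the samples of `g`
#' @param config a [qc_config()] list
#' @return list with `genotypes`, `report` (a `qc_report`), `relatedness`
#'   (the PI-HAT matrix computed on the post-missingness sample set), and
#'   `removed_related` (sample ids removed at the relatedness stage)
#' @export
run_qc <- function(g, pm, config = qc_config()) {
  check_popmap(g, pm)
  stages <- list()
  s <- filter_call_rate(g, config$min_call_rate)
  stages <- c(stages, list(s$stage)); g <- s$genotypes
  s <- filter_mac(g, config$min_mac)
  stages <- c(stages, list(s$stage)); g <- s$genotypes
  s <- drop_indels(g)
  stages <- c(stages, list(s$stage)); g <- s$genotypes
  s <- drop_samples(g, config$fail_missing, stage_name = "failed_samples")
  stages <- c(stages, list(s$stage)); g <- s$genotypes
  s <- hwe_filter(g, pm, config$hwe_alpha, config$hwe_min_pops)
  stages <- c(stages, list(s$stage)); g <- s$genotypes
  s <- ld_prune(g, config$ld_r2, config$ld_window, config$ld_step)
  stages <- c(stages, list(s$stage)); g <- s$genotypes
  s <- drop_samples(g, config$max_missing, stage_name = "missingness")
  stages <- c(stages, list(s$stage)); g <- s$genotypes
  rm <- pihat(g, config$pihat_min_overlap)
  removed <- resolve_related(rm, config$pihat_max, individual_missingness(g))
  stages <- c(stages, list(qc_stage("relatedness", "sample", n_samples(g),
                                    length(removed),
                                    list(pihat_max = config$pihat_max))))
  if (length(removed))
    g <- gm_subset(g, samples = !(g$sample_ids %in% removed))
  list(genotypes = g, report = qc_report(stages), relatedness = rm,
       removed_related = removed)
}
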