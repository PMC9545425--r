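#' Run configuration
#'
#' Assembles and checks the configuration of a full pipeline run. Unknown
#' keys are rejected so config typos fail fast.
#'
#' @param vcf input VCF path
#' @param popmap input popmap TSV path
#' @param out_dir output directory (created if needed)
#' @param qc a [qc_config()] list
#' @param scenarios character vector of scenario YAML paths (optional; when
#'   given, the ABC stages run)
#' @param n_per_scenario simulations per scenario for the reference table
#' @param n_loci_sim loci per simulated dataset (default: the observed locus
#'   count is used when `NULL`)
#' @param n_trees trees for the random forests
#' @param n_boot,n_perm resampling sizes for the F_ST table
#' @param nj_boot bootstrap replicates for the NJ tree
#' @param seed master seed for every stochastic stage
#' @param resume skip a stage when its outputs already exist
#' @return object of class `run_config`
#' @export
run_config <- function(vcf, popmap, out_dir, qc = qc_config(),
                       scenarios = NULL, n_per_scenario = 500,
                       n_loci_sim = NULL, n_trees = 500,
                       n_boot = 500, n_perm = 1000, nj_boot = 200,
                       seed = 1L, resume = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline: QC, statistics, and (optionally) ABC-RF
#'
#' Executes QC ([run_qc()]) then the statistics stage (per-population
#' diversity, pairwise F_ST with CIs and permutation p-values, Nei/NJ tree
#' with bootstrap supports, PCA scores), then — when scenario files are
#' configured — the ABC stage (reference table, model choice, parameter
#' posteriors with unit conversion). Every stage writes its tables under
#' `out_dir` and a manifest (seeds, package version, file hashes) makes the
#' run reproducible; rerunning with the same config and seed reproduces the
#' outputs. With `resume = TRUE` a stage whose outputs already exist is
#' skipped, so deleting one stage's outputs recomputes only from that stage
#' on.
#'
#' @param cfg a [run_config()]
#' @return the output directory, invisibly; stage results as attributes
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(cfg$out_dir, paste0(...))
  done <- function(...) cfg$resume &&
    all(file.exists(file.path(cfg$out_dir, c(...))))
  set.seed(cfg$seed)
  g <- read_vcf(cfg$vcf)
  pm <- read_popmap(cfg$popmap, g)

  # --- QC stage ---
  if (!done("filtered.vcf")) {
    qc <- run_qc(g, pm, cfg$qc)
    write_vcf(qc$genotypes, pth("filtered.vcf"))
    write_qc_report(qc$report, pth("qc_report"))
    utils::write.table(round(unclass(qc$relatedness), 5), pth("relatedness.tsv"),
                       sep = "\t", quote = FALSE)
  }
  gf <- read_vcf(pth("filtered.vcf"))
  pmf <- population_map(pm$assignments[gf$sample_ids])

  # --- statistics stage ---
  if (!done("popstats.tsv", "fst.tsv", "nj_tree.nwk", "pca_scores.tsv")) {
    set.seed(cfg$seed + 1L)
    utils::write.table(population_stats(gf, pmf), pth("popstats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pairwise_fst(gf, pmf, cfg$n_boot, cfg$n_perm),
                       pth("fst.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nj <- nj_bootstrap(gf, pmf, cfg$nj_boot)
    ape::write.tree(nj$tree, pth("nj_tree.nwk"))
    pc <- pca(gf)
    sc <- cbind(data.frame(sample = rownames(pc$scores)), pc$scores)
    utils::write.table(sc, pth("pca_scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(axis = seq_along(pc$varfrac),
                                  varfrac = pc$varfrac),
                       pth("pca_varfrac.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # --- ABC stage ---
  if (!is.null(cfg$scenarios) && !done("model_choice.json")) {
    set.seed(cfg$seed + 2L)
    scen <- lapply(cfg$scenarios, scenario_load)
    names(scen) <- vapply(scen, function(s) s$name, character(1))
    ss <- table(factor(pmf$assignments, levels = pmf$populations))
    ss <- setNames(as.integer(ss), names(ss))
    n_loci <- cfg$n_loci_sim %||% length(unique(gf$variant_meta$locus_id))
    missr <- vapply(pmf$populations, function(p)
      mean(is.na(gf$calls[pop_samples(gf, pmf, p), ])), numeric(1))
    trios <- unique(do.call(c, lapply(scen, function(s) s$trios)))
    rt <- generate_reference_table(scen, cfg$n_per_scenario, ss, n_loci,
                                   missr, trios)
    obs <- summarize(gf, pmf, trios)
    if (length(scen) > 1) {
      mc <- model_choice(rt, obs, cfg$n_trees, seed = cfg$seed + 3L)
      best <- mc$selected
      jsonlite::write_json(
        list(selected = mc$selected,
             vote_fractions = setNames(as.list(mc$vote_fractions),
                                       names(mc$votes)),
             prior_error_rate = mc$prior_error_rate,
             posterior_probability = mc$posterior_probability,
             n_trees = mc$n_trees),
        pth("model_choice.json"), auto_unbox = TRUE, digits = NA)
    } else {
      best <- names(scen)[1]
      jsonlite::write_json(list(selected = best, note = "single scenario"),
                           pth("model_choice.json"), auto_unbox = TRUE)
    }
    keep <- rt$scenario == best
    rtb <- structure(list(scenario = droplevels(rt$scenario[keep]),
                          params = rt$params[keep, , drop = FALSE],
                          sumstats = rt$sumstats[keep, , drop = FALSE],
                          schema = rt$schema, meta = rt$meta),
                     class = "reference_table")
    post <- estimate_parameters(rtb, obs, n_trees = cfg$n_trees,
                                seed = cfg$seed + 4L)
    est <- post$estimates
    tpar <- grepl("^t", est$parameter)
    est$mean_years <- ifelse(tpar, convert_units(est$mean), NA)
    est$q_lo_years <- ifelse(tpar, convert_units(est$q_lo), NA)
    est$q_hi_years <- ifelse(tpar, convert_units(est$q_hi), NA)
    utils::write.table(est, pth("parameter_posteriors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package = "radabc",
                   version = as.character(utils::packageVersion("radabc")),
                   seed = cfg$seed,
                   inputs = list(vcf = cfg$vcf, popmap = cfg$popmap),
                   input_md5 = as.list(tools::md5sum(c(cfg$vcf, cfg$popmap))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  invisible(cfg$out_dir)
}

#' Generate a demonstration dataset (VCF + popmap)
#'
#' Simulates a synthetic SNP dataset under the shipped best-supported
#' divergence/admixture scenario fixture and writes it as a VCF and a popmap
#' TSV — a self-contained input for exercising the whole pipeline.
#'
#' @param out_dir output directory
#' @param n_per_pop diploid samples per population
#' @param n_loci unlinked SNP loci
#' @param missingness per-call missing rate
#' @param seed RNG seed
#' @return named list with the `vcf` and `popmap` paths
#' @export
make_demo_data <- function(out_dir, n_per_pop = 10, n_loci = 1000,
                           missingness = 0.045, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sc <- scenario_load(scenario_fixtures()[["step2_best"]])
  ss <- setNames(rep(as.integer(n_per_pop), length(sc$populations)),
                 sc$populations)
  sim <- simulate_genotypes(sc, sample_sizes = ss, n_loci = n_loci,
                            missingness = missingness)
  vcf <- file.path(out_dir, "demo.vcf")
  popmap <- file.path(out_dir, "demo_popmap.tsv")
  write_vcf(sim$genotypes, vcf)
  write_popmap(sim$popmap, popmap)
  list(vcf = vcf, popmap = popmap)
}
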