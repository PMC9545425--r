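#' Simulate unlinked SNP genotypes under a demographic scenario
#'
#' For each locus independently, runs a backward-in-time Kingman coalescent
#' over the scenario's demes (coalescence rate k(k-1)/(4N) per generation in
#' a deme of diploid size N; merges, pulse admixtures and size changes at the
#' scheduled times), places exactly one mutation uniformly at random on the
#' total branch length — so every locus carries one biallelic SNP polymorphic
#' in the pooled sample, reproducing the ascertainment of discovered SNPs —
#' and pairs haploid lineages into diploid dosages. Per-population missing
#' data are then masked at the template rates; loci left monomorphic among
#' called genotypes are redrawn so `n_loci` is preserved. No mutation rate
#' enters the simulation; the per-year substitution rate is metadata used
#' only for unit conversion when reporting.
#'
#' @param sc an [scenario_from_list()] scenario
#' @param params named parameter values (one draw); defaults to the
#'   scenario's `point_estimates`
#' @param sample_sizes named integer vector of diploid sample sizes per
#'   sampled population; defaults to the scenario's `sample_sizes`
#' @param n_loci number of unlinked SNP loci to emit
#' @param missingness per-population missing-call rates: a scalar, a named
#'   vector, or `NULL` to use the scenario's `missingness` (default 0 if
#'   unset)
#' @param max_redraw maximum redraw rounds for post-masking monomorphic loci
#' @return list with `genotypes` (a [genotype_matrix()]; ALT is the derived
#'   allele), `popmap` (a [population_map()]), `tmrca` (per-locus tree
#'   height, generations), `params`
#' @export
simulate_genotypes <- function(sc, params = NULL, sample_sizes = NULL,
                               n_loci = 1000, missingness = NULL,
                               max_redraw = 50) {
  stopifnot(n_loci >= 1)
  if (is.null(params)) params <- unlist(sc$point_estimates)
  if (is.data.frame(params)) params <- unlist(params[1, , drop = TRUE])
  if (is.null(sample_sizes)) sample_sizes <- unlist(sc$sample_sizes)
  if (is.null(sample_sizes)) stop("sample_sizes required")
  pops <- sc$populations
  miss <- missingness %||% sc$missingness %||% 0
  if (length(miss) == 1 && is.null(names(miss)))
    miss <- setNames(rep(as.numeric(miss), length(pops)), pops)
  miss <- unlist(miss)[pops]
  ss <- sample_sizes[pops]
  if (any(is.na(ss))) stop("sample_sizes must cover every sampled population")
  demes <- c(pops, sc$ghosts)
  ss_all <- c(as.integer(ss), rep(0L, length(sc$ghosts)))
  N0 <- vapply(demes, function(d) .resolve(sc$ne[[d]], params), numeric(1))
  ev <- .build_events(sc, params)$matrix

  sim <- .sim_loci_cpp(n_loci, ss_all, N0, ev)
  pop_of <- rep(pops, times = ss)
  mask_rates <- miss[pop_of]
  mask <- function(d) {
    m <- matrix(runif(length(d)) < mask_rates, nrow = nrow(d))
    d[m] <- NA_integer_
    d
  }
  polymorphic <- function(d) {
    alt <- colSums(d, na.rm = TRUE)
    n <- 2L * colSums(!is.na(d))
    alt > 0L & alt < n
  }
  dosage <- mask(sim$dosage)
  tmrca <- sim$tmrca
  for (round in seq_len(max_redraw)) {
    bad <- which(!polymorphic(dosage))
    if (!length(bad)) break
    re <- .sim_loci_cpp(length(bad), ss_all, N0, ev)
    dosage[, bad] <- mask(re$dosage)
    tmrca[bad] <- re$tmrca
  }
  ids <- paste0(pop_of, "_", unlist(lapply(ss, seq_len)))
  meta <- data.frame(contig = sprintf("locus_%06d", seq_len(n_loci)),
                     pos = 75L, ref = "A", alt = "T",
                     locus_id = sprintf("locus_%06d", seq_len(n_loci)),
                     is_indel = FALSE, stringsAsFactors = FALSE)
  g <- genotype_matrix(dosage, meta, sample_ids = ids)
  pm <- population_map(setNames(pop_of, ids))
  list(genotypes = g, popmap = pm, tmrca = tmrca, params = params)
}

#' Build an ABC reference table
#'
#' Draws `n_per_scenario` parameter vectors from each scenario's priors,
#' simulates a SNP dataset of the observed shape for each draw, and computes
#' its summary-statistic vector ([summarize()]). All scenarios must sample
#' the same population set so the summary schema is shared.
#'
#' @param scenarios named list of scenarios (or a single scenario)
#' @param n_per_scenario simulations per scenario
#' @param sample_sizes,n_loci,missingness observed dataset shape, as in
#'   [simulate_genotypes()]
#' @param trios admixture trios for the summary vector; default: the union
#'   of the scenarios' declared trios
#' @param progress print a line every `progress` simulations (0 = quiet)
#' @return object of class `reference_table`: list with `scenario` (factor),
#'   `params` (data.frame, union of parameter columns), `sumstats` (matrix),
#'   `schema`, `meta`
#' @export
generate_reference_table <- function(scenarios, n_per_scenario,
                                     sample_sizes = NULL, n_loci = 1000,
                                     missingness = NULL, trios = NULL,
                                     progress = 0) {
  if (inherits(scenarios, "abc_scenario")) scenarios <- list(scenarios)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, function(s) s$name %||% "scenario",
                               character(1))
  pops0 <- scenarios[[1]]$populations
  for (s in scenarios)
    if (!setequal(s$populations, pops0))
      stop("all scenarios must share the sampled population set")
  if (is.null(trios))
    trios <- unique(do.call(c, lapply(scenarios, function(s) s$trios)))
  lab <- character(0); prows <- list(); srows <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    draws <- sample_prior(sc, n_per_scenario)
    for (i in seq_len(n_per_scenario)) {
      sim <- simulate_genotypes(sc, unlist(draws[i, , drop = FALSE]),
                                sample_sizes, n_loci, missingness)
      v <- summarize(sim$genotypes, sim$popmap, trios)
      lab <- c(lab, nm)
      prows[[length(prows) + 1]] <- draws[i, , drop = FALSE]
      srows[[length(srows) + 1]] <- v
      if (progress > 0 && (length(srows) %% progress == 0))
        message(length(srows), " simulations done")
    }
  }
  allp <- unique(unlist(lapply(prows, names)))
  params <- do.call(rbind, lapply(prows, function(p) {
    out <- as.data.frame(setNames(as.list(rep(NA_real_, length(allp))), allp))
    out[names(p)] <- p
    out
  }))
  sumstats <- do.call(rbind, srows)
  structure(list(scenario = factor(lab, levels = names(scenarios)),
                 params = params, sumstats = sumstats,
                 schema = colnames(sumstats),
                 meta = list(n_loci = n_loci, sample_sizes = sample_sizes,
                             trios = trios)),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("reference_table: %d simulations, %d scenario(s), %d summary statistics\n",
              length(x$scenario), nlevels(x$scenario), ncol(x$sumstats)))
  invisible(x)
}

#' Simulate a pseudo-observed summary vector
#'
#' One simulation at fixed parameters, summarised identically to reference-
#' table rows — the standard device for parameter-recovery and calibration
#' experiments.
#'
#' @inheritParams simulate_genotypes
#' @param trios admixture trios, as in [summarize()]
#' @return named summary-statistic vector
#' @export
make_pseudo_observed <- function(sc, params = NULL, sample_sizes = NULL,
                                 n_loci = 1000, missingness = NULL,
                                 trios = NULL) {
  if (is.null(trios)) trios <- sc$trios
  sim <- simulate_genotypes(sc, params, sample_sizes, n_loci, missingness)
  summarize(sim$genotypes, sim$popmap, trios)
}
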