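---
title: "Models and methods in radabc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in radabc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics and models it
implements: what is computed, under which assumptions, which defaults matter
and why, and what the synthetic-data generator does and does not emulate.

## The data model

Genotypes are stored as a samples × variants matrix of diploid ALT-allele
dosages in {0, 1, 2, NA} (`genotype_matrix`). Two conventions are fixed once
and never revisited:

* **Polarity.** Dosages count the ALT allele exactly as written in the
  source VCF. Minor-allele frequencies are derived downstream; storage is
  never re-polarised, so a write→read round trip is the identity and no
  polarity drift can accumulate between pipeline stages. All statistics in
  the package are invariant to a consistent within-locus allele flip.
* **Coordinates.** VCF positions are 1-based inclusive (the standard);
  internal indices are 0-based only inside the compiled simulator.

RAD loci (150-bp fragments) default to one locus per contig, matching a de
novo RAD reference where each fragment is its own contig; a `LOCUS=` INFO
tag overrides this for data aligned to a real assembly. The locus grouping
is the resampling unit everywhere (F_ST bootstrap CIs, NJ node supports), so
linked SNPs on one fragment always resample together.

## The QC chain

`run_qc()` applies, in order: variant call rate, minor-allele count, indel
removal, failed samples, Hardy–Weinberg filtering, LD pruning, sample
missingness, and relatedness. Threshold semantics are strict inequalities on
the removal side: "called in < 80%" and "minor count < 10" remove
strictly-below; "> 25% missing" and "PI-HAT > 0.20" remove strictly-above. A
variant called in exactly 80% of samples is kept.

* **HWE.** The per-population test is the two-sided exact test: conditioning
  on the observed allele counts, all heterozygote counts of matching parity
  are enumerated and the p-value is the total probability of configurations
  no more probable than the observed one. The exact test was chosen over the
  chi-square because SNP-panel genotype counts per population are small
  (7–31 individuals here) and the enumeration is cheap and exact; the suite
  verifies it against an independent closed-form enumeration for n ≤ 25.
  A variant is removed when it deviates (p < .05) in at least all-but-one of
  the populations — deviation in most populations indicates a genotyping
  artefact rather than local inbreeding or selection.
* **LD pruning.** Only the r² > 0.20 threshold is a substantive choice; the
  windowing (50 SNPs, step 5) is a conventional default and configurable.
  Within a window, the pair with the highest dosage r² (pairwise-complete)
  is located and the member with the lower call rate is dropped, ties to the
  higher index — a deterministic greedy rule whose post-condition (no
  retained within-window pair above threshold) is verified exhaustively in
  the tests. Note that strong population structure itself induces r²
  between physically unlinked loci; pruning a strongly structured sample
  therefore removes real signal along with linkage, which is the standard
  behaviour of whole-sample LD pruning.
* **Relatedness.** PI-HAT = P(IBD=2) + P(IBD=1)/2 by method-of-moments from
  identity-by-state counts. Expected IBS probabilities use factorial-moment
  (draw-without-replacement) forms of the allele-frequency products, which
  removes the finite-sample inflation of plug-in estimates; estimates are
  truncated to the probability simplex. Frequencies come from the full
  sample, not per population — per-population frequencies would bias
  cross-population pairs, and pooled frequencies (the standard usage)
  instead inflate within-population pairs in strongly drifted demes, which
  is visible on synthetic data with small Ne. Removal is iterative-greedy:
  the sample in the most over-threshold pairs goes first, ties broken by
  higher missingness then lexicographic id — determinism was preferred over
  reproducing any particular manual choice.

## Diversity and differentiation

* π per site is 2·n₋·n₊/(n(n−1)) over called alleles; sites with fewer than
  two called alleles are excluded.
* F_IS per individual is (O_hom − E_hom)/(N − E_hom) with E_hom from
  small-sample-corrected expected heterozygosity (2p̂q̂·n/(n−1)).
* Tajima's D uses the standard a₁…e₂ constants per RAD locus. With missing
  data the locus' allele number n is the rounded mean called-allele count
  across its sites — exact when data are complete (which is what the
  closed-form test covers), a documented approximation otherwise.
* Pairwise F_ST is the two-population Weir–Cockerham estimator with
  multi-locus aggregation as a **ratio of sums** of the per-site variance
  components, not a mean of per-site ratios: low-information sites make the
  per-site ratio wildly variable and its mean biased. Negative estimates are
  retained so that averages stay unbiased and CI coverage is honest. The
  implementation is checked to 1e-12 against an independently coded
  nested-ANOVA (mean-squares) route on random datasets.
* Nei's distance defaults to the **minimum distance** Dm (the variant named
  for the population tree in the motivating analysis); the 1972 standard
  distance is available by option since the two are easy to conflate.
  Missing data enter only through allele-frequency estimation from called
  alleles, which is equivalent to mean-imputation of allele counts.
* PCA uses Patterson normalisation and mean imputation (0 after centring).
  Mean imputation shrinks scores of high-missingness samples toward the
  origin; no probabilistic imputation is attempted, consistent with the
  NJ-tree treatment.

## The coalescent scenario engine

Scenarios are declarative YAML: sampled populations (plus unsampled "ghost"
branches), per-deme diploid effective sizes, and a backward-time event list
of merges, pulse admixtures, and size changes, with parameters bound to
uniform or log-uniform priors under order constraints (rejection-sampled).
Time is continuous, in generations; k lineages in a deme of diploid size N
coalesce at rate k(k−1)/(4N).

**Ascertainment by construction.** Each locus receives exactly one mutation,
placed uniformly at random on the realised gene tree, so every emitted SNP
is polymorphic in the pooled sample — the fixed-S conditioning that mirrors
how discovered SNP panels are simulated. No mutation rate enters the
simulation; the per-year substitution rate (1.5 × 10⁻⁹/site/year for the
motivating taxon) is reporting metadata only. A consequence worth noting:
with one uniformly placed mutation per tree the derived-allele spectrum is
E[Lᵢ/L_tot], which is *not* the unconditional 1/i spectrum (that would
correspond to mutation-rate-weighted trees); the test suite validates the
simulator against an independent per-tree Monte-Carlo oracle of exactly this
quantity rather than against 1/i.

Missingness is masked per population per call at template rates (default
4.5%, the genotyped-at-95.5% figure of the motivating dataset); loci left
monomorphic among called genotypes after masking are redrawn so the locus
count stays fixed. Randomness flows from R's global RNG (`set.seed()`), a
single sequential stream: the simulator is single-threaded and this keeps
reproducibility in the idiom every R user already knows.

**What the generator emulates:** population counts and sample sizes (8 demes
of 7–31 diploids), thousands of unlinked one-SNP loci, SNP ascertainment,
per-population missingness, divergence times of ~500–6,000 generations,
pulse-admixture fractions of ~0.3–0.7, and effective sizes of
~4,000–50,000. **What it does not emulate:** multiple SNPs per fragment
(simulated loci carry one SNP; real fragments average ~2–3, which the
locus-bootstrap machinery handles but simulations do not generate),
sequencing error, depth-dependent genotype error, recombination within
fragments, continuous migration (only pulses), and selection. Passing tests
on synthetic data therefore validate estimator correctness and calibration
under the stated model, not robustness to these unmodelled features.

**Fixture choices.** The shipped scenario library covers the four Step-1
rootings described in the motivating analysis and the best-supported Step-2
scenario (five divergences, three admixture pulses, a Nearctic refugial
ghost branch). Its prior ranges bracket the published posterior credible
intervals where printed (the original supplementary prior tables are not
redistributable here) and are flagged non-canonical in the files. Point
values that were never printed — the two Palearctic backbone split times,
the piersmai admixture time, the refugium↔roselaari admixture fraction r3,
and the per-branch sizes not individually published — were chosen once
inside the printed ranges (e.g. r3 = 0.5, backbone splits at 1,333 and
2,000 generations, ancestral sizes 20,000) and recorded in the fixture with
in-file comments; they are study conditions, not tuning knobs.

## Summary statistics and ABC-RF

The summary vector is fixed by (populations, trios): per population the
proportion of monomorphic loci and the mean/variance of unbiased gene
diversity 2p̂q̂·n/(n−1); per pair the mean/variance of per-locus
Weir–Cockerham F_ST (over loci polymorphic in the pooled pair), the mean Nei
minimum distance, and the pooled-monomorphic proportion; per declared trio
the mean/variance of the per-locus least-squares admixture coefficient
â = (p_T − p₂)/(p₁ − p₂) clipped to [0, 1] (loci with p₁ ≈ p₂ excluded; a
trio with no informative locus falls back to 0.5/0 so the vector is
NaN-free). The least-squares coefficient is a documented stand-in for the
unpublished trio statistic of the original toolchain; it is exact for the
one-site-per-locus case. With 8 populations and 2 trios this yields
3·8 + 4·28 + 2·2 = 140 statistics, plus k−1 LDA axes for model choice; a
schema report (`summary_schema()`) makes the exact catalogue explicit rather
than chasing an external statistic-for-statistic match.

LDA axes are fit on the reference table only (standardised inputs, pooled
within-class covariance with a small ridge for stability) and the observed
vector is projected identically — fitting on the observed vector would leak.

Model choice trains a classification forest; the per-tree predictions at the
observed point are the votes; the out-of-bag misclassification fraction is
the prior error rate; and the posterior probability of the selected scenario
is 1 minus the prediction of a regression forest trained on the out-of-bag
misclassification indicator — the local-error regression of the cited
ABC-RF methodology (its response encoding follows that methodology, which
the motivating paper cites rather than restates). Ties in the vote argmax
select the lowest scenario index and set a flag.

Parameter estimation trains one regression forest per parameter
(mtry = p/3). Posterior weights of training draws are leaf co-occurrence
weights: in each tree, the in-bag copies of draws landing in the observed
point's terminal node share that tree's unit weight; weights are averaged
over trees and normalised. Posterior means, medians and quantiles are those
of the weighted empirical distribution. A parameter fixed by a degenerate
prior returns a zero-width posterior at the constant.

## Problem sizes

Desk-scale runs use 2,000 prior draws of 8 × 10 diploids × 500–1,000 loci
with 500–1,000 trees — the package's chosen demonstration scale, roughly
1/10 to 1/50 of a publication-scale training set (20,000 per scenario for
model choice, 100,000 for estimation, 1,000–1,500 trees). At this scale the
posterior for a weakly identified parameter shrinks only part-way from the
prior toward the generating value; recovery tests therefore assert interval
coverage and bounded bias, not point equality. All sizes are config-driven
(`n_per_scenario`, `n_trees`), so publication-scale runs are the same code
with larger numbers.

## Known limitations

* The LD-pruning window convention and the Tajima's-D allele-number rule
  under missingness are documented approximations of under-specified
  upstream conventions.
* PI-HAT on strongly structured samples inherits the pooled-frequency
  biases of the method-of-moments estimator; interpret within-deme flags in
  small-Ne populations accordingly.
* `run_pipeline()` resumes by skipping stages whose outputs exist
  (`resume = TRUE`) — a deliberately lightweight reading of incremental
  recomputation; it does not hash inputs, so stale upstream outputs are the
  user's responsibility.
* The scenario engine supports pulse admixture only; continuous gene flow
  would need a different event type and is out of scope.
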