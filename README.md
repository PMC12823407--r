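# specdrift

Trait specificity, coding length, and genetic drift in GWAS and
burden-test gene prioritization.

## The problem

GWAS and rare-variant loss-of-function (LoF) burden tests are both used
to rank targets for a trait, and the two rankings disagree far more than
practitioners expect. specdrift implements the population-genetic and
statistical-genetic machinery that explains the disagreement under
stabilizing selection:

* a burden test's expected signal is
  `E[z² − 1] ∝ γ₁² · p_LoF(1 − p_LoF)` with
  `p_LoF(1 − p_LoF) ∝ μL / s_het` and `s_het ≈ Σₜ γₜ²`, so burden tests
  rank genes by **trait specificity** `Ψ_G = γ₁² / Σₜ γₜ²` times
  **coding length** (`μL`), not by trait importance `γ₁²`;
* a GWAS ranks variants by realized heritability `2α²p(1−p)`, and at
  equilibrium `p ≈ μ/α²` for large effects, so ranking among
  well-powered hits is dominated by the drift-driven luck of `p`, not by
  `α²`.

The package is built for simulation studies of these effects: it is not
a GWAS/burden pipeline for raw genotype data (summary-statistic tables
in its TSV schema can be supplied where relevant).

## What is in the package

* **Equilibrium allele-frequency spectra** under heterozygote selection:
  a conditioned discrete-time Wright–Fisher solver
  (`compute_equilibrium_afs()`), a diffusion oracle
  (`diffusion_stationary_afs()`), trajectory simulation
  (`simulate_trajectories()`), and adaptive-resolution spectrum grids
  (`build_selection_grid()`, `nearest_spectrum()`).
* **Synthetic effects**: correlated log-normal squared effect matrices
  across 18 traits (`draw_squared_effects()`), gene panels with
  independent importance and mutational target size
  (`make_gene_panel()`), and planted expression/ATAC matrices
  (`synth_specificity_matrices()`).
* **Association simulators**: GWAS estimates with Gaussian noise and
  χ²₁ P values (`simulate_gwas_estimates()`, `pvalues_and_hits()`), LoF
  burden tests with carrier aggregation and the 1% rare-variant mask
  (`simulate_burden_tests()`), GWAS subsampling (`subsample_summary()`),
  and the realized-heritability experiment
  (`realized_heritability_experiment()`).
* **Estimators**: unbiased trait importance `γ̂² − s²`
  (`unbiased_importance()`), equal-occupancy binning (`bin_by_key()`),
  z²-based heritability enrichment with IVW across traits
  (`enrichment_from_z2()`), and the heritability-flattening analysis
  (`flattening_analysis()`).
* **Locus algebra**: 1 Mb transitive-closure grouping of clumped hits
  (`group_hits_into_loci()`), gene assignment, ranking, power-matched
  top-locus selection, burden/GWAS overlap statistics, and LD-block
  comparison.
* **Pleiotropy profiling**: P-value quartile profiles of hit MAF,
  cross-trait hit counts and true specificity
  (`quartile_pleiotropy_profile()`, `run_pleiotropy_simulation()`).
* **Specificity proxies**: expression specificity (TPM share above a
  10 TPM floor) and ATAC peak tissue sharing/intensity bins.

## A worked example

Burden power is driven by coding length, not importance — two gene sets
identical except for a doubled number of LoF sites:

```r
library(specdrift)

grid <- build_selection_grid()   # 50 equilibrium spectra, ~2 min

genes <- function(n_sites) list(
  genes = data.frame(gene_id = sprintf("g%03d", 1:400),
                     s_het_gene = 1e-2, n_sites = n_sites),
  gamma_sq = matrix(4e-4, 400, 1))

b1 <- simulate_burden_tests(genes(15000), grid, seed = 31)
b2 <- simulate_burden_tests(genes(30000), grid, seed = 32)
mean(b2$se) / mean(b1$se)
#> [1] 0.7111658
mean(b2$z2) / mean(b1$z2)
#> [1] 1.769816
mean(b2$gamma_hat) / mean(b1$gamma_hat)
#> [1] 0.9922588
```

Doubling the mutational target leaves the estimated effect unchanged
(ratio ≈ 1) but shrinks the standard error by ≈ 1/√2 (0.711 vs 0.707
expected) and raises the mean z² accordingly: longer genes are
prioritized at identical biology.

The pleiotropy artifact — the most significant GWAS hits are
simultaneously the most pleiotropic by hit counting and the most
trait-specific in truth:

```r
res <- run_pleiotropy_simulation(grid, n_positions = 4e6,
                                 min_hits = 1, seed = 11)
subset(res$profile, trait == 1)
#>   trait quartile  n   rel_maf mean_traits_hit  mean_psi
#> 1     1        1 10 1.0494123             2.5 0.1721231
#> 2     1        2 10 0.9350764             1.8 0.1139567
#> 3     1        3 10 0.9859279             1.2 0.1563245
#> 4     1        4 10 1.0295834             1.6 0.0987563
```

A single trait contributes only ~10 hits per quartile at this scale, so
per-trait profiles are noisy; pooling hits across the 18 traits (as the
acceptance script does) gives quartile-1 over quartile-4 ratios of 1.12
for relative MAF, 1.48 for cross-trait hit counts and 1.42 for true
Ψ_V (seed 1): the top hits are common, multiply significant, and
genuinely more trait-specific — all three a consequence of statistical
power at common variants, not of biology.

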