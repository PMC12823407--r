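# Simulation of GWAS and LoF burden-test summary statistics.
#
# Phenotypes are variance-1 and covariate-free throughout, so the sampling
# variance of a per-allele effect estimate at minor allele frequency q in
# an effective sample of n_eff is 1 / (2 * n_eff * q * (1 - q)). P values
# are carried in log10 space so that magnitudes like 1e-185 survive.

chisq1_log10p <- function(z2) {
  pchisq(z2, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Sample a GWAS-sample allele frequency from a population frequency
#'
#' Binomial resampling of `n_alleles` haploid genomes: models the slight
#' difference between the population frequency and the frequency realized
#' in a finite GWAS sample.
#'
#' @param pop_freq vector of population frequencies in `[0, 1]`.
#' @param n_alleles number of sampled allele copies (default 600,000,
#'   roughly 300,000 diploids).
#' @param seed optional integer seed.
#' @return vector of sample frequencies.
#' @export
sample_gwas_frequency <- function(pop_freq, n_alleles = 600000, seed = NULL) {
  if (any(pop_freq < 0 | pop_freq > 1)) stop("pop_freq must be in [0, 1]")
  if (n_alleles < 1) stop("n_alleles must be >= 1")
  with_seed_opt(seed, rbinom(length(pop_freq), n_alleles, pop_freq) / n_alleles)
}

#' Simulate GWAS effect-size estimates with Gaussian estimation noise
#'
#' For variant j and trait k, the estimate is drawn as
#' `Normal(alpha_jk, 1 / (2 * n_eff * MAF_j * (1 - MAF_j)))`, independently
#' across traits, where `alpha_jk` is the signed square root of the
#' supplied squared effect with a fair random sign per variant-trait.
#'
#' @param sq_effects matrix of squared effects (variants x traits), e.g.
#'   from [draw_squared_effects()].
#' @param maf vector of minor allele frequencies in `(0, 1)`, one per
#'   variant.
#' @param n_eff effective sample size / noise scaling (default 1e7).
#' @param seed optional integer seed.
#' @return an object of class `"gwas_summary"`: list with matrices
#'   `alpha_hat` and `alpha_sq` (the true squared effects), vector `se`
#'   (one per variant), `maf` and `n_eff`. P values and hit flags are
#'   added by [pvalues_and_hits()].
#' @export
simulate_gwas_estimates <- function(sq_effects, maf, n_eff = 1e7,
                                    seed = NULL) {
  sq_effects <- as.matrix(sq_effects)
  if (length(maf) != nrow(sq_effects)) stop("maf must have one entry per variant")
  if (any(maf <= 0)) stop("zero or negative MAF gives infinite estimation variance")
  if (any(maf >= 1)) stop("maf must be in (0, 1)")
  if (n_eff <= 0) stop("n_eff must be > 0")
  n <- nrow(sq_effects); k <- ncol(sq_effects)
  se <- 1 / sqrt(2 * n_eff * maf * (1 - maf))
  with_seed_opt(seed, {
    sgn <- matrix(sample(c(-1, 1), n * k, replace = TRUE), n, k)
    alpha_hat <- sgn * sqrt(sq_effects) + matrix(rnorm(n * k), n, k) * se
    structure(list(alpha_hat = alpha_hat, alpha_sq = sq_effects, se = se,
                   maf = maf, n_eff = n_eff),
              class = "gwas_summary")
  })
}

#' Chi-squared P values and hit flags for a GWAS summary
#'
#' Squared z-scores `(alpha_hat / se)^2` are referred to the chi-squared
#' distribution with 1 degree of freedom; a variant-trait pair is flagged
#' as a hit when its P value is below `threshold`.
#'
#' @param gs a `"gwas_summary"` from [simulate_gwas_estimates()].
#' @param threshold P-value hit threshold (default 1e-5 for simulated
#'   studies; 5e-8 is conventional for real GWAS).
#' @return `gs` with matrices `z2`, `log10p` and logical `hit` added, plus
#'   the threshold used.
#' @export
pvalues_and_hits <- function(gs, threshold = 1e-5) {
  stopifnot(inherits(gs, "gwas_summary"))
  z2 <- (gs$alpha_hat / gs$se)^2
  gs$z2 <- z2
  gs$log10p <- chisq1_log10p(z2)
  gs$hit <- gs$log10p < log10(threshold)
  gs$threshold <- threshold
  gs
}

#' @export
print.gwas_summary <- function(x, ...) {
  cat(sprintf("gwas_summary: %d variants x %d traits, n_eff=%g\n",
              nrow(x$alpha_hat), ncol(x$alpha_hat), x$n_eff))
  if (!is.null(x$hit)) {
    cat(sprintf("  hits at P<%g: %d variant-trait pairs\n",
                x$threshold, sum(x$hit)))
  }
  invisible(x)
}

#' @export
as.data.frame.gwas_summary <- function(x, ...) {
  n <- nrow(x$alpha_hat); k <- ncol(x$alpha_hat)
  out <- data.frame(
    variant_id = rep(sprintf("var%07d", seq_len(n)), k),
    trait = rep(seq_len(k), each = n),
    beta = as.vector(x$alpha_hat),
    se = rep(x$se, k),
    maf = rep(x$maf, k))
  if (!is.null(x$log10p)) out$log10p <- as.vector(x$log10p)
  if (!is.null(x$hit)) out$hit <- as.vector(x$hit)
  out
}

#' Simulate LoF burden-test summary statistics for a gene panel
#'
#' For each gene, per-site LoF frequencies are drawn from the equilibrium
#' spectrum at the grid value nearest the gene's total selection
#' coefficient; sites above the frequency cap are discarded (rare-variant
#' mask), and the aggregate carrier allele frequency is
#' `p_LoF = 1 - prod(1 - p_i)`. The burden effect estimate for each trait
#' is `Normal(gamma_t, SE^2)` with
#' `SE = 1 / sqrt(2 * n_samples * p_LoF * (1 - p_LoF))`.
#' Genes whose sites are all capped away or never segregate are flagged
#' untestable and excluded from the summary (not an error).
#'
#' @param panel a `"gene_panel"` from [make_gene_panel()], or a list with
#'   elements `genes` (data.frame with `gene_id`, `s_het_gene`, `n_sites`)
#'   and `gamma_sq` (genes x traits matrix).
#' @param grid a `"selection_grid"` of equilibrium spectra.
#' @param n_samples burden-test sample size (diploids; default 300,000).
#' @param freq_cap per-site allele-frequency upper bound for inclusion
#'   (default 0.01).
#' @param seed optional integer seed.
#' @return an object of class `"burden_summary"`: list with `gene_id`,
#'   `p_lof`, `se` (per tested gene), matrices `gamma_hat`, `z2`, `log10p`
#'   (genes x traits), `gamma_true` (the signed true effects), and
#'   `untestable` (gene ids with no usable burden genotype).
#' @export
simulate_burden_tests <- function(panel, grid, n_samples = 300000,
                                  freq_cap = 0.01, seed = NULL) {
  genes <- panel$genes
  gamma_sq <- panel$gamma_sq
  stopifnot(inherits(grid, "selection_grid"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  n_genes <- nrow(genes)
  with_seed_opt(seed, {
    site_gene <- rep(seq_len(n_genes), genes$n_sites)
    freqs <- sample_equilibrium_frequencies(grid, genes$s_het_gene[site_gene])
    freqs[freqs > freq_cap] <- 0 # capped sites contribute nothing
    log_surv <- log1p(-freqs)
    p_lof <- 1 - exp(as.vector(rowsum(log_surv, site_gene)))
    testable <- p_lof > 0
    gamma_true <- sqrt(gamma_sq)
    se <- 1 / sqrt(2 * n_samples * p_lof[testable] * (1 - p_lof[testable]))
    k <- ncol(gamma_sq); m <- sum(testable)
    gamma_hat <- gamma_true[testable, , drop = FALSE] +
      matrix(rnorm(m * k), m, k) * se
    z2 <- (gamma_hat / se)^2
    structure(list(gene_id = genes$gene_id[testable],
                   p_lof = p_lof[testable], se = se,
                   gamma_hat = gamma_hat, z2 = z2,
                   log10p = chisq1_log10p(z2),
                   gamma_true = gamma_true[testable, , drop = FALSE],
                   untestable = genes$gene_id[!testable],
                   n_samples = n_samples, freq_cap = freq_cap),
              class = "burden_summary")
  })
}

#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf("burden_summary: %d testable genes x %d traits (%d untestable)\n",
              length(x$gene_id), ncol(x$gamma_hat), length(x$untestable)))
  invisible(x)
}

#' @export
as.data.frame.burden_summary <- function(x, ...) {
  n <- length(x$gene_id); k <- ncol(x$gamma_hat)
  data.frame(
    gene_id = rep(x$gene_id, k),
    trait = rep(seq_len(k), each = n),
    beta = as.vector(x$gamma_hat),
    se = rep(x$se, k),
    log10p = as.vector(x$log10p),
    p_lof = rep(x$p_lof, k))
}

#' Resample summary statistics for a smaller GWAS
#'
#' Draws subsample effect estimates conditional on full-sample estimates:
#' `alpha_sub ~ Normal(alpha_full, ((n_full - n_sub) / n_sub) * se_full^2)`,
#' independently across variants, and inflates the standard errors for the
#' 1/n scaling of sampling variance.
#'
#' @param alpha_full,se_full full-sample estimates and standard errors.
#' @param n_sub,n_full subsample and full sample sizes, `0 < n_sub <= n_full`.
#' @param seed optional integer seed.
#' @param se_mode `"sqrt"` (default) multiplies standard errors by
#'   `sqrt(n_full / n_sub)` (variance scales as 1/n); `"linear"` multiplies
#'   them by `n_full / n_sub`, the literal reading of an SE inflation
#'   "by a factor of N/n".
#' @return list with `alpha_sub` and `se_sub`.
#' @export
subsample_summary <- function(alpha_full, se_full, n_sub, n_full,
                              seed = NULL, se_mode = c("sqrt", "linear")) {
  se_mode <- match.arg(se_mode)
  if (n_sub <= 0 || n_sub > n_full) stop("need 0 < n_sub <= n_full")
  if (any(se_full <= 0)) stop("se_full must be positive")
  ratio <- (n_full - n_sub) / n_sub
  with_seed_opt(seed, {
    alpha_sub <- alpha_full + rnorm(length(alpha_full)) * sqrt(ratio) * se_full
    infl <- if (se_mode == "sqrt") sqrt(n_full / n_sub) else n_full / n_sub
    list(alpha_sub = alpha_sub, se_sub = se_full * infl)
  })
}

#' Realized-heritability simulation for unlinked variants
#'
#' Simulates variants spanning a log-spaced grid of selection coefficients,
#' with all variants equally trait-specific so that the squared effect on
#' the focal trait is proportional to s_het. Population frequencies are
#' drawn from the equilibrium spectra, resampled into a finite GWAS sample,
#' and each variant's realized heritability is
#' `2 * s_het * f_sample * (1 - f_sample)`. Both the squared effect and the
#' realized heritability are reported scaled by their maxima, which absorbs
#' the unspecified proportionality constant.
#'
#' @param grid a `"selection_grid"` covering the s_het range.
#' @param n_shet number of s_het grid values (default 1000).
#' @param shet_lo,shet_hi s_het range (defaults 1e-7 and 2.3e-4).
#' @param variants_per_shet variants simulated per s_het value (default 50).
#' @param n_alleles GWAS sample size in allele copies (default 600,000).
#' @param seed optional integer seed.
#' @return a data.frame with columns `s_het`, `pop_freq`, `sample_freq`,
#'   `scaled_sq_effect` and `scaled_h2`.
#' @export
realized_heritability_experiment <- function(grid, n_shet = 1000,
                                             shet_lo = 1e-7, shet_hi = 2.3e-4,
                                             variants_per_shet = 50,
                                             n_alleles = 600000, seed = NULL) {
  s_values <- exp(seq(log(shet_lo), log(shet_hi), length.out = n_shet))
  s_het <- rep(s_values, each = variants_per_shet)
  with_seed_opt(seed, {
    pop_freq <- sample_equilibrium_frequencies(grid, s_het)
    sample_freq <- rbinom(length(pop_freq), n_alleles, pop_freq) / n_alleles
    h2 <- 2 * s_het * sample_freq * (1 - sample_freq)
    data.frame(s_het = s_het, pop_freq = pop_freq, sample_freq = sample_freq,
               scaled_sq_effect = s_het / max(s_het),
               scaled_h2 = if (max(h2) > 0) h2 / max(h2) else h2)
  })
}

#' Drift decoupling statistic of a realized-heritability table
#'
#' Spearman correlation between scaled squared effect and scaled realized
#' heritability among large-effect variants. Following the convention that
#' only variants observed in the sample are ranked, variants lost from the
#' GWAS sample (`sample_freq == 0`) are excluded.
#'
#' @param tab output of [realized_heritability_experiment()].
#' @param effect_cutoff lower bound on `scaled_sq_effect` (default 0.25).
#' @return list with `rho` and `n` (subset size).
#' @export
realized_h2_decoupling <- function(tab, effect_cutoff = 0.25) {
  sub <- tab[tab$scaled_sq_effect > effect_cutoff & tab$sample_freq > 0, ]
  list(rho = suppressWarnings(
         cor(sub$scaled_sq_effect, sub$scaled_h2, method = "spearman")),
       n = nrow(sub))
}
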