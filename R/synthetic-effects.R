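# Synthetic pleiotropic effect sizes, gene panels, and tissue matrices.
#
# Squared per-trait effects are drawn from a correlated log-normal: the
# latent Gaussian has unit marginal variance and pairwise correlation
# 1 - p, so p = 1 gives independent traits and p = 0 a single shared
# factor. The prefactor 1e-7 / f and latent scale 3 * f jointly set the
# range of total effects; f also shifts the distribution of trait
# specificities. The latent scale must stay of order one: squared effects
# are in variance units of a variance-1 trait, and a latent scale much
# above one would routinely produce single variants exceeding the whole
# trait variance.

#' Draw squared per-trait effect sizes with tunable pleiotropy
#'
#' Each row (one variant or gene) is drawn as
#' `(1e-7 / f) * scale * exp((3 * f) * Z)` where `Z` is multivariate normal
#' with covariance `p * I + (1 - p) * 11'` and the exponential is
#' elementwise. Trait 1 is the focal study trait by convention.
#'
#' @param n_positions number of rows to draw.
#' @param n_traits number of traits (default 18).
#' @param f shape parameter (> 0) controlling the spread of total effects
#'   (default 0.33).
#' @param p latent-correlation parameter in `[0, 1]`; pairwise correlation
#'   of log squared effects is `1 - p` (default 0.5).
#' @param scale multiplier on the `1e-7` prefactor (default 1).
#' @param seed optional integer seed.
#' @return a numeric matrix (`n_positions` x `n_traits`) of squared
#'   effects, with attributes `f`, `p` and `scale`.
#' @export
draw_squared_effects <- function(n_positions, n_traits = 18, f = 0.33,
                                 p = 0.5, scale = 1, seed = NULL) {
  stopifnot_scalar(n_positions, "n_positions"); stopifnot_scalar(n_traits, "n_traits")
  stopifnot_scalar(f, "f"); stopifnot_scalar(p, "p")
  if (n_traits < 1) stop("n_traits must be >= 1")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (f <= 0) stop("f must be > 0")
  with_seed_opt(seed, {
    z <- matrix(rnorm(n_positions * n_traits), n_positions, n_traits)
    z <- sqrt(p) * z + sqrt(1 - p) * rnorm(n_positions) # shared factor per row
    sq <- (1e-7 / f) * scale * exp((3 * f) * z)
    attr(sq, "f") <- f; attr(sq, "p") <- p; attr(sq, "scale") <- scale
    sq
  })
}

#' Selection coefficient implied by a squared-effect vector
#'
#' Under the stabilizing-selection model the strength of selection against
#' a variant equals its total trait effect, the L1 norm of the squared
#' per-trait effects.
#'
#' @param sq_effects a nonnegative vector, or a matrix with one row per
#'   variant.
#' @return the row sums (a scalar for a vector input).
#' @export
selection_coefficient <- function(sq_effects) {
  if (any(sq_effects < 0)) stop("squared effects must be nonnegative")
  if (is.matrix(sq_effects)) rowSums(sq_effects) else sum(sq_effects)
}

#' Trait specificity of a variant or gene
#'
#' The importance for the focal trait relative to total importance across
#' all fitness-relevant traits: `sq_effects[focal] / sum(sq_effects)`.
#' Applies identically to variants (Psi_V) and genes (Psi_G).
#'
#' @param sq_effects nonnegative vector of squared per-trait effects, or a
#'   matrix with one row per entity.
#' @param focal_index index of the focal trait (default 1).
#' @return specificity in `[0, 1]` (a vector for matrix input).
#' @export
trait_specificity <- function(sq_effects, focal_index = 1L) {
  if (is.matrix(sq_effects)) {
    tot <- selection_coefficient(sq_effects)
    if (any(tot == 0)) stop("specificity undefined for an all-zero effect vector")
    return(sq_effects[, focal_index] / tot)
  }
  tot <- selection_coefficient(sq_effects)
  if (tot == 0) stop("specificity undefined for an all-zero effect vector")
  sq_effects[focal_index] / tot
}

#' Generate a synthetic gene panel with cis variants
#'
#' Synthesizes a gene-level world in which total trait effect
#' (`s_het_gene = sum of gamma_t^2`) and mutational target size (the
#' expected number of unique LoFs, `mu * L`) are independent by
#' construction, so that any length-importance correlation downstream is a
#' property of the test statistic, not of the panel. Per-gene squared
#' effect vectors use the same correlated log-normal machinery as
#' [draw_squared_effects()], rescaled to the target total; focal-trait
#' share can be overridden through `specificity_mix`. Each gene carries cis
#' variants whose squared effect on trait t is `beta^2 * gamma_t^2`.
#'
#' @param n_genes number of genes.
#' @param n_traits number of traits (default 18; trait 1 is focal).
#' @param shet_range range over which `sum(gamma^2)` is drawn log-uniformly.
#' @param lof_length_range range over which the expected number of unique
#'   LoFs (`mu * L`) is drawn log-uniformly, independent of effects.
#' @param specificity_mix `NULL` for the natural focal share implied by the
#'   log-normal draw, or a list `list(type = "fixed", value = psi)` /
#'   `list(type = "beta", shape1 =, shape2 =)` giving the distribution of
#'   the focal-trait share Psi_G.
#' @param genome_layout list with `n_chrom`, `gap` (bp between genes) and
#'   `bp_per_site` (gene span per potential LoF site).
#' @param n_cis_variants cis variants per gene.
#' @param beta_meanlog,beta_sdlog log-normal parameters of the squared cis
#'   effect `beta^2` (a free modelling knob; see the methods vignette).
#' @param f,p shape parameters passed to the effect draw.
#' @param mu per-site mutation rate used to convert `mu * L` into a site
#'   count `L`.
#' @param seed optional integer seed.
#' @return an object of class `"gene_panel"`: list with `genes` (data.frame:
#'   gene_id, chrom, start, end, s_het_gene, expected_lofs, n_sites, psi_g),
#'   `gamma_sq` (genes x traits matrix), `variants` (data.frame: variant_id,
#'   gene_id, beta_sq) and `alpha_sq` (variants x traits matrix).
#' @export
make_gene_panel <- function(n_genes, n_traits = 18,
                            shet_range = c(1e-4, 0.05),
                            lof_length_range = c(2e-7, 2e-5),
                            specificity_mix = NULL,
                            genome_layout = list(n_chrom = 22, gap = 5e4,
                                                 bp_per_site = 10),
                            n_cis_variants = 5,
                            beta_meanlog = 0, beta_sdlog = 1,
                            f = 0.33, p = 0.5, mu = 1.25e-8, seed = NULL) {
  stopifnot_scalar(n_genes, "n_genes")
  if (any(shet_range <= 0) || diff(shet_range) < 0) stop("invalid shet_range")
  if (any(lof_length_range <= 0) || diff(lof_length_range) < 0) {
    stop("invalid lof_length_range")
  }
  with_seed_opt(seed, {
    s_tot <- exp(runif(n_genes, log(shet_range[1]), log(shet_range[2])))
    w <- draw_squared_effects(n_genes, n_traits, f = f, p = p)
    gamma_sq <- w / rowSums(w) * s_tot
    if (!is.null(specificity_mix)) {
      psi <- switch(specificity_mix$type,
        fixed = rep(specificity_mix$value, n_genes),
        beta = rbeta(n_genes, specificity_mix$shape1, specificity_mix$shape2),
        stop("unknown specificity_mix type: ", specificity_mix$type))
      if (n_traits == 1L) {
        gamma_sq <- matrix(s_tot, ncol = 1L)
      } else {
        rest <- gamma_sq[, -1L, drop = FALSE]
        rest <- rest / pmax(rowSums(rest), .Machine$double.xmin)
        gamma_sq <- cbind(psi * s_tot, rest * (1 - psi) * s_tot)
      }
    }
    expected_lofs <- exp(runif(n_genes, log(lof_length_range[1]),
                               log(lof_length_range[2])))
    n_sites <- pmax(1L, as.integer(round(expected_lofs / mu)))
    # tandem layout, genes cycled across chromosomes
    chrom_idx <- rep_len(seq_len(genome_layout$n_chrom), n_genes)
    len <- pmax(1000, n_sites * genome_layout$bp_per_site)
    start <- integer(n_genes); cursor <- numeric(genome_layout$n_chrom)
    for (i in seq_len(n_genes)) {
      cc <- chrom_idx[i]
      start[i] <- cursor[cc]
      cursor[cc] <- cursor[cc] + len[i] + genome_layout$gap
    }
    genes <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      chrom = paste0("chr", chrom_idx),
      start = start, end = start + len,
      s_het_gene = rowSums(gamma_sq),
      expected_lofs = expected_lofs,
      n_sites = n_sites,
      psi_g = gamma_sq[, 1L] / rowSums(gamma_sq),
      stringsAsFactors = FALSE)
    n_var <- n_genes * n_cis_variants
    beta_sq <- rlnorm(n_var, beta_meanlog, beta_sdlog)
    gene_of <- rep(seq_len(n_genes), each = n_cis_variants)
    variants <- data.frame(
      variant_id = sprintf("var%06d", seq_len(n_var)),
      gene_id = genes$gene_id[gene_of],
      beta_sq = beta_sq, stringsAsFactors = FALSE)
    alpha_sq <- gamma_sq[gene_of, , drop = FALSE] * beta_sq
    structure(list(genes = genes, gamma_sq = gamma_sq, variants = variants,
                   alpha_sq = alpha_sq),
              class = "gene_panel")
  })
}

#' Synthetic expression and ATAC-presence matrices with planted structure
#'
#' Builds a TPM matrix (genes x tissues) whose focal-tissue specificity
#' scores fall in known quintile bands, and a peak-presence matrix
#' (peaks x tissues) with known tissue-sharing classes, for round-trip
#' testing of the specificity proxies. Tissue 1 is the focal tissue.
#'
#' @param n_genes number of genes.
#' @param n_tissues number of expression tissues (default 17).
#' @param planted_bins integer vector (length `n_genes`) of target
#'   specificity quintiles 1..5, or 0 for a gene left unexpressed in the
#'   focal tissue; `NULL` for uniform random quintiles.
#' @param n_peaks number of ATAC peaks (default `n_genes`).
#' @param n_atac_tissues number of ATAC tissues (default 19).
#' @param planted_sharing integer vector (length `n_peaks`) of target
#'   sharing classes 1..5 (present in 1-2, 3-8, 9-15, 16-18, all tissues);
#'   `NULL` for uniform random classes.
#' @param seed optional integer seed.
#' @return list with `tpm` (matrix, attr `focal_tissue`), `peaks` (matrix,
#'   attr `focal_tissue`), `planted_bins`, `planted_sharing`.
#' @export
synth_specificity_matrices <- function(n_genes, n_tissues = 17,
                                       planted_bins = NULL,
                                       n_peaks = n_genes,
                                       n_atac_tissues = 19,
                                       planted_sharing = NULL, seed = NULL) {
  if (n_tissues < 2) stop("n_tissues must be >= 2")
  if (!is.null(planted_bins) && length(planted_bins) != n_genes) {
    stop("planted_bins must have length n_genes")
  }
  if (!is.null(planted_sharing) && length(planted_sharing) != n_peaks) {
    stop("planted_sharing must have length n_peaks")
  }
  with_seed_opt(seed, {
    if (is.null(planted_bins)) planted_bins <- sample(1:5, n_genes, TRUE)
    if (is.null(planted_sharing)) planted_sharing <- sample(1:5, n_peaks, TRUE)
    tpm <- matrix(0, n_genes, n_tissues,
                  dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                  sprintf("tissue%02d", seq_len(n_tissues))))
    for (i in seq_len(n_genes)) {
      q <- planted_bins[i]
      if (q == 0L) {
        tpm[i, 1L] <- runif(1, 0, 10)
        tpm[i, -1L] <- rexp(n_tissues - 1L, rate = 1 / 20)
        next
      }
      # target specificity score, kept away from quintile edges so that
      # empirical breakpoint noise cannot flip the recovered bin
      u <- runif(1, (q - 1) / 5 + 0.025, q / 5 - 0.025)
      focal <- runif(1, 15, 200)
      rest_total <- focal * (1 - u) / u
      shares <- rexp(n_tissues - 1L)
      tpm[i, 1L] <- focal
      tpm[i, -1L] <- rest_total * shares / sum(shares)
    }
    attr(tpm, "focal_tissue") <- colnames(tpm)[1L]
    share_lo <- c(1, 3, 9, 16, n_atac_tissues)
    share_hi <- c(2, 8, 15, n_atac_tissues - 1L, n_atac_tissues)
    peaks <- matrix(0, n_peaks, n_atac_tissues,
                    dimnames = list(sprintf("peak%05d", seq_len(n_peaks)),
                                    sprintf("tissue%02d", seq_len(n_atac_tissues))))
    for (i in seq_len(n_peaks)) {
      cls <- planted_sharing[i]
      k <- if (share_lo[cls] == share_hi[cls]) share_lo[cls] else
        sample(share_lo[cls]:share_hi[cls], 1L)
      others <- if (k > 1L) sample(2:n_atac_tissues, k - 1L) else integer(0)
      peaks[i, ] <- runif(n_atac_tissues, 0, 0.04) # below presence threshold
      peaks[i, c(1L, others)] <- runif(k, 0.1, 0.9)
    }
    attr(peaks, "focal_tissue") <- colnames(peaks)[1L]
    list(tpm = tpm, peaks = peaks, planted_bins = planted_bins,
         planted_sharing = planted_sharing)
  })
}
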