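# Trait-importance estimators, binning, z^2 heritability enrichment, and
# the heritability-flattening analysis.

#' Unbiased estimator of squared trait importance
#'
#' If an effect estimate is normally distributed about its true value with
#' known standard error, `estimate^2 - se^2` is unbiased for the squared
#' true effect. The naive square is biased upward, and the bias is
#' anticorrelated with allele frequency, which induces spurious
#' correlations with gene properties such as s_het. Negative estimates are
#' permitted and deliberately not truncated, so bin means stay unbiased.
#'
#' @param gamma_hat effect estimate(s).
#' @param se standard error(s), > 0.
#' @return `gamma_hat^2 - se^2`, possibly negative.
#' @export
unbiased_importance <- function(gamma_hat, se) {
  if (any(se <= 0)) stop("se must be positive")
  gamma_hat^2 - se^2
}

#' Split records into equal-occupancy bins by a key
#'
#' Records are sorted by the key (ties broken by `id_col` for determinism)
#' and split into `n_bins` contiguous groups whose sizes differ by at most
#' one; when the count is not divisible, the extra records go to the
#' lowest-key bins.
#'
#' @param records a data.frame.
#' @param key name of the numeric column to bin by.
#' @param n_bins number of bins (at most `nrow(records)`).
#' @param id_col optional name of an id column used to break key ties.
#' @return `records` sorted by key with an integer `bin` column appended;
#'   the attribute `"bin_summary"` holds a data.frame of per-bin size and
#'   key mean.
#' @export
bin_by_key <- function(records, key, n_bins, id_col = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a nonempty data.frame")
  }
  if (n_bins < 1L || n_bins > nrow(records)) {
    stop("n_bins must be in [1, nrow(records)]")
  }
  ord <- if (is.null(id_col)) order(records[[key]]) else
    order(records[[key]], records[[id_col]])
  out <- records[ord, , drop = FALSE]
  n <- nrow(out)
  base <- n %/% n_bins; extra <- n %% n_bins
  sizes <- rep(base, n_bins) + (seq_len(n_bins) <= extra)
  out$bin <- rep(seq_len(n_bins), times = sizes)
  attr(out, "bin_summary") <- data.frame(
    bin = seq_len(n_bins), n = sizes,
    key_mean = as.vector(tapply(out[[key]], out$bin, mean)))
  out
}

#' Heritability enrichment per bin from burden z-squared statistics
#'
#' Heritability tagged by a gene's burden statistic is proportional to
#' `z^2 - 1`, so the enrichment of a bin for one trait is the bin mean of
#' `z^2 - 1` relative to the all-gene mean. Empirical standard errors come
#' from the within-bin standard deviation; traits are combined per bin by
#' inverse-variance weighting, and the combined estimates are renormalized
#' either to average to one or to sum to one.
#'
#' @param z2 matrix of squared z-scores (genes x traits).
#' @param bins integer vector assigning each gene to a bin.
#' @param normalization `"average_to_one"` (default) or `"sum_to_one"`.
#' @return a data.frame with columns `bin`, `enrichment`, `se`,
#'   `normalization`; attribute `"traits_used"` lists the traits retained.
#'   Traits whose overall mean `z^2 - 1` is not positive carry no
#'   heritability signal and are dropped with a warning.
#' @export
enrichment_from_z2 <- function(z2, bins,
                               normalization = c("average_to_one", "sum_to_one")) {
  normalization <- match.arg(normalization)
  z2 <- as.matrix(z2)
  if (length(bins) != nrow(z2)) stop("bins must have one entry per gene")
  bin_ids <- sort(unique(bins))
  keep <- logical(ncol(z2))
  rel <- se <- matrix(NA_real_, length(bin_ids), ncol(z2))
  for (t in seq_len(ncol(z2))) {
    d <- z2[, t] - 1
    overall <- mean(d)
    if (!is.finite(overall) || overall <= 0) next
    keep[t] <- TRUE
    for (b in seq_along(bin_ids)) {
      db <- d[bins == bin_ids[b]]
      if (length(db) == 0L) stop("every bin must be nonempty for every trait")
      rel[b, t] <- mean(db) / overall
      se[b, t] <- sd(db) / (sqrt(length(db)) * overall)
    }
  }
  if (!any(keep)) stop("no trait has positive mean z^2 - 1")
  if (any(!keep)) {
    warning(sprintf("dropping %d trait(s) with non-positive mean z^2 - 1",
                    sum(!keep)))
  }
  rel <- rel[, keep, drop = FALSE]; se <- se[, keep, drop = FALSE]
  est <- numeric(length(bin_ids)); est_se <- numeric(length(bin_ids))
  for (b in seq_along(bin_ids)) {
    if (any(se[b, ] == 0)) { # degenerate bins carry no sampling noise
      exact <- se[b, ] == 0
      est[b] <- mean(rel[b, exact]); est_se[b] <- 0
    } else {
      w <- 1 / se[b, ]^2
      est[b] <- sum(rel[b, ] * w) / sum(w)
      est_se[b] <- sqrt(1 / sum(w))
    }
  }
  norm_const <- if (normalization == "average_to_one") mean(est) else sum(est)
  out <- data.frame(bin = bin_ids, enrichment = est / norm_const,
                    se = est_se / abs(norm_const),
                    normalization = normalization)
  attr(out, "traits_used") <- which(keep)
  out
}

#' Expected heritability contributions: flattening at the variant level,
#' monotonicity at the gene level
#'
#' For each gene on a grid of LoF effects gamma, cis-variant effects are
#' `alpha = beta * gamma` with `beta^2` log-normal. A variant's expected
#' contribution to heritability is `2 * alpha^2 * E[p(1-p)]` with the
#' frequency expectation taken under the equilibrium spectrum at
#' `s_het = alpha^2` (single-trait specificity), interpolated log-log
#' across the supplied grid. Mutation-selection balance makes
#' `E[p(1-p)]` scale as `1 / alpha^2` for large effects, so per-variant
#' contributions plateau while per-gene totals keep growing with gamma^2:
#' a larger gamma pushes more of the gene's cis variants past the
#' contribution threshold.
#'
#' The same `beta^2` draws are reused for every gene on the grid so the
#' gene-level comparison is a pure effect of gamma.
#'
#' @param gamma_grid strictly increasing positive LoF effect sizes
#'   (`gamma`, not squared).
#' @param grid a `"selection_grid"` of equilibrium spectra.
#' @param beta_meanlog,beta_sdlog log-normal parameters for `beta^2`.
#' @param n_variants_per_gene cis variants per gene.
#' @param seed optional integer seed.
#' @return list with `per_variant` (data.frame: `gamma`, `beta_sq`,
#'   `alpha_sq`, `h2`) and `per_gene` (data.frame: `gamma`, `gamma_sq`,
#'   `total_h2`).
#' @export
flattening_analysis <- function(gamma_grid, grid, beta_meanlog = 0,
                                beta_sdlog = 1, n_variants_per_gene = 100,
                                seed = NULL) {
  if (any(gamma_grid < 0) || any(diff(gamma_grid) <= 0)) {
    stop("gamma_grid must be nondecreasing and nonnegative")
  }
  stopifnot(inherits(grid, "selection_grid"))
  gs <- grid_summary(grid)
  h_of_alpha_sq <- function(a2) {
    out <- numeric(length(a2))
    pos <- a2 > 0
    out[pos] <- 2 * a2[pos] * loglog_interp(gs$s_het, gs$e_pq, a2[pos])
    out
  }
  with_seed_opt(seed, {
    beta_sq <- rlnorm(n_variants_per_gene, beta_meanlog, beta_sdlog)
    if (any(beta_sq == 0)) stop("degenerate beta distribution at 0")
    per_variant <- do.call(rbind, lapply(gamma_grid, function(g) {
      a2 <- beta_sq * g^2
      data.frame(gamma = g, beta_sq = beta_sq, alpha_sq = a2,
                 h2 = h_of_alpha_sq(a2))
    }))
    per_gene <- data.frame(
      gamma = gamma_grid, gamma_sq = gamma_grid^2,
      total_h2 = vapply(gamma_grid,
                        function(g) sum(h_of_alpha_sq(beta_sq * g^2)),
                        numeric(1)))
    list(per_variant = per_variant, per_gene = per_gene)
  })
}

#' Octave slopes of a per-variant heritability curve
#'
#' Utility for assessing flattening: averages the curve within factor-of-2
#' bins of `x` and reports the slope between consecutive octave means.
#'
#' @param x positive predictor (e.g. `alpha_sq`).
#' @param y response (e.g. expected heritability contribution).
#' @return data.frame with `octave`, `x_mean`, `y_mean`, `slope` (slope of
#'   `y` vs `log2(x)` between consecutive octaves; NA for the first).
#' @export
octave_slopes <- function(x, y) {
  stopifnot(all(x > 0), length(x) == length(y))
  oct <- floor(log2(x))
  xm <- as.vector(tapply(log2(x), oct, mean))
  ym <- as.vector(tapply(y, oct, mean))
  data.frame(octave = sort(unique(oct)), x_mean = 2^xm, y_mean = ym,
             slope = c(NA, diff(ym) / diff(xm)))
}
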