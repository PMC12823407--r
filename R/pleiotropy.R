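# Hit-pleiotropy quartile profiles: the statistical artifact by which the
# strongest GWAS hits look simultaneously more pleiotropic (hit in more
# traits) and are in truth more trait-specific. Power at common variants
# drives both: a high-MAF variant needs a smaller effect to reach
# significance, and selection keeps multi-trait variants rarer.

#' Quartile pleiotropy profile of GWAS hits
#'
#' For each trait with at least `min_hits` hits, splits that trait's hits
#' into four P-value quartiles (quartile 1 most significant; sizes differ
#' by at most one, extras to the more significant quartiles) and reports
#' per quartile the mean MAF relative to the trait's overall hit mean, the
#' mean number of traits (including the focal one) in which the variant is
#' a hit, and, when true effects are available, the mean trait specificity
#' Psi_V.
#'
#' @param gs a `"gwas_summary"` that has been through [pvalues_and_hits()].
#' @param min_hits minimum hit count for a trait to be profiled
#'   (default 100).
#' @param psi optional vector of true focal-shares per variant; by default
#'   computed from `gs$alpha_sq` with the profiled trait as focal.
#' @return data.frame with columns `trait`, `quartile`, `n`, `rel_maf`,
#'   `mean_traits_hit`, `mean_psi` (NA when truth is unavailable). Traits
#'   below `min_hits` are skipped and listed in the attribute
#'   `"excluded_traits"`.
#' @export
quartile_pleiotropy_profile <- function(gs, min_hits = 100, psi = NULL) {
  stopifnot(inherits(gs, "gwas_summary"))
  if (is.null(gs$hit)) stop("run pvalues_and_hits() first")
  k <- ncol(gs$hit)
  cross_count <- rowSums(gs$hit)
  rows <- list(); excluded <- integer(0)
  for (t in seq_len(k)) {
    idx <- which(gs$hit[, t])
    if (length(idx) < min_hits) { excluded <- c(excluded, t); next }
    idx <- idx[order(gs$log10p[idx, t], idx)]
    n <- length(idx)
    base <- n %/% 4L; extra <- n %% 4L
    sizes <- rep(base, 4L) + (seq_len(4L) <= extra)
    q_of <- rep(1:4, times = sizes)
    overall_maf <- mean(gs$maf[idx])
    psi_t <- if (!is.null(psi)) psi else if (!is.null(gs$alpha_sq)) {
      gs$alpha_sq[, t] / rowSums(gs$alpha_sq)
    } else NULL
    for (q in 1:4) {
      iq <- idx[q_of == q]
      rows[[length(rows) + 1L]] <- data.frame(
        trait = t, quartile = q, n = length(iq),
        rel_maf = mean(gs$maf[iq]) / overall_maf,
        mean_traits_hit = mean(cross_count[iq]),
        mean_psi = if (is.null(psi_t)) NA_real_ else mean(psi_t[iq]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = integer(), quartile = integer(), n = integer(),
               rel_maf = numeric(), mean_traits_hit = numeric(),
               mean_psi = numeric())
  attr(out, "excluded_traits") <- excluded
  out
}

#' End-to-end pleiotropy simulation
#'
#' Runs the full generative chain: draw squared per-trait effects with
#' pleiotropy correlation, set the selection coefficient of each position
#' to its total effect, draw an equilibrium allele frequency from the
#' nearest spectrum, simulate noisy GWAS estimates for segregating
#' positions, call hits, and compute the quartile profile.
#'
#' @param grid a `"selection_grid"` of equilibrium spectra.
#' @param n_positions number of (not necessarily segregating) positions
#'   (default 1e6; the headline analyses use 1e7, which scales linearly).
#' @param n_traits number of traits (default 18).
#' @param f,p effect-distribution shape parameters (defaults 0.33 and 0.5).
#' @param n_eff effective GWAS sample size (default 1e7).
#' @param threshold hit-calling P threshold (default 1e-5).
#' @param min_hits minimum hits per trait for profiling.
#' @param seed optional integer seed.
#' @return list with `profile` (quartile profile data.frame), `summary`
#'   (the `"gwas_summary"` for segregating positions), `n_segregating`,
#'   and the parameters used. A warning is issued when no trait reaches
#'   the hit threshold often enough to be profiled.
#' @export
run_pleiotropy_simulation <- function(grid, n_positions = 1e6, n_traits = 18,
                                      f = 0.33, p = 0.5, n_eff = 1e7,
                                      threshold = 1e-5, min_hits = 100,
                                      seed = NULL) {
  stopifnot(inherits(grid, "selection_grid"))
  with_seed_opt(seed, {
    sq <- draw_squared_effects(n_positions, n_traits, f = f, p = p)
    s_het <- selection_coefficient(sq)
    freq <- sample_equilibrium_frequencies(grid, s_het)
    seg <- freq > 0
    # conditioned spectra keep the derived allele minor, so freq is the MAF
    gs <- simulate_gwas_estimates(sq[seg, , drop = FALSE], freq[seg],
                                  n_eff = n_eff)
    gs <- pvalues_and_hits(gs, threshold)
    profile <- quartile_pleiotropy_profile(gs, min_hits = min_hits)
    if (nrow(profile) == 0L) {
      warning("no trait reached the minimum hit count; profile is empty")
    }
    list(profile = profile, summary = gs, n_segregating = sum(seg),
         params = list(n_positions = n_positions, n_traits = n_traits,
                       f = f, p = p, n_eff = n_eff, threshold = threshold),
         seed = seed)
  })
}
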