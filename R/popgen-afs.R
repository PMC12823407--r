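# Equilibrium allele-frequency spectra under heterozygote selection.
#
# The population-genetic model: a derived allele with no fitness effect in
# homozygotes and fitness 1 - s_het in heterozygous carriers, recurrent
# one-way mutation at rate mu per site per generation, and binomial
# (Wright-Fisher) resampling of two_N haploid copies each generation. This
# fitness scheme approximates stabilizing selection on a polygenic trait:
# rare trait-altering alleles are effectively selected against in carriers
# with strength proportional to their total squared trait effect.

#' Construct a selection model
#'
#' Bundles the three parameters of the Wright-Fisher model used throughout:
#' the selection coefficient against heterozygous carriers, the per-site
#' per-generation mutation rate, and the haploid population size.
#'
#' @param s_het selection coefficient against heterozygotes, in `[0, 1]`.
#' @param mu per-site per-generation mutation rate, in `[0, 1)`.
#' @param two_N number of haploid copies (twice the diploid size); an even
#'   integer of at least 4.
#' @return an object of class `"selection_model"`.
#' @examples
#' selection_model(s_het = 1e-3, mu = 1.25e-8, two_N = 2000)
#' @export
selection_model <- function(s_het, mu, two_N) {
  stopifnot_scalar(s_het, "s_het"); stopifnot_scalar(mu, "mu")
  stopifnot_scalar(two_N, "two_N")
  if (s_het < 0 || s_het > 1) stop("s_het must be in [0, 1]")
  if (mu < 0 || mu >= 1) stop("mu must be in [0, 1)")
  if (two_N < 4 || two_N != round(two_N) || two_N %% 2 != 0) {
    stop("two_N must be an even integer >= 4")
  }
  structure(list(s_het = s_het, mu = mu, two_N = as.integer(two_N)),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("selection_model: s_het=%g, mu=%g, two_N=%d\n",
              x$s_het, x$mu, x$two_N))
  invisible(x)
}

# Expected post-selection frequency of the derived allele at frequency f
# under fitnesses (1, 1 - s_het, 1) for (anc hom, het, derived hom).
post_selection_freq <- function(f, s_het) {
  (f^2 + f * (1 - f) * (1 - s_het)) / (1 - 2 * s_het * f * (1 - f))
}

# Transition matrix of the conditioned discrete-time Wright-Fisher chain.
# States are derived-allele counts 0..M. Conditioning: the fixation state is
# excluded always ("ancestral allele known"); for s_het > 0 the derived
# allele is additionally conditioned to remain the minor allele (counts
# <= floor(two_N / 2)), because the heterozygote-disadvantage scheme is
# formally underdominant and the unconditioned truncated chain carries an
# artifactual near-fixation mode of stationary mass O(4 N mu). Rows are
# renormalized after truncation. A state_cap below two_N / 2 truncates the
# state space further; legitimate only when selection makes the discarded
# states unreachable in practice (checked after the solve).
wf_transition_matrix <- function(model, state_cap = NULL) {
  two_N <- model$two_N
  M <- if (model$s_het > 0) two_N %/% 2L else two_N - 1L
  if (!is.null(state_cap) && model$s_het > 0) M <- min(M, as.integer(state_cap))
  f <- (0:M) / two_N
  p_sel <- post_selection_freq(f, model$s_het)
  p_mut <- p_sel + (1 - p_sel) * model$mu
  P <- t(vapply(p_mut, function(p) dbinom(0:M, two_N, p), numeric(M + 1L)))
  P / rowSums(P)
}

new_frequency_distribution <- function(probs, model, method) {
  if (any(probs < 0)) probs[probs < 0] <- 0
  probs <- probs / sum(probs)
  structure(list(probs = probs, model = model, method = method),
            class = "frequency_distribution")
}

#' Equilibrium allele-frequency spectrum of the Wright-Fisher chain
#'
#' Computes the stationary distribution of derived-allele counts for the
#' discrete-time Wright-Fisher chain with recurrent one-way mutation and
#' selection against heterozygous carriers. The chain is conditioned on the
#' derived allele never fixing; for `s_het > 0` it is further conditioned on
#' the derived allele remaining the minor allele (counts at most
#' `two_N / 2`), which isolates the mutation-selection branch of the
#' formally underdominant fitness scheme (see the methods vignette). The
#' returned probability vector has length `two_N`, with mass on counts
#' `0 .. two_N - 1` (entries beyond the conditioning bound are zero).
#'
#' @param model a [selection_model()].
#' @param method `"solve"` (default) obtains the stationary vector of the
#'   conditioned chain by a direct linear solve; `"power"` uses power
#'   iteration from a point mass at count 0. Both backends satisfy the same
#'   contract and agree to numerical precision.
#' @param tol convergence/residual tolerance on the L1 scale.
#' @param max_iter iteration cap for the power backend.
#' @param state_cap optional truncation of the state space below
#'   `two_N / 2` for strong selection, where high counts carry negligible
#'   equilibrium mass; the solve fails if the cap visibly bites (mass at
#'   the last kept state above 1e-8).
#' @return an object of class `"frequency_distribution"` with elements
#'   `probs` (length `two_N`, sums to 1) and `model`.
#' @seealso [diffusion_stationary_afs()] for the independent diffusion
#'   oracle, [mean_frequency()], [het_expectation()].
#' @examples
#' m <- selection_model(s_het = 0.05, mu = 1e-5, two_N = 200)
#' fd <- compute_equilibrium_afs(m)
#' mean_frequency(fd)       # close to mu / s_het
#' @export
compute_equilibrium_afs <- function(model, method = c("solve", "power"),
                                    tol = 1e-12, max_iter = 1e6,
                                    state_cap = NULL) {
  stopifnot(inherits(model, "selection_model"))
  method <- match.arg(method)
  natural_states <- if (model$s_het > 0) model$two_N %/% 2L else model$two_N - 1L
  solved_states <- min(natural_states,
                       if (is.null(state_cap)) Inf else state_cap)
  if (solved_states > 20000) {
    stop("state space above the tractability guard of 20,000; ",
         "use a rescaled model preserving 4*N*mu and 2*N*s_het, ",
         "or a state_cap where selection permits")
  }
  P <- wf_transition_matrix(model, state_cap)
  n <- nrow(P)
  if (method == "solve") {
    A <- t(P) - diag(n)
    A[n, ] <- 1
    v <- solve(A, c(rep(0, n - 1L), 1))
    v[v < 0] <- 0
    v <- v / sum(v)
    resid <- sum(abs(as.vector(v %*% P) - v))
    if (!is.finite(resid) || resid > 1e-8) {
      stop(sprintf("stationary solve did not converge: L1 residual %.3e", resid))
    }
  } else {
    v <- c(1, rep(0, n - 1L))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      v2 <- as.vector(v %*% P)
      delta <- sum(abs(v2 - v))
      v <- v2
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop(sprintf("power iteration did not converge in %d iterations: L1 change %.3e",
                   as.integer(max_iter), delta))
    }
    v <- v / sum(v)
  }
  if (n - 1L < natural_states && v[n] > 1e-8) {
    stop(sprintf("state_cap %d truncates non-negligible mass (%.3e at the boundary)",
                 n - 1L, v[n]))
  }
  probs <- numeric(model$two_N)
  probs[seq_len(n)] <- v
  new_frequency_distribution(probs, model, method)
}

#' @export
print.frequency_distribution <- function(x, ...) {
  cat(sprintf("frequency_distribution (%s): two_N=%d, s_het=%g, mu=%g\n",
              x$method %||% "dtwf", x$model$two_N, x$model$s_het, x$model$mu))
  cat(sprintf("  mean frequency %.4g, P(segregating) %.4g\n",
              mean_frequency(x), 1 - x$probs[1]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean derived-allele frequency of a spectrum
#' @param fd a `"frequency_distribution"` or `"diffusion_afs"` object.
#' @return the expectation of the allele frequency.
#' @export
mean_frequency <- function(fd) {
  UseMethod("mean_frequency")
}

#' @export
mean_frequency.frequency_distribution <- function(fd) {
  f <- (seq_along(fd$probs) - 1) / fd$model$two_N
  sum(f * fd$probs)
}

#' Expected heterozygosity factor of a spectrum
#' @param fd a `"frequency_distribution"` or `"diffusion_afs"` object.
#' @return the expectation of `p * (1 - p)`.
#' @export
het_expectation <- function(fd) {
  UseMethod("het_expectation")
}

#' @export
het_expectation.frequency_distribution <- function(fd) {
  f <- (seq_along(fd$probs) - 1) / fd$model$two_N
  sum(f * (1 - f) * fd$probs)
}

#' Stationary allele-frequency density under the diffusion approximation
#'
#' Independent oracle for [compute_equilibrium_afs()]: discretizes the
#' stationary density proportional to
#' `exp(-2 * two_N * s_het * f * (1 - f)) * f^(2 two_N mu - 1) * (1 - f)^(2 two_N mu - 1)`
#' on a frequency grid. The Beta-measure singularities at the boundaries are
#' handled exactly by placing cell boundaries at Beta quantiles; the smooth
#' selection factor is evaluated at cell midpoints. Mirroring the chain's
#' conditioning, for `s_het > 0` the density is truncated to `f <= 1/2`
#' (the mutation-origin branch of the bimodal underdominant density); at
#' `s_het = 0` the full symmetric density is returned.
#'
#' @param model a [selection_model()]; requires `2 * two_N * mu > 0`.
#' @param n_points number of discretization cells before truncation.
#' @return an object of class `"diffusion_afs"` with fields `f`
#'   (cell-midpoint frequencies), `probs` (normalized masses) and `model`.
#' @export
diffusion_stationary_afs <- function(model, n_points = 2000) {
  stopifnot(inherits(model, "selection_model"))
  a <- 2 * model$two_N * model$mu
  if (a <= 0) stop("non-integrable parameters: need 2 * two_N * mu > 0")
  u <- seq(0, 1, length.out = n_points + 1L)
  mids <- qbeta((u[-1L] + u[-(n_points + 1L)]) / 2, a, a)
  w <- exp(-2 * model$two_N * model$s_het * mids * (1 - mids))
  if (model$s_het > 0) {
    keep <- mids <= 0.5
    mids <- mids[keep]; w <- w[keep]
  }
  if (!any(w > 0) || !all(is.finite(w))) {
    stop("diffusion density is degenerate for these parameters")
  }
  structure(list(f = mids, probs = w / sum(w), model = model),
            class = "diffusion_afs")
}

#' @export
mean_frequency.diffusion_afs <- function(fd) sum(fd$f * fd$probs)

#' @export
het_expectation.diffusion_afs <- function(fd) sum(fd$f * (1 - fd$f) * fd$probs)

#' Deterministic mutation-selection balance frequency
#'
#' The closed-form equilibrium frequency `mu / s_het` of a deleterious
#' allele under strong selection, valid when selection dominates both
#' mutation and drift. Guarded to the regime `s_het >= 100 * mu`.
#'
#' @param mu mutation rate.
#' @param s_het heterozygote selection coefficient (> 0).
#' @return the expected equilibrium frequency `mu / s_het`.
#' @export
closed_form_balance <- function(mu, s_het) {
  stopifnot_scalar(mu, "mu"); stopifnot_scalar(s_het, "s_het")
  if (s_het <= 0 || s_het < 100 * mu) {
    stop("weak-selection regime: closed form requires s_het >= 100 * mu and s_het > 0")
  }
  mu / s_het
}

#' Simulate Wright-Fisher frequency trajectories of a new mutation
#'
#' Forward simulation without recurrent mutation: each generation the
#' expected frequency is moved by selection against heterozygous carriers
#' and then resampled binomially. Frequencies 0 and 1 are absorbing.
#'
#' @param model a [selection_model()] (its `mu` is ignored: trajectories
#'   model a single existing mutation).
#' @param generations number of generations to simulate (>= 1).
#' @param n_reps number of replicate trajectories.
#' @param init_count initial derived-allele count, in `[1, two_N - 1]`.
#' @param seed optional integer seed.
#' @return an object of class `"trajectory_ensemble"`: a list with
#'   `frequencies` (`n_reps` x `generations + 1` matrix whose first column
#'   is the initial frequency) and `model`.
#' @export
simulate_trajectories <- function(model, generations, n_reps, init_count,
                                  seed = NULL) {
  stopifnot(inherits(model, "selection_model"))
  stopifnot_scalar(generations, "generations"); stopifnot_scalar(n_reps, "n_reps")
  stopifnot_scalar(init_count, "init_count")
  if (generations < 1) stop("generations must be >= 1")
  if (init_count < 1 || init_count > model$two_N - 1) {
    stop("init_count must be in [1, two_N - 1]")
  }
  two_N <- model$two_N
  with_seed_opt(seed, {
    freq <- matrix(0, nrow = n_reps, ncol = generations + 1L)
    freq[, 1L] <- init_count / two_N
    f <- freq[, 1L]
    for (t in seq_len(generations)) {
      p <- post_selection_freq(f, model$s_het)
      f <- rbinom(n_reps, two_N, p) / two_N
      freq[, t + 1L] <- f
    }
    structure(list(frequencies = freq, model = model),
              class = "trajectory_ensemble")
  })
}

#' Default s_het grid
#'
#' Fifty selection coefficients from 1e-7 to 0.05, evenly spaced on the
#' log scale.
#'
#' @param n number of grid values.
#' @param lo,hi grid endpoints.
#' @return a strictly increasing numeric vector.
#' @export
default_shet_grid <- function(n = 50, lo = 1e-7, hi = 0.05) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Build a grid of equilibrium spectra over s_het values
#'
#' Computes one equilibrium spectrum per selection coefficient. Population
#' size can be rescaled for tractability: spectra are computed at fewer
#' haploid copies with `mu` and `s_het` multiplied by the rescaling factor,
#' preserving the diffusion-scale parameters `4 N mu` and `2 N s_het` of
#' the nominal population. Grid values are labelled by the nominal
#' (unrescaled) s_het.
#'
#' With `two_N = "adaptive"` (the default) each grid point picks its own
#' resolution: strongly selected spectra are computed at the full nominal
#' population size, which costs little because selection confines the
#' equilibrium to low counts (the state space is truncated where the tail
#' mass is negligible, and the solve verifies this), while weakly selected
#' spectra, whose mass spreads over many frequencies, are rescaled down to
#' `base_two_N`. This matters downstream: the minimum representable
#' frequency is `1 / two_N`, and a coarse state space at strong selection
#' would inflate the association power of rare large-effect variants.
#'
#' @param s_values strictly increasing nominal s_het values.
#' @param two_N `"adaptive"` (default) or a fixed haploid size for all
#'   grid points.
#' @param mu nominal per-site mutation rate.
#' @param pop_two_N nominal haploid population size (default 40,000, i.e.
#'   20,000 diploids).
#' @param base_two_N smallest haploid size used by the adaptive rule.
#' @param resolution_factor adaptive rule: a grid point at nominal s_het
#'   uses `two_N = min(pop_two_N, max(base_two_N, resolution_factor * s_het))`.
#' @param ... passed to [compute_equilibrium_afs()].
#' @return an object of class `"selection_grid"` with fields `s_het`
#'   (nominal grid), `spectra` (list of `"frequency_distribution"`),
#'   `two_N` (integer vector, per grid point), `mu`, `pop_two_N`.
#' @export
build_selection_grid <- function(s_values = default_shet_grid(),
                                 two_N = "adaptive", mu = 1.25e-8,
                                 pop_two_N = 40000, base_two_N = 4000,
                                 resolution_factor = 2e6, ...) {
  if (length(s_values) < 1L || any(diff(s_values) <= 0) || any(s_values < 0)) {
    stop("s_values must be nonempty, nonnegative and strictly increasing")
  }
  adaptive <- identical(two_N, "adaptive")
  two_N_k <- if (adaptive) {
    pmin(pop_two_N, pmax(base_two_N,
                         2 * ceiling(resolution_factor * s_values / 2)))
  } else rep(as.integer(two_N), length(s_values))
  r <- pop_two_N / two_N_k
  if (any(s_values * r > 1 + 1e-9)) {
    stop("rescaled s_het exceeds 1; increase two_N or lower the grid maximum")
  }
  spectra <- lapply(seq_along(s_values), function(k) {
    s_eff <- min(s_values[k] * r[k], 1)
    cap <- if (adaptive && s_eff > 0) {
      max(1000L, ceiling(50 / s_eff))
    } else NULL
    compute_equilibrium_afs(selection_model(s_eff, mu * r[k], two_N_k[k]),
                            state_cap = cap, ...)
  })
  structure(list(s_het = s_values, spectra = spectra,
                 two_N = as.integer(two_N_k),
                 mu = mu, pop_two_N = pop_two_N),
            class = "selection_grid")
}

#' @export
print.selection_grid <- function(x, ...) {
  cat(sprintf("selection_grid: %d s_het values in [%g, %g], two_N %d-%d (nominal %d)\n",
              length(x$s_het), min(x$s_het), max(x$s_het), min(x$two_N),
              max(x$two_N), x$pop_two_N))
  invisible(x)
}

#' Index of the nearest grid spectrum on the log10 scale
#'
#' @param grid a `"selection_grid"`.
#' @param s_het vector of positive selection coefficients.
#' @return integer indices into `grid$s_het`; ties between two equally
#'   distant grid values resolve to the smaller one.
#' @export
nearest_grid_index <- function(grid, s_het) {
  stopifnot(inherits(grid, "selection_grid"))
  if (length(grid$s_het) == 0L) stop("empty grid")
  if (any(s_het <= 0)) stop("s_het must be positive")
  lg <- log10(grid$s_het)
  ls <- log10(s_het)
  # midpoints between adjacent grid values; a query exactly at a midpoint
  # belongs to the smaller grid value, so assignment uses strict >
  mid <- (lg[-1L] + lg[-length(lg)]) / 2
  idx <- rep(1L, length(ls))
  for (k in seq_along(mid)) idx <- idx + (ls > mid[k])
  idx
}

#' Spectrum with the closest s_het on the log10 scale
#'
#' @inheritParams nearest_grid_index
#' @param s_het a single positive selection coefficient.
#' @return the `"frequency_distribution"` at the nearest grid value.
#' @export
nearest_spectrum <- function(grid, s_het) {
  stopifnot_scalar(s_het, "s_het")
  grid$spectra[[nearest_grid_index(grid, s_het)]]
}

#' Draw one equilibrium allele frequency per query
#'
#' For each element of `s_het`, samples a derived-allele count from the
#' equilibrium spectrum at the nearest grid value and returns the count
#' divided by the grid's `two_N`. Under the minor-allele conditioning all
#' returned frequencies are at most 1/2.
#'
#' @param grid a `"selection_grid"`.
#' @param s_het vector of positive selection coefficients.
#' @param seed optional integer seed.
#' @return numeric vector of frequencies in `[0, 0.5]` (0 means the site is
#'   not segregating).
#' @export
sample_equilibrium_frequencies <- function(grid, s_het, seed = NULL) {
  idx <- nearest_grid_index(grid, s_het)
  with_seed_opt(seed, {
    out <- numeric(length(s_het))
    for (k in unique(idx)) {
      sel <- which(idx == k)
      probs <- grid$spectra[[k]]$probs
      two_N <- grid$spectra[[k]]$model$two_N
      # restrict to states that can carry mass to keep sampling cheap
      top <- max(which(probs > 0))
      out[sel] <- (sample.int(top, length(sel), replace = TRUE,
                              prob = probs[seq_len(top)]) - 1L) / two_N
    }
    out
  })
}

#' Summaries of a selection grid for interpolation
#'
#' @param grid a `"selection_grid"`.
#' @return a data.frame with columns `s_het` (nominal), `mean_freq` and
#'   `e_pq` (the expectation of `p(1-p)`).
#' @export
grid_summary <- function(grid) {
  stopifnot(inherits(grid, "selection_grid"))
  data.frame(
    s_het = grid$s_het,
    mean_freq = vapply(grid$spectra, mean_frequency, numeric(1)),
    e_pq = vapply(grid$spectra, het_expectation, numeric(1))
  )
}

#' Serialize a selection grid to a TSV pair
#'
#' Writes `<prefix>_grid.tsv` (nominal s_het values and grid metadata) and
#' `<prefix>_spectra.tsv` (one row per grid value, columns are allele
#' counts).
#'
#' @param grid a `"selection_grid"`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_selection_grid <- function(grid, prefix) {
  stopifnot(inherits(grid, "selection_grid"))
  grid_path <- paste0(prefix, "_grid.tsv")
  spec_path <- paste0(prefix, "_spectra.tsv")
  meta <- data.frame(s_het = grid$s_het, two_N = grid$two_N, mu = grid$mu,
                     pop_two_N = grid$pop_two_N)
  utils::write.table(meta, grid_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  width <- max(vapply(grid$spectra, function(s) length(s$probs), integer(1)))
  mat <- do.call(rbind, lapply(grid$spectra, function(s) {
    c(s$probs, numeric(width - length(s$probs)))
  }))
  utils::write.table(format(mat, digits = 17), spec_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(grid_path, spec_path))
}

#' Read a selection grid written by [write_selection_grid()]
#'
#' @param prefix path prefix used when writing.
#' @return a `"selection_grid"`.
#' @export
read_selection_grid <- function(prefix) {
  meta <- utils::read.table(paste0(prefix, "_grid.tsv"), header = TRUE,
                            sep = "\t")
  mat <- as.matrix(utils::read.table(paste0(prefix, "_spectra.tsv"),
                                     header = FALSE, sep = "\t"))
  mu <- meta$mu[1L]; pop_two_N <- meta$pop_two_N[1L]
  spectra <- lapply(seq_len(nrow(mat)), function(i) {
    two_N <- meta$two_N[i]
    r <- pop_two_N / two_N
    new_frequency_distribution(
      as.numeric(mat[i, seq_len(two_N)]),
      selection_model(min(1, meta$s_het[i] * r), mu * r, two_N),
      method = "file")
  })
  structure(list(s_het = meta$s_het, spectra = spectra,
                 two_N = as.integer(meta$two_N), mu = mu,
                 pop_two_N = pop_two_N),
            class = "selection_grid")
}
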