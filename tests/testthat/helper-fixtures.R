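# Shared fixtures, memoized so expensive spectra are built once per session.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small, fast grid for unit tests: rescaled 10x from a 2,000-diploid
# nominal population
small_grid <- function() {
  get_fixture("small_grid", function() {
    build_selection_grid(
      s_values = exp(seq(log(1e-7), log(0.01), length.out = 12)),
      two_N = 400, mu = 1.25e-8, pop_two_N = 4000)
  })
}

# mid-sized grid at the true nominal population (20,000 diploids),
# rescaled 20x; realistic mutation-selection-drift balance for burden and
# flattening tests
mid_grid <- function() {
  get_fixture("mid_grid", function() {
    build_selection_grid(
      s_values = exp(seq(log(1e-6), log(0.05), length.out = 16)),
      two_N = 2000, mu = 1.25e-8, pop_two_N = 40000)
  })
}

# the package-default adaptive grid (50 s_het values, nominal 20,000
# diploids); expensive, shared by the acceptance checks
default_grid <- function() {
  get_fixture("default_grid", function() build_selection_grid())
}

# brute-force construction of the conditioned Wright-Fisher transition
# matrix, written independently of the package internals (explicit loops)
oracle_transition_matrix <- function(two_N, mu, s_het) {
  M <- if (s_het > 0) floor(two_N / 2) else two_N - 1
  P <- matrix(0, M + 1, M + 1)
  for (i in 0:M) {
    f <- i / two_N
    w_bar <- f^2 + 2 * f * (1 - f) * (1 - s_het) + (1 - f)^2
    f_sel <- (f^2 + f * (1 - f) * (1 - s_het)) / w_bar
    f_mut <- f_sel + (1 - f_sel) * mu
    for (j in 0:M) P[i + 1, j + 1] <- dbinom(j, two_N, f_mut)
    P[i + 1, ] <- P[i + 1, ] / sum(P[i + 1, ])
  }
  P
}

# power-iteration oracle for the stationary vector, from a new-mutation
# start
oracle_stationary <- function(P, tol = 1e-13, max_iter = 5e5) {
  v <- c(1, rep(0, nrow(P) - 1))
  for (i in seq_len(max_iter)) {
    v2 <- as.vector(v %*% P)
    if (sum(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  stop("oracle power iteration did not converge")
}

# random hit tables for locus tests
random_hits <- function(n, n_chrom = 2, span = 1e7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- sample.int(span, n)
  data.frame(chrom = paste0("chr", sample.int(n_chrom, n, TRUE)),
             pos = pos,
             log10p = -runif(n, 8, 30),
             beta = rnorm(n),
             maf = runif(n, 0.01, 0.5))
}

# transitive-closure oracle for locus grouping: repeatedly add any hit
# within the window of a member, seeding at the most significant
# unassigned hit
oracle_group_loci <- function(hits, window = 1e6) {
  n <- nrow(hits)
  assigned <- logical(n)
  out <- list()
  ord <- order(hits$log10p, hits$chrom, hits$pos)
  for (i in ord) {
    if (assigned[i]) next
    member <- i
    assigned[i] <- TRUE
    repeat {
      grew <- FALSE
      for (j in seq_len(n)) {
        if (assigned[j] || hits$chrom[j] != hits$chrom[i]) next
        if (any(abs(hits$pos[j] - hits$pos[member]) <= window)) {
          member <- c(member, j)
          assigned[j] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    out[[length(out) + 1]] <- sort(member)
  }
  out
}
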