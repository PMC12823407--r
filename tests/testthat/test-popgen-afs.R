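test_that("selection_model validates its parameters", {
  expect_s3_class(selection_model(1e-3, 1.25e-8, 2000), "selection_model")
  expect_error(selection_model(-0.1, 1e-8, 100), "s_het")
  expect_error(selection_model(0.1, 1.5, 100), "mu")
  expect_error(selection_model(0.1, 1e-8, 3), "two_N")
  expect_error(selection_model(0.1, 1e-8, 101), "two_N")
})

test_that("equilibrium spectrum is a distribution and matches a brute-force oracle", {
  m <- selection_model(0.05, 1e-4, 400)
  fd <- compute_equilibrium_afs(m)
  expect_true(all(fd$probs >= 0))
  expect_equal(sum(fd$probs), 1, tolerance = 1e-10)
  expect_length(fd$probs, 400)

  P <- oracle_transition_matrix(400, 1e-4, 0.05)
  v <- oracle_stationary(P)
  expect_lt(max(abs(fd$probs[seq_along(v)] - v)), 1e-8)

  # both backends agree to numerical precision
  fd_pow <- compute_equilibrium_afs(m, method = "power")
  expect_lt(max(abs(fd$probs - fd_pow$probs)), 1e-8)
})

test_that("no mutational input leaves all mass on frequency zero", {
  for (s in c(0, 0.01)) {
    fd <- compute_equilibrium_afs(selection_model(s, 0, 100))
    expect_equal(fd$probs[1], 1, tolerance = 1e-12)
    expect_equal(mean_frequency(fd), 0, tolerance = 1e-12)
  }
})

test_that("state-space guard and state_cap behave", {
  expect_error(compute_equilibrium_afs(selection_model(0, 1e-8, 50000)),
               "guard")
  m <- selection_model(0.2, 1e-5, 2000)
  full <- compute_equilibrium_afs(m)
  capped <- compute_equilibrium_afs(m, state_cap = 400)
  expect_lt(max(abs(full$probs - capped$probs)), 1e-10)
  # a cap that visibly truncates mass must fail loudly
  expect_error(compute_equilibrium_afs(selection_model(1e-4, 1e-5, 2000),
                                       state_cap = 30), "state_cap")
})

test_that("mean frequency decreases monotonically in s_het across the grid", {
  gs <- grid_summary(small_grid())
  sel <- gs$s_het >= 100 * 1.25e-8
  expect_equal(cor(gs$s_het[sel], gs$mean_freq[sel], method = "spearman"), -1)
})

test_that("DTWF equilibrium agrees with the diffusion stationary density", {
  two_N <- 1000; r <- 4000 / two_N # scaled-down nominal population
  for (s0 in c(2.5e-4, 1e-3, 1e-2)) { # 2Ns in [1, 40] at nominal 2N = 4000
    mu <- 1.25e-7
    m <- selection_model(s0 * r, mu * r, two_N)
    dt <- compute_equilibrium_afs(m)
    df <- diffusion_stationary_afs(m)
    expect_equal(mean_frequency(dt), mean_frequency(df), tolerance = 0.15)
    expect_equal(het_expectation(dt), het_expectation(df), tolerance = 0.15)
  }
})

test_that("neutral diffusion density is symmetric; selection lowers the mean", {
  m0 <- selection_model(0, 1e-5, 2000)
  d0 <- diffusion_stationary_afs(m0)
  expect_equal(mean_frequency(d0), 0.5, tolerance = 1e-6)
  means <- sapply(c(1e-4, 1e-3, 1e-2), function(s) {
    mean_frequency(diffusion_stationary_afs(selection_model(s, 1e-5, 2000)))
  })
  expect_true(all(diff(means) < 0))
  expect_error(diffusion_stationary_afs(selection_model(0.1, 0, 2000)),
               "non-integrable")
})

test_that("closed-form balance matches its guard and the DTWF mean", {
  expect_equal(closed_form_balance(1.25e-8, 0.05), 2.5e-7)
  expect_equal(closed_form_balance(0, 0.01), 0)
  expect_error(closed_form_balance(1e-4, 1e-3), "weak-selection")
  # s_het = 1e-3 at nominal 2N = 40,000, rescaled 40x
  m <- selection_model(0.04, 5e-7, 1000)
  expect_equal(mean_frequency(compute_equilibrium_afs(m)),
               closed_form_balance(1.25e-8, 1e-3), tolerance = 0.1)
})

test_that("trajectories: lethal heterozygotes die out, rare-allele mean follows (1-s)^t", {
  m <- selection_model(1, 1e-8, 200)
  tr <- simulate_trajectories(m, generations = 50, n_reps = 200,
                              init_count = 1, seed = 1)
  expect_true(all(tr$frequencies[, 51] == 0))
  expect_true(all(tr$frequencies[, 1] == 1 / 200))

  m2 <- selection_model(1e-3, 1e-8, 2000)
  n_reps <- 4000; gens <- 100
  tr2 <- simulate_trajectories(m2, gens, n_reps, init_count = 1, seed = 2)
  f <- tr2$frequencies
  expect_true(all(f >= 0 & f <= 1))
  for (t in c(25, 50, 100)) {
    expected <- (1 / 2000) * (1 - 1e-3)^t
    mc_se <- sd(f[, t + 1]) / sqrt(n_reps)
    expect_lt(abs(mean(f[, t + 1]) - expected), 3 * mc_se + 1e-12)
  }
  expect_error(simulate_trajectories(m2, 10, 5, init_count = 0), "init_count")
})

test_that("study-scale trajectory ensemble fans out and mostly dies", {
  # 10,000 identical mutations, s_het 1e-3, 10,000 diploids, 1,000
  # generations, no recurrent mutation
  m <- selection_model(1e-3, 0, 20000)
  tr <- simulate_trajectories(m, generations = 1000, n_reps = 10000,
                              init_count = 1, seed = 3)
  final <- tr$frequencies[, 1001]
  expect_gt(mean(final == 0), 0.9)           # most replicates lost
  expect_gt(max(final), 20 / 20000)          # a lucky few drift far up
  expect_true(all(tr$frequencies[, 1] == 1 / 20000))
})

test_that("nearest_spectrum picks the log-closest grid value, ties to the smaller", {
  g <- small_grid()
  expect_identical(nearest_spectrum(g, g$s_het[4]), g$spectra[[4]])
  # geometric midpoint between adjacent grid values goes to the smaller
  mid <- sqrt(g$s_het[3] * g$s_het[4])
  expect_identical(nearest_grid_index(g, mid), 3L)
  set.seed(42)
  s_query <- exp(runif(200, log(1e-8), log(0.1)))
  idx <- nearest_grid_index(g, s_query)
  brute <- vapply(s_query, function(s) {
    d <- abs(log10(s) - log10(g$s_het))
    which(d == min(d))[1L] # exhaustive scan; ties to the smaller index
  }, integer(1))
  expect_identical(idx, brute)
  expect_error(nearest_grid_index(g, -1), "positive")
})

test_that("selection grid serializes and reads back", {
  g <- small_grid()
  prefix <- file.path(withr::local_tempdir(), "grid")
  write_selection_grid(g, prefix)
  g2 <- read_selection_grid(prefix)
  expect_equal(g2$s_het, g$s_het)
  expect_equal(g2$two_N, g$two_N)
  for (k in seq_along(g$spectra)) {
    expect_equal(g2$spectra[[k]]$probs, g$spectra[[k]]$probs,
                 tolerance = 1e-12)
  }
})

test_that("sampled equilibrium frequencies follow the spectrum", {
  g <- small_grid()
  s <- rep(g$s_het[10], 20000)
  f <- sample_equilibrium_frequencies(g, s, seed = 9)
  expect_true(all(f >= 0 & f <= 0.5))
  expect_equal(mean(f), mean_frequency(g$spectra[[10]]), tolerance = 0.1)
})
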