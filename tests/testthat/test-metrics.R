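test_that("mode overlap is the absolute cosine", {
  v <- with_seed(1, rnorm(30))
  expect_equal(mode_overlap(v, 2.5 * v), 1)
  w <- c(1, rep(0, 29)); u <- c(0, 1, rep(0, 28))
  expect_equal(mode_overlap(w, u), 0)
  # 60 degree angle
  a <- c(1, 0, rep(0, 28)); b <- c(cos(pi / 3), sin(pi / 3), rep(0, 28))
  expect_equal(mode_overlap(a, b), 0.5)
  expect_error(mode_overlap(v, numeric(30)), "zero displacement")
})

test_that("cumulative overlap accumulates in quadrature", {
  V <- diag(6)[, 1:3]
  m <- fake_modes(V, c(1, 2, 3))
  disp <- 0.6 * V[, 1] + 0.8 * V[, 2]
  expect_equal(cumulative_overlap(m, disp, k = 2), 1)
  expect_equal(cumulative_overlap(m, disp, k = 1), 0.6)
  co <- vapply(1:3, function(k) cumulative_overlap(m, disp, k), numeric(1))
  expect_true(all(diff(co) >= 0))
})

test_that("full mode sets capture internal displacements completely", {
  g <- get_globule()
  m <- normal_modes(build_network(g))
  raw <- with_seed(4, rnorm(150))
  # project off the rigid-body subspace
  Z <- m$zero_vectors
  disp <- raw - Z %*% crossprod(Z, raw)
  expect_equal(cumulative_overlap(m, disp, k = length(m$values)), 1,
               tolerance = 1e-8)
})

test_that("variance fractions invert eigenvalues and normalize", {
  m <- fake_modes(diag(6)[, 1:2], c(1, 1))
  expect_equal(variance_fractions(m, 2)$fractions, c(0.5, 0.5))
  m2 <- fake_modes(diag(6)[, 1:2], c(1, 3))
  expect_equal(variance_fractions(m2, 2)$fractions, c(0.75, 0.25))
  expect_equal(variance_fractions(m2, k = 2)$cfv, 1)
})

test_that("collectivity spans its entropy bounds", {
  n <- 30
  uniform <- rep(1, 3 * n)
  expect_equal(collectivity(uniform), 1)
  single <- c(c(1, 1, 1), rep(0, 3 * (n - 1)))
  expect_equal(collectivity(single), 1 / n)
  # N = 4 with squared amplitudes (0.5, 0.5, 0, 0)
  v <- c(sqrt(0.5), 0, 0, sqrt(0.5), 0, 0, rep(0, 6))
  expect_equal(collectivity(v), 0.5)
})

test_that("best-mode search matches an exhaustive oracle", {
  V <- diag(12)[, 1:6]
  m <- fake_modes(V, 1:6)
  expect_equal(best_mode(m, V[, 4])$rank, 3L)
  expect_equal(best_mode(m, V[, 1])$rank, 0L)
  g <- make_globule(20, seed = 13)
  modes <- normal_modes(build_network(g))
  disp <- with_seed(5, rnorm(60))
  got <- best_mode(modes, disp)
  o <- vapply(seq_along(modes$values), function(j)
    mode_overlap(modes$vectors[, j], disp), numeric(1))
  expect_equal(got$max_overlap, max(o))
  expect_equal(got$rank, which.max(o) - 1L)
  expect_equal(got$collectivity, collectivity(modes$vectors[, which.max(o)]))
})

test_that("mode counts to target overlap respect their definitions", {
  V <- diag(9)[, 1:3]
  m <- fake_modes(V, 1:3)
  expect_equal(unname(modes_to_reach(m, V[, 1])), c(1, 1, 1))
  disp <- 0.6 * V[, 1] + 0.6 * V[, 2] + sqrt(1 - 0.72) * diag(9)[, 9]
  got <- modes_to_reach(m, disp)
  expect_equal(unname(got), c(2, 2, Inf))
  r <- unname(modes_to_reach(m, with_seed(6, rnorm(9))))
  expect_false(is.unsorted(r))   # handles Inf sentinels
})

test_that("fluctuation profiles correlate affinely with references", {
  g <- make_globule(20, seed = 14)
  m <- normal_modes(build_network(g))
  msf <- fluctuation_profile(m, k = 10)
  expect_equal(profile_correlation(msf, msf)$correlation, 1)
  expect_equal(profile_correlation(msf, 2 * msf + 5)$correlation, 1)
  prof <- c(1, 2, 3, 4, 5)
  ref <- c(2, 1, 5, 2, 1)
  expect_equal(profile_correlation(prof, ref)$correlation,
               sum((prof - 3) * (ref - 2.2)) /
                 sqrt(sum((prof - 3)^2) * sum((ref - 2.2)^2)))
})

test_that("rmsip detects identical, permuted and orthogonal subspaces", {
  U <- with_seed(7, random_orthonormal(30, 10))
  expect_equal(rmsip(U, U), 1)
  V <- U[, c(2, 1, 3:10)]
  expect_equal(rmsip(U, V), 1)
  W <- diag(30)[, 1:10]; X <- diag(30)[, 11:20]
  expect_equal(rmsip(W, X), 0)
})

test_that("rwsip weighs directions by their variances", {
  U <- diag(6)[, 1:2]
  expect_equal(rwsip(U, c(2, 1), U, c(2, 1)), 1)
  # same span, weight mass on swapped directions: 2-mode toy by hand,
  # numerator u1*v2 + u2*v1 = 4 over denominator u1*v1 + u2*v2 = 5
  v <- rwsip(U, c(2, 1), U[, c(2, 1)], c(2, 1))
  expect_lt(v, 1)
  expect_equal(v, sqrt(4 / 5))
  expect_equal(rwsip(diag(6)[, 1:2], c(1, 1), diag(6)[, 3:4], c(1, 1)), 0)
  # symmetry under exchanging the two spaces
  A <- with_seed(8, random_orthonormal(12, 3))
  B <- with_seed(9, random_orthonormal(12, 3))
  wa <- c(3, 2, 1); wb <- c(2, 2, 1)
  expect_equal(rwsip(A, wa, B, wb), rwsip(B, wb, A, wa))
})

test_that("ensemble PCA recovers directions and variances", {
  base <- matrix(0, 5, 3)
  axis <- matrix(0, 5, 3); axis[3, 1] <- 1
  ens <- lapply(c(-2, -1, 0, 1, 2), function(a) base + a * axis)
  p <- ensemble_pca(ens)
  expect_equal(length(p$variances), 1L)
  expect_equal(abs(p$directions[7, 1]), 1)
  # total variance equals the mean squared deviation from the mean
  g <- make_globule(15, seed = 17)
  modes <- normal_modes(build_network(g))
  d1 <- modes$vectors[, 1]; d2 <- modes$vectors[, 2]
  ens2 <- with_seed(10, lapply(1:500, function(i)
    g$coords + matrix(rnorm(1, 0, 2) * d1 + rnorm(1, 0, 1) * d2,
                      ncol = 3, byrow = TRUE)))
  p2 <- ensemble_pca(ens2)
  X <- t(vapply(ens2, function(m) as.vector(t(m)), numeric(45)))
  msd <- mean(rowSums(sweep(X, 2, colMeans(X))^2))
  expect_equal(sum(p2$variances), msd, tolerance = 1e-10)
  # parameter recovery from the generating two-mode sampler
  expect_equal(p2$variances[1], 4, tolerance = 0.4)
  expect_equal(p2$variances[2], 1, tolerance = 0.1)
  expect_equal(abs(sum(p2$directions[, 1] * d1)), 1, tolerance = 1e-2)
})
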