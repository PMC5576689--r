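test_that("spring constants evaluate their closed forms", {
  expect_equal(spring_constant(spring_scheme("hca"), 3.0), 45.3)
  expect_equal(spring_constant(spring_scheme("hca"), 5.0), 3.059e5 * 5^-6)
  # the linear branch is clamped at zero below b/a
  expect_equal(spring_constant(spring_scheme("hca"), 2.0), 0)
  ed <- spring_scheme("edenm")
  expect_equal(spring_constant(ed, 8.0, s_ij = 2, N = 100), 15)
  expect_equal(spring_constant(ed, 12.0, s_ij = 10, N = 100), 0)
  expect_equal(spring_constant(ed, 10.0, s_ij = 10, N = 100), (6 / 10)^6)
  expect_equal(edenm_cutoff(100), 2.9 * log(100) - 2.9)
  un <- spring_scheme("uniform_cutoff", gamma = 2, r_c = 10)
  expect_equal(spring_constant(un, 10.0), 2)
  expect_equal(spring_constant(un, 10.01), 0)
})

test_that("stabilized cutoff networks satisfy the degree and edge minima", {
  g <- get_globule()
  net <- build_network(g)
  expect_true(all(network_degrees(net) >= 4))
  expect_gte(nrow(net$edges), 3 * 50 - 6)
  # sparse geometry: an extended chain needs stabilizers to reach degree 4
  ext <- assign_sse(extended_chain(10))
  net2 <- build_network(ext, spring_scheme("uniform_cutoff", r_c = 10))
  expect_true(all(network_degrees(net2) >= 4))
  expect_true(any(net2$edges$origin == "stabilizer"))
})

test_that("edenm gives the prescribed bonded ladder on an extended chain", {
  ext <- extended_chain(10)
  net <- build_network(ext, spring_scheme("edenm"))
  e <- net$edges
  k_by_sep <- function(s) unique(e$k[e$j - e$i == s])
  expect_equal(k_by_sep(1), 60)
  expect_equal(k_by_sep(2), 15)
  expect_equal(k_by_sep(3), 60 / 9)
})

test_that("surgery respects separation, stability and identity", {
  g <- get_globule()
  net <- build_network(g)
  # short-range pair is retained
  short <- net$edges[net$edges$j - net$edges$i == 2, ][1, ]
  out <- modify_network(net, remove = cbind(short$i, short$j))
  expect_equal(nrow(out$edges), nrow(net$edges))
  # empty surgery leaves the spectrum untouched
  same <- modify_network(net, remove = NULL, add = NULL)
  expect_equal(normal_modes(same)$values, normal_modes(net)$values)
  # removing all observed breaking contacts keeps six zero modes
  hp <- memo("hinge_s1", function() make_hinge_pair(seed = 1))
  mc <- mcenm_net(hp$pair$start, hp$tmap)
  expect_equal(normal_modes(mc)$n_zero, 6L)
})

test_that("stabilizer edges survive surgery and degrees stay protected", {
  ext <- assign_sse(extended_chain(10))
  net <- build_network(ext)
  stab <- net$edges[net$edges$origin == "stabilizer", ][1, ]
  out <- suppressWarnings(
    modify_network(net, remove = cbind(stab$i, stab$j), min_sep = 0))
  expect_true(any(out$edges$i == stab$i & out$edges$j == stab$j))
  # stripping every long-range native edge cannot push degrees below 4
  lr <- net$edges[abs(net$edges$j - net$edges$i) >= 4 &
                  net$edges$origin == "native", c("i", "j")]
  out2 <- suppressWarnings(modify_network(net, remove = as.matrix(lr)))
  expect_true(all(network_degrees(out2) >= 4))
})

test_that("the dimer Hessian has the closed-form spectrum", {
  net <- structure(list(coords = rbind(c(0, 0, 0), c(3.8, 0, 0)),
                        edges = data.frame(i = 1L, j = 2L, k = 1,
                                           origin = "native"),
                        scheme = spring_scheme()),
                   class = "elastic_network")
  ev <- sort(eigen(hessian(net), symmetric = TRUE)$values)
  expect_equal(ev, c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
  modes <- normal_modes(hessian(net))
  expect_equal(modes$n_zero, 5L)       # collinear body: only 5 rigid modes
  expect_equal(modes$values, 2)
})

test_that("the Hessian annihilates rigid-body motions", {
  g <- get_globule()
  H <- hessian(build_network(g))
  n <- n_residues(g)
  tx <- rep(c(1, 0, 0), n)
  rot_z <- as.vector(t(cbind(-g$coords[, 2], g$coords[, 1], 0)))
  expect_lt(max(abs(H %*% tx)), 1e-10)
  expect_lt(max(abs(H %*% rot_z)) / max(abs(rot_z)), 1e-10)
})

test_that("the Hessian equals finite differences of the network energy", {
  g <- make_globule(20, seed = 5)
  net <- build_network(g)
  H <- hessian(net)
  Hfd <- fd_hessian(net)
  expect_lt(max(abs(H - Hfd)) / max(abs(H)), 1e-5)
})

test_that("mode sets are orthonormal with six zero modes on globules", {
  g <- get_globule()
  m <- normal_modes(build_network(g))
  expect_equal(m$n_zero, 6L)
  V <- cbind(m$zero_vectors, m$vectors)
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  expect_true(all(diff(m$values) >= -1e-12))
})

test_that("removing an edge never raises a nonzero eigenvalue", {
  g <- make_globule(20, seed = 8)
  net <- build_network(g)
  full <- sort(eigen(hessian(net), symmetric = TRUE)$values)
  lr <- which(abs(net$edges$j - net$edges$i) >= 4)
  with_seed(1, {
    for (pick in sample(lr, 5)) {
      cut <- net
      cut$edges <- net$edges[-pick, ]
      reduced <- sort(eigen(hessian(cut), symmetric = TRUE)$values)
      expect_true(all(reduced <= full + 1e-9))
    }
  })
})

test_that("the energy is quadratic near equilibrium with Hessian curvature", {
  g <- make_globule(20, seed = 9)
  net <- build_network(g)
  H <- hessian(net)
  delta <- with_seed(2, rnorm(60))
  delta <- delta / sqrt(sum(delta^2))
  for (h in c(1e-2, 1e-3)) {
    v <- network_energy(net, g$coords + matrix(h * delta, ncol = 3,
                                               byrow = TRUE))
    quad <- 0.5 * h^2 * as.numeric(crossprod(delta, H %*% delta))
    expect_equal(v / quad, 1, tolerance = 20 * h)
  }
})

test_that("ofc scaling multiplies stiffness by the configured table", {
  helix <- assign_sse(ideal_helix(12))
  net <- build_network(helix, spring_scheme("ofc", r_c = 10))
  e <- net$edges[net$edges$origin == "native", ]
  close_hh <- e$j - e$i <= 4
  expect_true(all(e$k[close_hh] == 3))
  expect_true(all(e$k[!close_hh] == 1))
})
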