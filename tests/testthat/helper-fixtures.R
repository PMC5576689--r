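# Shared fixtures. The benchmark corpus is expensive to extract features
# for, so it is built once per session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Ideal poly-alanine alpha helix: rise 1.5 A, 100 degree twist,
# radius 2.3 A.
ideal_helix <- function(n = 12) {
  t <- (seq_len(n) - 1) * 100 * pi / 180
  z <- (seq_len(n) - 1) * 1.5
  ca_structure(cbind(2.3 * cos(t), 2.3 * sin(t), z))
}

# Fully extended collinear chain with 3.8 A steps.
extended_chain <- function(n = 10, step = 3.8) {
  ca_structure(cbind((seq_len(n) - 1) * step, 0, 0))
}

random_rigid_transform <- function(coords) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, pi)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sweep(coords %*% t(R), 2, stats::rnorm(3, 0, 10), "+")
}

# 20-pair benchmark corpus (10 hinge + 10 loop), without features.
get_corpus <- function() memo("corpus", function() {
  make_corpus(n_pairs = 20, seed = 100, with_features = FALSE)
})

# Same corpus with per-protein contact features (used by classifier
# recovery experiments).
get_corpus_features <- function() memo("corpus_feats", function() {
  make_corpus(n_pairs = 20, seed = 100, with_features = TRUE)
})

get_globule <- function() memo("globule", function() make_globule(50, seed = 3))

# CO(10) of a network against a pair's displacement, restricted to
# matched residues.
co10_of <- function(net, pair, k = 10) {
  m <- normal_modes(net)
  keep <- as.vector(t(outer(pair$corr[, 1], 1:3,
                            function(i, c) 3 * (i - 1) + c)))
  m$vectors <- m$vectors[keep, , drop = FALSE]
  m$n_atoms <- nrow(pair$corr)
  cumulative_overlap(m, displacement_vector(pair),
                     k = min(k, length(m$values)))
}

baseline_net <- function(st) {
  if (is.null(st$sse)) st <- assign_sse(st)
  build_network(st, spring_scheme("uniform_cutoff", r_c = 10))
}

mcenm_net <- function(st, tmap) {
  suppressWarnings(modify_network(
    baseline_net(st),
    remove = transition_pairs(tmap, "breaking", min_sep = 4)))
}
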