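# Evaluation measures: mode overlap, cumulative overlap, variance
# fractions, collectivity, best-mode search, fluctuation correlations and
# subspace similarity.

#' Overlap between a mode and a displacement field
#'
#' Absolute cosine between a 3N mode vector and a 3N displacement vector:
#' \eqn{O_j = |M_j \cdot \Delta r| / (|M_j| |\Delta r|)}, in [0, 1] with 1 a
#' perfect match.
#'
#' @param mode numeric 3N vector.
#' @param disp numeric 3N displacement vector (nonzero).
#' @return overlap in [0, 1].
#' @export
mode_overlap <- function(mode, disp) {
  nd <- sqrt(sum(disp^2))
  if (nd == 0) stop("undefined overlap: zero displacement")
  abs(sum(mode * disp)) / (sqrt(sum(mode^2)) * nd)
}

# Overlaps of every internal mode with a displacement vector.
all_overlaps <- function(modes, disp) {
  nd <- sqrt(sum(disp^2))
  if (nd == 0) stop("undefined overlap: zero displacement")
  nv <- sqrt(colSums(modes$vectors^2))
  abs(as.vector(crossprod(modes$vectors, disp))) / (nv * nd)
}

#' Cumulative mode overlap CO(k)
#'
#' Root-sum-square of the overlaps of the first \code{k} internal
#' (nonzero) modes with the displacement field; non-decreasing in \code{k}
#' and equal to 1 over the full internal mode set when the displacement
#' has no rigid-body component.
#'
#' @param modes a \code{\link{normal_modes}} result.
#' @param disp numeric 3N displacement vector.
#' @param k number of low-frequency modes (default 10).
#' @return CO(k) in [0, 1].
#' @export
cumulative_overlap <- function(modes, disp, k = 10L) {
  k <- as.integer(k)
  if (k < 1L || k > length(modes$values))
    stop("k must be between 1 and the number of internal modes")
  o <- all_overlaps(modes, disp)
  sqrt(sum(o[seq_len(k)]^2))
}

#' Per-mode variance fractions and CFV(k)
#'
#' With unit stiffness scaling the variance carried by internal mode j is
#' proportional to \eqn{1/\lambda_j}; fractions are normalized over all
#' internal modes so CFV over the full set is 1.
#'
#' @param modes a \code{\link{normal_modes}} result.
#' @param k number of modes for the cumulative fraction (default 10).
#' @return list with \code{fractions} (per internal mode) and \code{cfv}
#'   (= sum of the first k fractions).
#' @export
variance_fractions <- function(modes, k = 10L) {
  inv <- 1 / modes$values
  fr <- inv / sum(inv)
  k <- min(as.integer(k), length(fr))
  list(fractions = fr, cfv = sum(fr[seq_len(k)]))
}

#' Degree of collectivity of a mode
#'
#' Entropy-based count of the residues involved in a motion:
#' \eqn{\kappa = \exp(-\sum_i u_i^2 \log u_i^2) / N} with \eqn{u_i^2} the
#' normalized per-residue squared amplitude (unit masses). Ranges from
#' 1/N (one residue moves) to 1 (all residues move equally).
#'
#' @param mode numeric 3N vector (nonzero).
#' @return collectivity in [1/N, 1].
#' @export
collectivity <- function(mode) {
  if (length(mode) %% 3L != 0L) stop("mode length must be a multiple of 3")
  amp2 <- rowSums(matrix(mode^2, ncol = 3L, byrow = TRUE))
  tot <- sum(amp2)
  if (tot == 0) stop("zero mode vector")
  u2 <- amp2 / tot
  n <- length(u2)
  nz <- u2 > 0
  exp(-sum(u2[nz] * log(u2[nz]))) / n
}

#' Best single mode for a displacement
#'
#' Scans all internal modes for the maximum single-mode overlap; ties go
#' to the lower rank. Ranks are 0-based (rank 0 = first internal mode).
#'
#' @param modes a \code{\link{normal_modes}} result.
#' @param disp numeric 3N displacement vector.
#' @return list with \code{max_overlap}, \code{rank} (0-based),
#'   \code{collectivity} and \code{variance_fraction} of that mode.
#' @export
best_mode <- function(modes, disp) {
  o <- all_overlaps(modes, disp)
  r <- which.max(o)   # first maximum = lowest rank on ties
  vf <- variance_fractions(modes, k = 1L)$fractions
  list(max_overlap = o[r], rank = r - 1L,
       collectivity = collectivity(modes$vectors[, r]),
       variance_fraction = vf[r])
}

#' Modes needed to reach target cumulative overlaps
#'
#' Smallest k with CO(k) at or above each threshold; \code{Inf} when the
#' threshold is never reached within the internal mode set.
#'
#' @param modes a \code{\link{normal_modes}} result.
#' @param disp numeric 3N displacement vector.
#' @param thresholds target overlaps (default 0.7, 0.8, 0.9).
#' @return named numeric vector, one entry per threshold.
#' @export
modes_to_reach <- function(modes, disp, thresholds = c(0.7, 0.8, 0.9)) {
  o <- all_overlaps(modes, disp)
  co <- sqrt(cumsum(o^2))
  out <- vapply(thresholds, function(th) {
    k <- which(co >= th)
    if (length(k) == 0L) Inf else as.numeric(k[1L])
  }, numeric(1L))
  names(out) <- paste0(thresholds * 100, "%")
  out
}

#' Predicted per-residue mean-square fluctuations
#'
#' \eqn{MSF_i = \sum_{j \le k} |m_{j,i}|^2 / \lambda_j} over the first k
#' internal modes (unit masses and stiffness scale).
#'
#' @param modes a \code{\link{normal_modes}} result.
#' @param k number of modes (default all internal modes).
#' @return numeric vector of length N.
#' @export
fluctuation_profile <- function(modes, k = length(modes$values)) {
  k <- min(as.integer(k), length(modes$values))
  msf <- numeric(modes$n_atoms)
  for (j in seq_len(k)) {
    amp2 <- rowSums(matrix(modes$vectors[, j]^2, ncol = 3L, byrow = TRUE))
    msf <- msf + amp2 / modes$values[j]
  }
  msf
}

#' Correlation between a predicted profile and a reference
#'
#' Least-squares scales the profile to the reference, then reports the
#' Pearson product-moment coefficient (which is invariant to the affine
#' scaling; the scaled profile is returned for plotting).
#'
#' @param profile predicted per-residue values.
#' @param reference observed values (same length), e.g. squared
#'   displacements or B-factors.
#' @return list with \code{correlation} and \code{scaled} profile.
#' @export
profile_correlation <- function(profile, reference) {
  if (length(profile) != length(reference))
    stop("profile and reference lengths differ")
  fit <- stats::lm.fit(cbind(1, profile), reference)
  list(correlation = stats::cor(profile, reference),
       scaled = fit$coefficients[1L] + fit$coefficients[2L] * profile)
}

#' Root mean square inner product of two subspaces
#'
#' \eqn{RMSIP(k) = [\sum_{i,j \le k} (U_i \cdot V_j)^2 / k]^{1/2}} over the
#' first k columns of two orthonormal mode matrices; 1 when the subspaces
#' coincide, 0 when orthogonal.
#'
#' @param U,V matrices with orthonormal columns (3N x >= k).
#' @param k subspace dimension (default 10).
#' @return RMSIP in [0, 1].
#' @export
rmsip <- function(U, V, k = 10L) {
  k <- min(k, ncol(U), ncol(V))
  P <- crossprod(U[, seq_len(k), drop = FALSE], V[, seq_len(k), drop = FALSE])
  sqrt(sum(P^2) / k)
}

#' Root weighted square inner product of two mode spaces
#'
#' Eigenvalue-weighted subspace similarity over the full non-trivial
#' spaces:
#' \eqn{RWSIP = [\sum_{ij} u_i v_j (U_i \cdot V_j)^2 / \sum_i u_i v_i]^{1/2}}.
#' Weights must be on an amplitude-variance scale and both sets ordered by
#' decreasing weight (elastic-network modes: pass \code{1 / eigenvalues},
#' see \code{\link{mode_weights}}; PCA: the variances). Under that
#' convention the measure is 1 exactly when directions and relative
#' weights coincide.
#'
#' @param U matrix of orthonormal columns; \code{u} their variance weights.
#' @param V,v the second space and weights.
#' @return RWSIP in [0, 1]; 1 iff directions and weights coincide.
#' @export
rwsip <- function(U, u, V, v) {
  m <- min(ncol(U), ncol(V), length(u), length(v))
  U <- U[, seq_len(m), drop = FALSE]; u <- u[seq_len(m)]
  V <- V[, seq_len(m), drop = FALSE]; v <- v[seq_len(m)]
  P2 <- crossprod(U, V)^2
  sqrt(sum(outer(u, v) * P2) / sum(u * v))
}

#' Variance weights of an elastic-network mode set
#' @param modes a \code{\link{normal_modes}} result.
#' @return \code{1 / eigenvalues}, proportional to the amplitude variance
#'   along each internal mode.
#' @export
mode_weights <- function(modes) 1 / modes$values

#' Principal component analysis of a conformational ensemble
#'
#' Essential-dynamics style PCA of the 3N coordinate covariance of a
#' pre-superposed ensemble (population covariance: divisor n, so the total
#' variance equals the mean squared deviation from the ensemble mean).
#'
#' @param ensemble list of N x 3 coordinate matrices over a common residue
#'   set, already superposed onto a common frame.
#' @return list with \code{directions} (3N x m, unit columns, variance
#'   descending), \code{variances}, and \code{mean} coordinates.
#' @export
ensemble_pca <- function(ensemble) {
  if (length(ensemble) < 3L) stop("need at least 3 conformers")
  X <- t(vapply(ensemble, function(m) as.vector(t(m)),
                numeric(length(ensemble[[1L]]))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- svd(Xc, nu = 0)
  vars <- s$d^2 / nrow(X)
  keep <- vars > max(vars) * 1e-12
  list(directions = s$v[, keep, drop = FALSE], variances = vars[keep],
       mean = matrix(mu, ncol = 3L, byrow = TRUE))
}
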