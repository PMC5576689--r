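# Independent reference implementations used as oracles. These stay
# deliberately naive (loops, closed forms) and share no code with the
# package internals they check.

# Quaternion (Horn) superposition: rotation from the largest eigenvector
# of the 4x4 key matrix; returns the post-fit rmsd.
quaternion_rmsd <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  S <- crossprod(A, B)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
  fit <- t(R %*% t(A))
  sqrt(mean(rowSums((fit - B)^2)))
}

# Element-by-element transition labeling straight from the definition.
naive_transitions <- function(coords_s, coords_e, r_c, e_c) {
  n <- nrow(coords_s)
  lab <- matrix("none", n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ds <- sqrt(sum((coords_s[i, ] - coords_s[j, ])^2))
    de <- sqrt(sum((coords_e[i, ] - coords_e[j, ])^2))
    cs <- ds <= r_c; ce <- de <= r_c
    if (cs) {
      e <- abs((ds - de) / ds)
      lab[i, j] <- if (e <= e_c) "maintained" else "breaking"
    } else if (ce) lab[i, j] <- "forming"
  }
  lab
}

# Finite-difference Hessian of the network potential.
fd_hessian <- function(net, h = 1e-4) {
  x0 <- as.vector(t(net$coords))
  m <- length(x0)
  V <- function(x) network_energy(net, matrix(x, ncol = 3, byrow = TRUE))
  H <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in a:m) {
    ea <- eb <- numeric(m); ea[a] <- h; eb[b] <- h
    H[a, b] <- H[b, a] <-
      (V(x0 + ea + eb) - V(x0 + ea - eb) - V(x0 - ea + eb) +
       V(x0 - ea - eb)) / (4 * h^2)
  }
  H
}

# Exhaustive-pair AUROC (probability a positive outranks a negative,
# ties counting half).
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force neighborhood node set from the definition.
naive_in_nodes <- function(i, j, C, sse) {
  n <- nrow(C)
  nodes <- c(i, j, i - 1, i + 1, j - 1, j + 1,
             which(C[i, ] == 1), which(C[j, ] == 1))
  if (sse[i] == "H") nodes <- c(nodes, i - 4, i + 4)
  if (sse[j] == "H") nodes <- c(nodes, j - 4, j + 4)
  as.integer(sort(unique(nodes[nodes >= 1 & nodes <= n])))
}

# Random orthonormal columns via QR.
random_orthonormal <- function(nrow, ncol) {
  qr.Q(qr(matrix(stats::rnorm(nrow * ncol), nrow, ncol)))
}

# A fake mode_set with prescribed orthonormal vectors and eigenvalues,
# for metric tests that need exact overlaps.
fake_modes <- function(vectors, values) {
  structure(list(values = values, vectors = vectors,
                 n_zero = 0L, zero_vectors = matrix(0, nrow(vectors), 0),
                 zero_tol = 1e-8, n_atoms = nrow(vectors) / 3L),
            class = "mode_set")
}
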