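# Elastic-network construction, spring schemes, network surgery, Hessian
# assembly and normal mode analysis.

#' Define a spring scheme
#'
#' Four parameterizations of the pairwise force constant are supported:
#' \describe{
#'   \item{uniform_cutoff}{\eqn{k = \gamma} for \eqn{d \le r_c}, else 0
#'     (the classical distance-cutoff ANM).}
#'   \item{hca}{cutoff-free, fast-decaying distance dependence:
#'     \eqn{k = a d - b} for \eqn{d < 4} Angstrom, else \eqn{c d^{-6}},
#'     with a = 205.5, b = 571.2, c = 3.059e5 (kcal/mol Angstrom units).
#'     The linear branch is clamped at zero for the (physically absent)
#'     distances below b/a.}
#'   \item{edenm}{bond-cutoff hybrid: sequence neighbors up to 3 apart get
#'     \eqn{k = a / s^b} (a = 60, b = 2); spatial pairs within the
#'     size-dependent cutoff \eqn{r_c(N) = 2.9 \ln N - 2.9} get
#'     \eqn{k = (c / d)^d} (c = 6, exponent 6); remote pairs 0.}
#'   \item{ofc}{cutoff network with secondary-structure scaled stiffness;
#'     the multiplier table is configuration-supplied (default: 3x for
#'     helix-helix pairs at sequence separation <= 4, 2x for strand-strand,
#'     1x otherwise).}
#' }
#'
#' @param name one of \code{"uniform_cutoff"}, \code{"hca"}, \code{"edenm"},
#'   \code{"ofc"}.
#' @param gamma uniform stiffness constant (default 1).
#' @param r_c distance cutoff in Angstrom for \code{uniform_cutoff} and
#'   \code{ofc} (default 10); fixed internally for \code{hca} (4.0) and
#'   size-dependent for \code{edenm}.
#' @param ofc_table optional function \code{(sse_i, sse_j, s)} returning a
#'   stiffness multiplier for the \code{ofc} scheme.
#' @return object of class \code{"spring_scheme"}.
#' @export
spring_scheme <- function(name = c("uniform_cutoff", "hca", "edenm", "ofc"),
                          gamma = 1, r_c = 10, ofc_table = NULL) {
  name <- match.arg(name)
  if (name == "ofc" && is.null(ofc_table)) ofc_table <- default_ofc_table
  structure(list(name = name, gamma = gamma, r_c = r_c,
                 hca = list(a = 205.5, b = 571.2, c = 3.059e5, d = 6,
                            r_c = 4.0),
                 edenm = list(a = 60, b = 2, c = 6, d = 6),
                 ofc_table = ofc_table),
            class = "spring_scheme")
}

# Default secondary-structure stiffness multipliers for the ofc scheme.
default_ofc_table <- function(sse_i, sse_j, s) {
  ifelse(sse_i == "H" & sse_j == "H" & s <= 4, 3,
         ifelse(sse_i == "E" & sse_j == "E", 2, 1))
}

#' Pairwise spring constant under a scheme
#'
#' @param scheme a \code{\link{spring_scheme}}.
#' @param d_ij Calpha distance in Angstrom (> 0); vectorized.
#' @param s_ij sequence separation (>= 1); vectorized.
#' @param N number of residues (needed by \code{edenm}).
#' @param sse_i,sse_j secondary-structure labels of the two residues
#'   (needed by \code{ofc}; default coil).
#' @return numeric force constant(s), always >= 0.
#' @export
spring_constant <- function(scheme, d_ij, s_ij = 1L, N = NULL,
                            sse_i = "C", sse_j = "C") {
  if (any(d_ij <= 0)) stop("d_ij must be positive")
  switch(scheme$name,
    uniform_cutoff = ifelse(d_ij <= scheme$r_c, scheme$gamma, 0),
    hca = {
      p <- scheme$hca
      ifelse(d_ij < p$r_c, pmax(0, p$a * d_ij - p$b), p$c * d_ij^(-p$d))
    },
    edenm = {
      p <- scheme$edenm
      if (is.null(N)) stop("edenm needs N")
      rc <- edenm_cutoff(N)
      ifelse(s_ij <= 3, p$a / s_ij^p$b,
             ifelse(d_ij <= rc, (p$c / d_ij)^p$d, 0))
    },
    ofc = ifelse(d_ij <= scheme$r_c,
                 scheme$gamma * scheme$ofc_table(sse_i, sse_j, s_ij), 0),
    stop("unknown scheme: ", scheme$name))
}

#' Size-dependent edENM cutoff
#' @param N number of residues.
#' @return cutoff radius \code{2.9 * log(N) - 2.9} in Angstrom.
#' @export
edenm_cutoff <- function(N) 2.9 * log(N) - 2.9

#' Build an elastic network over a Calpha structure
#'
#' Creates an edge wherever the scheme's spring constant is positive. For
#' cutoff-based schemes (\code{uniform_cutoff}, \code{ofc}) the network is
#' by default stabilized so that every node has degree at least
#' \code{min_degree}: under-constrained nodes are connected to their
#' closest not-yet-connected neighbors along the sequence irrespective of
#' distance (stabilizer edges carry \code{k = gamma}). A stabilized cutoff
#' network has exactly six zero modes for any non-degenerate geometry.
#'
#' @param structure a \code{\link{ca_structure}} (secondary structure is
#'   assigned on the fly if the \code{ofc} scheme needs it).
#' @param scheme a \code{\link{spring_scheme}} (default classical cutoff
#'   ANM at 10 Angstrom).
#' @param stabilize logical; default \code{TRUE} for cutoff schemes,
#'   \code{FALSE} for \code{hca}/\code{edenm} (which are intrinsically
#'   well-connected).
#' @param min_degree stabilization degree target (default 4).
#' @return object of class \code{"elastic_network"}: list with
#'   \code{coords}, \code{edges} (data.frame \code{i, j, k, origin} with
#'   origin in native/stabilizer/added_forming), \code{scheme}.
#' @export
build_network <- function(structure, scheme = spring_scheme(),
                          stabilize = NULL, min_degree = 4L) {
  n <- n_residues(structure)
  if (n < 3L) stop("network too small")
  if (is.null(stabilize))
    stabilize <- scheme$name %in% c("uniform_cutoff", "ofc")
  sse <- structure$sse
  if (scheme$name == "ofc" && is.null(sse))
    sse <- assign_sse(structure)$sse
  if (is.null(sse)) sse <- rep("C", n)
  D <- coord_dist(structure$coords)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  s_ij <- idx[, 2L] - idx[, 1L]
  k <- spring_constant(scheme, D[idx], s_ij, N = n,
                       sse_i = sse[idx[, 1L]], sse_j = sse[idx[, 2L]])
  keep <- k > 0
  edges <- data.frame(i = idx[keep, 1L], j = idx[keep, 2L], k = k[keep],
                      origin = "native", stringsAsFactors = FALSE)
  net <- structure(list(coords = structure$coords, edges = edges,
                        scheme = scheme), class = "elastic_network")
  if (stabilize) net <- stabilize_network(net, min_degree = min_degree)
  net
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("Elastic network (%s): %d nodes, %d edges (%d native, %d stabilizer, %d added)\n",
              x$scheme$name, nrow(x$coords), nrow(x$edges),
              sum(x$edges$origin == "native"),
              sum(x$edges$origin == "stabilizer"),
              sum(x$edges$origin == "added_forming")))
  invisible(x)
}

#' Node degrees of an elastic network
#' @param network an \code{\link{build_network}} result.
#' @return integer vector of node degrees.
#' @export
network_degrees <- function(network) {
  tabulate(c(network$edges$i, network$edges$j), nbins = nrow(network$coords))
}

# Connect under-constrained nodes to their nearest unconnected sequence
# neighbors until every node reaches min_degree. Closer sequence neighbor
# first; ties broken toward the lower index.
stabilize_network <- function(network, min_degree = 4L) {
  n <- nrow(network$coords)
  adj <- matrix(FALSE, n, n)
  adj[cbind(network$edges$i, network$edges$j)] <- TRUE
  adj[cbind(network$edges$j, network$edges$i)] <- TRUE
  deg <- network_degrees(network)
  new_i <- integer(); new_j <- integer()
  repeat {
    under <- which(deg < min_degree)
    if (length(under) == 0L) break
    v <- under[1L]
    cand <- setdiff(seq_len(n), c(v, which(adj[v, ])))
    if (length(cand) == 0L) break
    cand <- cand[order(abs(cand - v), cand)]
    w <- cand[1L]
    adj[v, w] <- adj[w, v] <- TRUE
    deg[v] <- deg[v] + 1L; deg[w] <- deg[w] + 1L
    new_i <- c(new_i, min(v, w)); new_j <- c(new_j, max(v, w))
  }
  if (length(new_i) > 0L)
    network$edges <- rbind(network$edges,
                           data.frame(i = new_i, j = new_j,
                                      k = network$scheme$gamma,
                                      origin = "stabilizer",
                                      stringsAsFactors = FALSE))
  network
}

#' Network surgery: remove and add contacts
#'
#' Removes listed native edges whose residues are at least \code{min_sep}
#' sequence positions apart (closer pairs are retained; stabilizer edges
#' are never removed), and adds listed edges with \code{k = gamma}. A
#' removal that would drop either endpoint below degree \code{min_degree}
#' is skipped with a warning: network stability takes precedence. Removing
#' the observed breaking contacts yields the mcENM, removing predicted
#' breaking contacts the lmcENM, additionally adding forming contacts the
#' mfcENM.
#'
#' @param network an \code{\link{build_network}} result.
#' @param remove 2-column matrix of residue index pairs to remove (may be
#'   \code{NULL}).
#' @param add 2-column matrix of pairs to add (may be \code{NULL}).
#' @param min_sep minimum sequence separation for removals (default 4).
#' @param min_degree protected minimum node degree (default 4).
#' @return the modified \code{elastic_network}.
#' @export
modify_network <- function(network, remove = NULL, add = NULL,
                           min_sep = 4L, min_degree = 4L) {
  edges <- network$edges
  deg <- network_degrees(network)
  n_skipped_deg <- 0L
  if (!is.null(remove) && NROW(remove) > 0L) {
    remove <- as.matrix(remove)
    for (r in seq_len(nrow(remove))) {
      a <- min(remove[r, 1:2]); b <- max(remove[r, 1:2])
      if (b - a < min_sep) next
      hit <- which(edges$i == a & edges$j == b & edges$origin == "native")
      if (length(hit) == 0L) next
      if (deg[a] - 1L < min_degree || deg[b] - 1L < min_degree) {
        n_skipped_deg <- n_skipped_deg + 1L
        next
      }
      edges <- edges[-hit[1L], , drop = FALSE]
      deg[a] <- deg[a] - 1L; deg[b] <- deg[b] - 1L
    }
  }
  if (n_skipped_deg > 0L)
    warning(sprintf("modify_network: %d removal(s) skipped to protect degree >= %d",
                    n_skipped_deg, min_degree), call. = FALSE)
  if (!is.null(add) && NROW(add) > 0L) {
    add <- as.matrix(add)
    for (r in seq_len(nrow(add))) {
      a <- min(add[r, 1:2]); b <- max(add[r, 1:2])
      if (a == b) next
      if (any(edges$i == a & edges$j == b)) next
      edges <- rbind(edges, data.frame(i = a, j = b,
                                       k = network$scheme$gamma,
                                       origin = "added_forming",
                                       stringsAsFactors = FALSE))
    }
  }
  network$edges <- edges
  network
}

#' ANM potential energy of a deformed configuration
#'
#' \eqn{V = \sum_{edges} (k_{ij}/2) (d_{ij} - d^0_{ij})^2} with equilibrium
#' distances taken from the network's reference coordinates.
#'
#' @param network an \code{\link{build_network}} result.
#' @param coords N x 3 matrix of instantaneous coordinates.
#' @return potential energy (gamma Angstrom^2 units).
#' @export
network_energy <- function(network, coords) {
  e <- network$edges
  d0 <- sqrt(rowSums((network$coords[e$i, , drop = FALSE] -
                      network$coords[e$j, , drop = FALSE])^2))
  d <- sqrt(rowSums((coords[e$i, , drop = FALSE] -
                     coords[e$j, , drop = FALSE])^2))
  sum(e$k / 2 * (d - d0)^2)
}

#' Assemble the ANM Hessian
#'
#' Standard anisotropic-network super-element assembly: the off-diagonal
#' 3x3 block of edge (i, j) is \eqn{-k_{ij} \hat r \hat r^T} with
#' \eqn{\hat r} the unit equilibrium direction; diagonal blocks are the
#' negated sums of their row's off-diagonal blocks. The result is symmetric
#' positive semidefinite with the six rigid-body motions in its null space.
#'
#' @param network an \code{\link{build_network}} result.
#' @return 3N x 3N symmetric matrix.
#' @export
hessian <- function(network) {
  n <- nrow(network$coords)
  H <- matrix(0, 3L * n, 3L * n)
  e <- network$edges
  for (r in seq_len(nrow(e))) {
    i <- e$i[r]; j <- e$j[r]
    dv <- network$coords[j, ] - network$coords[i, ]
    d2 <- sum(dv^2)
    blk <- -e$k[r] * tcrossprod(dv) / d2
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Normal mode analysis of a Hessian or network
#'
#' Full eigen-decomposition with unit masses. Eigenvalues below
#' \code{zero_tol} times the largest eigenvalue are counted as zero
#' (rigid-body motions); the remaining modes are reported in ascending
#' eigenvalue order. Mode ranks are 0-based: rank 0 is the first nonzero
#' (lowest-frequency internal) mode.
#'
#' @param x an \code{elastic_network} or a precomputed symmetric Hessian.
#' @param zero_tol relative zero threshold (default 1e-8).
#' @return object of class \code{"mode_set"}: \code{values} (ascending
#'   nonzero eigenvalues), \code{vectors} (3N x m orthonormal columns),
#'   \code{n_zero}, \code{zero_vectors}, \code{zero_tol}, \code{n_atoms}.
#' @export
normal_modes <- function(x, zero_tol = 1e-8) {
  H <- if (inherits(x, "elastic_network")) hessian(x) else as.matrix(x)
  dec <- tryCatch(eigen(H, symmetric = TRUE), error = function(e)
    stop("NMA failed: ", conditionMessage(e)))
  vals <- rev(dec$values)
  vecs <- dec$vectors[, rev(seq_along(dec$values)), drop = FALSE]
  vmax <- max(vals)
  if (vmax <= 0) stop("NMA failed: Hessian has no positive eigenvalue")
  nz <- vals < zero_tol * vmax
  structure(list(values = vals[!nz],
                 vectors = vecs[, !nz, drop = FALSE],
                 n_zero = sum(nz),
                 zero_vectors = vecs[, nz, drop = FALSE],
                 zero_tol = zero_tol,
                 n_atoms = nrow(H) / 3L),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("Mode set: %d atoms, %d zero modes, %d internal modes\n",
              x$n_atoms, x$n_zero, length(x$values)))
  invisible(x)
}

#' Export network edges as a plain table
#' @param network an \code{\link{build_network}} result.
#' @param path optional file; when given, a whitespace-separated table is
#'   written.
#' @return the edge data.frame, invisibly when written to file.
#' @export
export_network <- function(network, path = NULL) {
  e <- network$edges[order(network$edges$i, network$edges$j), ]
  if (!is.null(path)) {
    utils::write.table(e, path, quote = FALSE, row.names = FALSE, sep = "\t")
    return(invisible(e))
  }
  e
}

#' Export modes as plain columns (NMD-style)
#' @param modes a \code{\link{normal_modes}} result.
#' @param path output file.
#' @param k number of modes to write (default 10).
#' @return invisibly, \code{path}.
#' @export
export_modes <- function(modes, path, k = 10L) {
  k <- min(k, length(modes$values))
  m <- cbind(eigenvalue = modes$values[seq_len(k)],
             t(modes$vectors[, seq_len(k), drop = FALSE]))
  utils::write.table(m, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
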