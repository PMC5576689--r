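# Synthetic Calpha structures and conformation pairs with known motion
# and ground-truth contact transitions. The generators are caricatures of
# protein architecture -- compact self-avoiding chains, a two-domain
# "hinge" pair and a displaced surface loop -- built to exercise the
# machinery, not to mimic real folds.

# Self-avoiding compact chain growth. Consecutive Calpha distances are
# 3.8 +/- jitter Angstrom, non-bonded pairs stay >= 4 Angstrom apart, and
# the chain is confined to a sphere sized to give a radius of gyration
# near 3 * n^(1/3) Angstrom. `centers` may vary per residue (used by the
# two-domain generator); `confine` radius may be Inf for linker residues.
grow_chain <- function(n, centers, confine, bond = 3.8, jitter = 0.1,
                       min_nb = 4.0, max_restarts = 40L, axis = NULL) {
  axis_radial <- function(p) {
    if (is.null(axis)) return(0)
    v <- p - axis$point
    sqrt(sum(v^2) - sum(v * axis$dir)^2)
  }
  for (restart in seq_len(max_restarts)) {
    xyz <- matrix(NA_real_, n, 3L)
    xyz[1L, ] <- centers[1L, ] + stats::runif(3L, -1, 1)
    ok <- TRUE
    i <- 2L
    fails <- 0L
    while (i <= n) {
      placed <- FALSE
      for (try in seq_len(300L)) {
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u^2))
        cand <- xyz[i - 1L, ] + u * (bond + stats::runif(1L, -jitter, jitter))
        if (sqrt(sum((cand - centers[i, ])^2)) > confine[i]) next
        if (!is.null(axis) && is.finite(axis$max_r[i]) &&
            axis_radial(cand) > max(axis$max_r[i],
                                    axis_radial(xyz[i - 1L, ]))) next
        if (i > 2L) {
          d2 <- rowSums(sweep(xyz[seq_len(i - 2L), , drop = FALSE], 2L,
                              cand)^2)
          if (min(d2) < min_nb^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        fails <- fails + 1L
        if (fails > 30L) { ok <- FALSE; break }
        i <- max(2L, i - 5L)   # back up and regrow
        next
      }
      i <- i + 1L
    }
    if (ok) return(xyz)
  }
  stop("packing failed: could not grow a self-avoiding chain (re-seed)")
}

# Random 3-letter residue names (uniform over the 20 standard types).
random_resid <- function(n) {
  sample(names(SOLVATION_SCALE), n, replace = TRUE)
}

# Surface-biased synthetic B-factors: residues far from the centroid get
# larger values, which is the qualitative pattern of crystallographic
# B-factors.
synthetic_bfactors <- function(xyz) {
  cd <- sqrt(rowSums(sweep(xyz, 2L, colMeans(xyz))^2))
  20 + 2 * cd + stats::rnorm(nrow(xyz), 0, 1)
}

#' Generate a compact self-avoiding globule
#'
#' Deterministic per seed. Consecutive Calpha distances are
#' 3.8 +/- 0.1 Angstrom, non-bonded residues stay at least 4 Angstrom
#' apart, and the chain is confined so its radius of gyration is near
#' \code{3 * n^(1/3)} Angstrom. Residue identities are drawn uniformly,
#' B-factors increase with distance from the centroid, and secondary
#' structure is assigned geometrically.
#'
#' @param n number of residues (>= 10).
#' @param seed integer seed governing all randomness.
#' @param center centre of the confinement sphere (default origin).
#' @return a \code{\link{ca_structure}}.
#' @export
make_globule <- function(n, seed = 1L, center = c(0, 0, 0)) {
  if (n < 10L) stop("n_residues must be >= 10")
  with_seed(seed, {
    confine_r <- sqrt(5 / 3) * 3 * n^(1 / 3)
    xyz <- grow_chain(n, matrix(center, n, 3L, byrow = TRUE),
                      rep(confine_r, n))
    st <- ca_structure(xyz, resid = random_resid(n),
                       b = synthetic_bfactors(xyz))
    assign_sse(st)
  })
}

#' Generate a two-domain pair with an interfacial twist
#'
#' Builds two compact domains joined by a 5-residue linker, with the
#' domains packed against each other. The end conformation rotates the
#' second domain rigidly by \code{angle} degrees about the inter-domain
#' axis through the linker (the rotation tapers linearly across the
#' linker so the backbone stays intact). Intra-domain distances are
#' preserved exactly, so the ground-truth breaking contacts concentrate
#' at the inter-domain interface.
#'
#' @param n_residues total length (two domains plus 5 linker residues;
#'   default 75, comfortably above the 70-residue curation minimum).
#' @param angle hinge rotation in degrees, in (0, 90].
#' @param seed integer seed.
#' @param r_c,e_c contact cutoff and extension threshold used for the
#'   ground truth (defaults 10 Angstrom, 0.09).
#' @return list with \code{pair} (a \code{\link{build_pair}} result),
#'   \code{tmap} (ground-truth \code{\link{classify_transitions}} on the
#'   generated coordinates), and \code{domains} (index lists A, linker,
#'   B).
#' @export
make_hinge_pair <- function(n_residues = 75L, angle = 45, seed = 1L,
                            r_c = 10, e_c = 0.09) {
  if (n_residues < 15L) stop("n_residues must be >= 15")
  if (angle <= 0 || angle > 90) stop("hinge angle must be in (0, 90] degrees")
  n_link <- 5L
  n1 <- (n_residues - n_link) %/% 2L
  n2 <- n_residues - n_link - n1
  start <- with_seed(seed, {
    rA <- sqrt(5 / 3) * 3 * n1^(1 / 3)
    rB <- sqrt(5 / 3) * 3 * n2^(1 / 3)
    cA <- c(0, 0, 0)
    # confinement radii are maximal extents, so packed (touching) domains
    # need their spheres to interpenetrate
    cB <- c(0.7 * (rA + rB), 0, 0)
    centers <- rbind(matrix(cA, n1, 3L, byrow = TRUE),
                     matrix(cB, n_link, 3L, byrow = TRUE),
                     matrix(cB, n2, 3L, byrow = TRUE))
    confine <- c(rep(rA, n1), rep(Inf, n_link), rep(rB, n2))
    # the linker hugs the inter-domain axis so that the tapered rotation
    # below cannot stretch its bonds into chain breaks
    axis <- list(point = cA, dir = c(1, 0, 0),
                 max_r = c(rep(Inf, n1), rep(8, n_link), rep(Inf, n2)))
    xyz <- grow_chain(n_residues, centers, confine, axis = axis)
    st <- ca_structure(xyz, resid = random_resid(n_residues),
                       b = synthetic_bfactors(xyz))
    assign_sse(st)
  })
  idxA <- seq_len(n1)
  idxL <- n1 + seq_len(n_link)
  idxB <- n1 + n_link + seq_len(n2)
  # rotate domain B (full angle) and the linker (tapered) about the
  # inter-domain axis through the linker centroid
  axis_pt <- colMeans(start$coords[idxL, , drop = FALSE])
  axis_dir <- colMeans(start$coords[idxB, , drop = FALSE]) -
              colMeans(start$coords[idxA, , drop = FALSE])
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  end <- start
  theta <- angle * pi / 180
  for (k in seq_len(n_link))
    end$coords[idxL[k], ] <- rotate_about_axis(start$coords[idxL[k], ],
                                               axis_pt, axis_dir,
                                               theta * k / (n_link + 1L))
  end$coords[idxB, ] <- t(apply(start$coords[idxB, , drop = FALSE], 1L,
                                rotate_about_axis, axis_pt, axis_dir, theta))
  pair <- build_pair(start, end)
  half <- idxL[seq_len(ceiling(n_link / 2))]
  list(pair = pair, tmap = classify_transitions(pair, r_c = r_c, e_c = e_c),
       domains = list(A = idxA, linker = idxL, B = idxB),
       # rigid-half partition (linker split at its midpoint): every
       # residue belongs to the moving or the static half
       sides = list(A = c(idxA, half), B = setdiff(c(idxL, idxB), half)))
}

# Rodrigues rotation of a point about the axis (pt, unit dir) by theta.
rotate_about_axis <- function(x, pt, dir, theta) {
  p <- x - pt
  p_rot <- p * cos(theta) + pracma_cross(dir, p) * sin(theta) +
           dir * sum(dir * p) * (1 - cos(theta))
  p_rot + pt
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Generate a globule pair with a displaced surface loop
#'
#' Starts from \code{\link{make_globule}} and displaces a contiguous
#' surface span (the window with the largest mean distance from the
#' centroid) radially outward by \code{amplitude} Angstrom, with a smooth
#' sinusoidal taper at the span ends; the rest of the structure is fixed.
#' This emulates a localized functional transition.
#'
#' @param n_residues chain length (default 72).
#' @param span loop length in residues (default 8).
#' @param amplitude peak outward displacement in Angstrom (> 0, default 6).
#' @param seed integer seed.
#' @param r_c,e_c ground-truth contact parameters.
#' @return list with \code{pair}, \code{tmap} and \code{loop} (the
#'   displaced indices).
#' @export
make_loop_pair <- function(n_residues = 72L, span = 8L, amplitude = 6,
                           seed = 1L, r_c = 10, e_c = 0.09) {
  if (amplitude <= 0) stop("amplitude must be > 0")
  start <- make_globule(n_residues, seed = seed)
  centroid <- colMeans(start$coords)
  cd <- sqrt(rowSums(sweep(start$coords, 2L, centroid)^2))
  # most surface-exposed window, away from the termini
  lo <- 3L; hi <- n_residues - span - 2L
  means <- vapply(lo:hi, function(s) mean(cd[s:(s + span - 1L)]), numeric(1L))
  s0 <- (lo:hi)[which.max(means)]
  loop <- s0:(s0 + span - 1L)
  end <- start
  taper <- sin(pi * seq_len(span) / (span + 1L))^2
  for (k in seq_along(loop)) {
    r <- loop[k]
    u <- start$coords[r, ] - centroid
    u <- u / sqrt(sum(u^2))
    end$coords[r, ] <- start$coords[r, ] + amplitude * taper[k] * u
  }
  pair <- build_pair(start, end)
  list(pair = pair, tmap = classify_transitions(pair, r_c = r_c, e_c = e_c),
       loop = loop)
}

#' Random edge-removal control network
#'
#' Removes \code{n_remove} uniformly chosen native long-range edges
#' (sequence separation >= 4) via \code{\link{modify_network}}, so the
#' degree-4 protection applies. Matching the removal count of an
#' informed surgery, this is the control that separates "removing the
#' right contacts" from "removing any contacts".
#'
#' @param network an \code{\link{build_network}} result.
#' @param n_remove number of edges to remove.
#' @param seed integer seed.
#' @return the modified \code{elastic_network}.
#' @export
random_removal_control <- function(network, n_remove, seed = 1L) {
  if (n_remove == 0L) return(network)
  e <- network$edges
  cand <- which(e$origin == "native" & abs(e$j - e$i) >= 4L)
  n_remove <- min(n_remove, length(cand))
  pick <- with_seed(seed, sample(cand, n_remove))
  suppressWarnings(
    modify_network(network, remove = cbind(e$i[pick], e$j[pick])))
}

#' Materialize a synthetic benchmark corpus
#'
#' Generates a mixed set of hinge and loop pairs (alternating), writes
#' optional fixture PDB and ground-truth label files, and returns the
#' in-memory corpus used by the classifier tests.
#'
#' @param n_pairs number of conformation pairs (default 20).
#' @param seed corpus seed; pair k uses \code{seed + k}.
#' @param dir optional output directory for PDB + label TSV fixtures.
#' @param with_features compute \code{\link{contact_features}} per protein
#'   (default TRUE; needed for classifier work).
#' @param r_c,e_c contact parameters.
#' @return list of corpus entries (id, kind, pair, tmap, structure,
#'   features).
#' @export
make_corpus <- function(n_pairs = 20L, seed = 1L, dir = NULL,
                        with_features = TRUE, r_c = 10, e_c = 0.09) {
  corpus <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    kind <- if (k %% 2L == 1L) "hinge" else "loop"
    gen <- if (kind == "hinge")
      make_hinge_pair(seed = seed + k, r_c = r_c, e_c = e_c)
    else
      make_loop_pair(seed = seed + k, r_c = r_c, e_c = e_c)
    st <- gen$pair$start
    entry <- list(id = sprintf("%s_%03d", kind, k), kind = kind,
                  pair = gen$pair, tmap = gen$tmap, structure = st)
    if (with_features) {
      cmap <- build_contact_map(st, r_c = r_c)
      entry$features <- contact_features(st, cmap, min_sep = 4L)
      entry$cmap <- cmap
    }
    if (!is.null(dir)) {
      write_ca_structure(st, file.path(dir, paste0(entry$id, "_start.pdb")))
      write_ca_structure(gen$pair$end,
                         file.path(dir, paste0(entry$id, "_end.pdb")))
      utils::write.table(transition_table(gen$tmap),
                         file.path(dir, paste0(entry$id, "_labels.tsv")),
                         quote = FALSE, row.names = FALSE, sep = "\t")
    }
    corpus[[k]] <- entry
  }
  corpus
}
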