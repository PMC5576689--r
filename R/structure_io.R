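# Calpha-level structure input/output, residue correspondence and
# superposition.

#' Construct a Calpha structure object
#'
#' Low-level constructor for the coarse-grained structure container used
#' throughout the package: one record per residue, represented by its
#' Calpha atom.
#'
#' @param coords numeric N x 3 matrix of Calpha coordinates (Angstrom).
#' @param resno integer vector of author residue numbers (insertion codes
#'   may be appended, e.g. "52A"); defaults to 1..N.
#' @param resid character vector of 3-letter residue names.
#' @param chain single chain identifier.
#' @param b numeric vector of B-factors (Angstrom^2).
#' @param sse per-residue secondary-structure labels in \code{c("H","E","C")},
#'   or \code{NULL} if not yet assigned.
#' @param annotations named list of optional per-residue annotations
#'   (conservation, depth, pocket, symmetry, ...).
#' @param resolution crystallographic resolution (Angstrom) or \code{NA}.
#' @return an object of class \code{"ca_structure"}.
#' @export
ca_structure <- function(coords, resno = NULL, resid = NULL, chain = "A",
                         b = NULL, sse = NULL, annotations = list(),
                         resolution = NA_real_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 1L) stop("empty structure")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  resno <- resno %||% seq_len(n)
  resid <- resid %||% rep("ALA", n)
  b <- b %||% rep(0, n)
  if (!is.null(sse)) {
    sse <- as.character(sse)
    if (length(sse) != n || !all(sse %in% c("H", "E", "C")))
      stop("sse labels must be H/E/C, one per residue")
  }
  structure(list(coords = coords, resno = resno, resid = as.character(resid),
                 chain = chain, b = as.numeric(b), sse = sse,
                 annotations = annotations, resolution = resolution),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("Calpha structure: %d residues, chain %s%s\n",
              nrow(x$coords), x$chain,
              if (is.na(x$resolution)) "" else
                sprintf(", resolution %.2f A", x$resolution)))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a \code{ca_structure}.
#' @return integer residue count.
#' @export
n_residues <- function(structure) nrow(structure$coords)

#' Read a Calpha trace from a PDB file
#'
#' Parses one chain of a PDB file at the Calpha level. Only residues with a
#' Calpha atom are kept (others are dropped with a message); alternate
#' locations are resolved to the highest-occupancy conformer, ties broken by
#' altloc letter order. The header resolution (REMARK 2) is captured when
#' present.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier to extract.
#' @return a \code{\link{ca_structure}}.
#' @export
read_ca_structure <- function(path, chain) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain not found: ", chain)
  n_res_all <- length(unique(paste(at$resno, at$insert)))
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("empty structure: no Calpha atoms in chain ", chain)
  key <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  if (anyDuplicated(key)) {
    # altloc resolution: highest occupancy, ties by altloc letter order
    keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, unique(key))),
                          function(idx) {
      o <- ca$o[idx]
      o[is.na(o)] <- 1
      alt <- ifelse(is.na(ca$alt[idx]), "", ca$alt[idx])
      idx[order(-o, alt)][1L]
    }), use.names = FALSE)
    ca <- ca[sort(keep), , drop = FALSE]
  }
  if (nrow(ca) < n_res_all)
    message(sprintf("read_ca_structure: dropped %d residue(s) without Calpha",
                    n_res_all - nrow(ca)))
  resno <- ifelse(is.na(ca$insert) | ca$insert == "",
                  as.character(ca$resno), paste0(ca$resno, ca$insert))
  ca_structure(coords = cbind(ca$x, ca$y, ca$z), resno = resno,
               resid = ca$resid, chain = chain, b = ca$b,
               resolution = read_pdb_resolution(path))
}

# REMARK 2 resolution line; NA when absent (e.g. NMR entries, fixtures).
read_pdb_resolution <- function(path) {
  ln <- grep("^REMARK   2 RESOLUTION", readLines(path, warn = FALSE),
             value = TRUE)
  if (length(ln) == 0L) return(NA_real_)
  m <- regmatches(ln[1L], regexpr("[0-9]+\\.[0-9]+", ln[1L]))
  if (length(m) == 0L) NA_real_ else as.numeric(m)
}

#' Write a Calpha structure as a minimal PDB file
#'
#' @param structure a \code{\link{ca_structure}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_ca_structure <- function(structure, path) {
  n <- n_residues(structure)
  resno <- suppressWarnings(as.integer(structure$resno))
  resno[is.na(resno)] <- seq_len(n)[is.na(resno)]
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$coords)),
                   resno = resno,
                   resid = structure$resid,
                   chain = rep(structure$chain, n),
                   elety = rep("CA", n),
                   b = structure$b, o = rep(1, n))
  invisible(path)
}

#' Detect chain breaks in a Calpha trace
#'
#' A break is flagged between consecutive residues whose Calpha-Calpha
#' distance exceeds 4.2 Angstrom (strict inequality).
#'
#' @param structure a \code{\link{ca_structure}} with at least two residues.
#' @param threshold break distance in Angstrom (default 4.2).
#' @return integer vector of positions \code{i} such that the break lies
#'   between residues \code{i} and \code{i + 1}; empty when the chain is
#'   continuous.
#' @export
detect_chain_breaks <- function(structure, threshold = 4.2) {
  xyz <- structure$coords
  if (nrow(xyz) < 2L) stop("need at least 2 residues")
  d <- sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                     xyz[-nrow(xyz), , drop = FALSE])^2))
  which(d > threshold)
}

# 3-letter -> 1-letter residue codes; unknowns become X.
aa_one_letter <- function(resid) {
  a <- bio3d::aa321(resid)
  a[is.na(a) | !(a %in% LETTERS)] <- "X"
  a
}

# Global Needleman-Wunsch correspondence between two residue sequences
# (match +1, mismatch -1, linear gap -2). Returns a 2-column matrix of
# matched (iS, iE) positions, strictly increasing in both columns.
align_residues <- function(seq_s, seq_e) {
  letters_all <- sort(unique(c(seq_s, seq_e)))
  sub <- matrix(-1, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = paste(seq_s, collapse = ""),
    subject = paste(seq_e, collapse = ""),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  is_ <- cumsum(ap != "-")
  ie_ <- cumsum(as_ != "-")
  keep <- ap != "-" & as_ != "-"
  cbind(iS = is_[keep], iE = ie_[keep])
}

# Least-squares rigid superposition (Kabsch, SVD form) of `mobile` onto
# `fixed` (both M x 3, row-matched). Returns the transformed coordinates.
kabsch_superpose <- function(fixed, mobile, apply_to = mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  A <- crossprod(sweep(mobile, 2, cm), sweep(fixed, 2, cf))
  s <- svd(A)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t(R %*% (t(apply_to) - cm)) + matrix(cf, nrow(apply_to), 3, byrow = TRUE)
}

#' Pair two conformations of a protein
#'
#' Computes the residue correspondence between a start (unbound) and end
#' (bound) conformation by global sequence alignment, rigid-body superposes
#' the end conformation onto the start over all matched Calpha pairs
#' (least-squares), and records the per-residue displacement field
#' \eqn{\Delta r_i = r_i^S - r_i^E}.
#'
#' @param start,end \code{\link{ca_structure}} objects.
#' @return an object of class \code{"conformation_pair"} with elements
#'   \code{start}, \code{end} (end coordinates superposed), \code{corr}
#'   (2-column matched-index matrix), \code{rmsd} (Angstrom), \code{disp}
#'   (matched x 3 displacement matrix) and the two header resolutions.
#' @export
build_pair <- function(start, end) {
  if (n_residues(start) < 1L || n_residues(end) < 1L)
    stop("empty structure")
  corr <- align_residues(aa_one_letter(start$resid), aa_one_letter(end$resid))
  if (nrow(corr) < 2L) stop("no correspondence")
  fixed <- start$coords[corr[, 1L], , drop = FALSE]
  mob <- end$coords[corr[, 2L], , drop = FALSE]
  end_fit <- end
  end_fit$coords <- kabsch_superpose(fixed, mob, apply_to = end$coords)
  disp <- fixed - end_fit$coords[corr[, 2L], , drop = FALSE]
  structure(list(start = start, end = end_fit, corr = corr,
                 rmsd = sqrt(mean(rowSums(disp^2))), disp = disp,
                 resolution_start = start$resolution,
                 resolution_end = end$resolution),
            class = "conformation_pair")
}

#' @export
print.conformation_pair <- function(x, ...) {
  cat(sprintf("Conformation pair: %d matched residues, rmsd %.3f A\n",
              nrow(x$corr), x$rmsd))
  invisible(x)
}

#' Displacement field of a pair as a 3M vector
#' @param pair a \code{\link{build_pair}} result.
#' @return numeric vector of length 3 x matched residues (x,y,z interleaved
#'   per residue).
#' @export
displacement_vector <- function(pair) as.vector(t(pair$disp))

#' Assign three-state secondary structure
#'
#' When \code{backend} supplies labels (a character vector of per-residue
#' 8- or 3-state codes, or a function of the structure returning one) they
#' are collapsed to \code{H/E/C} and used. Otherwise a geometric assignment
#' from Calpha i to i+3 / i+4 distance patterns is applied: helical windows
#' have d(i,i+3) in [4.4, 6.2] and d(i,i+4) in [4.8, 6.8] Angstrom;
#' extended windows have d(i,i+3) >= 9.0 Angstrom. Runs of H or E shorter
#' than three residues are relabeled to coil.
#'
#' @param structure a \code{\link{ca_structure}}.
#' @param backend optional external assignment (vector or function); on
#'   failure the geometric fallback is used with a warning.
#' @return the structure with \code{$sse} filled.
#' @export
assign_sse <- function(structure, backend = NULL) {
  n <- n_residues(structure)
  lab <- NULL
  if (!is.null(backend)) {
    lab <- tryCatch({
      raw <- if (is.function(backend)) backend(structure) else backend
      raw <- toupper(as.character(raw))
      if (length(raw) != n) stop("backend returned ", length(raw), " labels")
      out <- rep("C", n)
      out[raw %in% c("H", "G", "I")] <- "H"
      out[raw %in% c("E", "B")] <- "E"
      out
    }, error = function(e) {
      warning("secondary-structure backend failed (", conditionMessage(e),
              "); using geometric fallback", call. = FALSE)
      NULL
    })
  }
  if (is.null(lab)) lab <- sse_geometric(structure$coords)
  structure$sse <- lab
  structure
}

# Geometric 3-state assignment from Calpha distances alone.
sse_geometric <- function(xyz) {
  n <- nrow(xyz)
  lab <- rep("C", n)
  if (n >= 5L) {
    for (i in seq_len(n - 4L)) {
      d3 <- sqrt(sum((xyz[i + 3L, ] - xyz[i, ])^2))
      d4 <- sqrt(sum((xyz[i + 4L, ] - xyz[i, ])^2))
      if (d3 >= 4.4 && d3 <= 6.2 && d4 >= 4.8 && d4 <= 6.8)
        lab[i:(i + 4L)] <- "H"
    }
  }
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      if (any(lab[i:(i + 3L)] == "H")) next
      d3 <- sqrt(sum((xyz[i + 3L, ] - xyz[i, ])^2))
      if (d3 >= 9.0) lab[i:(i + 3L)] <- "E"
    }
  }
  enforce_min_run(lab, 3L)
}

# Relabel H/E runs shorter than min_len to coil.
enforce_min_run <- function(lab, min_len) {
  r <- rle(lab)
  short <- r$values %in% c("H", "E") & r$lengths < min_len
  r$values[short] <- "C"
  inverse.rle(r)
}
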