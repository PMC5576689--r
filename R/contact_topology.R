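# Binary contact maps and contact-transition labeling between two
# conformations.

#' Build a binary Calpha contact map
#'
#' Residues \code{i != j} are in contact when their Calpha-Calpha distance
#' is at most \code{r_c} (boundary inclusive).
#'
#' @param structure a \code{\link{ca_structure}} with at least two residues.
#' @param r_c distance cutoff in Angstrom (default 10).
#' @return object of class \code{"contact_map"}: list with the symmetric
#'   binary matrix \code{C}, the distance matrix \code{D} (Angstrom) and
#'   \code{r_c}.
#' @export
build_contact_map <- function(structure, r_c = 10) {
  stopifnot_scalar(r_c, "r_c")
  if (r_c <= 0) stop("r_c must be positive")
  if (n_residues(structure) < 2L) stop("need at least 2 residues")
  D <- coord_dist(structure$coords)
  C <- (D <= r_c) * 1L
  diag(C) <- 0L
  structure(list(C = C, D = D, r_c = r_c), class = "contact_map")
}

#' List the contacts of a contact map
#' @param cmap a \code{\link{build_contact_map}} result.
#' @param min_sep minimum sequence separation \code{|i - j|} (default 0).
#' @return 2-column integer matrix of pairs with \code{i < j}.
#' @export
contact_pairs <- function(cmap, min_sep = 0L) {
  idx <- which(upper.tri(cmap$C) & cmap$C == 1L, arr.ind = TRUE)
  idx <- idx[abs(idx[, 1L] - idx[, 2L]) >= min_sep, , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Label contact transitions between two conformations
#'
#' For every residue pair matched in both conformations, start contacts are
#' labeled \emph{maintained} when the contact strain
#' \eqn{e_{ij} = |d^S_{ij} - d^E_{ij}| / d^S_{ij}} stays within the
#' extension threshold \code{e_c} and \emph{breaking} otherwise (stretch
#' and compression both count); pairs in contact only in the end
#' conformation are \emph{forming}. Pairs involving unmatched residues are
#' labeled \code{none} and excluded from all denominators.
#'
#' @param pair a \code{\link{build_pair}} result.
#' @param r_c contact cutoff in Angstrom (default 10).
#' @param e_c extension threshold as a fraction of the start distance
#'   (default 0.09, the data-set optimum of the method).
#' @return object of class \code{"transition_map"}: list with the label
#'   matrix \code{T} (levels maintained/breaking/forming/none, indices of
#'   the start structure), strain matrix \code{E} (defined where the start
#'   conformation has a contact between matched residues), \code{r_c},
#'   \code{e_c} and \code{matched} (start indices with a correspondent).
#' @export
classify_transitions <- function(pair, r_c = 10, e_c = 0.09) {
  nS <- n_residues(pair$start)
  if (nrow(pair$corr) < 2L) stop("need at least 2 matched residues")
  iS <- pair$corr[, 1L]
  iE <- pair$corr[, 2L]
  DS_full <- coord_dist(pair$start$coords)
  dS <- DS_full[iS, iS, drop = FALSE]
  dE <- coord_dist(pair$end$coords[iE, , drop = FALSE])
  CS <- (dS <= r_c) * 1L; diag(CS) <- 0L
  CE <- (dE <= r_c) * 1L; diag(CE) <- 0L
  n_unmatched <- nS - length(iS)
  if (n_unmatched > 0L)
    message(sprintf("classify_transitions: %d unmatched residue(s) labeled none",
                    n_unmatched))
  strain <- abs(dS - dE) / dS
  diag(strain) <- NA_real_
  lab <- matrix("none", length(iS), length(iS))
  lab[CS == 1L & strain <= e_c] <- "maintained"
  lab[CS == 1L & strain > e_c] <- "breaking"
  lab[CS == 0L & CE == 1L] <- "forming"
  diag(lab) <- "none"
  # embed back into full start indexing
  Tm <- matrix("none", nS, nS)
  Tm[iS, iS] <- lab
  Em <- matrix(NA_real_, nS, nS)
  keep <- CS == 1L
  strain[!keep] <- NA_real_
  Em[iS, iS] <- strain
  structure(list(T = Tm, E = Em, r_c = r_c, e_c = e_c, matched = iS),
            class = "transition_map")
}

#' Extract labeled pairs from a transition map
#' @param tmap a \code{\link{classify_transitions}} result.
#' @param label one of \code{"maintained"}, \code{"breaking"},
#'   \code{"forming"}.
#' @param min_sep minimum sequence separation (default 0).
#' @return 2-column integer matrix (\code{i < j}) of pairs with that label.
#' @export
transition_pairs <- function(tmap, label, min_sep = 0L) {
  idx <- which(upper.tri(tmap$T) & tmap$T == label, arr.ind = TRUE)
  idx <- idx[abs(idx[, 1L] - idx[, 2L]) >= min_sep, , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Summarize transition counts
#'
#' Counts and fractions of each transition label over pairs with sequence
#' separation at least \code{min_sep}. The breaking fraction (breaking over
#' start contacts) is the per-protein statistic the classifier's class
#' imbalance is quoted in.
#'
#' @param tmap a \code{\link{classify_transitions}} result.
#' @param min_sep minimum \code{|i - j|} (default 0).
#' @return list with \code{counts} (named integer vector), \code{n_start_contacts}
#'   and \code{fractions} (labels over start contacts for maintained /
#'   breaking, over all labeled pairs for forming).
#' @export
transition_counts <- function(tmap, min_sep = 0L) {
  if (min_sep < 0L) stop("min_sep must be >= 0")
  counts <- vapply(c(maintained = "maintained", breaking = "breaking",
                     forming = "forming"),
                   function(l) nrow(transition_pairs(tmap, l, min_sep)),
                   integer(1L))
  n_start <- counts[["maintained"]] + counts[["breaking"]]
  fr <- c(maintained = if (n_start > 0) counts[["maintained"]] / n_start else NA_real_,
          breaking = if (n_start > 0) counts[["breaking"]] / n_start else NA_real_)
  list(counts = counts, n_start_contacts = n_start, fractions = fr)
}

#' Export a transition map as a long table
#' @param tmap a \code{\link{classify_transitions}} result.
#' @param min_sep minimum sequence separation (default 0).
#' @return data.frame with columns \code{i}, \code{j}, \code{label},
#'   \code{strain}.
#' @export
transition_table <- function(tmap, min_sep = 0L) {
  rows <- lapply(c("maintained", "breaking", "forming"), function(l) {
    p <- transition_pairs(tmap, l, min_sep)
    if (nrow(p) == 0L) return(NULL)
    data.frame(i = p[, 1L], j = p[, 2L], label = l,
               strain = tmap$E[p])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(i = integer(), j = integer(), label = character(),
                      strain = numeric())
  out[order(out$i, out$j), , drop = FALSE]
}
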