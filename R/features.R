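# Contact feature extraction: immediate-neighborhood graph, secondary-
# structure-element graph, and the 170-entry feature vector in seven
# blocks (pairwise 63, graph topology 10, graph spectrum 5, single node
# 12, node label statistics 57, edge label statistics 13, whole protein
# 10). Features whose source annotation is unavailable are reported with
# an availability mask so downstream standardization can neutralize them.

# residue chemical classes (coarse 4-way grouping)
CHEM_CLASSES <- c("hydrophobic", "polar", "charged", "special")
chem_class <- function(resid) {
  hydro <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO", "GLY")
  polar <- c("SER", "THR", "CYS", "TYR", "ASN", "GLN")
  charged <- c("ASP", "GLU", "LYS", "ARG", "HIS")
  ifelse(resid %in% hydro, "hydrophobic",
         ifelse(resid %in% polar, "polar",
                ifelse(resid %in% charged, "charged", "special")))
}

# Consensus hydrophobicity per residue type, used as a per-residue
# solvation-energy surrogate (higher = more hydrophobic).
SOLVATION_SCALE <- c(ALA = 0.62, ARG = -2.53, ASN = -0.78, ASP = -0.90,
  CYS = 0.29, GLN = -0.85, GLU = -0.74, GLY = 0.48, HIS = -0.40,
  ILE = 1.38, LEU = 1.06, LYS = -1.50, MET = 0.64, PHE = 1.19,
  PRO = 0.12, SER = -0.18, THR = -0.05, TRP = 0.81, TYR = 0.26,
  VAL = 1.08)
solvation_value <- function(resid) {
  v <- SOLVATION_SCALE[resid]
  v[is.na(v)] <- 0
  unname(v)
}

#' Feature vector layout
#'
#' Names and block membership of the 170 features emitted by
#' \code{\link{feature_vector}}.
#'
#' @return data.frame with columns \code{name} and \code{block}; block
#'   sizes are (pairwise 63, graph_topology 10, graph_spectrum 5,
#'   single_node 12, node_stats 57, edge_stats 13, whole_protein 10).
#' @export
feature_layout <- function() {
  pw <- c(paste0("sse_i_", c("H", "E", "C")), paste0("sse_j_", c("H", "E", "C")),
          paste0("sse_pair_", c("HH", "HE", "HC", "EE", "EC", "CC")),
          "intra_sse", "seq_sep", "sse_seq_sep", "sse_centroid_dist",
          "contact_dist", "rel_pos_i", "rel_pos_j",
          "terminal_sse_i", "terminal_sse_j", "sse_len_i", "sse_len_j",
          "intra_contacts_i", "intra_contacts_j", "interface_contacts",
          "interface_density", "degree_i", "degree_j",
          "b_factor_i", "b_factor_j", "term_sep_i", "term_sep_j",
          paste0("chem_i_", CHEM_CLASSES), paste0("chem_j_", CHEM_CLASSES),
          "hbond", "sidechain_contact", "pocket_contact",
          "pocket_atom_contacts",
          paste0("pocket_", c("polarity", "hydrophobicity", "volume",
                              "drug_score")),
          "symmetric_i", "symmetric_j", "symmetry_plane_dist",
          "symmetry_coverage_sse_i", "symmetry_coverage_sse_j",
          paste0("contact_depth_bin_", 1:4), paste0("depth_diff_bin_", 1:4),
          "mutual_information")
  gt <- paste0("in_", c("n_nodes", "n_edges", "avg_degree_centrality",
                        "avg_closeness", "avg_betweenness", "radius",
                        "diameter", "avg_eccentricity", "n_endpoints",
                        "avg_clustering"))
  gs <- paste0("in_", c("eig1", "eig2", "n_distinct_eig", "eig_sum",
                        "eig_energy"))
  sn <- c(paste0(c("node_degree", "node_closeness", "node_betweenness",
                   "node_term_sep", "conservation", "nbhd_conservation"),
                 "_i"),
          paste0(c("node_degree", "node_closeness", "node_betweenness",
                   "node_term_sep", "conservation", "nbhd_conservation"),
                 "_j"))
  nl <- c(paste0("nl_chem_frac_", CHEM_CLASSES), "nl_chem_entropy",
          paste0("nl_sse_frac_", c("H", "E", "C")), "nl_sse_entropy",
          paste0("nl_acc_frac_", c("buried", "intermediate", "exposed")),
          "nl_acc_mean", "nl_hbond_frac", "nl_solv_mean",
          paste0("nl_solv_bin_", 1:4), "nl_label_entropy", "nl_impurity",
          "nl_centroid_dist_mean", "nl_centroid_dist_sd",
          "nl_sym_coverage", "nl_sym_degree_mean",
          "nl_depth_mean", paste0("nl_depth_bin_", 1:5),
          "nl_hse_up_mean", "nl_hse_down_mean",
          paste0("nl_hse_ratio_bin_", 1:5),
          "nl_cons_mean", paste0("nl_cons_bin_", 1:5), "nl_cons_nbhd_mean",
          "nl_degree_mean", "nl_degree_sd", "nl_degree_min",
          "nl_degree_max", "nl_b_mean", "nl_b_sd", "nl_solv_sd",
          "nl_depth_sd", "nl_cons_sd", "nl_hbond_count_mean",
          "nl_sse_runlen_mean", "nl_terminal_frac")
  el <- c("el_link_impurity", paste0("el_mi_bin_", 1:5), "el_mi_cum",
          "el_mi_mean", "el_hbond_frac", "el_dist_mean", "el_dist_sd",
          "el_longrange_frac", "el_intra_sse_frac")
  wp <- c(paste0("wp_sse_frac_", c("H", "E", "C")),
          paste0("wp_conn_bin_", 1:5), "wp_sym_coverage",
          "wp_contact_density")
  data.frame(
    name = c(pw, gt, gs, sn, nl, el, wp),
    block = rep(c("pairwise", "graph_topology", "graph_spectrum",
                  "single_node", "node_stats", "edge_stats",
                  "whole_protein"),
                c(length(pw), length(gt), length(gs), length(sn),
                  length(nl), length(el), length(wp))),
    stringsAsFactors = FALSE)
}

#' Immediate neighborhood graph of a contact
#'
#' Node set: the contact residues i and j, their sequence neighbors
#' (i, j +/- 1), all residues in contact with i or j, and additionally
#' i +/- 4 (j +/- 4) when the residue is helical (one helix turn away).
#' Edges are the contacts induced on the node set. Out-of-range indices
#' at the termini are omitted.
#'
#' @param contact integer pair \code{c(i, j)}, a contact of \code{cmap}.
#' @param cmap a \code{\link{build_contact_map}} result.
#' @param structure the underlying \code{\link{ca_structure}} (needs
#'   \code{sse} for the helix rule; coil assumed when absent).
#' @return list with \code{nodes} (sorted indices), \code{edges}
#'   (2-column matrix over node indices) and \code{contact}.
#' @export
neighborhood_graph <- function(contact, cmap, structure) {
  i <- as.integer(contact[1L]); j <- as.integer(contact[2L])
  if (cmap$C[i, j] != 1L) stop("(i, j) is not a contact of the map")
  n <- nrow(cmap$C)
  sse <- structure$sse %||% rep("C", n)
  nodes <- c(i, j, i - 1L, i + 1L, j - 1L, j + 1L,
             which(cmap$C[i, ] == 1L), which(cmap$C[j, ] == 1L))
  if (sse[i] == "H") nodes <- c(nodes, i - 4L, i + 4L)
  if (sse[j] == "H") nodes <- c(nodes, j - 4L, j + 4L)
  nodes <- sort(unique(nodes[nodes >= 1L & nodes <= n]))
  sub <- cmap$C[nodes, nodes, drop = FALSE]
  ed <- which(upper.tri(sub) & sub == 1L, arr.ind = TRUE)
  edges <- cbind(nodes[ed[, 1L]], nodes[ed[, 2L]])
  colnames(edges) <- c("i", "j")
  list(nodes = nodes, edges = edges, contact = c(i, j))
}

#' Secondary-structure-element graph
#'
#' Segments the chain into maximal runs of the per-residue labels (H/E
#' runs shorter than three residues are relabeled coil before
#' segmentation), then connects two segments when they share at least one
#' residue-residue contact.
#'
#' @param structure a \code{\link{ca_structure}} with \code{sse} assigned
#'   (assigned geometrically when absent).
#' @param cmap a \code{\link{build_contact_map}} result.
#' @return list with \code{segments} (data.frame type/start/end/length),
#'   \code{seg_of} (per-residue segment id), \code{edges} (2-column matrix
#'   of segment pairs in contact) and \code{interface} (contact count per
#'   segment pair, named "a_b").
#' @export
sse_graph <- function(structure, cmap) {
  n <- n_residues(structure)
  sse <- structure$sse
  if (is.null(sse)) sse <- assign_sse(structure)$sse
  sse <- enforce_min_run(sse, 3L)
  r <- rle(sse)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  segments <- data.frame(type = r$values, start = start, end = end,
                         length = r$lengths, stringsAsFactors = FALSE)
  seg_of <- rep(seq_along(r$values), r$lengths)
  cp <- contact_pairs(cmap)
  a <- seg_of[cp[, 1L]]; b <- seg_of[cp[, 2L]]
  inter <- a != b
  key <- paste(pmin(a, b), pmax(a, b), sep = "_")
  interface <- table(key[inter])
  edges <- unique(cbind(pmin(a, b)[inter], pmax(a, b)[inter]))
  colnames(edges) <- c("a", "b")
  list(segments = segments, seg_of = seg_of, edges = edges,
       interface = interface)
}

#' Topology and spectrum descriptors of a neighborhood graph
#'
#' Ten topology descriptors (node and edge counts, normalized degree /
#' closeness / betweenness centrality averages, radius, diameter, average
#' eccentricity, end-point count, average local clustering) and five
#' spectral descriptors of the unlabeled adjacency matrix (two largest
#' eigenvalues, number of distinct eigenvalues, eigenvalue sum, graph
#' energy). Path lengths are computed on the component containing the
#' contact.
#'
#' @param graph a \code{\link{neighborhood_graph}} result.
#' @return list with \code{topology} (10 named values) and
#'   \code{spectrum} (5 named values).
#' @export
graph_features <- function(graph) {
  nodes <- graph$nodes
  nn <- length(nodes)
  id <- match(c(graph$edges[, 1L], graph$edges[, 2L]), nodes)
  g <- igraph::make_empty_graph(n = nn, directed = FALSE)
  if (nrow(graph$edges) > 0L)
    g <- igraph::add_edges(g, rbind(id[seq_len(nrow(graph$edges))],
                                    id[-seq_len(nrow(graph$edges))]))
  deg <- igraph::degree(g)
  clo <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  clo[!is.finite(clo)] <- 0
  btw <- igraph::betweenness(g, normalized = nn > 2L)
  comp <- igraph::components(g)
  core <- which(comp$membership == comp$membership[match(graph$contact[1L],
                                                         nodes)])
  sub <- igraph::induced_subgraph(g, core)
  ecc <- igraph::eccentricity(sub)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  topology <- c(n_nodes = nn, n_edges = nrow(graph$edges),
                avg_degree_centrality = mean(deg) / max(1L, nn - 1L),
                avg_closeness = mean(clo), avg_betweenness = mean(btw),
                radius = min(ecc), diameter = max(ecc),
                avg_eccentricity = mean(ecc),
                n_endpoints = sum(deg == 1L), avg_clustering = mean(cc))
  A <- matrix(0, nn, nn)
  if (nrow(graph$edges) > 0L) {
    ii <- match(graph$edges[, 1L], nodes); jj <- match(graph$edges[, 2L], nodes)
    A[cbind(ii, jj)] <- 1; A[cbind(jj, ii)] <- 1
  }
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  spectrum <- c(eig1 = ev[1L], eig2 = if (nn >= 2L) ev[2L] else 0,
                n_distinct_eig = length(unique(round(ev, 8L))),
                eig_sum = sum(ev), eig_energy = sum(abs(ev)))
  list(topology = topology, spectrum = spectrum)
}

# ---- per-structure context shared by all contacts -----------------------

# Geometric Calpha-level hydrogen-bond surrogate: helical i,i+3/i+4
# pattern or cross-strand proximity.
hbond_surrogate <- function(structure, cmap) {
  n <- n_residues(structure)
  sse <- structure$sse %||% rep("C", n)
  D <- cmap$D
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  hb <- (outer(sse == "H", sse == "H", "&") & sep %in% 3:4 & D <= 6.8) |
        (outer(sse == "E", sse == "E", "&") & sep > 2L & D <= 5.5)
  diag(hb) <- FALSE
  hb | t(hb)
}

# Calpha half-sphere exposure: split a residue's 10-Angstrom neighbors by
# the plane normal to the local backbone bisector.
hse_ca <- function(structure, radius = 10) {
  xyz <- structure$coords
  n <- nrow(xyz)
  D <- coord_dist(xyz)
  up <- integer(n); down <- integer(n)
  for (i in seq_len(n)) {
    vs <- rbind(if (i > 1L) xyz[i - 1L, ] - xyz[i, ],
                if (i < n) xyz[i + 1L, ] - xyz[i, ])
    u <- -colSums(vs)
    nu <- sqrt(sum(u^2))
    u <- if (nu > 0) u / nu else c(0, 0, 1)
    nb <- which(D[i, ] <= radius & seq_len(n) != i)
    side <- (xyz[nb, , drop = FALSE] -
             matrix(xyz[i, ], length(nb), 3L, byrow = TRUE)) %*% u
    up[i] <- sum(side > 0)
    down[i] <- length(nb) - up[i]
  }
  list(up = up, down = down, ratio = up / pmax(1L, up + down))
}

# Precompute everything that does not depend on the individual contact.
structure_context <- function(structure, cmap, annotations = NULL) {
  n <- n_residues(structure)
  if (is.null(structure$sse)) structure <- assign_sse(structure)
  ann <- annotations %||% structure$annotations %||% list()
  sg <- sse_graph(structure, cmap)
  centroid <- colMeans(structure$coords)
  cdist <- sqrt(rowSums(sweep(structure$coords, 2L, centroid)^2))
  nb_count <- rowSums(cmap$C)
  acc_class <- cut(nb_count, c(-Inf, 6.5, 11.5, Inf),
                   labels = c("exposed", "intermediate", "buried"))
  hse <- hse_ca(structure)
  n_contacts <- nrow(contact_pairs(cmap))
  conn_bin <- cut(n_contacts / n, c(-Inf, 3.5, 4.5, 5.5, 6.5, Inf),
                  labels = FALSE)
  seg_len_of <- sg$segments$length[sg$seg_of]
  terminal_seg <- sg$seg_of %in% c(1L, nrow(sg$segments))
  list(structure = structure, cmap = cmap, ann = ann, sg = sg,
       sse = structure$sse, chem = chem_class(structure$resid),
       solv = solvation_value(structure$resid),
       cdist = cdist, nb_count = nb_count, acc_class = as.character(acc_class),
       acc_value = 1 - nb_count / max(1, max(nb_count)),
       hse = hse, hbond = hbond_surrogate(structure, cmap),
       n_contacts = n_contacts, conn_bin = conn_bin,
       seg_len_of = seg_len_of, terminal_seg = terminal_seg,
       term_sep = pmin(seq_len(n) - 1L, n - seq_len(n)),
       rel_pos = (seq_len(n) - 1L) / max(1L, n - 1L))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log(p))
}

bin_fractions <- function(x, breaks) {
  b <- cut(x, breaks, labels = FALSE, include.lowest = TRUE)
  tabulate(b, nbins = length(breaks) - 1L) / length(x)
}

#' Feature vector of one contact
#'
#' Emits the 170 features of \code{\link{feature_layout}} for a single
#' contact, together with an availability mask. Features that need an
#' annotation not present (conservation, mutual information, pocket
#' membership and descriptors, residue depth, symmetry, side-chain
#' contacts) are masked; structural, topological, spectral and
#' surrogate-based features are always available. Values are raw;
#' standardization (and the masked-to-zero convention) is applied by the
#' classifier with statistics fit on its training corpus.
#'
#' @param contact integer pair \code{c(i, j)}.
#' @param structure a \code{\link{ca_structure}}.
#' @param cmap a \code{\link{build_contact_map}} result.
#' @param context optional precomputed \code{structure_context}; computed
#'   on the fly when absent (pass one when extracting many contacts).
#' @param annotations optional named list of annotation tables overriding
#'   \code{structure$annotations}.
#' @return list with \code{values} (named numeric, length 170) and
#'   \code{mask} (named logical, length 170).
#' @export
feature_vector <- function(contact, structure, cmap, context = NULL,
                           annotations = NULL) {
  ctx <- context %||% structure_context(structure, cmap, annotations)
  lay <- feature_layout()
  v <- stats::setNames(numeric(nrow(lay)), lay$name)
  m <- stats::setNames(rep(TRUE, nrow(lay)), lay$name)
  i <- contact[1L]; j <- contact[2L]
  n <- n_residues(ctx$structure)
  sse <- ctx$sse; sg <- ctx$sg; ann <- ctx$ann
  si <- sg$seg_of[i]; sj <- sg$seg_of[j]

  set <- function(name, val) v[name] <<- as.numeric(val)
  mask_off <- function(names) m[names] <<- FALSE

  ## ---- pairwise block -------------------------------------------------
  set(paste0("sse_i_", sse[i]), 1)
  set(paste0("sse_j_", sse[j]), 1)
  pc <- paste(sort(c(sse[i], sse[j]), decreasing = FALSE), collapse = "")
  pc <- chartr("CE", "CE", pc)
  pair_key <- c(CC = "CC", CE = "EC", CH = "HC", EE = "EE", EH = "HE",
                HH = "HH")[pc]
  set(paste0("sse_pair_", pair_key), 1)
  set("intra_sse", si == sj)
  set("seq_sep", abs(j - i))
  set("sse_seq_sep", abs(sj - si))
  ci <- colMeans(ctx$structure$coords[sg$segments$start[si]:sg$segments$end[si], ,
                                      drop = FALSE])
  cj <- colMeans(ctx$structure$coords[sg$segments$start[sj]:sg$segments$end[sj], ,
                                      drop = FALSE])
  set("sse_centroid_dist", sqrt(sum((ci - cj)^2)))
  set("contact_dist", cmap$D[i, j])
  set("rel_pos_i", ctx$rel_pos[i]); set("rel_pos_j", ctx$rel_pos[j])
  set("terminal_sse_i", ctx$terminal_seg[i])
  set("terminal_sse_j", ctx$terminal_seg[j])
  set("sse_len_i", ctx$seg_len_of[i]); set("sse_len_j", ctx$seg_len_of[j])
  intra_ct <- function(s) {
    idx <- sg$segments$start[s]:sg$segments$end[s]
    sum(cmap$C[idx, idx]) / 2
  }
  set("intra_contacts_i", intra_ct(si)); set("intra_contacts_j", intra_ct(sj))
  if (si == sj) {
    set("interface_contacts", intra_ct(si))
    set("interface_density", intra_ct(si) / ctx$seg_len_of[i]^2)
  } else {
    key <- paste(min(si, sj), max(si, sj), sep = "_")
    ic <- if (key %in% names(sg$interface)) as.numeric(sg$interface[[key]]) else 0
    set("interface_contacts", ic)
    set("interface_density",
        ic / (sg$segments$length[si] * sg$segments$length[sj]))
  }
  set("degree_i", ctx$nb_count[i]); set("degree_j", ctx$nb_count[j])
  set("b_factor_i", ctx$structure$b[i]); set("b_factor_j", ctx$structure$b[j])
  set("term_sep_i", ctx$term_sep[i]); set("term_sep_j", ctx$term_sep[j])
  set(paste0("chem_i_", ctx$chem[i]), 1)
  set(paste0("chem_j_", ctx$chem[j]), 1)
  set("hbond", if (!is.null(ann$hbond)) ann$hbond[i, j] else ctx$hbond[i, j])
  if (!is.null(ann$sidechain)) set("sidechain_contact", ann$sidechain[i, j])
  else mask_off("sidechain_contact")   # needs side-chain atoms
  if (!is.null(ann$pocket)) {
    pk <- ann$pocket
    set("pocket_contact", isTRUE(pk$member[i]) || isTRUE(pk$member[j]))
    if (!is.null(pk$atom_contacts))
      set("pocket_atom_contacts", pk$atom_contacts[i] + pk$atom_contacts[j])
    else mask_off("pocket_atom_contacts")
    de <- pk$descriptors %||% numeric()
    for (d in c("polarity", "hydrophobicity", "volume", "drug_score")) {
      if (d %in% names(de)) set(paste0("pocket_", d), de[[d]])
      else mask_off(paste0("pocket_", d))
    }
  } else {
    mask_off(c("pocket_contact", "pocket_atom_contacts",
               paste0("pocket_", c("polarity", "hydrophobicity", "volume",
                                   "drug_score"))))
  }
  if (!is.null(ann$symmetry)) {
    sym <- ann$symmetry
    set("symmetric_i", isTRUE(sym$member[i]))
    set("symmetric_j", isTRUE(sym$member[j]))
    if (!is.null(sym$plane)) {
      mid <- (ctx$structure$coords[i, ] + ctx$structure$coords[j, ]) / 2
      set("symmetry_plane_dist",
          abs(sum((mid - sym$plane$point) * sym$plane$normal)))
    } else mask_off("symmetry_plane_dist")
    seg_cov <- function(s) {
      idx <- sg$segments$start[s]:sg$segments$end[s]
      mean(sym$member[idx])
    }
    set("symmetry_coverage_sse_i", seg_cov(si))
    set("symmetry_coverage_sse_j", seg_cov(sj))
  } else {
    mask_off(c("symmetric_i", "symmetric_j", "symmetry_plane_dist",
               "symmetry_coverage_sse_i", "symmetry_coverage_sse_j"))
  }
  if (!is.null(ann$depth)) {
    dep <- ann$depth
    cd_bin <- findInterval(mean(dep[c(i, j)]),
                           stats::quantile(dep, c(0.25, 0.5, 0.75))) + 1L
    set(paste0("contact_depth_bin_", cd_bin), 1)
    dd_bin <- findInterval(abs(dep[i] - dep[j]),
                           stats::quantile(abs(dep - mean(dep)),
                                           c(0.25, 0.5, 0.75))) + 1L
    set(paste0("depth_diff_bin_", min(dd_bin, 4L)), 1)
  } else {
    mask_off(c(paste0("contact_depth_bin_", 1:4),
               paste0("depth_diff_bin_", 1:4)))
  }
  if (!is.null(ann$mutual_information))
    set("mutual_information", ann$mutual_information[i, j])
  else mask_off("mutual_information")

  ## ---- graph topology + spectrum blocks ------------------------------
  ing <- neighborhood_graph(c(i, j), cmap, ctx$structure)
  gf <- graph_features(ing)
  v[paste0("in_", names(gf$topology))] <- gf$topology
  v[paste0("in_", names(gf$spectrum))] <- gf$spectrum

  ## ---- single node block ----------------------------------------------
  nodes <- ing$nodes
  nn <- length(nodes)
  deg_in <- tabulate(match(c(ing$edges[, 1L], ing$edges[, 2L]), nodes),
                     nbins = nn)
  id <- match(c(ing$edges[, 1L], ing$edges[, 2L]), nodes)
  g <- igraph::make_empty_graph(n = nn, directed = FALSE)
  if (nrow(ing$edges) > 0L)
    g <- igraph::add_edges(g, rbind(id[seq_len(nrow(ing$edges))],
                                    id[-seq_len(nrow(ing$edges))]))
  clo <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  clo[!is.finite(clo)] <- 0
  btw <- igraph::betweenness(g, normalized = nn > 2L)
  for (side in c("i", "j")) {
    r <- if (side == "i") i else j
    p <- match(r, nodes)
    set(paste0("node_degree_", side), deg_in[p])
    set(paste0("node_closeness_", side), clo[p])
    set(paste0("node_betweenness_", side), btw[p])
    set(paste0("node_term_sep_", side), ctx$term_sep[r])
    if (!is.null(ann$conservation)) {
      set(paste0("conservation_", side), ann$conservation[r])
      w <- max(1L, r - 2L):min(n, r + 2L)
      set(paste0("nbhd_conservation_", side), mean(ann$conservation[w]))
    } else {
      mask_off(paste0(c("conservation_", "nbhd_conservation_"), side))
    }
  }

  ## ---- node label statistics block ------------------------------------
  ch <- ctx$chem[nodes]
  for (cl in CHEM_CLASSES) set(paste0("nl_chem_frac_", cl), mean(ch == cl))
  set("nl_chem_entropy", shannon_entropy(table(ch) / nn))
  ss <- sse[nodes]
  for (s in c("H", "E", "C")) set(paste0("nl_sse_frac_", s), mean(ss == s))
  set("nl_sse_entropy", shannon_entropy(table(ss) / nn))
  ac <- ctx$acc_class[nodes]
  for (a in c("buried", "intermediate", "exposed"))
    set(paste0("nl_acc_frac_", a), mean(ac == a))
  set("nl_acc_mean", mean(ctx$acc_value[nodes]))
  hb_any <- rowSums(ctx$hbond[nodes, , drop = FALSE]) > 0
  set("nl_hbond_frac", mean(hb_any))
  sv <- ctx$solv[nodes]
  set("nl_solv_mean", mean(sv))
  v[paste0("nl_solv_bin_", 1:4)] <- bin_fractions(sv, c(-Inf, -1, 0, 1, Inf))
  lab_full <- paste(ch, ss, sep = "/")
  set("nl_label_entropy", shannon_entropy(table(lab_full) / nn))
  if (nrow(ing$edges) > 0L) {
    diff_cl <- ctx$chem[ing$edges[, 1L]] != ctx$chem[ing$edges[, 2L]]
    imp <- vapply(seq_len(nn), function(p) {
      inc <- ing$edges[, 1L] == nodes[p] | ing$edges[, 2L] == nodes[p]
      if (!any(inc)) return(0)
      mean(diff_cl[inc])
    }, numeric(1L))
    set("nl_impurity", mean(imp))
    set("el_link_impurity", mean(diff_cl))
  }
  set("nl_centroid_dist_mean", mean(ctx$cdist[nodes]))
  set("nl_centroid_dist_sd", if (nn > 1L) stats::sd(ctx$cdist[nodes]) else 0)
  if (!is.null(ann$symmetry)) {
    set("nl_sym_coverage", mean(ann$symmetry$member[nodes]))
    degsym <- ann$symmetry$degree %||% as.numeric(ann$symmetry$member)
    set("nl_sym_degree_mean", mean(degsym[nodes]))
  } else mask_off(c("nl_sym_coverage", "nl_sym_degree_mean"))
  if (!is.null(ann$depth)) {
    dn <- ann$depth[nodes]
    set("nl_depth_mean", mean(dn))
    set("nl_depth_sd", if (nn > 1L) stats::sd(dn) else 0)
    qs <- stats::quantile(ann$depth, seq(0.2, 0.8, by = 0.2))
    v[paste0("nl_depth_bin_", 1:5)] <- bin_fractions(dn, c(-Inf, qs, Inf))
  } else mask_off(c("nl_depth_mean", "nl_depth_sd",
                    paste0("nl_depth_bin_", 1:5)))
  set("nl_hse_up_mean", mean(ctx$hse$up[nodes]))
  set("nl_hse_down_mean", mean(ctx$hse$down[nodes]))
  v[paste0("nl_hse_ratio_bin_", 1:5)] <-
    bin_fractions(ctx$hse$ratio[nodes], seq(0, 1, by = 0.2))
  if (!is.null(ann$conservation)) {
    cn <- ann$conservation[nodes]
    set("nl_cons_mean", mean(cn))
    set("nl_cons_sd", if (nn > 1L) stats::sd(cn) else 0)
    qs <- stats::quantile(ann$conservation, seq(0.2, 0.8, by = 0.2))
    v[paste0("nl_cons_bin_", 1:5)] <- bin_fractions(cn, c(-Inf, qs, Inf))
    nbc <- vapply(nodes, function(r)
      mean(ann$conservation[max(1L, r - 2L):min(n, r + 2L)]), numeric(1L))
    set("nl_cons_nbhd_mean", mean(nbc))
  } else mask_off(c("nl_cons_mean", "nl_cons_sd",
                    paste0("nl_cons_bin_", 1:5), "nl_cons_nbhd_mean"))
  set("nl_degree_mean", mean(deg_in))
  set("nl_degree_sd", if (nn > 1L) stats::sd(deg_in) else 0)
  set("nl_degree_min", min(deg_in)); set("nl_degree_max", max(deg_in))
  set("nl_b_mean", mean(ctx$structure$b[nodes]))
  set("nl_b_sd", if (nn > 1L) stats::sd(ctx$structure$b[nodes]) else 0)
  set("nl_solv_sd", if (nn > 1L) stats::sd(sv) else 0)
  hb_counts <- rowSums(ctx$hbond[nodes, , drop = FALSE])
  set("nl_hbond_count_mean", mean(hb_counts))
  set("nl_sse_runlen_mean", mean(ctx$seg_len_of[nodes]))
  set("nl_terminal_frac", mean(ctx$terminal_seg[nodes]))

  ## ---- edge label statistics block ------------------------------------
  ne <- nrow(ing$edges)
  if (ne > 0L) {
    ed <- cmap$D[ing$edges]
    set("el_dist_mean", mean(ed))
    set("el_dist_sd", if (ne > 1L) stats::sd(ed) else 0)
    set("el_longrange_frac",
        mean(abs(ing$edges[, 1L] - ing$edges[, 2L]) >= 4L))
    set("el_intra_sse_frac",
        mean(sg$seg_of[ing$edges[, 1L]] == sg$seg_of[ing$edges[, 2L]]))
    set("el_hbond_frac", mean(ctx$hbond[ing$edges]))
    if (!is.null(ann$mutual_information)) {
      mi <- ann$mutual_information[ing$edges]
      set("el_mi_cum", sum(mi)); set("el_mi_mean", mean(mi))
      rng <- range(ann$mutual_information, na.rm = TRUE)
      brk <- seq(rng[1L], rng[2L], length.out = 6L)
      if (brk[1L] == brk[6L]) brk <- brk + seq(0, 1e-6, length.out = 6L)
      v[paste0("el_mi_bin_", 1:5)] <- bin_fractions(mi, brk)
    } else mask_off(c("el_mi_cum", "el_mi_mean", paste0("el_mi_bin_", 1:5)))
  } else if (is.null(ann$mutual_information)) {
    mask_off(c("el_mi_cum", "el_mi_mean", paste0("el_mi_bin_", 1:5)))
  }

  ## ---- whole protein block --------------------------------------------
  for (s in c("H", "E", "C"))
    set(paste0("wp_sse_frac_", s), mean(sse == s))
  set(paste0("wp_conn_bin_", ctx$conn_bin), 1)
  if (!is.null(ann$symmetry)) set("wp_sym_coverage", mean(ann$symmetry$member))
  else mask_off("wp_sym_coverage")
  set("wp_contact_density", ctx$n_contacts / n)

  list(values = v, mask = m)
}

#' Feature matrix for a set of contacts
#'
#' Extracts \code{\link{feature_vector}} for every listed contact of a
#' structure, sharing the per-structure context.
#'
#' @param structure a \code{\link{ca_structure}}.
#' @param cmap a \code{\link{build_contact_map}} result.
#' @param contacts 2-column matrix of contacts; default all contacts with
#'   sequence separation at least \code{min_sep}.
#' @param min_sep minimum \code{|i - j|} when \code{contacts} is NULL
#'   (default 4, the separation the classifier operates on).
#' @param annotations optional annotation list (see
#'   \code{\link{feature_vector}}).
#' @return list with \code{x} (contacts x 170 matrix, rownames "i_j"),
#'   \code{mask} (logical matrix) and \code{contacts}.
#' @export
contact_features <- function(structure, cmap, contacts = NULL, min_sep = 4L,
                             annotations = NULL) {
  if (is.null(contacts)) contacts <- contact_pairs(cmap, min_sep = min_sep)
  ctx <- structure_context(structure, cmap, annotations)
  lay <- feature_layout()
  x <- matrix(0, nrow(contacts), nrow(lay),
              dimnames = list(paste(contacts[, 1L], contacts[, 2L], sep = "_"),
                              lay$name))
  msk <- matrix(TRUE, nrow(contacts), nrow(lay),
                dimnames = dimnames(x))
  for (r in seq_len(nrow(contacts))) {
    fv <- feature_vector(contacts[r, ], structure, cmap, context = ctx)
    x[r, ] <- fv$values
    msk[r, ] <- fv$mask
  }
  list(x = x, mask = msk, contacts = contacts)
}
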