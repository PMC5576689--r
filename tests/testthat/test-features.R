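# a tiny structure with a fully controlled contact map: two strands of 6
# residues, 3.8 A spacing, 5.2 A apart, so cross-strand partners and
# sequence neighbors are the only contacts at r_c = 5.5.
two_strand_fixture <- function() {
  xyz <- rbind(cbind((0:5) * 3.8, 0, 0),
               cbind((5:0) * 3.8, 5.2, 0))
  st <- ca_structure(xyz)
  st$sse <- rep("C", 12)
  list(st = st, cmap = build_contact_map(st, r_c = 5.5))
}

test_that("neighborhood graphs follow the node-set definition", {
  fx <- two_strand_fixture()
  # residues 3 and 10 are cross-strand partners (same x)
  expect_equal(fx$cmap$C[3, 10], 1L)
  g <- neighborhood_graph(c(3, 10), fx$cmap, fx$st)
  expect_identical(g$nodes, naive_in_nodes(3L, 10L, fx$cmap$C, fx$st$sse))
  # terminus: i = 1 has no i - 1
  g2 <- neighborhood_graph(c(1, 12), fx$cmap, fx$st)
  expect_true(all(g2$nodes >= 1 & g2$nodes <= 12))
  # helix rule pulls in i +/- 4 (residues 5 and 8 are in contact)
  sth <- fx$st; sth$sse[1:8] <- "H"
  gh <- neighborhood_graph(c(5, 8), fx$cmap, sth)
  expect_true(all(c(1, 9, 4, 12) %in% gh$nodes))
  expect_identical(gh$nodes, naive_in_nodes(5L, 8L, fx$cmap$C, sth$sse))
})

test_that("neighborhood node sets match brute force on a globule", {
  g <- make_globule(30, seed = 21)
  cmap <- build_contact_map(g, r_c = 10)
  cp <- contact_pairs(cmap)
  for (r in seq_len(nrow(cp))) {
    got <- neighborhood_graph(cp[r, ], cmap, g)
    expect_identical(got$nodes, naive_in_nodes(cp[r, 1], cp[r, 2],
                                               cmap$C, g$sse))
  }
})

test_that("SSE graphs segment, relabel short runs and count interfaces", {
  helix <- assign_sse(ideal_helix(12))
  sg <- sse_graph(helix, build_contact_map(helix, 10))
  expect_equal(nrow(sg$segments), 1L)
  expect_equal(sg$segments$type, "H")
  expect_equal(nrow(sg$edges), 0L)
  # an H run of length 2 collapses to coil
  st <- extended_chain(8)
  st$sse <- c("C", "H", "H", "C", "C", "C", "C", "C")
  sg2 <- sse_graph(st, build_contact_map(st, 5))
  expect_true(all(sg2$segments$type == "C"))
  # two helices packed side by side with a coil linker: two H nodes
  # joined by an edge; the interface count agrees with a brute-force scan
  xyzA <- ideal_helix(10)$coords
  xyzB <- sweep(ideal_helix(10)$coords, 2, c(9, 0, 0), "+")
  linker <- cbind(seq(2.3, 11.3, length.out = 4), c(4, 7, 7, 4),
                  c(15, 16, 17, 18))
  both <- ca_structure(rbind(xyzA, linker, xyzB))
  both$sse <- c(rep("H", 10), rep("C", 4), rep("H", 10))
  cm <- build_contact_map(both, 10)
  sg3 <- sse_graph(both, cm)
  hseg <- which(sg3$segments$type == "H")
  expect_equal(length(hseg), 2L)
  a <- hseg[1]; b <- hseg[2]
  expect_true(any(sg3$edges[, 1] == a & sg3$edges[, 2] == b))
  manual <- 0
  for (i in sg3$segments$start[a]:sg3$segments$end[a])
    for (j in sg3$segments$start[b]:sg3$segments$end[b])
      if (cm$C[i, j] == 1) manual <- manual + 1
  key <- paste(a, b, sep = "_")
  expect_equal(as.numeric(sg3$interface[[key]]), manual)
})

test_that("graph descriptors reproduce textbook values", {
  path3 <- list(nodes = c(1, 2, 3),
                edges = cbind(i = c(1, 2), j = c(2, 3)), contact = c(1, 2))
  gf <- graph_features(path3)
  expect_equal(unname(gf$topology[c("n_nodes", "n_edges", "n_endpoints",
                                    "diameter", "avg_clustering")]),
               c(3, 2, 2, 2, 0))
  tri <- list(nodes = 1:3, edges = cbind(i = c(1, 1, 2), j = c(2, 3, 3)),
              contact = c(1, 2))
  gt <- graph_features(tri)
  expect_equal(unname(gt$topology["avg_clustering"]), 1)
  expect_equal(unname(gt$spectrum[c("eig1", "eig2")]), c(2, -1))
  expect_equal(unname(gt$spectrum["n_distinct_eig"]), 2)
  expect_equal(unname(gt$spectrum["eig_energy"]), 4)
  single <- list(nodes = 1:2, edges = cbind(i = 1, j = 2), contact = c(1, 2))
  expect_equal(unname(graph_features(single)$spectrum["eig_sum"]), 0)
})

test_that("feature vectors have the published block structure", {
  lay <- feature_layout()
  expect_equal(nrow(lay), 170L)
  expect_equal(as.integer(table(factor(lay$block, unique(lay$block)))),
               c(63L, 10L, 5L, 12L, 57L, 13L, 10L))
})

test_that("annotations control the availability mask", {
  g <- make_globule(30, seed = 22)
  cmap <- build_contact_map(g, 10)
  cp <- contact_pairs(cmap, min_sep = 4)
  contact <- cp[1, ]
  # no annotations: still 170 entries, annotation features masked
  fv <- feature_vector(contact, g, cmap)
  expect_length(fv$values, 170L)
  expect_false(any(is.na(fv$values)))
  expect_false(fv$mask[["mutual_information"]])
  expect_false(fv$mask[["conservation_i"]])
  expect_true(fv$mask[["contact_dist"]])
  # all annotations supplied: mask fully true
  n <- n_residues(g)
  ann <- list(
    conservation = with_seed(1, runif(n)),
    depth = with_seed(2, runif(n, 1, 6)),
    mutual_information = with_seed(3, {
      m <- matrix(runif(n * n), n); (m + t(m)) / 2
    }),
    pocket = list(member = with_seed(4, runif(n) < 0.3),
                  atom_contacts = with_seed(5, rpois(n, 2)),
                  descriptors = c(polarity = 0.4, hydrophobicity = 0.2,
                                  volume = 310, drug_score = 0.6)),
    symmetry = list(member = rep(c(TRUE, FALSE), length.out = n),
                    degree = rep(1, n),
                    plane = list(point = c(0, 0, 0), normal = c(0, 0, 1))),
    sidechain = matrix(TRUE, n, n))
  fv2 <- feature_vector(contact, g, cmap, annotations = ann)
  expect_true(all(fv2$mask))
  expect_length(fv2$values, 170L)
})

test_that("feature extraction is deterministic", {
  g <- make_globule(25, seed = 23)
  cmap <- build_contact_map(g, 10)
  a <- contact_features(g, cmap, min_sep = 4)
  b <- contact_features(g, cmap, min_sep = 4)
  expect_identical(a$x, b$x)
  expect_identical(a$mask, b$mask)
})
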