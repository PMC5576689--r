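# Orchestration: data-set curation filters, per-pair evaluation across
# network variants, classifier-driven lmcENM construction, and the
# removal-fraction sensitivity scan.

#' Curate a conformation pair
#'
#' Applies the data-set admission filters: (a) significant motion
#' (RMSD > 1 Angstrom), (b) alignment length of at least 70 matched
#' residues, (c) resolution at most 2.5 Angstrom where a resolution is
#' recorded, (d) no chain breaks (consecutive Calpha distance above
#' 4.2 Angstrom) in either conformation, (e) no bound peptide and (f) not
#' largely extended/disordered. Filters (e) and (f) need information the
#' Calpha model cannot see (ligand atoms, shape judgment); they are
#' advisory flags taken from \code{config} and default to pass with a
#' waiver note.
#'
#' @param pair a \code{\link{build_pair}} result.
#' @param config optional list with \code{min_rmsd} (default 1.0),
#'   \code{min_alignment} (70), \code{max_resolution} (2.5),
#'   \code{break_distance} (4.2), and advisory flags
#'   \code{has_bound_peptide}, \code{is_extended} (logical or NA).
#' @return object of class \code{"curation_result"}: list with
#'   \code{pass} and per-filter \code{verdicts} (TRUE = clean, FALSE =
#'   violated, NA = not assessable / waived).
#' @export
curate_pair <- function(pair, config = list()) {
  cfg <- utils::modifyList(list(min_rmsd = 1.0, min_alignment = 70L,
                                max_resolution = 2.5, break_distance = 4.2,
                                has_bound_peptide = NA, is_extended = NA),
                           config)
  res <- c(pair$resolution_start, pair$resolution_end)
  verdicts <- c(
    a_motion = pair$rmsd > cfg$min_rmsd,
    b_alignment = nrow(pair$corr) >= cfg$min_alignment,
    c_resolution = if (all(is.na(res))) NA else
      all(res[!is.na(res)] <= cfg$max_resolution),
    d_chain_break =
      length(detect_chain_breaks(pair$start, cfg$break_distance)) == 0L &&
      length(detect_chain_breaks(pair$end, cfg$break_distance)) == 0L,
    e_bound_peptide = if (is.na(cfg$has_bound_peptide)) NA
                      else !isTRUE(cfg$has_bound_peptide),
    f_extended = if (is.na(cfg$is_extended)) NA else !isTRUE(cfg$is_extended))
  structure(list(pass = all(verdicts[!is.na(verdicts)]),
                 verdicts = verdicts),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("Curation:", if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$verdicts)) {
    v <- x$verdicts[[nm]]
    cat(sprintf("  %-16s %s\n", nm,
                if (is.na(v)) "waived" else if (v) "clean" else "violated"))
  }
  invisible(x)
}

# Build one network variant on the start conformation of a pair.
build_variant <- function(variant, pair, config, model = NULL) {
  st <- pair$start
  if (is.null(st$sse)) st <- assign_sse(st)
  gamma <- config$gamma %||% 1
  r_c <- config$r_c %||% 10
  min_sep <- config$min_sep %||% 4L
  base <- function() build_network(st, spring_scheme("uniform_cutoff",
                                                     gamma = gamma,
                                                     r_c = r_c))
  switch(variant,
    enm = base(),
    hca = build_network(st, spring_scheme("hca", gamma = gamma)),
    edenm = build_network(st, spring_scheme("edenm", gamma = gamma)),
    ofc = build_network(st, spring_scheme("ofc", gamma = gamma, r_c = r_c)),
    mcenm = {
      tm <- classify_transitions(pair, r_c = r_c,
                                 e_c = config$e_c %||% 0.09)
      suppressWarnings(modify_network(base(),
        remove = transition_pairs(tm, "breaking", min_sep = min_sep),
        min_sep = min_sep))
    },
    mfcenm = {
      tm <- classify_transitions(pair, r_c = r_c,
                                 e_c = config$e_c %||% 0.09)
      suppressWarnings(modify_network(base(),
        remove = transition_pairs(tm, "breaking", min_sep = min_sep),
        add = transition_pairs(tm, "forming"),
        min_sep = min_sep))
    },
    lmcenm = {
      if (is.null(model)) stop("lmcENM variant needs a trained classifier")
      predict_and_build(st, model, config = config)$network
    },
    stop("unknown variant: ", variant))
}

# Restrict a 3N mode matrix/vector to matched residues.
restrict_to_matched <- function(vecs, matched) {
  keep <- as.vector(t(outer(matched, 1:3, function(i, k) 3L * (i - 1L) + k)))
  if (is.matrix(vecs)) vecs[keep, , drop = FALSE] else vecs[keep]
}

#' Evaluate network variants against an observed transition
#'
#' Builds each requested variant on the start conformation, runs normal
#' mode analysis, and scores the predicted motion against the pair's
#' displacement field: CO(10), CFV(10), fluctuation correlations against
#' squared displacements and B-factors, the best single mode (overlap,
#' 0-based rank, collectivity, variance fraction), and the number of
#' modes needed for 70/80/90% of the transition. Mode components are
#' restricted to matched residues before comparison.
#'
#' @param pair a \code{\link{build_pair}} result (should pass curation).
#' @param variants character vector of variant names among
#'   \code{c("enm", "hca", "edenm", "ofc", "mcenm", "mfcenm", "lmcenm")}.
#' @param config list of parameters (r_c, e_c, gamma, min_sep, k, selection
#'   strategy/param for lmcENM).
#' @param model optional \code{\link{train_breaking_classifier}} result
#'   (required for the \code{lmcenm} variant).
#' @return data.frame, one row per variant, with the metric columns.
#' @export
analyze_pair <- function(pair, variants = c("enm", "hca", "edenm", "ofc",
                                            "mcenm"),
                         config = list(), model = NULL) {
  k <- config$k %||% 10L
  disp <- displacement_vector(pair)
  matched <- pair$corr[, 1L]
  rows <- lapply(variants, function(vn) {
    net <- build_variant(vn, pair, config, model)
    modes <- normal_modes(net, zero_tol = config$zero_tol %||% 1e-8)
    mv <- restrict_to_matched(modes$vectors, matched)
    mm <- modes; mm$vectors <- mv; mm$n_atoms <- length(matched)
    kk <- min(k, length(mm$values))
    bm <- best_mode(mm, disp)
    mtr <- modes_to_reach(mm, disp)
    msf <- fluctuation_profile(mm, k = kk)
    disp2 <- rowSums(pair$disp^2)
    bref <- pair$start$b[matched]
    data.frame(variant = vn,
               n_edges = nrow(net$edges),
               n_zero = modes$n_zero,
               co = cumulative_overlap(mm, disp, k = kk),
               cfv = variance_fractions(mm, k = kk)$cfv,
               disp_correlation = profile_correlation(msf, disp2)$correlation,
               b_correlation = if (stats::sd(bref) > 0)
                 profile_correlation(msf, bref)$correlation else NA_real_,
               max_overlap = bm$max_overlap,
               best_rank = bm$rank,
               best_collectivity = bm$collectivity,
               best_variance_fraction = bm$variance_fraction,
               modes_to_70 = mtr[["70%"]],
               modes_to_80 = mtr[["80%"]],
               modes_to_90 = mtr[["90%"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict breaking contacts and build the lmcENM
#'
#' Scores all long-range contacts of the structure with the classifier,
#' selects the removal subset under the given strategy, and removes the
#' selected contacts from the stabilized baseline cutoff network.
#'
#' @param structure a \code{\link{ca_structure}}.
#' @param model a \code{\link{train_breaking_classifier}} result.
#' @param strategy selection strategy (default \code{"relative"}).
#' @param param strategy parameter (default 0.16: top 16 percent).
#' @param config list with r_c, gamma, min_sep overrides.
#' @param features optional precomputed \code{\link{contact_features}}.
#' @return list with \code{network} (the lmcENM), \code{ranked} (full
#'   ranking) and \code{removed} (selected pairs).
#' @export
predict_and_build <- function(structure, model, strategy = "relative",
                              param = NULL, config = list(),
                              features = NULL) {
  strategy <- config$selection_strategy %||% strategy
  param <- param %||% config$selection_param %||%
    switch(strategy, relative = 0.16, constant = 60L, score = 0.4)
  r_c <- config$r_c %||% 10
  if (is.null(structure$sse)) structure <- assign_sse(structure)
  cmap <- build_contact_map(structure, r_c = r_c)
  ranked <- rank_contacts(model, structure, cmap, features = features)
  removed <- select_removals(ranked, strategy = strategy, param = param)
  base <- build_network(structure,
                        spring_scheme("uniform_cutoff",
                                      gamma = config$gamma %||% 1, r_c = r_c))
  net <- suppressWarnings(modify_network(base, remove = removed,
                                         min_sep = config$min_sep %||% 4L))
  list(network = net, ranked = ranked, removed = removed)
}

#' Sensitivity of accuracy to the removal fraction
#'
#' Gradually removes larger prefixes of a contact ranking from the
#' baseline network of the start conformation and records CO(10) against
#' the pair's displacement at each fraction.
#'
#' @param pair a \code{\link{build_pair}} result.
#' @param ranked a ranking table (columns i, j, score) over the start
#'   structure's long-range contacts.
#' @param fractions removal fractions (default 1% to 50% in 7 steps).
#' @param config parameter overrides (r_c, gamma, min_sep, k).
#' @return data.frame with \code{fraction}, \code{n_removed},
#'   \code{co}.
#' @export
sensitivity_scan <- function(pair, ranked,
                             fractions = c(0.01, 0.05, 0.1, 0.16, 0.25,
                                           0.4, 0.5),
                             config = list()) {
  st <- pair$start
  if (is.null(st$sse)) st <- assign_sse(st)
  k <- config$k %||% 10L
  base <- build_network(st, spring_scheme("uniform_cutoff",
                                          gamma = config$gamma %||% 1,
                                          r_c = config$r_c %||% 10))
  disp <- displacement_vector(pair)
  matched <- pair$corr[, 1L]
  rows <- lapply(fractions, function(f) {
    sel <- select_removals(ranked, strategy = "relative", param = f)
    net <- suppressWarnings(modify_network(base, remove = sel,
                                           min_sep = config$min_sep %||% 4L))
    modes <- normal_modes(net)
    mm <- modes
    mm$vectors <- restrict_to_matched(modes$vectors, matched)
    mm$n_atoms <- length(matched)
    data.frame(fraction = f, n_removed = nrow(sel),
               co = cumulative_overlap(mm, disp,
                                       k = min(k, length(mm$values))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
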