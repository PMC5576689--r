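# Breaking-contact classifier: corpus assembly with undersampling,
# RBF-SVM training with class weights and Platt-scaled probabilities,
# leave-one-protein-out tuning, contact ranking, removal selection,
# evaluation metrics and linear feature weights.

#' Assemble an undersampled training set
#'
#' Per protein, all observed breaking contacts (sequence separation >= 4)
#' are positives; \code{ratio} times as many maintained contacts are drawn
#' uniformly without replacement as negatives (capped at availability).
#' Per-protein sampling seeds are derived from the corpus seed and the
#' protein id, so adding or removing proteins does not reshuffle the
#' others.
#'
#' @param proteins list of entries, each a list with \code{id},
#'   \code{features} (a \code{\link{contact_features}} result) and
#'   \code{tmap} (a \code{\link{classify_transitions}} result).
#' @param ratio negatives per positive (default 3).
#' @param seed corpus-level sampling seed.
#' @param min_sep minimum sequence separation (default 4).
#' @return object of class \code{"training_set"}: \code{x}, \code{mask},
#'   \code{y} (factor breaking/maintained), \code{protein},
#'   \code{contact} (data.frame i, j).
#' @export
build_training_set <- function(proteins, ratio = 3, seed = 1L,
                               min_sep = 4L) {
  xs <- list(); ms <- list(); ys <- list(); pid <- list(); cts <- list()
  for (p in proteins) {
    br <- transition_pairs(p$tmap, "breaking", min_sep = min_sep)
    mt <- transition_pairs(p$tmap, "maintained", min_sep = min_sep)
    if (nrow(br) == 0L) {
      message("build_training_set: protein ", p$id,
              " has no breaking contacts; skipped")
      next
    }
    n_neg <- min(nrow(mt), round(ratio * nrow(br)))
    neg_idx <- with_seed(derive_seed(seed, p$id),
                         sample.int(nrow(mt), n_neg))
    sel <- rbind(br, mt[neg_idx, , drop = FALSE])
    key <- paste(sel[, 1L], sel[, 2L], sep = "_")
    rows <- match(key, rownames(p$features$x))
    if (anyNA(rows))
      stop("protein ", p$id, ": feature table lacks ",
           sum(is.na(rows)), " labeled contact(s)")
    xs[[length(xs) + 1L]] <- p$features$x[rows, , drop = FALSE]
    ms[[length(ms) + 1L]] <- p$features$mask[rows, , drop = FALSE]
    ys[[length(ys) + 1L]] <- rep(c("breaking", "maintained"),
                                 c(nrow(br), n_neg))
    pid[[length(pid) + 1L]] <- rep(p$id, nrow(br) + n_neg)
    cts[[length(cts) + 1L]] <- sel
  }
  if (length(xs) == 0L) stop("no usable proteins in corpus")
  structure(list(x = do.call(rbind, xs), mask = do.call(rbind, ms),
                 y = factor(unlist(ys), levels = c("breaking", "maintained")),
                 protein = unlist(pid),
                 contact = do.call(rbind, cts), ratio = ratio, seed = seed),
            class = "training_set")
}

# Standardization statistics fit on a training matrix; masked entries are
# excluded from the statistics and set to 0 (the neutral standardized
# value) when applied.
fit_standardizer <- function(x, mask) {
  mu <- numeric(ncol(x)); sdv <- numeric(ncol(x))
  for (c in seq_len(ncol(x))) {
    ok <- mask[, c]
    mu[c] <- if (any(ok)) mean(x[ok, c]) else 0
    s <- if (sum(ok) > 1L) stats::sd(x[ok, c]) else 0
    sdv[c] <- if (is.finite(s) && s > 0) s else 1
  }
  list(mean = mu, sd = sdv)
}

apply_standardizer <- function(std, x, mask) {
  z <- sweep(sweep(x, 2L, std$mean), 2L, std$sd, "/")
  z[!mask] <- 0
  z
}

#' Train the breaking-contact classifier
#'
#' Radial-basis-function support vector machine with class weights
#' inversely proportional to class frequency and Platt-scaled probability
#' output. Features are standardized with statistics fit on this training
#' set (masked entries neutralized to 0); the statistics travel with the
#' model.
#'
#' @param tset a \code{\link{build_training_set}} result.
#' @param cost SVM cost parameter (default 100).
#' @param gamma RBF kernel width (default 1e-5).
#' @param kernel \code{"radial"} (default) or \code{"linear"}.
#' @return object of class \code{"breaking_classifier"} wrapping the SVM,
#'   the standardizer and the feature mask availability.
#' @export
train_breaking_classifier <- function(tset, cost = 100, gamma = 1e-5,
                                      kernel = "radial") {
  if (nlevels(droplevels(tset$y)) < 2L) stop("degenerate labels")
  std <- fit_standardizer(tset$x, tset$mask)
  z <- apply_standardizer(std, tset$x, tset$mask)
  tab <- table(tset$y)
  cw <- as.numeric(sum(tab) / (length(tab) * tab))
  names(cw) <- names(tab)
  fit <- e1071::svm(x = z, y = tset$y, kernel = kernel, cost = cost,
                    gamma = gamma, class.weights = cw, probability = TRUE,
                    scale = FALSE)
  structure(list(svm = fit, standardizer = std, cost = cost, gamma = gamma,
                 kernel = kernel, feature_names = colnames(tset$x),
                 version = 1L),
            class = "breaking_classifier")
}

#' Score contacts with a trained classifier
#' @param model a \code{\link{train_breaking_classifier}} result.
#' @param features a \code{\link{contact_features}} result.
#' @return numeric vector of Platt-scaled breaking probabilities in [0, 1].
#' @export
predict_breaking <- function(model, features) {
  z <- apply_standardizer(model$standardizer, features$x, features$mask)
  pr <- stats::predict(model$svm, z, probability = TRUE)
  p <- attr(pr, "probabilities")[, "breaking"]
  unname(p)
}

#' Leave-one-protein-out hyperparameter tuning
#'
#' For each (cost, gamma) grid point, trains on all proteins but one and
#' evaluates the precision among the held-out protein's top floor(L/5)
#' scored contacts (L = protein length); the grid point with the highest
#' mean precision wins, ties toward smaller cost then smaller gamma.
#'
#' @param proteins corpus as in \code{\link{build_training_set}}, with
#'   each entry also carrying \code{structure}.
#' @param costs,gammas grid values (defaults \code{10^(0:3)} and
#'   \code{10^(-6:-3)}).
#' @param ratio,seed undersampling controls.
#' @return list with \code{cost}, \code{gamma} and the full \code{grid}
#'   data.frame of mean precisions.
#' @export
tune_loocv <- function(proteins, costs = 10^(0:3), gammas = 10^(-6:-3),
                       ratio = 3, seed = 1L) {
  grid <- expand.grid(cost = costs, gamma = gammas)
  grid <- grid[order(grid$cost, grid$gamma), ]
  prec <- matrix(NA_real_, nrow(grid), length(proteins))
  for (h in seq_along(proteins)) {
    tset <- build_training_set(proteins[-h], ratio = ratio, seed = seed)
    held <- proteins[[h]]
    L <- n_residues(held$structure)
    top_n <- max(1L, floor(L / 5))
    obs <- transition_pairs(held$tmap, "breaking", min_sep = 4L)
    obs_key <- paste(obs[, 1L], obs[, 2L], sep = "_")
    for (g in seq_len(nrow(grid))) {
      model <- train_breaking_classifier(tset, cost = grid$cost[g],
                                         gamma = grid$gamma[g])
      sc <- predict_breaking(model, held$features)
      ord <- order(-sc)
      top <- rownames(held$features$x)[ord[seq_len(min(top_n, length(ord)))]]
      prec[g, h] <- mean(top %in% obs_key)
    }
  }
  grid$precision <- rowMeans(prec)
  best <- which.max(grid$precision)  # grid sorted: ties -> smaller cost/gamma
  list(cost = grid$cost[best], gamma = grid$gamma[best], grid = grid)
}

#' Rank a structure's contacts by predicted breaking probability
#'
#' Scores every contact with sequence separation at least 4 and returns
#' them sorted by decreasing probability (ties broken toward the
#' lexicographically smaller pair).
#'
#' @param model a \code{\link{train_breaking_classifier}} result.
#' @param structure a \code{\link{ca_structure}}.
#' @param cmap a \code{\link{build_contact_map}} result.
#' @param annotations optional annotation list.
#' @param features optional precomputed \code{\link{contact_features}}.
#' @return data.frame with columns \code{i}, \code{j}, \code{score},
#'   sorted by decreasing score.
#' @export
rank_contacts <- function(model, structure, cmap, annotations = NULL,
                          features = NULL) {
  feats <- features %||%
    contact_features(structure, cmap, min_sep = 4L,
                     annotations = annotations)
  if (nrow(feats$x) == 0L)
    return(data.frame(i = integer(), j = integer(), score = numeric()))
  sc <- predict_breaking(model, feats)
  out <- data.frame(i = feats$contacts[, 1L], j = feats$contacts[, 2L],
                    score = sc)
  out[order(-out$score, out$i, out$j), , drop = FALSE]
}

#' Select contacts to remove from a ranking
#'
#' Three selection strategies over a decreasing-score ranking: constant
#' (top n), relative (top fraction of the scored contacts, floor), and
#' score (all with probability strictly above a threshold). Counts
#' truncate strictly; tied scores at a count boundary are not pulled in.
#'
#' @param ranked a \code{\link{rank_contacts}} result.
#' @param strategy \code{"relative"} (default), \code{"constant"} or
#'   \code{"score"}.
#' @param param top fraction (default 0.16), top count, or score cutoff
#'   depending on strategy.
#' @return 2-column matrix of selected pairs, ranking order preserved.
#' @export
select_removals <- function(ranked, strategy = c("relative", "constant",
                                                 "score"),
                            param = 0.16) {
  strategy <- match.arg(strategy)
  n_avail <- nrow(ranked)
  n_take <- switch(strategy,
    constant = min(as.integer(param), n_avail),
    relative = floor(param * n_avail),
    score = sum(ranked$score > param))
  sel <- if (strategy == "score") ranked[ranked$score > param, , drop = FALSE]
         else ranked[seq_len(n_take), , drop = FALSE]
  as.matrix(sel[, c("i", "j"), drop = FALSE])
}

# Rank-based AUROC (Mann-Whitney statistic); NA with a single class.
auroc_score <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification metrics for a predicted breaking set
#'
#' Precision = TP / (TP + FP) over the selected set; coverage = TP over
#' all observed breaking contacts; AUROC over all scored contacts when
#' scores are supplied.
#'
#' @param predicted 2-column matrix of selected pairs.
#' @param tmap observed \code{\link{classify_transitions}} result.
#' @param ranked optional full \code{\link{rank_contacts}} table for the
#'   AUROC.
#' @param min_sep sequence-separation restriction (default 4).
#' @return list with \code{precision}, \code{coverage}, \code{auroc}.
#' @export
classifier_metrics <- function(predicted, tmap, ranked = NULL,
                               min_sep = 4L) {
  obs <- transition_pairs(tmap, "breaking", min_sep = min_sep)
  obs_key <- paste(obs[, 1L], obs[, 2L], sep = "_")
  pred_key <- if (NROW(predicted) > 0L)
    paste(pmin(predicted[, 1L], predicted[, 2L]),
          pmax(predicted[, 1L], predicted[, 2L]), sep = "_") else character()
  tp <- sum(pred_key %in% obs_key)
  prec <- if (length(pred_key) > 0L) tp / length(pred_key) else NA_real_
  cov <- if (length(obs_key) > 0L) tp / length(obs_key) else NA_real_
  auc <- NA_real_
  if (!is.null(ranked) && nrow(ranked) > 0L) {
    key <- paste(ranked$i, ranked$j, sep = "_")
    auc <- auroc_score(ranked$score, key %in% obs_key)
  }
  list(precision = prec, coverage = cov, auroc = auc)
}

#' Linear feature weights
#'
#' Trains a linear maximum-margin classifier on the standardized features
#' and reports the primal weight vector sorted by decreasing weight.
#' Features masked across the entire training set are excluded.
#'
#' @param tset a \code{\link{build_training_set}} result.
#' @param cost linear SVM cost (default 1).
#' @return data.frame with \code{feature} and \code{weight} (positive
#'   weights push toward the breaking class), sorted by decreasing weight;
#'   ties keep layout order.
#' @export
linear_feature_weights <- function(tset, cost = 1) {
  if (nlevels(droplevels(tset$y)) < 2L) stop("degenerate labels")
  std <- fit_standardizer(tset$x, tset$mask)
  z <- apply_standardizer(std, tset$x, tset$mask)
  avail <- colSums(tset$mask) > 0L
  z <- z[, avail, drop = FALSE]
  fit <- e1071::svm(x = z, y = tset$y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- as.vector(crossprod(fit$coefs, fit$SV))
  # libsvm's first class is the first factor level ("breaking"); positive
  # decision values then point toward breaking already
  out <- data.frame(feature = colnames(z), weight = w,
                    stringsAsFactors = FALSE)
  out[order(-out$weight), , drop = FALSE]
}

#' Serialize / restore a classifier
#'
#' The model artifact contains the SVM, Platt coefficients, the
#' standardization statistics, the feature name list and a format version.
#'
#' @param model a \code{\link{train_breaking_classifier}} result.
#' @param path file path (RDS).
#' @return \code{save_classifier}: invisibly, the path;
#'   \code{load_classifier}: the model.
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "breaking_classifier")) stop("not a classifier artifact")
  m
}
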