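# fabricate a protein entry with a prescribed number of breaking and
# maintained long-range contacts, and feature rows keyed to them.
fake_protein <- function(id, n_break, n_maint, n_feat = 6, seed = 1) {
  n <- 400L
  pairs <- cbind(seq_len(n_break + n_maint),
                 seq_len(n_break + n_maint) + 10L)
  Tm <- matrix("none", n, n)
  for (r in seq_len(nrow(pairs))) {
    lab <- if (r <= n_break) "breaking" else "maintained"
    Tm[pairs[r, 1], pairs[r, 2]] <- Tm[pairs[r, 2], pairs[r, 1]] <- lab
  }
  tmap <- structure(list(T = Tm, E = matrix(NA_real_, n, n), r_c = 10,
                         e_c = 0.09, matched = seq_len(n)),
                    class = "transition_map")
  x <- with_seed(seed, matrix(rnorm(nrow(pairs) * n_feat), nrow(pairs),
                              dimnames = list(paste(pairs[, 1], pairs[, 2],
                                                    sep = "_"),
                                              paste0("f", seq_len(n_feat)))))
  # feature 1 separates the classes
  x[, 1] <- x[, 1] + rep(c(3, -3), c(n_break, n_maint))
  list(id = id, tmap = tmap,
       features = list(x = x, mask = matrix(TRUE, nrow(x), n_feat,
                                            dimnames = dimnames(x)),
                       contacts = pairs))
}

test_that("undersampling keeps all positives and a capped 1:3 draw", {
  p <- fake_protein("a", 10, 200)
  ts <- build_training_set(list(p), ratio = 3, seed = 5)
  expect_equal(sum(ts$y == "breaking"), 10L)
  expect_equal(sum(ts$y == "maintained"), 30L)
  p2 <- fake_protein("b", 10, 20)
  ts2 <- build_training_set(list(p2), ratio = 3, seed = 5)
  expect_equal(sum(ts2$y == "maintained"), 20L)   # capped at availability
  # same positives under different seeds, generally different negatives
  tsA <- build_training_set(list(p), ratio = 3, seed = 1)
  tsB <- build_training_set(list(p), ratio = 3, seed = 2)
  keyA <- paste(tsA$contact[tsA$y == "breaking", 1],
                tsA$contact[tsA$y == "breaking", 2])
  keyB <- paste(tsB$contact[tsB$y == "breaking", 1],
                tsB$contact[tsB$y == "breaking", 2])
  expect_identical(keyA, keyB)
  negA <- sort(paste(tsA$contact[tsA$y == "maintained", 1],
                     tsA$contact[tsA$y == "maintained", 2]))
  negB <- sort(paste(tsB$contact[tsB$y == "maintained", 1],
                     tsB$contact[tsB$y == "maintained", 2]))
  expect_false(identical(negA, negB))
  # a protein without breaking contacts is skipped, not fatal
  p0 <- fake_protein("c", 0, 50)
  p0$tmap$T[p0$tmap$T == "breaking"] <- "maintained"
  expect_message(ts3 <- build_training_set(list(p, p0), seed = 1),
                 "no breaking contacts")
  expect_true(all(ts3$protein == "a"))
})

test_that("a separable toy trains to perfect accuracy", {
  p <- fake_protein("a", 20, 60, seed = 9)
  ts <- build_training_set(list(p), ratio = 3, seed = 3)
  m <- train_breaking_classifier(ts, cost = 10, gamma = 0.1)
  sc <- predict_breaking(m, list(x = ts$x, mask = ts$mask))
  expect_true(all(sc[ts$y == "breaking"] > 0.5))
  expect_true(all(sc[ts$y == "maintained"] < 0.5))
  expect_error(train_breaking_classifier(
    structure(list(x = ts$x, mask = ts$mask,
                   y = factor(rep("breaking", nrow(ts$x)),
                              levels = c("breaking", "maintained")),
                   protein = ts$protein, contact = ts$contact),
              class = "training_set")), "degenerate")
})

test_that("shuffled labels give chance-level ranking", {
  p <- fake_protein("a", 40, 120, seed = 4)
  ts <- build_training_set(list(p), ratio = 3, seed = 3)
  ts$y <- with_seed(77, sample(ts$y))
  half <- seq_len(nrow(ts$x)) %% 2 == 0
  tr <- ts; tr$x <- ts$x[half, ]; tr$mask <- ts$mask[half, ]
  tr$y <- ts$y[half]
  m <- train_breaking_classifier(tr, cost = 10, gamma = 0.01)
  sc <- predict_breaking(m, list(x = ts$x[!half, ], mask = ts$mask[!half, ]))
  auc <- pROC::auc(pROC::roc(response = ts$y[!half] == "breaking",
                             predictor = sc, quiet = TRUE))
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("leave-one-protein-out tuning returns a dominant grid point", {
  ps <- lapply(1:3, function(k) {
    p <- fake_protein(paste0("p", k), 12, 50, seed = k)
    p$structure <- extended_chain(50)
    p
  })
  got <- tune_loocv(ps, costs = 10, gammas = 0.01, ratio = 3, seed = 1)
  expect_equal(got$cost, 10)
  expect_equal(got$gamma, 0.01)
  expect_equal(nrow(got$grid), 1L)
})

test_that("contact ranking is a sorted version of the raw scores", {
  cf <- get_corpus_features()
  p <- cf[[1]]
  ts <- build_training_set(cf[1:6], ratio = 3, seed = 2)
  m <- train_breaking_classifier(ts)
  r <- rank_contacts(m, p$structure, p$cmap, features = p$features)
  expect_true(all(r$score >= 0 & r$score <= 1))
  expect_true(all(diff(r$score) <= 0))
  expect_true(all(abs(r$j - r$i) >= 4))
  # brute-force oracle: score everything, then sort
  sc <- predict_breaking(m, p$features)
  ord <- order(-sc, p$features$contacts[, 1], p$features$contacts[, 2])
  expect_equal(r$score, sc[ord])
  expect_equal(r$i, unname(p$features$contacts[ord, 1]))
})

test_that("removal selection strategies follow their counting rules", {
  ranked <- data.frame(i = seq_len(250), j = seq_len(250) + 10,
                       score = seq(1, 0.2, length.out = 250))
  expect_equal(nrow(select_removals(ranked, "relative", 0.16)), 40L)
  short <- ranked[1:50, ]
  expect_equal(nrow(select_removals(short, "constant", 60)), 50L)
  sc4 <- data.frame(i = 1:4, j = 11:14, score = c(0.9, 0.5, 0.41, 0.39))
  expect_equal(nrow(select_removals(sc4, "score", 0.4)), 3L)
  # selections are prefixes of the ranking
  sel <- select_removals(ranked, "relative", 0.1)
  expect_equal(unname(sel[, "i"]), ranked$i[seq_len(nrow(sel))])
})

test_that("precision, coverage and AUROC match hand counting", {
  p <- fake_protein("a", 5, 20)
  obs <- transition_pairs(p$tmap, "breaking", min_sep = 4)
  met <- classifier_metrics(obs, p$tmap)
  expect_equal(met$precision, 1)
  expect_equal(met$coverage, 1)
  none <- transition_pairs(p$tmap, "maintained", min_sep = 4)[1:5, ]
  met0 <- classifier_metrics(none, p$tmap)
  expect_equal(met0$precision, 0)
  expect_equal(met0$coverage, 0)
  # two positives ranked 1st and 3rd of 4: pair statistic 0.75
  ranked <- data.frame(i = c(1, 2, 3, 4), j = c(11, 12, 13, 14),
                       score = c(0.9, 0.7, 0.5, 0.3))
  Tm <- matrix("none", 20, 20)
  for (r in 1:4) {
    lab <- if (r %in% c(1, 3)) "breaking" else "maintained"
    Tm[ranked$i[r], ranked$j[r]] <- Tm[ranked$j[r], ranked$i[r]] <- lab
  }
  tm <- structure(list(T = Tm, E = matrix(NA_real_, 20, 20), r_c = 10,
                       e_c = 0.09, matched = 1:20),
                  class = "transition_map")
  met2 <- classifier_metrics(ranked[1, c("i", "j")], tm, ranked = ranked)
  expect_equal(met2$auroc, 0.75)
  lbl <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(met2$auroc, pairwise_auroc(ranked$score, lbl))
})

test_that("linear weights identify the separating feature", {
  p <- fake_protein("a", 30, 90, seed = 6)
  ts <- build_training_set(list(p), ratio = 3, seed = 3)
  w <- linear_feature_weights(ts)
  expect_equal(w$feature[which.max(abs(w$weight))], "f1")
  expect_gt(w$weight[w$feature == "f1"], 0)   # points toward breaking
})

test_that("classifier artifacts survive serialization", {
  p <- fake_protein("a", 20, 60, seed = 10)
  ts <- build_training_set(list(p), ratio = 3, seed = 3)
  m <- train_breaking_classifier(ts, cost = 10, gamma = 0.1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, f)
  m2 <- load_classifier(f)
  sc1 <- predict_breaking(m, list(x = ts$x, mask = ts$mask))
  sc2 <- predict_breaking(m2, list(x = ts$x, mask = ts$mask))
  expect_identical(sc1, sc2)
})
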