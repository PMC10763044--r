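# Exhaustive pairwise-concordance oracle for the ROC area
# (Mann-Whitney identity; ties count 1/2).
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

test_that("pair features concatenate miRNA then SM embeddings", {
  emb <- rbind("mir:m1" = c(1, 2, 3, 4), "sm:s1" = c(5, 6, 7, 8),
               "sm:s2" = rep(0, 4))
  pairs <- edge_set(c("s1", "s2"), c("m1", "m1"), c("up", "up"), label = c(1, 0))
  tab <- pair_features(emb, pairs)
  expect_equal(ncol(tab$features), 8L)
  expect_equal(tab$features[1, ], c(1:4, 5:8))        # miRNA block first
  expect_equal(tab$features[2, 5:8], rep(0, 4))
  expect_equal(tab$label, c(1L, 0L))
  expect_error(pair_features(emb, edge_set("s9", "m1", "up")), "sm:s9")
})

test_that("the boosted-tree classifier fits separable data and is seeded", {
  set.seed(5)
  x <- matrix(rnorm(200 * 6), 200)
  y <- as.integer(x[, 1] > 0)
  x[, 1] <- x[, 1] + 2 * (y - 0.5)       # widen the margin
  tab <- list(features = x, label = y)
  clf <- fit_classifier(tab, "gbt", params = list(nrounds = 50), seed = 3)
  expect_equal(as.integer(predict(clf, x) >= 0.5), y)

  clf2 <- fit_classifier(tab, "gbt", params = list(nrounds = 50), seed = 3)
  expect_identical(predict(clf, x), predict(clf2, x))

  expect_error(fit_classifier(list(features = x, label = rep(1, 200))), "both classes")
})

test_that("alternate classifiers sit behind the same interface", {
  set.seed(6)
  x <- matrix(rnorm(120 * 4), 120)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  tab <- list(features = x, label = y)
  for (kind in c("lr", "rf")) {
    if (kind == "rf") skip_if_not_installed("randomForest")
    clf <- fit_classifier(tab, kind, seed = 2)
    p <- predict(clf, x)
    expect_length(p, 120L)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(concordance_auc(p, y), 0.8)
  }
})

test_that("confusion counts follow the tie-positive threshold rule", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cm)[c("TP", "FP", "TN", "FN")],
               list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))

  cm <- confusion(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(cm$FN, 0L)
  expect_equal(cm$TN, 0L)
  expect_equal(cm$TP, 3L)
  expect_equal(cm$FP, 3L)

  set.seed(7)
  s <- runif(100); y <- rbinom(100, 1, 0.5)
  cm <- confusion(s, y, threshold = 0.4)
  manual <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in 1:100) {
    call <- s[i] >= 0.4
    key <- if (call && y[i] == 1) "TP" else if (call) "FP"
           else if (y[i] == 0) "TN" else "FN"
    manual[key] <- manual[key] + 1L
  }
  expect_equal(unlist(unclass(cm)[names(manual)]), manual)
  expect_error(confusion(s, y + 1), "binary")
})

test_that("threshold metrics match their closed forms", {
  perfect <- classification_metrics(list(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  m <- classification_metrics(list(TP = 40, FN = 10, TN = 35, FP = 15))
  expect_equal(m[["Acc"]], 0.75)
  expect_equal(m[["Sen"]], 0.8)
  expect_equal(m[["Spec"]], 0.7)
  mcc <- (40 * 35 - 15 * 10) / sqrt(55 * 50 * 50 * 45)
  expect_equal(m[["MCC"]], mcc)
  expect_equal(round(m[["MCC"]], 4), 0.5025)

  degenerate <- classification_metrics(list(TP = 0, FN = 10, TN = 10, FP = 0))
  expect_equal(degenerate[["Sen"]], 0)
  expect_equal(degenerate[["Spec"]], 1)
  expect_equal(degenerate[["MCC"]], 0)
  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "empty")
})

test_that("metrics are invariant under joint permutations of scores and labels", {
  set.seed(8)
  s <- runif(60); y <- rbinom(60, 1, 0.4)
  ref <- classification_metrics(confusion(s, y))
  for (rep in 1:5) {
    p <- sample(60)
    expect_identical(classification_metrics(confusion(s[p], y[p])), ref)
  }
})

test_that("ROC/PR areas match the concordance oracle and boundary cases", {
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_pr(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), y)$AUC, 1)
  expect_equal(roc_pr(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), y)$AUPR, 1)

  s6 <- c(0.9, 0.4, 0.7, 0.7, 0.2, 0.5)
  expect_equal(roc_pr(s6, y)$AUC, concordance_auc(s6, y), tolerance = 1e-12)

  set.seed(9)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    s <- round(runif(n), 2)                 # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_pr(s, y)$AUC, concordance_auc(s, y), tolerance = 1e-12)
  }

  set.seed(10)
  s <- runif(4000); y <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_pr(s, y)$AUC - 0.5), 0.05)
  expect_error(roc_pr(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC areas agree with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- runif(150); y <- rbinom(150, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_pr(s, y)$AUC, ref, tolerance = 1e-10)
})

test_that("stratified folds balance both classes to within one member", {
  y <- c(rep(1, 23), rep(0, 19))
  folds <- mhesmmr:::stratified_folds(y, 5, seed = 3)
  for (cls in 0:1) {
    sizes <- table(folds[y == cls])
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("cross-validation reports coherent per-fold and mean metrics", {
  cfg <- synthetic_config(n_sm = 16, n_mirna = 12, n_edges_per_relation = 60,
                          seed = 5)
  study <- generate_study(cfg)
  fps <- study$fingerprints
  sim_sm <- similarity_matrix(fps$sm_fps)
  attrs <- c(lapply(fps$sm_blocks, function(b) as.numeric(1:4 == b)),
             lapply(fps$mirna_blocks, function(b) as.numeric(1:4 == b)))
  negs <- sample_negatives(study$edges, sim_sm, "up", seed = 4,
                           mirna_ids = fps$mirna$mirna_id)
  pos <- study$edges[study$edges$relation == "up", ]
  rep <- cross_validate(pos, negs, attrs, "up", k = 3, seed = 2,
                        gatne = list(d = 8, s = 4, a = 2, epochs = 2,
                                     walks_per_vertex = 4),
                        classifier_params = list(nrounds = 40))
  expect_equal(nrow(rep$folds), 3L)
  expect_true(all(rep$folds$Acc >= 0 & rep$folds$Acc <= 1))
  expect_true(all(rep$folds$MCC >= -1 & rep$folds$MCC <= 1))
  expect_equal(rep$mean[["Acc"]], mean(rep$folds$Acc), tolerance = 1e-12)
  expect_equal(rep$mean[["AUC"]], mean(rep$folds$AUC), tolerance = 1e-12)
  for (metric in colnames(rep$folds)) {
    expect_gte(rep$mean[[metric]], min(rep$folds[[metric]]))
    expect_lte(rep$mean[[metric]], max(rep$folds[[metric]]))
  }
})

test_that("candidate ranking is descending with lexicographic tie-breaks", {
  set.seed(12)
  emb <- matrix(rnorm(5 * 6), 5, 6,
                dimnames = list(c("sm:drug", paste0("mir:", c("a", "b", "c", "d"))), NULL))
  y <- c(1, 1, 0, 0, 1, 0)
  x <- matrix(rnorm(6 * 12), 6, 12)
  clf <- fit_classifier(list(features = x, label = y), "gbt",
                        params = list(nrounds = 10), seed = 1)
  ranked <- rank_candidates(clf, emb, "drug", c("c", "a", "d", "b"))
  expect_equal(nrow(ranked), 4L)
  expect_true(all(diff(ranked$probability) <= 0))

  # identical embeddings force ties -> lexicographic order
  emb_tie <- emb
  for (m in c("mir:a", "mir:b", "mir:c", "mir:d")) emb_tie[m, ] <- emb["mir:a", ]
  tied <- rank_candidates(clf, emb_tie, "drug", c("c", "a", "d", "b"))
  expect_equal(tied$mirna_id, c("a", "b", "c", "d"))

  expect_equal(nrow(rank_candidates(clf, emb, "drug", c("a", "b", "c"), top_k = 2)), 2L)
  expect_error(rank_candidates(clf, emb, "drug", "zz"), "mir:zz")
})
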