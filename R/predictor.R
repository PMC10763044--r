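#' Pair feature table from node embeddings
#'
#' The feature vector of a (small molecule, miRNA) pair is the
#' concatenation of the miRNA embedding followed by the SM embedding
#' (order fixed for reproducibility), giving width `2 d`.
#'
#' @param emb Matrix of node embeddings for the modelled relation, with
#'   namespaced vertex ids as row names.
#' @param pairs A `regulation_edge_set` with a `label` column.
#' @return A `pair_feature_table`: list with `features` (matrix), `label`,
#'   and the pair ids.
#' @export
pair_features <- function(emb, pairs) {
  mv <- ns_mir(pairs$mirna_id)
  sv <- ns_sm(pairs$sm_id)
  missing <- setdiff(unique(c(mv, sv)), rownames(emb))
  if (length(missing)) stopf("no embedding for vertex/vertices: %s",
                             paste(head(missing, 10L), collapse = ", "))
  feats <- cbind(emb[mv, , drop = FALSE], emb[sv, , drop = FALSE])
  dimnames(feats) <- NULL
  structure(list(features = feats, label = as.integer(pairs$label),
                 sm_id = pairs$sm_id, mirna_id = pairs$mirna_id,
                 relation = pairs$relation),
            class = "pair_feature_table")
}

#' Fit the link classifier
#'
#' Default is a gradient-boosted decision-tree ensemble with histogram
#' binning and leaf-wise (best-first) growth; logistic regression, naive
#' Bayes, SVM and random forest are available as drop-in alternates behind
#' the same interface.
#'
#' @param table A `pair_feature_table` (or list with `features`/`label`).
#' @param classifier One of `"gbt"`, `"lr"`, `"nb"`, `"svm"`, `"rf"`.
#' @param params Named list of overrides; for `"gbt"`: `nrounds` (500),
#'   `max_leaves` (31), `eta` (0.05).
#' @param seed Integer seed.
#' @return An `mh_classifier` with a [predict()] method returning
#'   positive-class probabilities.
#' @export
fit_classifier <- function(table, classifier = c("gbt", "lr", "nb", "svm", "rf"),
                           params = list(), seed = 1L) {
  classifier <- match.arg(classifier)
  x <- table$features
  y <- as.integer(table$label)
  if (length(unique(y)) < 2L) stopf("need both classes to fit a classifier")
  fit <- switch(classifier,
    gbt = {
      p <- utils::modifyList(list(nrounds = 500, max_leaves = 31, eta = 0.05), params)
      dtr <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", tree_method = "hist",
                      grow_policy = "lossguide", max_depth = 0,
                      max_leaves = p$max_leaves, eta = p$eta,
                      nthread = 1, seed = as.integer(seed)),
        data = dtr, nrounds = p$nrounds, verbose = 0)
    },
    lr = {
      df <- data.frame(y = y, x)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    nb = {
      if (!requireNamespace("e1071", quietly = TRUE)) stopf("classifier 'nb' needs e1071")
      e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) stopf("classifier 'svm' needs e1071")
      with_seed(seed, e1071::svm(x, factor(y, levels = c(0, 1)), probability = TRUE))
    },
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE)) stopf("classifier 'rf' needs randomForest")
      with_seed(seed, randomForest::randomForest(x, factor(y, levels = c(0, 1))))
    })
  structure(list(kind = classifier, fit = fit, width = ncol(x)),
            class = "mh_classifier")
}

#' @param object An `mh_classifier`.
#' @param newdata Feature matrix of width `2 d`.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @rdname fit_classifier
#' @export
predict.mh_classifier <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$width) stopf("feature width %d != %d", ncol(newdata), object$width)
  switch(object$kind,
    gbt = predict(object$fit, xgboost::xgb.DMatrix(newdata)),
    lr = as.numeric(predict(object$fit, data.frame(newdata), type = "response")),
    nb = predict(object$fit, newdata, type = "raw")[, "1"],
    svm = attr(predict(object$fit, newdata, probability = TRUE), "probabilities")[, "1"],
    rf = predict(object$fit, newdata, type = "prob")[, "1"])
}

#' Confusion counts at a score threshold
#'
#' A pair is called positive when its score is greater than or equal to
#' `threshold` (ties count as positive calls).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary 0/1")
  call_pos <- scores >= threshold
  structure(list(TP = sum(call_pos & labels == 1),
                 FP = sum(call_pos & labels == 0),
                 TN = sum(!call_pos & labels == 0),
                 FN = sum(!call_pos & labels == 1)),
            class = "confusion_counts")
}

#' Threshold classification metrics
#'
#' Accuracy, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the
#' Matthews correlation coefficient; a zero denominator in MCC (or an
#' undefined rate) yields 0 by convention.
#'
#' @param counts A `confusion_counts` (or list with TP/FP/TN/FN).
#' @return Named numeric vector `Acc`, `Sen`, `Spec`, `MCC`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stopf("empty confusion counts")
  rate <- function(num, den) if (den > 0) num / den else 0
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  c(Acc = (TP + TN) / total,
    Sen = rate(TP, TP + FN),
    Spec = rate(TN, TN + FP),
    MCC = if (denom > 0) (TP * TN - FP * FN) / denom else 0)
}

#' ROC and precision-recall analysis
#'
#' Sweeps all score thresholds; the ROC area uses the trapezoidal rule
#' (equal to the tie-aware concordance probability) and the PR area uses
#' step-wise interpolation of precision over increasing recall.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return List with `AUC`, `AUPR`, `roc_points` (fpr, tpr) and
#'   `pr_points` (recall, precision).
#' @export
roc_pr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary 0/1")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stopf("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties: cumulative counts at each distinct threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  recall <- tp / npos
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(AUC = auc, AUPR = aupr,
       roc_points = data.frame(fpr = fpr, tpr = tpr),
       pr_points = data.frame(recall = recall, precision = precision))
}

# Stratified fold assignment: positives and negatives are split
# independently into k folds whose sizes differ by at most one.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Fivefold cross-validated evaluation of the full pipeline
#'
#' Stratified k-fold evaluation with leakage control: in every fold the
#' test-fold positive edges are removed from the multiplex graph before
#' walk generation, the GATNE embeddings are retrained on the remaining
#' edges, the classifier is fit on the training folds and scored on the
#' held-out fold.
#'
#' @param positives,negatives `regulation_edge_set`s for one relation
#'   (labels 1 and 0).
#' @param attributes Named list mapping raw ids to node-attribute vectors
#'   (e.g. from [line_attributes()]).
#' @param relation The modelled relation layer.
#' @param k Number of folds (default 5).
#' @param seed Integer seed driving fold assignment, model initialization
#'   and training.
#' @param mode `"full"` (attributes + GATNE), `"gatne_only"` (one-hot
#'   attributes), `"attrs_only"` (attribute concatenations fed directly to
#'   the classifier) or `"transductive"` (structure-only embeddings).
#' @param gatne Named list of GATNE hyperparameter overrides (`d`, `s`,
#'   `a`, `K`, `epochs`, `batch`, `lr`, `walk_length`, `walks_per_vertex`,
#'   `window`, `negatives`).
#' @param classifier,classifier_params Passed to [fit_classifier()].
#' @param shuffle_labels Permute the labels before evaluation (negative
#'   control; the signal should vanish).
#' @return A `cv_report`: per-fold and mean/sd Acc, Sen, Spec, MCC, AUC,
#'   AUPR plus per-fold ROC/PR curve points and test-fold scores.
#' @export
cross_validate <- function(positives, negatives, attributes, relation,
                           k = 5, seed = 1L,
                           mode = c("full", "gatne_only", "attrs_only", "transductive"),
                           gatne = list(), classifier = "gbt",
                           classifier_params = list(),
                           shuffle_labels = FALSE) {
  mode <- match.arg(mode)
  hp <- utils::modifyList(list(d = 128, s = 64, a = 20, K = 1, epochs = 10,
                               batch = 512, lr = 0.15, walk_length = 10,
                               walks_per_vertex = 20, window = 5, negatives = 5),
                          gatne)
  pairs <- rbind(as.data.frame(positives), as.data.frame(negatives))
  pairs <- pairs[pairs$relation == relation, , drop = FALSE]
  labels <- pairs$label
  if (shuffle_labels) labels <- with_seed(child_seed(seed, 99L), sample(labels))
  if (min(table(labels)) < k) stopf("fewer members than folds in one class")
  folds <- stratified_folds(labels, k, child_seed(seed, 1L))

  fold_metrics <- vector("list", k)
  curves <- vector("list", k)
  scores_out <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    train_pos <- pairs[!test & labels == 1, , drop = FALSE]
    if (!nrow(train_pos)) stopf("fold %d has no positive training edges", f)
    emb <- fold_embeddings(train_pos, pairs, attributes, relation, mode, hp,
                           child_seed(seed, 100L + f))
    feats <- pair_features(emb, transform(pairs, label = labels))
    clf <- fit_classifier(
      list(features = feats$features[!test, , drop = FALSE],
           label = labels[!test]),
      classifier = classifier, params = classifier_params,
      seed = child_seed(seed, 200L + f))
    sc <- predict(clf, feats$features[test, , drop = FALSE])
    if (length(unique(labels[test])) < 2L) stopf("fold %d has a single class", f)
    cm <- classification_metrics(confusion(sc, labels[test]))
    rp <- roc_pr(sc, labels[test])
    fold_metrics[[f]] <- c(cm, AUC = rp$AUC, AUPR = rp$AUPR)
    curves[[f]] <- rp[c("roc_points", "pr_points")]
    scores_out[[f]] <- data.frame(pairs[test, c("sm_id", "mirna_id")],
                                  label = labels[test], score = sc, fold = f)
  }
  tab <- do.call(rbind, fold_metrics)
  structure(list(relation = relation, mode = mode, k = k,
                 folds = as.data.frame(tab),
                 mean = colMeans(tab), sd = apply(tab, 2, stats::sd),
                 curves = curves, scores = do.call(rbind, scores_out),
                 shuffle_labels = shuffle_labels),
            class = "cv_report")
}

# Per-fold embedding construction for each ablation mode.
fold_embeddings <- function(train_pos, all_pairs, attributes, relation, mode,
                            hp, seed) {
  sm_ids <- unique(all_pairs$sm_id)
  mir_ids <- unique(all_pairs$mirna_id)
  if (mode == "attrs_only") {
    emb <- do.call(rbind, attributes[c(sm_ids, mir_ids)])
    rownames(emb) <- c(ns_sm(sm_ids), ns_mir(mir_ids))
    return(emb)
  }
  edges <- edge_set(train_pos$sm_id, train_pos$mirna_id, train_pos$relation)
  graph <- build_multiplex_graph(edges, attributes,
                                 sm_ids = sm_ids, mirna_ids = mir_ids)
  corpus_graph <- if (mode == "gatne_only") onehot_attributes(graph) else graph
  corpora <- lapply(names(graph$layers), function(r) {
    generate_walks(corpus_graph, r, walk_length = hp$walk_length,
                   walks_per_vertex = hp$walks_per_vertex,
                   seed = child_seed(seed, 3L))
  })
  fit <- switch(mode,
    full = train_gatne(graph, corpora, window = hp$window,
                       negatives = hp$negatives, epochs = hp$epochs,
                       batch = hp$batch, lr = hp$lr, seed = seed,
                       d = hp$d, s = hp$s, a = hp$a, K = hp$K),
    gatne_only = train_gatne(corpus_graph, corpora, window = hp$window,
                             negatives = hp$negatives, epochs = hp$epochs,
                             batch = hp$batch, lr = hp$lr, seed = seed,
                             d = hp$d, s = hp$s, a = hp$a, K = hp$K),
    transductive = transductive_embed(graph, corpora, d = hp$d, s = hp$s,
                                      a = hp$a, K = hp$K, window = hp$window,
                                      negatives = hp$negatives,
                                      epochs = hp$epochs, batch = hp$batch,
                                      lr = hp$lr, seed = seed))
  fit$embeddings[[relation]]
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold, relation '%s', mode '%s'%s\n", x$k,
              x$relation, x$mode, if (x$shuffle_labels) " (label-shuffled)" else ""))
  print(round(x$folds, 4))
  cat("mean:\n"); print(round(x$mean, 4))
  cat("sd:\n"); print(round(x$sd, 4))
  invisible(x)
}

#' Rank candidate miRNAs for a small molecule
#'
#' Scores every candidate pair with a trained classifier and orders the
#' candidates by decreasing predicted probability; exact ties are broken
#' lexicographically by miRNA id.
#'
#' @param clf A fitted `mh_classifier`.
#' @param emb Node-embedding matrix for the modelled relation.
#' @param sm_id Small-molecule id.
#' @param candidate_mirnas Character vector of candidate miRNA ids.
#' @param top_k Optional truncation of the ranking.
#' @return Data.frame `(mirna_id, probability)` in rank order.
#' @export
rank_candidates <- function(clf, emb, sm_id, candidate_mirnas, top_k = NULL) {
  pairs <- edge_set(rep(sm_id, length(candidate_mirnas)), candidate_mirnas,
                    rep("down", length(candidate_mirnas)), label = 0L)
  feats <- pair_features(emb, pairs)
  prob <- predict(clf, feats$features)
  out <- data.frame(mirna_id = candidate_mirnas, probability = prob,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$probability, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}
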