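#' Regulation-proximity score of an unlabelled pair
#'
#' The score of candidate pair `(sm, mirna)` is the arithmetic mean of the
#' Tanimoto coefficients between the candidate small molecule and every
#' small molecule already known to regulate that miRNA within the given
#' relation layer. A miRNA with no known regulator in the layer makes the
#' pair unscorable (`NA`).
#'
#' @param sm,mirna Ids of the candidate pair.
#' @param positives A `regulation_edge_set` of known positive pairs.
#' @param sim Small-molecule Tanimoto [similarity_matrix()].
#' @param relation Relation layer (`"up"` or `"down"`).
#' @return The mean-Tanimoto score in `[0, 1]`, or `NA_real_` if the miRNA
#'   has no known regulator in the layer.
#' @export
regulation_score <- function(sm, mirna, positives, sim, relation) {
  sub <- positives[positives$relation == relation, , drop = FALSE]
  if (any(sub$sm_id == sm & sub$mirna_id == mirna)) {
    stopf("(%s, %s) is a known positive in layer '%s'", sm, mirna, relation)
  }
  regs <- sub$sm_id[sub$mirna_id == mirna]
  if (!length(regs)) return(NA_real_)
  if (!sm %in% rownames(sim)) stopf("no similarity row for candidate %s", sm)
  mean(sim[sm, regs])
}

#' Eligible negative pool at a score threshold
#'
#' Enumerates every unlabelled (small molecule, miRNA) pair of a relation
#' layer whose regulation-proximity score is strictly below `threshold`.
#' Pairs whose miRNA has no known regulator in the layer are unscorable and
#' excluded.
#'
#' @inheritParams regulation_score
#' @param threshold Strict upper bound on the score (default 0.1).
#' @param mirna_ids miRNA universe; defaults to the miRNAs of the layer.
#' @return Data.frame `(sm_id, mirna_id, score)`, ordered by id.
#' @export
negative_pool <- function(positives, sim, relation, threshold = 0.1,
                          mirna_ids = NULL) {
  sub <- positives[positives$relation == relation, , drop = FALSE]
  sms <- rownames(sim)
  mirs <- sort(mirna_ids %||% unique(sub$mirna_id))
  reg_ind <- matrix(0, nrow = length(sms), ncol = length(mirs),
                    dimnames = list(sms, mirs))
  hit <- sub[sub$sm_id %in% sms & sub$mirna_id %in% mirs, , drop = FALSE]
  reg_ind[cbind(hit$sm_id, hit$mirna_id)] <- 1
  counts <- colSums(reg_ind)
  scores <- (sim[sms, sms, drop = FALSE] %*% reg_ind)
  scores <- sweep(scores, 2, ifelse(counts > 0, counts, NA), "/")

  eligible <- which(scores < threshold & reg_ind == 0, arr.ind = TRUE)
  out <- data.frame(sm_id = sms[eligible[, 1]], mirna_id = mirs[eligible[, 2]],
                    score = scores[eligible], stringsAsFactors = FALSE)
  out <- out[order(out$sm_id, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balanced negative sampling by regulation proximity
#'
#' Draws `n` negative pairs uniformly without replacement from the eligible
#' pool (score strictly below `threshold`, see [negative_pool()]), exactly
#' balancing the positives of the layer by default. The draw is
#' reproducible from `seed` and disjoint from the positives by
#' construction.
#'
#' @inheritParams negative_pool
#' @param n Number of negatives (default: number of positives in the layer).
#' @param seed Integer seed for the uniform draw.
#' @return A `regulation_edge_set` with `label = 0`.
#' @export
sample_negatives <- function(positives, sim, relation, threshold = 0.1,
                             n = NULL, seed = 1L, mirna_ids = NULL) {
  pool <- negative_pool(positives, sim, relation, threshold, mirna_ids)
  n <- n %||% sum(positives$relation == relation)
  if (nrow(pool) < n) {
    stopf("eligible pool has only %d pairs but %d negatives requested", nrow(pool), n)
  }
  pick <- with_seed(seed, sample.int(nrow(pool), n))
  out <- edge_set(pool$sm_id[pick], pool$mirna_id[pick],
                  rep(relation, n), label = 0L)
  msg_log(sprintf("sampled %d negatives for layer '%s' (pool %d, threshold %g, seed %d)",
                  n, relation, nrow(pool), threshold, as.integer(seed)))
  out
}
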