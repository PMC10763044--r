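# Shared fixtures and small numeric helpers. Everything is generated in
# code; expensive end-to-end results are memoised for the whole test run.

options(mhesmmr.verbose = FALSE)

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

logistic <- function(x) 1 / (1 + exp(-x))

# A small two-block bipartite study: block-aligned edges, 2-d attributes.
make_block_graph <- function(n_sm = 10, n_mir = 8, p_edge = 0.7, seed = 2) {
  set.seed(seed)
  sm <- sprintf("s%02d", seq_len(n_sm))
  mir <- sprintf("m%02d", seq_len(n_mir))
  blk_s <- rep(1:2, length.out = n_sm)
  blk_m <- rep(1:2, length.out = n_mir)
  rows <- list()
  for (i in seq_along(sm)) {
    for (j in seq_along(mir)) {
      if (blk_s[i] == blk_m[j] && runif(1) < p_edge) {
        rows[[length(rows) + 1L]] <- c(sm[i], mir[j])
      }
    }
  }
  ed <- do.call(rbind, rows)
  es <- edge_set(ed[, 1], ed[, 2], rep("up", nrow(ed)))
  attrs <- c(setNames(lapply(blk_s, function(b) c(b == 1, b == 2) + rnorm(2, 0, 0.1)), sm),
             setNames(lapply(blk_m, function(b) c(b == 1, b == 2) + rnorm(2, 0, 0.1)), mir))
  list(graph = build_multiplex_graph(es, attrs), edges = es, attrs = attrs,
       blk_s = setNames(blk_s, sm), blk_m = setNames(blk_m, mir))
}

# 6-vertex, 2-relation toy with random 3-d attributes (gradient checks).
make_two_relation_toy <- function(seed = 4) {
  set.seed(seed)
  es <- edge_set(c("s1", "s1", "s2", "s3", "s2", "s3"),
                 c("m1", "m2", "m2", "m3", "m3", "m1"),
                 c("up", "up", "up", "down", "down", "down"))
  attrs <- setNames(lapply(1:6, function(i) rnorm(3)),
                    c("s1", "s2", "s3", "m1", "m2", "m3"))
  list(graph = build_multiplex_graph(es, attrs), edges = es, attrs = attrs)
}

# Random fingerprint over `len` bits with `k` set bits.
rand_fp <- function(len = 30, k = 8) fingerprint(sample.int(len, k) - 1L, len)

# --- memoised end-to-end fixtures (the planted default study) -------------

.study_env <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.study_env$study)) {
    study <- generate_study(synthetic_config())
    fps <- study$fingerprints
    mir_fps <- lapply(fps$mirna$sequence, kmer_fingerprint, k = 4)
    names(mir_fps) <- fps$mirna$mirna_id
    sim_sm <- similarity_matrix(fps$sm_fps)
    sim_mir <- similarity_matrix(mir_fps)
    att_sm <- line_attributes(sim_sm, seed = 41)
    att_mir <- line_attributes(sim_mir, seed = 42)
    attrs <- c(mhesmmr:::split_rows(att_sm), mhesmmr:::split_rows(att_mir))
    negs <- sample_negatives(study$edges, sim_sm, "up", seed = 51,
                             mirna_ids = fps$mirna$mirna_id)
    .study_env$study <- list(
      study = study, sim_sm = sim_sm, sim_mir = sim_mir, attrs = attrs,
      negatives = negs,
      positives = study$edges[study$edges$relation == "up", , drop = FALSE])
  }
  .study_env$study
}

default_cv <- function(mode = "full", shuffle_labels = FALSE) {
  key <- paste0("cv_", mode, if (shuffle_labels) "_shuffled" else "")
  if (is.null(.study_env[[key]])) {
    st <- default_study()
    .study_env[[key]] <- cross_validate(st$positives, st$negatives, st$attrs,
                                        "up", k = 5, seed = 61, mode = mode,
                                        shuffle_labels = shuffle_labels)
  }
  .study_env[[key]]
}
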