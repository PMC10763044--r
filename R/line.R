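#' Weighted graph from a similarity matrix
#'
#' Creates the undirected weighted graph consumed by the LINE embedder: one
#' edge per pair `(i, j)`, `i < j`, with `S[i, j] > min_weight`; the
#' diagonal is discarded. The total weight `W` sums each undirected edge
#' once; the degree `d_i` sums the weights of all edges at `i`.
#'
#' @param sim Symmetric similarity matrix with ids as dimnames
#'   (see [similarity_matrix()]).
#' @param min_weight Edges with weight `<= min_weight` are dropped
#'   (default 0: keep all positive similarities).
#' @return A `weighted_graph`: list with `vertices`, `edges`
#'   (data.frame `i, j, w` of 1-based vertex indices), `W` and `degree`.
#' @export
build_similarity_graph <- function(sim, min_weight = 0) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  if (max(abs(sim - t(sim))) > 1e-12) stopf("similarity matrix is not symmetric")
  ids <- rownames(sim) %||% as.character(seq_len(nrow(sim)))
  keep <- which(upper.tri(sim) & sim > min_weight, arr.ind = TRUE)
  edges <- data.frame(i = keep[, 1], j = keep[, 2], w = sim[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  degree <- setNames(numeric(length(ids)), ids)
  for (col in c("i", "j")) {
    tab <- tapply(edges$w, edges[[col]], sum)
    degree[as.integer(names(tab))] <- degree[as.integer(names(tab))] + tab
  }
  isolated <- ids[degree == 0]
  if (length(isolated)) {
    warning(sprintf("%d isolated vertex/vertices will keep zero-information embeddings: %s",
                    length(isolated), paste(head(isolated, 5L), collapse = ", ")),
            call. = FALSE)
  }
  structure(list(vertices = ids, edges = edges, W = sum(edges$w), degree = degree),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d vertices, %d edges, total weight %.4f\n",
              length(x$vertices), nrow(x$edges), x$W))
  invisible(x)
}

#' First-order proximity probability
#'
#' The joint probability assigned by LINE to a directly connected vertex
#' pair: the sigmoid of the inner product of their embedding vectors. The
#' exponent is clipped at +/-30 to guard overflow.
#'
#' @param u_i,u_j Numeric embedding vectors of equal length.
#' @return A probability in `(0, 1)`.
#' @export
line_p1 <- function(u_i, u_j) {
  stopifnot(length(u_i) == length(u_j))
  sigmoid(sum(u_i * u_j))
}

#' Exact LINE objective (full softmax)
#'
#' Computes the first-order objective
#' `O1 = -sum_(i,j in E) w_ij log p1(v_i, v_j)` over undirected edges, or the
#' second-order objective `O2 = -sum w_ij log p2(v_j | v_i)` over both
#' directions of every edge, with `p2` the full softmax over context
#' vectors. This is the exact objective used as the reference for the
#' sampled optimizer in [train_line()].
#'
#' @param graph A `weighted_graph`.
#' @param emb Numeric matrix of vertex vectors (rows follow
#'   `graph$vertices`).
#' @param order 1 or 2.
#' @param ctx Context-vector matrix (required for `order = 2`).
#' @return The objective value (non-negative).
#' @export
line_objective <- function(graph, emb, order = 1, ctx = NULL) {
  if (!nrow(graph$edges)) stopf("graph has no edges")
  stopifnot(nrow(emb) == length(graph$vertices))
  e <- graph$edges
  if (order == 1) {
    p <- vapply(seq_len(nrow(e)), function(k) line_p1(emb[e$i[k], ], emb[e$j[k], ]),
                numeric(1))
    return(-sum(e$w * log(p)))
  }
  if (is.null(ctx)) stopf("order-2 objective needs context vectors")
  stopifnot(nrow(ctx) == nrow(emb))
  scores <- emb %*% t(ctx)                      # scores[i, k] = u_i . u'_k
  scores <- pmin(pmax(scores, -30), 30)
  logZ <- log(rowSums(exp(scores)))
  logp <- scores - logZ
  -sum(e$w * (logp[cbind(e$i, e$j)] + logp[cbind(e$j, e$i)]))
}

#' Train LINE embeddings by edge sampling with negative sampling
#'
#' The canonical LINE optimizer: edges are drawn with probability
#' proportional to their weight (alias method), each draw triggers one
#' stochastic-gradient update of the sampled pair plus `negatives` noise
#' vertices drawn from the weighted-degree distribution raised to 3/4.
#' Vectors are initialized uniformly in `[-0.5/dim, 0.5/dim]` and the
#' learning rate decays linearly from `lr`. Fully deterministic given
#' `seed`; for `order = 2` the vertex (not context) vectors are returned.
#' Isolated vertices receive the zero vector.
#'
#' @param graph A `weighted_graph`.
#' @param dim Embedding dimension (>= 2).
#' @param order 1 or 2.
#' @param epochs Passes over the (directed) edge multiset; one epoch draws
#'   one sample per directed edge. `epochs = 0` returns the initialization.
#' @param negatives Noise samples per positive (default 5).
#' @param lr Initial learning rate (default 0.025).
#' @param seed Integer seed.
#' @return Numeric matrix (vertices x `dim`) with vertex ids as row names.
#' @export
train_line <- function(graph, dim, order = 1, epochs = 50, negatives = 5,
                       lr = 0.025, seed = 1L) {
  stopifnot(dim >= 2, order %in% c(1, 2))
  n <- length(graph$vertices)
  fit <- cpp_line_train(
    src = graph$edges$i - 1L, dst = graph$edges$j - 1L, w = graph$edges$w,
    n = n, dim = as.integer(dim), order = as.integer(order),
    epochs = as.integer(epochs), negatives = as.integer(negatives),
    lr0 = lr, seed = as.integer(seed))
  emb <- fit$emb
  if (any(!is.finite(emb))) stopf("non-finite LINE embedding values; training aborted")
  emb[graph$degree == 0, ] <- 0
  rownames(emb) <- graph$vertices
  emb
}

#' Concatenate first- and second-order LINE embeddings
#'
#' Per-vertex concatenation with the first-order block first, the original
#' LINE convention; the result is splittable back at `ncol(e1)`.
#'
#' @param e1,e2 Embedding matrices over identical vertex sets (row names).
#' @return Matrix of width `ncol(e1) + ncol(e2)`.
#' @export
combine_orders <- function(e1, e2) {
  d <- union(setdiff(rownames(e1), rownames(e2)), setdiff(rownames(e2), rownames(e1)))
  if (length(d)) stopf("vertex sets differ: %s", paste(d, collapse = ", "))
  cbind(e1, e2[rownames(e1), , drop = FALSE])
}

#' Node-attribute vectors from a self-similarity network
#'
#' Convenience wrapper running [train_line()] at both proximity orders on a
#' Tanimoto self-similarity network and concatenating the results; the
#' combined vectors serve as GATNE node attributes.
#'
#' @param sim Similarity matrix.
#' @param dim1,dim2 Per-order dimensions (defaults 64 + 64, i.e. combined
#'   width 128).
#' @param epochs,negatives,lr Passed to [train_line()].
#' @param seed Integer seed; the two orders use derived sub-seeds.
#' @param min_weight Passed to [build_similarity_graph()].
#' @return Matrix of width `dim1 + dim2` with raw ids as row names.
#' @export
line_attributes <- function(sim, dim1 = 64, dim2 = 64, epochs = 50,
                            negatives = 5, lr = 0.025, seed = 1L,
                            min_weight = 0) {
  g <- build_similarity_graph(sim, min_weight)
  e1 <- train_line(g, dim1, order = 1, epochs = epochs, negatives = negatives,
                   lr = lr, seed = child_seed(seed, 1L))
  e2 <- train_line(g, dim2, order = 2, epochs = epochs, negatives = negatives,
                   lr = lr, seed = child_seed(seed, 2L))
  combine_orders(e1, e2)
}
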