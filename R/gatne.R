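GATNE_TYPES <- c("SM", "miRNA")

#' Initialize a GATNE model
#'
#' Creates the trainable parameter set for inductive GATNE over a
#' multiplex graph: per-type base transforms `h_z` (linear, no bias),
#' per-(type, relation) edge transforms `g_{z,r}`, per-relation attention
#' parameters `w_r`, `W_r`, projections `M_r`, per-type attribute
#' projections `D_z`, and per-vertex context embeddings. Weights use
#' Xavier-style uniform initialization, seeded.
#'
#' @param graph A `multiplex_graph` with attributes.
#' @param d Overall embedding dimension (default 128).
#' @param s Edge-embedding dimension (default 64).
#' @param a Attention hidden size (default 20).
#' @param alpha,beta Per-relation weights of the edge-embedding and
#'   attribute terms (recycled over relations; defaults 1).
#' @param K Aggregation depth (default 1).
#' @param seed Integer seed.
#' @return A `gatne_model` object.
#' @export
gatne_model <- function(graph, d = 128, s = 64, a = 20, alpha = 1, beta = 1,
                        K = 1, seed = 1L) {
  relations <- names(graph$layers)
  m <- length(relations)
  n <- nrow(graph$vertices)
  p <- vapply(GATNE_TYPES, function(ty) {
    v <- graph$vertices$vertex[graph$vertices$type == ty]
    if (!length(v)) 0L else length(graph$attributes[[v[[1]]]])
  }, integer(1))
  xavier <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  model <- with_seed(seed, {
    list(
      H = lapply(p, function(pz) xavier(d, pz)),
      G = setNames(lapply(relations, function(r) lapply(p, function(pz) xavier(s, pz))),
                   relations),
      w = setNames(lapply(relations, function(r) xavier(a, 1)[, 1]), relations),
      W = setNames(lapply(relations, function(r) xavier(a, s)), relations),
      M = setNames(lapply(relations, function(r) xavier(s, d)), relations),
      D = lapply(p, function(pz) xavier(pz, d)),
      alpha = setNames(rep_len(alpha, m), relations),
      beta = setNames(rep_len(beta, m), relations),
      ctx = matrix(runif(d * n, -0.5 / d, 0.5 / d), d, n,
                   dimnames = list(NULL, graph$vertices$vertex))
    )
  })
  model$d <- d; model$s <- s; model$a <- a; model$K <- K
  model$relations <- relations
  model$types <- GATNE_TYPES
  class(model) <- "gatne_model"
  model
}

#' @export
print.gatne_model <- function(x, ...) {
  cat(sprintf("gatne_model: d=%d s=%d a=%d K=%d, relations: %s\n",
              x$d, x$s, x$a, x$K, paste(x$relations, collapse = ", ")))
  invisible(x)
}

# Dense tensors consumed by the C++ core: per-type attribute matrices
# (p_z x n, zero columns off-type) and per-(relation, type) K-hop
# aggregated attribute matrices. Mean aggregation commutes with the linear
# edge transforms, so aggregation is folded into the attributes once.
gatne_tensors <- function(graph, model) {
  verts <- graph$vertices$vertex
  n <- length(verts)
  types0 <- match(graph$vertices$type, model$types) - 1L
  X <- lapply(seq_along(model$types), function(zi) {
    ty <- model$types[[zi]]
    pz <- nrow(model$D[[zi]])
    out <- matrix(0, pz, n)
    sel <- which(graph$vertices$type == ty)
    for (i in sel) out[, i] <- graph$attributes[[verts[[i]]]]
    out
  })
  Xagg <- lapply(model$relations, function(r) {
    A <- matrix(0, n, n, dimnames = list(verts, verts))
    layer <- graph$layers[[r]]
    ii <- match(layer$from, verts); jj <- match(layer$to, verts)
    A[cbind(ii, jj)] <- 1; A[cbind(jj, ii)] <- 1
    rs <- rowSums(A)
    Amean <- A / ifelse(rs > 0, rs, 1)
    iso <- which(rs == 0)
    Amean[cbind(iso, iso)] <- 1        # neighborless vertex keeps itself
    P <- diag(n)
    for (k in seq_len(model$K)) P <- Amean %*% P
    lapply(X, function(Xz) Xz %*% t(P))
  })
  names(Xagg) <- model$relations
  list(X = X, Xagg = Xagg, types0 = types0, vertices = verts)
}

#' Base embedding of a vertex
#'
#' `b_i = h_z(x_i)`: the shared (relation-independent) linear transform of
#' the vertex's attribute vector for its node type.
#'
#' @param model A `gatne_model`.
#' @param x Attribute vector.
#' @param type Node type (`"SM"` or `"miRNA"`).
#' @return Numeric vector of length `d`.
#' @export
base_embedding <- function(model, x, type) {
  z <- match(type, model$types)
  H <- model$H[[z]]
  if (length(x) != ncol(H)) stopf("attribute dim %d != transform input dim %d",
                                  length(x), ncol(H))
  drop(H %*% x)
}

#' K-hop mean-aggregated edge embedding
#'
#' Starts from `u^(0) = g_{z,r}(x_i)` and applies `K` rounds of mean
#' aggregation over the vertex's neighbourhood in the relation layer; a
#' vertex with no neighbours keeps its previous-level vector.
#'
#' @param graph A `multiplex_graph`.
#' @param model A `gatne_model`.
#' @param vertex Namespaced vertex id.
#' @param relation Relation layer.
#' @param K Aggregation depth (default: the model's `K`).
#' @return Numeric vector of length `s`.
#' @export
aggregate_edge_embedding <- function(graph, model, vertex, relation, K = NULL) {
  K <- K %||% model$K
  if (K < 0) stopf("K must be >= 0")
  verts <- graph$vertices$vertex
  types <- graph$vertices$type
  u <- lapply(seq_along(verts), function(i) {
    z <- match(types[[i]], model$types)
    drop(model$G[[relation]][[z]] %*% graph$attributes[[verts[[i]]]])
  })
  names(u) <- verts
  for (k in seq_len(K)) {
    u <- lapply(verts, function(v) {
      nb <- neighbors_of(graph, v, relation)
      if (!length(nb)) u[[v]] else rowMeans(do.call(cbind, u[nb]))
    })
    names(u) <- verts
  }
  u[[vertex]]
}

#' Self-attention coefficients over relation-wise edge embeddings
#'
#' `c_{i,r} = softmax(w_r^T tanh(W_r U_i))^T`: positive weights over the
#' `m` relation columns of `U_i`, summing to one.
#'
#' @param model A `gatne_model`.
#' @param U `s x m` matrix of per-relation aggregated edge embeddings.
#' @param relation Target relation (selects `w_r`, `W_r`).
#' @return Numeric vector of length `m` summing to 1.
#' @export
attention_coefficients <- function(model, U, relation) {
  if (ncol(U) != length(model$relations)) {
    stopf("U has %d columns but the model has %d relations", ncol(U),
          length(model$relations))
  }
  y <- drop(model$w[[relation]] %*% tanh(model$W[[relation]] %*% U))
  e <- exp(y - max(y))
  e / sum(e)
}

#' GATNE node embedding for one vertex and relation
#'
#' The full composition
#' `v_{i,r} = b_i + alpha_r M_r^T U_i c_{i,r} + beta_r D_z^T x_i`.
#'
#' @inheritParams aggregate_edge_embedding
#' @return Numeric vector of length `d`.
#' @export
node_embedding <- function(model, graph, vertex, relation) {
  type <- graph$vertices$type[graph$vertices$vertex == vertex]
  if (!length(type)) stopf("unknown vertex '%s'", vertex)
  z <- match(type, model$types)
  x <- graph$attributes[[vertex]]
  U <- do.call(cbind, lapply(model$relations, function(t) {
    aggregate_edge_embedding(graph, model, vertex, t)
  }))
  cc <- attention_coefficients(model, U, relation)
  b <- base_embedding(model, x, type)
  b + model$alpha[[relation]] * drop(t(model$M[[relation]]) %*% (U %*% cc)) +
    model$beta[[relation]] * drop(t(model$D[[z]]) %*% x)
}

#' Meta-path random walks over one relation layer
#'
#' Walks follow the alternating node-type scheme of the bipartite layer
#' (e.g. SM to miRNA to SM ...), starting from every vertex that has at
#' least one neighbour; the successor is drawn uniformly from the
#' neighbours of the expected next type and the walk truncates early when
#' that set is empty. Deterministic given `seed`.
#'
#' @param graph A `multiplex_graph`.
#' @param relation Relation layer to walk.
#' @param walk_length Vertices per walk (default 10).
#' @param walks_per_vertex Walks started at each eligible vertex
#'   (default 20).
#' @param seed Integer seed.
#' @return A `walk_corpus`: list of walks (character vectors of namespaced
#'   vertex ids) plus the walk settings.
#' @export
generate_walks <- function(graph, relation, walk_length = 10,
                           walks_per_vertex = 20, seed = 1L) {
  verts <- graph$vertices$vertex
  types <- setNames(graph$vertices$type, verts)
  eligible <- verts[vapply(verts, function(v) length(neighbors_of(graph, v, relation)) > 0,
                           logical(1))]
  flip <- c(SM = "miRNA", miRNA = "SM")
  walks <- with_seed(seed, {
    out <- vector("list", length(eligible) * walks_per_vertex)
    k <- 0L
    for (start in eligible) {
      for (w in seq_len(walks_per_vertex)) {
        walk <- character(walk_length)
        walk[1] <- start
        want <- flip[[types[[start]]]]
        len <- 1L
        for (stp in seq_len(walk_length - 1L)) {
          nb <- neighbors_of(graph, walk[len], relation)
          nb <- nb[types[nb] == want]
          if (!length(nb)) break
          walk[len + 1L] <- nb[[sample.int(length(nb), 1L)]]
          len <- len + 1L
          want <- flip[[want]]
        }
        k <- k + 1L
        out[[k]] <- walk[seq_len(len)]
      }
    }
    out[seq_len(k)]
  })
  structure(list(walks = walks, relation = relation, walk_length = walk_length,
                 walks_per_vertex = walks_per_vertex, seed = as.integer(seed)),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("walk_corpus: %d walks on layer '%s' (length %d)\n",
              length(x$walks), x$relation, x$walk_length))
  invisible(x)
}

# (center, context) skip-gram pairs within a symmetric window.
skipgram_pairs <- function(corpus, window = 5) {
  centers <- character(0); contexts <- character(0)
  for (walk in corpus$walks) {
    n <- length(walk)
    if (n < 2L) next
    for (c0 in seq_len(n)) {
      lo <- max(1L, c0 - window); hi <- min(n, c0 + window)
      off <- setdiff(lo:hi, c0)
      centers <- c(centers, rep(walk[[c0]], length(off)))
      contexts <- c(contexts, walk[off])
    }
  }
  data.frame(center = centers, context = contexts,
             relation = rep(corpus$relation, length(centers)),
             stringsAsFactors = FALSE)
}

#' Train GATNE embeddings by skip-gram with negative sampling
#'
#' Minimizes the skip-gram negative-sampling objective
#' `E = -log sigma(c_j' v_{i,r}) - sum_l E[log sigma(-c_k' v_{i,r})]`
#' over the (center, context) pairs of the walk corpora by seeded
#' mini-batch stochastic gradient descent; negatives are drawn from the
#' per-type unigram distribution of the corpus raised to 3/4, restricted to
#' the center vertex's type. With `epochs = 0` the returned embeddings are
#' the initialization-based node embeddings.
#'
#' @param graph A `multiplex_graph`.
#' @param corpora A `walk_corpus` or list of them (one per relation).
#' @param model A `gatne_model` (default: fresh model from `seed`).
#' @param window Skip-gram window size (default 5).
#' @param negatives Negative samples per pair (default 5).
#' @param epochs Passes over the pair set (default 10).
#' @param batch Mini-batch size (default 512).
#' @param lr Learning rate (default 0.15).
#' @param seed Integer seed (used for a fresh model and for training).
#' @param ... Passed to [gatne_model()] when `model` is NULL.
#' @return List with `embeddings` (named list per relation of vertex-by-`d`
#'   matrices), the trained `model`, and `epoch_loss`.
#' @export
train_gatne <- function(graph, corpora, model = NULL, window = 5,
                        negatives = 5, epochs = 10, batch = 512, lr = 0.15,
                        seed = 1L, ...) {
  if (inherits(corpora, "walk_corpus")) corpora <- list(corpora)
  model <- model %||% gatne_model(graph, seed = child_seed(seed, 11L), ...)
  tens <- gatne_tensors(graph, model)
  verts <- tens$vertices
  pairs <- do.call(rbind, lapply(corpora, skipgram_pairs, window = window))
  if (is.null(pairs) || !nrow(pairs)) stopf("walk corpora produced no training pairs")

  counts <- table(factor(c(pairs$center, pairs$context), levels = verts))
  noise_w <- lapply(model$types, function(ty) {
    w <- as.numeric(counts)^0.75
    w[graph$vertices$type != ty] <- 0
    if (all(w == 0)) w <- as.numeric(graph$vertices$type == ty)
    w
  })

  par0 <- model[c("H", "G", "w", "W", "M", "D", "alpha", "beta", "ctx")]
  par0$G <- lapply(par0$G, unname)
  if (epochs > 0) {
    fit <- cpp_gatne_train(
      model = par0, X = tens$X, Xagg = unname(tens$Xagg), types = tens$types0,
      centers = match(pairs$center, verts) - 1L,
      contexts = match(pairs$context, verts) - 1L,
      rels = match(pairs$relation, model$relations) - 1L,
      noise_w = noise_w, epochs = as.integer(epochs), batch = as.integer(batch),
      L = as.integer(negatives), lr = lr, seed = as.integer(child_seed(seed, 12L)))
    for (nm in c("H", "G", "w", "W", "M", "D", "ctx")) model[[nm]] <- fit[[nm]]
    names(model$G) <- model$relations
    for (nm in c("w", "W", "M")) names(model[[nm]]) <- model$relations
    colnames(model$ctx) <- verts
    epoch_loss <- fit$epoch_loss
  } else {
    epoch_loss <- numeric(0)
  }

  embeddings <- gatne_embeddings(model, graph, tensors = tens)
  list(embeddings = embeddings, model = model, epoch_loss = epoch_loss)
}

#' Node embeddings for every vertex and relation
#'
#' @param model A (trained) `gatne_model`.
#' @param graph The multiplex graph.
#' @param tensors Internal precomputed tensors (optional).
#' @return Named list per relation of vertex-by-`d` matrices.
#' @export
gatne_embeddings <- function(model, graph, tensors = NULL) {
  tens <- tensors %||% gatne_tensors(graph, model)
  par <- model[c("H", "G", "w", "W", "M", "D", "alpha", "beta", "ctx")]
  par$G <- lapply(par$G, unname)
  out <- lapply(seq_along(model$relations), function(r) {
    V <- cpp_gatne_forward(par, tens$X, unname(tens$Xagg), tens$types0,
                           r - 1L, seq_along(tens$vertices) - 1L)
    V <- t(V)
    rownames(V) <- tens$vertices
    V
  })
  names(out) <- model$relations
  out
}

# One-hot (standard basis) attribute assignment: vertex i of n gets e_i.
onehot_attributes <- function(graph) {
  verts <- graph$vertices$vertex
  n <- length(verts)
  attrs <- lapply(seq_len(n), function(i) { x <- numeric(n); x[i] <- 1; x })
  names(attrs) <- verts
  g <- graph
  g$attributes <- attrs
  g
}

#' Transductive GATNE embedding
#'
#' Structure-only variant: per-vertex free base and edge embeddings replace
#' the attribute transforms, so the result is independent of the attribute
#' vectors by construction. Implemented as inductive GATNE over standard
#' basis (one-hot) attributes with the attribute term switched off
#' (`beta_r = 0`), which makes `h_z` and `g_{z,r}` per-vertex free
#' parameters.
#'
#' @inheritParams train_gatne
#' @param d,s,a,K,alpha Model dimensions, see [gatne_model()].
#' @return As [train_gatne()].
#' @export
transductive_embed <- function(graph, corpora, d = 128, s = 64, a = 20,
                               alpha = 1, K = 1, window = 5, negatives = 5,
                               epochs = 10, batch = 512, lr = 0.15, seed = 1L) {
  g1 <- onehot_attributes(graph)
  model <- gatne_model(g1, d = d, s = s, a = a, alpha = alpha, beta = 0,
                       K = K, seed = child_seed(seed, 11L))
  train_gatne(g1, corpora, model = model, window = window,
              negatives = negatives, epochs = epochs, batch = batch,
              lr = lr, seed = seed)
}
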