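# Independent recursive oracle for K-hop mean aggregation.
brute_aggregate <- function(graph, model, vertex, relation, K) {
  rec <- function(v, k) {
    if (k == 0) {
      z <- match(graph$vertices$type[graph$vertices$vertex == v], model$types)
      return(drop(model$G[[relation]][[z]] %*% graph$attributes[[v]]))
    }
    nb <- neighbors_of(graph, v, relation)
    if (!length(nb)) return(rec(v, k - 1))
    rowMeans(vapply(nb, function(u) rec(u, k - 1), numeric(model$s)))
  }
  rec(vertex, K)
}

test_that("the base embedding is the per-type linear attribute transform", {
  toy <- make_two_relation_toy()
  model <- gatne_model(toy$graph, d = 3, s = 4, a = 2, seed = 1)
  model$H[[1]] <- diag(3)
  expect_equal(base_embedding(model, c(1, 0, 0), "SM"), c(1, 0, 0))
  expect_equal(base_embedding(model, c(0, 0, 0), "miRNA"), rep(0, 3))
  x <- c(0.3, -1, 2)
  expect_equal(base_embedding(model, 2 * x, "miRNA"),
               2 * base_embedding(model, x, "miRNA"))
  expect_error(base_embedding(model, 1:5, "SM"), "dim")
})

test_that("edge-embedding aggregation follows the recursive mean", {
  toy <- make_two_relation_toy()
  model <- gatne_model(toy$graph, d = 5, s = 4, a = 2, seed = 2)

  # K = 0: the raw transform
  z <- match("SM", model$types)
  expect_equal(aggregate_edge_embedding(toy$graph, model, "sm:s1", "up", K = 0),
               drop(model$G[["up"]][[z]] %*% toy$attrs$s1))

  # star layer: all leaves share one attribute vector -> center mean equals it
  es <- edge_set(rep("hub", 4), paste0("m", 1:4), rep("up", 4))
  attrs <- c(list(hub = c(1, 2)), setNames(rep(list(c(3, -1)), 4), paste0("m", 1:4)))
  star <- build_multiplex_graph(es, attrs)
  ms <- gatne_model(star, d = 4, s = 3, a = 2, seed = 3)
  zl <- match("miRNA", ms$types)
  expect_equal(aggregate_edge_embedding(star, ms, "sm:hub", "up", K = 1),
               drop(ms$G[["up"]][[zl]] %*% c(3, -1)))

  # random layer, K = 2, against the brute-force recursion
  for (v in c("sm:s1", "sm:s2", "mir:m3")) {
    for (r in c("up", "down")) {
      expect_equal(aggregate_edge_embedding(toy$graph, model, v, r, K = 2),
                   brute_aggregate(toy$graph, model, v, r, 2), tolerance = 1e-10)
    }
  }
  expect_error(aggregate_edge_embedding(toy$graph, model, "sm:s1", "up", K = -1), "K")
})

test_that("attention coefficients are a softmax over relation columns", {
  toy <- make_two_relation_toy()
  model <- gatne_model(toy$graph, d = 4, s = 3, a = 2, seed = 4)

  U <- matrix(rep(c(1, -2, 0.5), 2), ncol = 2)   # identical columns
  expect_equal(attention_coefficients(model, U, "up"), rep(0.5, 2))

  # single relation -> coefficient 1
  single <- build_multiplex_graph(edge_set("s1", "m1", "up"),
                                  list(s1 = 1, m1 = 2))
  m1 <- gatne_model(single, d = 2, s = 2, a = 2, seed = 5)
  expect_equal(attention_coefficients(m1, matrix(rnorm(2), 2, 1), "up"), 1)

  # crafted logits (ln 2, 0) -> (2/3, 1/3)
  crafted <- list(relations = c("r1", "r2"),
                  w = list(r1 = 1, r2 = 1),
                  W = list(r1 = matrix(1), r2 = matrix(1)))
  U <- matrix(c(atanh(log(2)), 0), nrow = 1)
  expect_equal(attention_coefficients(crafted, U, "r1"), c(2 / 3, 1 / 3),
               tolerance = 1e-12)

  expect_error(attention_coefficients(model, matrix(0, 3, 3), "up"), "relations")
})

test_that("the node embedding composes base, edge and attribute terms", {
  toy <- make_two_relation_toy()
  model <- gatne_model(toy$graph, d = 5, s = 4, a = 3, seed = 6)

  m0 <- model; m0$alpha[] <- 0; m0$beta[] <- 0
  expect_equal(node_embedding(m0, toy$graph, "sm:s1", "up"),
               base_embedding(m0, toy$attrs$s1, "SM"))

  ma <- model; ma$alpha[] <- 0
  expect_equal(node_embedding(ma, toy$graph, "mir:m2", "down"),
               base_embedding(ma, toy$attrs$m2, "miRNA") +
                 ma$beta[["down"]] * drop(t(ma$D[[2]]) %*% toy$attrs$m2))

  # full expression, term by term with independent pieces
  v <- "sm:s2"; r <- "up"; x <- toy$attrs$s2
  U <- cbind(brute_aggregate(toy$graph, model, v, "down", model$K),
             brute_aggregate(toy$graph, model, v, "up", model$K))
  y <- drop(model$w[[r]] %*% tanh(model$W[[r]] %*% U))
  cc <- exp(y - max(y)) / sum(exp(y - max(y)))
  manual <- drop(model$H[[1]] %*% x) +
    model$alpha[[r]] * drop(t(model$M[[r]]) %*% (U %*% cc)) +
    model$beta[[r]] * drop(t(model$D[[1]]) %*% x)
  expect_equal(node_embedding(model, toy$graph, v, r), manual, tolerance = 1e-12)
})

test_that("the R forward pass and the C++ forward pass agree exactly", {
  toy <- make_two_relation_toy()
  model <- gatne_model(toy$graph, d = 6, s = 4, a = 3, seed = 7)
  embs <- gatne_embeddings(model, toy$graph)
  for (v in toy$graph$vertices$vertex) {
    for (r in c("up", "down")) {
      expect_equal(unname(embs[[r]][v, ]), node_embedding(model, toy$graph, v, r),
                   tolerance = 1e-12)
    }
  }
})

test_that("meta-path walks are legal and uniform over valid successors", {
  bg <- make_block_graph()
  corp <- generate_walks(bg$graph, "up", walk_length = 6, walks_per_vertex = 30,
                         seed = 11)
  types <- setNames(bg$graph$vertices$type, bg$graph$vertices$vertex)
  for (walk in corp$walks) {
    if (length(walk) < 2) next
    for (t in seq_len(length(walk) - 1)) {
      expect_true(walk[t + 1] %in% neighbors_of(bg$graph, walk[t], "up"))
      expect_true(types[[walk[t]]] != types[[walk[t + 1]]])
    }
  }

  # Monte-Carlo transition law at a degree-2 vertex
  es <- edge_set(c("s1", "s1", "s2", "s2"), c("m1", "m2", "m1", "m2"),
                 rep("up", 4))
  attrs <- list(s1 = 1, s2 = 2, m1 = 3, m2 = 4)
  g <- build_multiplex_graph(es, attrs)
  corp <- generate_walks(g, "up", walk_length = 2, walks_per_vertex = 2500, seed = 13)
  succ <- vapply(Filter(function(w) w[1] == "sm:s1", corp$walks), `[`, character(1), 2L)
  n <- length(succ)
  expect_equal(n, 2500L)
  se <- sqrt(0.25 * n)
  expect_lt(abs(sum(succ == "mir:m1") - n / 2), 4 * se)

  expect_identical(corp, generate_walks(g, "up", walk_length = 2,
                                        walks_per_vertex = 2500, seed = 13))
})

test_that("walks truncate when no successor of the expected type exists", {
  es <- edge_set("s1", "m1", "up")
  g <- build_multiplex_graph(es, list(s1 = 1, m1 = 2))
  # remove m1's neighbour list to force truncation at step 2 is not possible;
  # instead walk length 5 on a single edge just bounces s1 <-> m1
  corp <- generate_walks(g, "up", walk_length = 5, walks_per_vertex = 2, seed = 1)
  expect_true(all(vapply(corp$walks, length, integer(1)) == 5L))
  expect_true(all(vapply(corp$walks, function(w) all(w %in% c("sm:s1", "mir:m1")),
                         logical(1))))
})

test_that("the skip-gram sample loss has the closed form at zero scores", {
  toy <- make_two_relation_toy()
  model <- gatne_model(toy$graph, d = 4, s = 3, a = 2, seed = 8)
  model$ctx[] <- 0
  tens <- mhesmmr:::gatne_tensors(toy$graph, model)
  par <- model[c("H", "G", "w", "W", "M", "D", "alpha", "beta", "ctx")]
  par$G <- lapply(par$G, unname)
  res <- mhesmmr:::cpp_gatne_pair_grad(par, tens$X, unname(tens$Xagg), tens$types0,
                                       0L, 0L, 3L, 4L)
  expect_equal(res$loss, 2 * 0.693147, tolerance = 1e-6)
})

test_that("zero training epochs return the initialization embeddings", {
  toy <- make_two_relation_toy()
  model <- gatne_model(toy$graph, d = 4, s = 3, a = 2, seed = 9)
  corp <- generate_walks(toy$graph, "up", walk_length = 4, walks_per_vertex = 3,
                         seed = 2)
  fit <- train_gatne(toy$graph, corp, model = model, epochs = 0)
  expect_equal(fit$embeddings, gatne_embeddings(model, toy$graph))
  expect_equal(unname(fit$embeddings$up["sm:s1", ]),
               node_embedding(model, toy$graph, "sm:s1", "up"))
})

test_that("training recovers planted block structure deterministically", {
  bg <- make_block_graph()
  corp <- generate_walks(bg$graph, "up", seed = 5)
  fit <- train_gatne(bg$graph, corp, d = 16, s = 8, a = 4, epochs = 8, seed = 9)
  expect_true(all(diff(fit$epoch_loss) < 0))
  emb <- fit$embeddings$up
  sm <- paste0("sm:", names(bg$blk_s))
  within <- mean(c(cosine(emb[sm[1], ], emb[sm[3], ]),
                   cosine(emb[sm[2], ], emb[sm[4], ])))
  between <- mean(c(cosine(emb[sm[1], ], emb[sm[2], ]),
                    cosine(emb[sm[3], ], emb[sm[6], ])))
  expect_gt(within, between)

  fit2 <- train_gatne(bg$graph, corp, d = 16, s = 8, a = 4, epochs = 8, seed = 9)
  expect_identical(fit$embeddings, fit2$embeddings)
})

test_that("transductive embeddings ignore attributes by construction", {
  bg <- make_block_graph()
  corp <- generate_walks(bg$graph, "up", seed = 5)
  g_other <- bg$graph
  g_other$attributes <- lapply(g_other$attributes, function(x) rev(x) + 100)
  fit_a <- transductive_embed(bg$graph, corp, d = 12, s = 6, a = 3, epochs = 4, seed = 3)
  fit_b <- transductive_embed(g_other, corp, d = 12, s = 6, a = 3, epochs = 4, seed = 3)
  expect_identical(fit_a$embeddings, fit_b$embeddings)

  init <- transductive_embed(bg$graph, corp, d = 12, s = 6, a = 3, epochs = 0, seed = 3)
  expect_false(identical(init$embeddings, fit_a$embeddings))

  emb <- fit_a$embeddings$up
  sm <- paste0("sm:", names(bg$blk_s))
  within <- cosine(emb[sm[1], ], emb[sm[3], ])
  between <- cosine(emb[sm[1], ], emb[sm[2], ])
  expect_gt(within, between)
})
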