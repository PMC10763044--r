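# Independent brute-force objectives, written as explicit loops.
brute_o1 <- function(graph, emb) {
  total <- 0
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]
    p <- 1 / (1 + exp(-sum(emb[i, ] * emb[j, ])))
    total <- total - graph$edges$w[k] * log(p)
  }
  total
}

brute_o2 <- function(graph, emb, ctx) {
  n <- nrow(emb)
  total <- 0
  directed <- rbind(graph$edges, data.frame(i = graph$edges$j, j = graph$edges$i,
                                            w = graph$edges$w))
  for (k in seq_len(nrow(directed))) {
    i <- directed$i[k]; j <- directed$j[k]
    scores <- vapply(seq_len(n), function(v) sum(ctx[v, ] * emb[i, ]), numeric(1))
    p <- exp(scores[j]) / sum(exp(scores))
    total <- total - directed$w[k] * log(p)
  }
  total
}

rand_graph <- function(n = 5, seed) {
  set.seed(seed)
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("v", seq_len(n))
  build_similarity_graph(S, min_weight = 0.2)
}

test_that("similarity graphs keep supra-threshold edges and drop the diagonal", {
  S <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  g <- build_similarity_graph(S)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$W, 3)
  expect_equal(unname(g$degree), rep(2, 3))

  expect_warning(g0 <- build_similarity_graph(diag(3)), "isolated")
  expect_equal(nrow(g0$edges), 0L)

  set.seed(9)
  S <- matrix(runif(36), 6, 6); S <- (S + t(S)) / 2; diag(S) <- 1
  g <- build_similarity_graph(S, min_weight = 0.5)
  manual <- sum(S[upper.tri(S)] > 0.5)
  expect_equal(nrow(g$edges), manual)
  expect_true(all(g$edges$w > 0.5))
})

test_that("first-order proximity is the clipped sigmoid of the inner product", {
  expect_equal(line_p1(rep(0, 4), rep(0, 4)), 0.5)
  expect_equal(line_p1(1e6, 1e6), 1)            # clipped limit
  u <- c(sqrt(log(3)), 0); v <- c(sqrt(log(3)), 0)
  expect_equal(line_p1(u, v), 0.75)
})

test_that("exact objectives match closed forms and the brute-force oracle", {
  S <- matrix(c(1, 0.999, 0.999, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  S[1, 2] <- S[2, 1] <- 1  # unit-weight single edge
  g <- build_similarity_graph(S)
  z <- matrix(0, 2, 3)
  expect_equal(line_objective(g, z, order = 1), -log(0.5), tolerance = 1e-12)

  # 4 vertices, one undirected edge (= two directed), all-zero vectors:
  # each conditional is the uniform softmax 1/4
  S4 <- diag(4); S4[1, 2] <- S4[2, 1] <- 1
  rownames(S4) <- colnames(S4) <- paste0("v", 1:4)
  suppressWarnings(g4 <- build_similarity_graph(S4))
  z4 <- matrix(0, 4, 3)
  expect_equal(line_objective(g4, z4, order = 2, ctx = z4), 2 * 1.386294,
               tolerance = 1e-6)

  for (seed in 1:5) {
    g <- rand_graph(5, seed)
    emb <- matrix(rnorm(5 * 4), 5, 4)
    ctx <- matrix(rnorm(5 * 4), 5, 4)
    expect_equal(line_objective(g, emb, order = 1), brute_o1(g, emb), tolerance = 1e-10)
    expect_equal(line_objective(g, emb, order = 2, ctx = ctx), brute_o2(g, emb, ctx),
                 tolerance = 1e-10)
  }
})

test_that("full-softmax conditionals sum to one for every source vertex", {
  set.seed(12)
  emb <- matrix(rnorm(24), 6, 4); ctx <- matrix(rnorm(24), 6, 4)
  scores <- emb %*% t(ctx)
  p2 <- exp(scores) / rowSums(exp(scores))
  expect_equal(rowSums(p2), rep(1, 6), tolerance = 1e-12)
})

test_that("training lowers the exact objective and separates cliques", {
  S <- matrix(0.01, 10, 10); S[1:5, 1:5] <- 1; S[6:10, 6:10] <- 1; diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("v", 1:10)
  g <- build_similarity_graph(S, min_weight = 0.5)

  e0 <- train_line(g, dim = 8, order = 1, epochs = 0, seed = 3)
  e1 <- train_line(g, dim = 8, order = 1, epochs = 30, seed = 3)
  expect_lt(line_objective(g, e1, 1), line_objective(g, e0, 1))

  intra <- mean(c(cosine(e1[1, ], e1[2, ]), cosine(e1[6, ], e1[7, ])))
  inter <- mean(c(cosine(e1[1, ], e1[6, ]), cosine(e1[2, ], e1[9, ])))
  expect_gt(intra, inter)

  expect_identical(e1, train_line(g, dim = 8, order = 1, epochs = 30, seed = 3))
  expect_false(identical(e1, train_line(g, dim = 8, order = 1, epochs = 30, seed = 4)))
})

test_that("vertices with identical similarity profiles embed nearby", {
  set.seed(31)
  S <- matrix(runif(64, 0.1, 0.9), 8, 8); S <- (S + t(S)) / 2; diag(S) <- 1
  S[2, ] <- S[1, ]; S[, 2] <- S[, 1]; S[1, 2] <- S[2, 1] <- 1; diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("v", 1:8)
  g <- build_similarity_graph(S)
  # identical profiles mean identical context distributions: second-order
  # proximity is the notion that makes such vertices embed together
  emb <- train_line(g, dim = 16, order = 2, epochs = 60, seed = 8)
  expect_gte(cosine(emb[1, ], emb[2, ]), 0.9)
})

test_that("negative-sampling gradients match central differences", {
  set.seed(41)
  u_c <- rnorm(6); u_pos <- rnorm(6); u_neg <- matrix(rnorm(18), 6, 3)
  ana <- mhesmmr:::cpp_line_pair_grad(u_c, u_pos, u_neg)

  # independent R loss for the same sample
  loss_r <- function(uc, up, un) {
    s <- function(x) 1 / (1 + exp(-x))
    -log(s(sum(uc * up))) - sum(log(s(-colSums(uc * un))))
  }
  expect_equal(ana$loss, loss_r(u_c, u_pos, u_neg), tolerance = 1e-10)

  h <- 1e-6
  num <- function(f) vapply(seq_along(u_c), function(i) {
    e <- numeric(length(u_c)); e[i] <- h
    (f(e) - f(-e)) / (2 * h)
  }, numeric(1))
  g_c <- num(function(e) loss_r(u_c + e, u_pos, u_neg))
  g_p <- num(function(e) loss_r(u_c, u_pos + e, u_neg))
  expect_lt(max(abs(g_c - ana$g_center)) / max(abs(g_c)), 1e-4)
  expect_lt(max(abs(g_p - ana$g_pos)) / max(abs(g_p)), 1e-4)
  for (l in 1:3) {
    g_n <- num(function(e) { un <- u_neg; un[, l] <- un[, l] + e; loss_r(u_c, u_pos, un) })
    expect_lt(max(abs(g_n - ana$g_neg[, l])) / max(abs(ana$g_neg[, l])), 1e-4)
  }
})

test_that("alias sampling reproduces edge weights within four standard errors", {
  w <- c(0.5, 1, 2, 4, 0.1, 1.4)
  n <- 100000
  counts <- mhesmmr:::cpp_alias_draw_counts(w, n, seed = 13)
  p <- w / sum(w)
  se <- sqrt(p * (1 - p) * n)
  expect_true(all(abs(counts - n * p) <= 4 * se))
})

test_that("order concatenation is order-1-first and validates vertex sets", {
  e1 <- matrix(1, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  e2 <- matrix(2, 3, 4, dimnames = list(c("c", "a", "b"), NULL))
  comb <- combine_orders(e1, e2)
  expect_equal(ncol(comb), 8L)
  expect_equal(unname(comb["a", 1:4]), rep(1, 4))   # order-1 block first
  expect_equal(unname(comb["a", 5:8]), rep(2, 4))
  e3 <- matrix(0, 2, 2, dimnames = list(c("a", "x"), NULL))
  expect_error(combine_orders(e1, e3), "x")
})
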