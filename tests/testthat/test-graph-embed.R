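test_that("graphs are built from positive contacts with sorted adjacency", {
  g <- toy_graph()
  expect_s3_class(g, "chrom_graph")
  expect_equal(g$n_nodes, 5)
  expect_equal(nrow(g$edges), 5)
  expect_true(all(g$edges$u < g$edges$v))
  expect_equal(g$adj[[2]], c(1L, 3L, 4L))
  expect_equal(g$w_adj[[2]], c(2, 1, 0.5))
  expect_false(any(g$isolated))
  ## the diagonal never creates self-edges
  m <- diag(c(5, 5)) + matrix(1, 2, 2)
  g2 <- build_graph(m)
  expect_equal(nrow(g2$edges), 1)
})

test_that("asymmetric and negative inputs are symmetrized and floored", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- 4            # asymmetric: (4 + 0)/2 = 2
  m[1, 3] <- -2; m[3, 1] <- -2  # negative: floored, no edge
  g <- build_graph(m)
  expect_equal(g$edges$weight, 2)
  expect_equal(g$edges$u, 1L)
  expect_equal(g$edges$v, 2L)
  expect_true(g$isolated[3])
})

test_that("min_weight and top_k sparsify as documented", {
  sim <- small_sim()
  g_all <- build_graph(sim$matrix)
  g_thr <- build_graph(sim$matrix, min_weight = 2)
  expect_lt(nrow(g_thr$edges), nrow(g_all$edges))
  expect_true(all(g_thr$edges$weight > 2))
  g_top <- build_graph(sim$matrix, top_k = 5)
  deg_in_top <- table(factor(c(g_top$edges$u, g_top$edges$v), levels = 1:120))
  ## union rule: a node keeps at most k own picks plus others' picks of it
  expect_lt(nrow(g_top$edges), nrow(g_all$edges))
  expect_true(all(deg_in_top >= 1))
})

test_that("the second-order transition rule reweights by p and q", {
  g <- toy_graph()
  ## first step: proportional to edge weight
  pr <- walk_transition_probs(g, NULL, 2)
  expect_equal(unname(pr), c(2, 1, 0.5) / 3.5)
  ## after moving 3 -> 2: node 1 is non-adjacent to 3 (1/q), 3 is the
  ## previous node (1/p), 4 is adjacent to 3 (1)
  pr2 <- walk_transition_probs(g, 3, 2, p = 4, q = 2)
  w <- c(2 * (1 / 2), 1 * (1 / 4), 0.5 * 1)
  expect_equal(unname(pr2), w / sum(w))
  expect_equal(sum(pr2), 1)
  expect_error(walk_transition_probs(g, 5, 2), "neighbor")
})

test_that("walks have the right shape, stay on edges and are seed-stable", {
  g <- toy_graph()
  walks <- generate_walks(g, walk_length = 20, num_walks = 4, seed = 3)
  expect_equal(dim(unclass(walks)), c(20L, 20L))  # 5 starts x 4 walks
  expect_equal(sort(unique(walks[, 1])), 1:5)
  expect_true(all(walks %in% 1:5))
  ## every consecutive pair is an edge of the graph
  ek <- paste(g$edges$u, g$edges$v)
  for (r in 1:4) {
    steps <- cbind(walks[r, -20], walks[r, -1])
    key <- paste(pmin(steps[, 1], steps[, 2]), pmax(steps[, 1], steps[, 2]))
    expect_true(all(key %in% ek))
  }
  expect_identical(generate_walks(g, 20, 4, seed = 3), walks)
  expect_false(identical(generate_walks(g, 20, 4, seed = 4), walks))
})

test_that("compiled biased walks follow the reference transition law", {
  g <- toy_graph()
  p <- 0.5; q <- 2
  walks <- generate_walks(g, walk_length = 3, num_walks = 4000, p = p, q = q,
                          seed = 9)
  ## condition on the move 3 -> 2 and compare third-step frequencies with
  ## the R reference implementation of the second-order rule
  sel <- walks[, 1] == 3 & walks[, 2] == 2
  expect_gt(sum(sel), 300)
  emp <- table(factor(walks[sel, 3], levels = 1:5)) / sum(sel)
  ref <- walk_transition_probs(g, 3, 2, p = p, q = q)
  expect_lt(max(abs(as.numeric(emp[names(ref)]) - unname(ref))), 0.05)
})

test_that("skip-gram embeddings are deterministic and zero for absent nodes", {
  sim <- small_sim()
  g <- build_graph(sim$matrix)
  walks <- generate_walks(g, walk_length = 30, num_walks = 2, seed = 5)
  e1 <- train_skipgram(walks, d = 16, epochs = 1, seed = 5)
  e2 <- train_skipgram(walks, d = 16, epochs = 1, seed = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(120L, 16L))
  expect_false(identical(train_skipgram(walks, d = 16, epochs = 1, seed = 6),
                         e1))
  ## a node absent from the corpus gets the zero vector
  trimmed <- structure(unclass(walks), n_nodes = 121L,
                       class = "walk_corpus")
  e3 <- train_skipgram(trimmed, d = 8, epochs = 1, seed = 1)
  expect_equal(e3[121, ], rep(0, 8))
})

test_that("embeddings place genomically interacting bins nearby", {
  sim <- small_sim()
  emb <- node2vec_embed(sim$matrix, d = 16, walk_length = 30, num_walks = 5,
                        epochs = 2, seed = 2)$embedding
  ## mean cosine similarity of adjacent bins beats that of random pairs
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  adj_sim <- mean(vapply(1:119, function(i) cosine(emb[i, ], emb[i + 1, ]),
                         numeric(1)))
  set.seed(1)
  far <- cbind(sample(120), sample(120))
  far <- far[abs(far[, 1] - far[, 2]) > 40, , drop = FALSE]
  far_sim <- mean(apply(far, 1, function(r) cosine(emb[r[1], ], emb[r[2], ])))
  expect_gt(adj_sim, far_sim)
})

test_that("embedding TSV round-trips in node order", {
  emb <- matrix(rnorm(40), 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(emb, path)
  expect_equal(read_embedding(path), emb, tolerance = 1e-12)
})
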